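# Synthetic TBP-like TATA-box count matrix (TATAWAWR), 8 positions.
# Hand-constructed stand-in for a curated TBP matrix; counts per 100 sites.
A	2	95	2	95	55	90	50	45
C	2	1	1	1	2	2	4	5
G	3	2	1	2	3	4	6	45
T	93	2	96	2	40	4	40	5
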