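# promoterTurnover

Evolutionary birth and death of promoters between two mammalian lineages.

Promoters — here the genomic spans of CAGE-defined TSS clusters — are born
and lost over evolutionary time. Between two focal species (e.g. human and
mouse), a promoter projected through whole-genome alignments can be
**aligned** in the other species, or fall in gapped/unmapped sequence.
Absence is ambiguous on its own: the sequence may have been **inserted** in
the focal lineage or **deleted** in the opposing one. The ambiguity is
resolved with outgroup species (dog, horse, cow, pig): sequence absent from
the opposing species *and* every outgroup is a lineage-specific insertion;
sequence retained by at least one outgroup but missing from the opposing
species was deleted there. Aligned promoters are further classified by the
expression at the projected locus: matched, divergent, diminished, or no
activity (expression turnover at conserved sequence).

This package is for comparative/regulatory genomicists who have promoter
intervals, precomputed dual-source alignment projections, a matched-tissue
expression panel, and population variant data, and want a tested,
reproducible implementation of the full downstream analysis. It provides:

- a **turnover classifier** combining two alignment sources (multiple
  alignment + pairwise) with outgroup presence calls; disagreements between
  sources leave a promoter unclassified rather than miscalled;
- **expression profiling**: RLE (median-of-ratios) normalization, replicate
  averaging, breadth (broad vs tissue-restricted, median TPM = 0) and
  tissue-bias calls (mean ≥ 5 × cross-tissue median for broad promoters,
  mean > 1 TPM for restricted ones), TATA-box scanning with exact PWM
  match *P*-values, CpG-island overlap;
- the **compensatory turnover statistic** per 1:1 orthologous gene,
  `T_c = Σt − |P_h − P_m|`, where `t` counts promoter gain/loss events
  (insertions, deletions, and complete expression loss) and `P_h`, `P_m`
  are expressed-promoter counts per species; a gene with `T_c > 0` has
  gains offset by losses (compensatory turnover);
- a **derived allele frequency (DAF) constraint test**: variants polarized
  against the ancestral allele, binned into rare (DAF < 1.5%) and nonrare
  (DAF > 5%), and compared with genome-wide reference counts by an exact
  (hypergeometric) test with odds ratio and 95% CI — an excess of rare
  derived alleles indicates purifying selection;
- **enrichment machinery**: mappability-aware, blacklist-avoiding interval
  permutation nulls; strand-oriented 50-bp-window profiles of per-base
  conservation scores; repeat-coverage enrichment around promoter anchors
  with 1000-resample bootstrap CIs; per-repeat-family overlap frequencies;
- a **synthetic two-lineage evolution simulator** that emits every input
  format (BED, bedGraph, alignment-status TSV, expression matrix + sample
  sheet, variant TSV/VCF, masks, ortholog tables) together with
  ground-truth labels, so the whole pipeline is testable end to end;
- a **pipeline driver** (`run_pipeline()`) with a machine-readable report
  and checksummed manifest, plus a thin CLI wrapper in
  `inst/scripts/ptk.R`.

## Worked example

```r
library(promoterTurnover)

ds <- simulate_dataset(sim_config(seed = 7))
cls <- classify_dataset(ds)
cls$lineage_table
#>       insertions deletions
#> human         66        54
#> mouse         41       196

bias <- deletion_bias_ratio(cls$lineage_table)
# fold = (del_mouse/ins_mouse) / (del_human/ins_human)
sprintf("deletion bias fold = %.2f (chi-square p = %.3g)", bias$fold, bias$p_value)
#> "deletion bias fold = 5.84 (chi-square p = 2.06e-13)"

ref <- expected_reference_counts(total = 2e6)
daf_test(ds$promoters$human, ds$variants, ref)
#> Derived allele frequency constraint test
#>   test set: 482 rare, 33 nonrare (n informative = 515)
#>   reference: 968872 rare, 731362 nonrare
#>   odds ratio = 11.026 [7.749, 15.688] (logit_normal CI), p = 3.8e-78
```

The lineage table counts de novo insertions per lineage and deletions in
the opposing lineage; the fold is the deletion:insertion ratio of the
second lineage over the first (this simulated draw, with a 3.5× deletion
rate on the mouse-like lineage and small event counts, lands at 5.8 —
single runs scatter around the configured rate ratio). The DAF odds ratio
far above 1 reflects the purifying regime the simulator applies to
promoter sequence: promoters carry a large excess of rare derived alleles
relative to the neutral genome-wide reference.

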