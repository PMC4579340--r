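---
title: "Methods: classifying promoter birth and death between lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying promoter birth and death between lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterTurnover)
```

This vignette documents the models, decision rules, parameters and
numerical choices behind the package, and what its synthetic data do and
do not establish about real data.

## The classification model

The unit of analysis is a promoter: the genomic span of a TSS cluster,
used as a proxy for the core promoter because core promoters lack a sharp
upstream boundary. Each promoter of a focal species is projected into the
opposing focal species and four outgroups through **two independent
alignment sources** — a whole-genome multiple alignment ("msa") and a
pairwise alignment ("pairwise"). Per source and target species the
projection outcome is ALIGNED (with target coordinates and an aligned
fraction), GAPPED, UNMAPPED, or MULTI (projected to multiple loci).

**Presence calls.** Per source, a projection counts as *present* when it
is ALIGNED with an aligned fraction at or above
`absence_max_aligned_fraction` (default 0.5); GAPPED/UNMAPPED, or a
sub-threshold ALIGNED, count as *absent*; a missing row is treated as
UNMAPPED. Combining sources: any MULTI gives PRESENT_MULTI; agreement
gives PRESENT_UNIQUE or ABSENT; disagreement gives CONFLICT. Using two
sources raises the confidence that an alignment gap is a genuine absence
rather than an alignment artefact; promoters where the sources disagree
are left unclassified rather than guessed.

**Sequence fate.** With presence calls for the opposing species and the
ordered outgroups (dog, horse, cow, pig — all diverged before the
human–mouse split):

- opposing ABSENT and **all** outgroups ABSENT → INSERTED in the focal
  lineage (the sequence was never in the common ancestor);
- opposing ABSENT and ≥ 1 outgroup PRESENT_UNIQUE → DELETED in the
  opposing lineage (the ancestor had it; the opposing lineage lost it);
- opposing PRESENT_UNIQUE → ALIGNED;
- any CONFLICT, an opposing PRESENT_MULTI, or deletion support resting
  only on multi-locus outgroup alignments → UNCLASSIFIED.

This is a parsimony argument on a known species tree; it assumes
independent loss events and cannot date events within a lineage.

**Expression outcome at aligned promoters.** The projected locus is mapped
to an opposing-species promoter by coordinate overlap (largest overlap
wins); a locus overlapping no promoter is silent sequence. Then:

- opposing max TPM ≤ `activity_floor_tpm` (default 0) → NO_ACTIVITY
  (expression turnover at conserved sequence);
- opposing max TPM < `diminished_ratio` × focal max TPM (default 0.1)
  → DIMINISHED;
- otherwise MATCHED when the biased-tissue sets are similar (Jaccard ≥
  `matched_min_jaccard`, default 0.5, or both empty), else DIVERGENT.

The alignment data name these categories; the numeric cutoffs are package
decisions, exposed in `classifier_config()` and recorded in the pipeline
report. Expression turnover is reported without a lineage assignment —
with two species one cannot tell which lineage changed.

## Expression profiling

Expression arrives as tags-per-million (TPM) over a matched panel of 52
cell/tissue samples per species (defaults mirror that design; the panel
size is configurable). Samples are RLE-normalized: the size factor of a
sample is the **median over features with positive geometric mean of the
ratio value/geometric-mean**. The median is taken in ratio space, exactly
as defined — at even feature counts this differs (harmlessly) from
log-space implementations; the test suite cross-checks against DESeq2 at
an odd feature count where both coincide. Replicates are then averaged,
and per-tissue means computed.

Breadth and bias follow fixed rules: a promoter is **tissue-restricted**
iff its median TPM across tissue types is 0 (tolerance 1e-9), else
**broad**. A broad promoter is biased toward a tissue when the tissue mean
is **at least** five times the cross-tissue median (the boundary is
inclusive by the rule's wording); a restricted promoter when its mean
there exceeds 1 TPM. The median includes the focal tissue: with ~52
tissues the difference from excluding it is negligible, and including it
keeps the rule symmetric across tissues. Tissue categories (testis,
immunity, brain, other) are carried on the sample sheet; a category is
biased iff one of its tissues is.

**TATA scanning** uses a position weight matrix over the window 20–30 nt
upstream of the promoter start, both strands. Match significance is the
exact probability of an equal-or-better score under an i.i.d. background
(default uniform, configurable), computed by exhaustive enumeration of all
4^w words — exact, reproducible, and cheap for motif widths ≤ 10. The
threshold is P ≤ 1e-3. A synthetic TBP-like count matrix (TATAWAWR, 8
positions) ships as `inst/extdata/tata_synthetic.pwm`; it is a
hand-constructed stand-in, not a curated database matrix, and users can
supply their own. CpG-promoter labelling is any-overlap (≥ 1 bp) with a
supplied CpG-island BED.

## Gene-level compensatory turnover

For each 1:1 orthologous gene pair, promoters with UNCLASSIFIED fate are
dropped, and:

- `P_h`, `P_m` — expressed promoters (max TPM > 0) assigned to the gene in
  each species;
- `t` — turnover events: INSERTED, DELETED_IN_OPPOSING, and NO_ACTIVITY
  promoters (complete expression loss counts; diminished expression does
  not);
- `T_c = t − |P_h − P_m|`, compensatory iff `T_c > 0`.

Each event changes the between-species promoter-count difference by at
most one, so `T_c ≥ 0` always (property-tested over 10^4 random
configurations). Events are counted once: an inserted, deleted, or
expression-lost promoter has a record in exactly one species. A promoter
present in one species but unassigned to the gene in the other counts
toward `t` and toward its own species' `P` only. Gene categories:
`conserved_architecture` (no events), `expression_turnover_only`,
`births_exceed_deaths` / `deaths_exceed_births` / `balanced` by comparing
insertion and deletion counts. Contingency enrichments (positive-selection
overlap, paralog status, tissue bias) run through one generic 2×2 engine:
fold of proportions, odds ratio, χ² without continuity correction,
switching to Fisher's exact test when any expected cell is below 5;
Benjamini–Hochberg FDR is reported alongside raw p-values for families of
tests.

## Derived allele frequency test

Variants are polarized against the ancestral allele: ancestral = ref maps
DAF to the alternate frequency, ancestral = alt complements it; unresolved
or mismatching ancestral states are discarded with a counter, as are
indels and multi-allelic records at parse time. DAFs bin into **rare
(< 1.5%)** and **nonrare (> 5%)** with the middle excluded; both bounds
are strict, so a value exactly at a bound is excluded (the bin wording
leaves the boundary ambiguous; strictness is the conservative reading and
is recorded in output metadata). The test-set rare:nonrare counts are
compared with fixed genome-wide reference counts by a two-sided exact
conditional (hypergeometric) test — the implementation sums the
probabilities of all equally-or-less-probable tables with the observed
margins, with the conventional 1e-7 relative tie tolerance, and is
verified against brute-force enumeration to 1e-12. The odds ratio is the
sample ratio of ratios; the 95% CI is the exact conditional interval up to
a table total of 10^4 and the logit-normal (Woolf) approximation above
(the method used is recorded). Reference counts are supplied as two
integers rather than recomputed from a whole-genome VCF: the genome-wide
ratio is a fixed quantity in this design and desk-scale runs should not
depend on a multi-gigabyte scan.

`calibrate_rare_threshold()` scans candidate rare bounds and picks the one
maximizing log-OR divided by its standard error (from the log-scale CI
width) — a scale-free operationalization of "maximize the odds ratio while
minimizing the confidence interval"; the full candidate table is always
returned so users can apply their own criterion, and a degenerate scan (no
CI excluding 1) returns the lowest candidate with a flag.

## Permutation nulls, profiles, bootstraps

Genome-wide expectations come from placing each interval,
length-preserved, uniformly at random over every valid start inside the
allowed regions (uniquely mappable minus blacklisted; optionally per
chromosome). Placement is rejection-free and permuted intervals may
overlap one another — the simple unbiased null. Score profiles average a
per-base track in fixed windows (default 50 bp over ±1000 bp) around the
promoter's 5′ boundary in transcription orientation, flipping for
minus-strand anchors; track gaps are excluded from means and windows with
no usable bases are reported missing. Note one discrete-grid subtlety: a
minus-strand anchor at base *a* covers bases *a+flank … a−flank+1*, the
mirror of a plus-strand anchor at *a+1* — the half-open convention makes
mirrors align base-for-base only with that one-base shift. Repeat
enrichment is base-pair coverage fraction per window (an explicit
operationalization of "repetitive element density"), compared against
either conserved promoters or permuted placements of the promoters
themselves, with a percentile bootstrap (default 1000 resamples) over the
promoter set; per-family frequencies (fraction of promoters with ≥ 1 bp
overlap per family) are reported as well. All samplers take explicit
seeds; one master seed derives per-operation substreams.

## The synthetic evolution simulator

The simulator defines the study conditions for every end-to-end test. It
works at the interval level (no nucleotide sequences — a stated non-goal):
an ancestral chromosome carries promoters in disjoint 3-kb slots (so
truth labels stay unambiguous and ±1-kb profiles never collide); two focal
lineages each draw Poisson numbers of whole-segment insertions and
whole-promoter deletions; aligned promoters can lose all expression in
one lineage or have it strongly diminished (×0.02, far below the 0.1
classification threshold). Defaults: 500 ancestral promoters on a 4-Mb
pseudo-chromosome, 50 expected insertions and deletions per lineage with
a 3.5× deletion multiplier on the second ("mouse-like") lineage —
matching the reported rodent deletion bias — 5% complete expression loss,
3% diminution, 0.3 independent per-outgroup loss of ancestral sequence
(so "present in ≥ 1 outgroup" is exercised non-trivially; a deletion's
support outgroup is forced to survive, otherwise the truth itself would
be an insertion), 60% of inserted segments repeat-derived against a 20%
genomic repeat background, 52 tissues × 3 replicates with log-normal
tissue architecture (40% restricted to 1–3 tissues), replicate noise 0.2
on the log scale and per-sample depth factors (sd 0.15) so RLE
normalization is non-trivial, conservation scores at mean +2 for
constrained promoters over a mean-0 background (mimicking
constraint-score semantics without computing them), and allele
frequencies from a 1/j neutral spectrum over 2000 sampled chromosomes,
down-weighted by exp(−0.01·j) under purifying selection and mirrored
under positive selection. Source-conflict and multi-mapping noise
(defaults 2% and 1%) apply to opposing-species projections of non-inserted
promoters, preserving the invariant that a truth-inserted promoter is
absent everywhere in both sources.

What the simulator does **not** emulate: nucleotide-level alignment error,
partial promoter deletions (whole-span only by default), correlated
outgroup loss along the tree, expression divergence between species beyond
loss/diminution (conserved promoters share their tissue architecture),
linked selection or demography in the frequency spectra, and repeat
families with realistic length/age distributions. Passing tests therefore
establish the correctness of the decision rules and statistics under
clean, label-known conditions — not the field accuracy of the thresholds
on real alignments, where conflict rates and aligned-fraction
distributions are data-dependent.

One known soft edge follows from RLE itself: size factors depend on the
species' promoter complement, so the two species' normalized tissue means
differ by slightly tissue-dependent factors. A conserved promoter with a
tissue sitting exactly at the 5×-median bias boundary can then flip its
bias call in one species and be labelled DIVERGENT rather than MATCHED
even with zero replicate noise (~1% of conserved promoters at the
defaults). Sequence fates are unaffected; the noise-free recovery
guarantee is therefore stated — and tested — for sequence fates (100%)
and for the expression outcomes with a wide decision margin (loss,
diminution), while conserved→MATCHED is asserted at > 95%.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere; `to_zero_based()` is the
  single conversion point for 1-based sources (VCF).
- Tissue-restriction uses a 1e-9 tolerance on the zero median; the 5×
  bias boundary is inclusive; the DAF bin bounds are strict.
- χ² tests are run without Yates correction (counts in the thousands;
  Fisher is available as a flag and switches in automatically for small
  expected cells).
- The exact-test tie tolerance (1e-7 relative) matches the conventional
  `fisher.test` behaviour so the two agree to numerical precision.
- Presence thresholds on `aligned_fraction` stand in for per-base gap
  arithmetic (the combination rule of the original alignment processing
  is not public); the threshold is exposed and its monotonicity is
  property-tested.
- Per-lineage event timing is not modelled: each lineage is a single
  branch with aggregate rates (the data cannot date events within a
  branch).
- Problem sizes in the tests (hundreds of promoters, 10^4–10^5 variant
  sites, 50–200 permutations) were chosen as the smallest sizes at which
  the sampling error of each check is comfortably below its assertion
  margin; the full acceptance pass (100 DAF replicates at 50,000 sites,
  50 permutation-null runs) completes in about two minutes on one core.

## Limitations

Real alignment-status tables must be produced upstream (MAF/EPO or
chain/net parsing is out of scope); CpG islands, conservation tracks,
repeat annotations and positive-selection gene lists are consumed as
given; GO enrichment and UTR analyses are not included. The classifier's
thresholds are deliberate, documented defaults — on real data they should
be examined with the exposed configuration, not taken as ground truth.
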