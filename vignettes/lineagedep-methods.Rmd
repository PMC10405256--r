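---
title: "Methods: lineage dependency, resistance and chromatin identity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage dependency, resistance and chromatin identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lineagedep)
```

# Scope and model

`lineagedep` implements a pan-cancer analysis of lineage fidelity in CRISPR
fitness screens, together with the chromatin-identity machinery used to
characterise the resistant state. The pipeline has two arms.

The **dependency arm** consumes a CERES gene-effect matrix (cell lines ×
genes; more negative = stronger fitness cost of knockout), a lineage
annotation per line, a TF list, and a mutation table. Its stages are LD
scoring, a three-filter cascade defining each lineage's core regulatory
circuitry (CRC), resistance classification, a permutation-FDR scan for
acquired dependencies, and Fisher-exact mutation contrasts.

The **chromatin arm** consumes narrowPeak calls, BED6 read intervals, a
gene model with differential-expression labels, and a binary regions ×
samples accessibility matrix. Its stages are consensus peak construction,
extended-read counting, differential-accessibility thresholding, windowed
accessibility–expression coupling, greedy correlation clustering, the
cluster-specific-region rule, and summit-window overlap enrichment.

All interval arithmetic is 0-based half-open (`width = end − start`),
matching the narrowPeak/BED formats the pipeline reads and writes, so no
coordinate shift happens at I/O. Strand is carried but ignored by overlap
logic except 5′-anchored read extension. Missing CERES values are excluded
pairwise from every mean and test, never imputed.

# Statistical details and assumptions

## LD scores and significance

`LD(t, x)` is the difference between the mean CERES of TF `t` inside
lineage `x` and its mean in the remaining *eligible* lineages. Lineages
with fewer than `min_lineage_size` (default 10) lines are removed before
scoring, so the out-group is the union of the other eligible lineages; this
keeps the mean decomposition over eligible lineages exactly conservative (a
property the tests assert).

Significance comes from the two-group Kruskal–Wallis test. Because the two
groups partition the same column, the column is ranked once and the
tie-corrected chi-square statistic (df = 1) is evaluated for every lineage
partition from group rank sums; this is algebraically identical to
`stats::kruskal.test` (the suite verifies agreement on tied data) but runs
the 1,600 TF × 25 lineage grid in seconds. A column with all values tied
has no evidence either way and is assigned p = 1; a partition with fewer
than two non-missing values on either side yields p = NA and a flag.

Benjamini–Hochberg adjustment is applied within each lineage's TF family
(~1,600 tests), because CRC sets are consumed per lineage; a `global` scope
switch is provided. Filter 1 uses the adjusted p by default, with a
`use_raw_p` switch, since the source text is ambiguous about which was
thresholded.

## The filter cascade

1. `ld_score < −1.2` and adjusted p `< 0.05`. The effect threshold
   dominates: under a pure-null cohort of the study's shape no TF passes
   (asserted over many seeds).
2. Strictly more than 50% of the lineage's lines (with a non-missing
   value for that TF — missing lines are excluded from the denominator)
   at CERES ≤ −0.5.
3. Pan-essential removal: median CERES across **all** cell lines (not only
   eligible lineages) ≤ −0.2 removes the TF.

Filters run in order; the trace records the first filter that removed each
candidate, and survival is the conjunction of the three conditions, which
makes the cascade monotone in every threshold (relaxing one never shrinks a
surviving set — a property test).

## Resistance and acquired dependencies

A line's `avg_ceres` is its mean CERES over its lineage's CRC TFs; values
above −0.45 label it resistant. The boundary is handled exactly: −0.44 is
resistant, −0.46 sensitive.

The acquired-dependency scan computes pooled-SD Cohen's D (resistant minus
sensitive) per gene, then shuffles labels `n_permutations` (default 1,000)
times preserving group sizes — within each lineage by default, since the
comparison is within-lineage; a pooled switch exists. The estimated FDR for
gene *i* divides the mean permuted count of effect sizes at least as
extreme as `|d_i|` by the observed count at least as extreme (the gene
counts itself, so the denominator is ≥ 1), capped at 1 for
interpretability.

The q-value is the minimum estimated FDR over all significance thresholds
that still call gene *i* — i.e. over genes with `|d| ≤ |d_i|` — which makes
q monotone non-increasing in `|d|` by construction, as the SAM-style
q-value convention requires. (Written in effect-size notation with the
inequality pointing the other way, the same formula would instead hand
every gene the FDR of the single most extreme gene; that reading is
rejected because it destroys the monotonicity the calls rely on.)
Significance is q < 0.1.

Numerical care: observed and permuted effect sizes go through the same
vectorised matrix products, and both groups are computed from their own
explicit indicator products rather than totals-minus-group, so exactly
symmetric assignments (identity, group swap) produce bitwise-equal `|d|`
and the ≥ comparisons count them correctly. `permutation_fdr()` also
accepts an explicit assignment matrix, which the tests use to compare
against full enumeration on tiny cohorts at 1e-12.

Degenerate inputs: zero pooled SD gives d = 0 when means agree and signed
infinity otherwise; a contingency table with a zero margin reports p = 1
and an undefined odds ratio.

## Consensus peaks and differential accessibility

Candidate windows are `[summit − 250, summit + 251)` (501 bp, odd width so
the summit is centred). Candidates are ranked by −log10(q) descending with
ties broken by (chromosome, summit) ascending — the ranking is total, so
the output is deterministic and independent of input order (asserted by
shuffling). Greedy acceptance keeps a candidate iff it overlaps (≥ 1 shared
base) no previously kept window; every dropped peak therefore overlaps a
kept peak of at least its significance. Windows that would start below
position 0 are dropped and counted by default (`clip = TRUE` preserves the
width rightward instead).

The −log10(q) ≥ 20 peak filter keeps highly significant peaks by default.
The source text literally reads as keeping *weak* peaks, which contradicts
its own description of high-confidence peak sets; both directions are
exposed and the keep-significant direction is the default because the
literal reading cannot be reconciled with the rest of the procedure.

Reads are set to 250 bp from their 5′ end in strand direction (minus-strand
reads extend leftward, clipped at 0; unstranded reads are treated as plus
with a warning) and counted into every peak they overlap. DA classes
require padj < 0.001 and `log2fc ≥ 1` (HA) or `≤ −1` (LA) at the default
fold-change 2. Matched controls are a uniform, seeded, without-replacement
sample of non-DA consensus peaks, defaulting to the DA set's size.

## Window coupling and enrichment

Windows `[center − h, center + h)` are anchored at region centres (the
summit for consensus-derived regions). A gene is captured when its TSS
falls in any window; capture is by TSS because the original tool's
convention is not recoverable, and a body-overlap strategy switch exists.
The window sizes are configuration (default 5 kb–1 Mb half-widths) since
no canonical list exists. Enrichment is the upper-tail hypergeometric
(`phyper`) of DE genes among captured universe genes; the universe is an
input column (`de_status != "not_expressed"`), not recomputed. Capture sets
are nested in `h` by construction, so counts are monotone.

## Profile clustering

Regions are ranked by binary variance `p(1 − p)` (ties by coordinate) and
the top `top_variable_regions` feed a Pearson correlation matrix between
samples (constant profiles get correlation 0 and a flag). The greedy pass
ranks remaining samples by their count of remaining partners with PCC >
0.6 (ties by sample id), seeds a cluster from the top sample plus everyone
correlated with the *seed* (an all-pairs variant is a switch, not the
default), and stops the whole loop at the first cluster smaller than 5 —
matching a procedure that halts when cluster size drops below the cutoff
rather than skipping seeds. The result is deterministic and invariant to
sample order.

A region is *present* in a cluster when open in ≥ 80% of its samples; the
same presence rule is reused for the "no more than two additional
clusters" condition, the stricter of the readings the source admits.
Overlap enrichment requires the ±25 bp summit window to be 100% contained
in a cluster region, and uses the consensus peak list as the hypergeometric
universe (the original universe is unstated; the consensus list is the
natural population from which the DA draw is made).

# The synthetic-data generators

The generators are first-class, tested code and define the study conditions
the acceptance checks run under.

`generate_dependency_bundle()` plants, on Gaussian background noise
(σ = 0.15): LD TFs shifted by δ = −1.5 in the sensitive lines of their
lineage; pan-essential decoys at mean −1.0 everywhere plus the LD shift in
one lineage (so they pass filter 1 and must be caught by filter 3);
resistant lines (default fraction 0.3, the rough shape of a 19/49
melanoma-like cohort) left at background for their lineage's LD TFs;
acquired-dependency genes shifted by −0.8 in resistant lines only; and
mutations at 0.47 vs 0.28 (the shape of the study's TP53 contrast).
Gaussian noise is a deliberate simplification: every downstream statistic
is rank- or mean-based, and σ = 0.15 keeps planted effects (|δ| ≥ 0.45)
separated at 10–20 lines per lineage. Note that with resistant lines
planted, the in-lineage mean is diluted to (1 − ρ)·δ, so recovery scenarios
for the filter cascade set ρ = 0, and classification scenarios average over
3 LD TFs per lineage so that group separation at the −0.45 cutoff is many
noise SDs wide; both choices are the stated conditions of those checks, not
tuning.

`generate_regulatory_bundle()` places peak summits on a jittered grid (so
base peaks never collide), draws −log10(q) from a log-normal (heavy-tailed,
positive), and appends a stated fraction of deliberately overlapping
partner peaks recorded in ground truth to exercise consensus de-overlap.
Reads scatter normally (SD 80 bp) around summits of open peaks. DE–DA
coupling multiplies a gene's odds of concordant differential expression
(down near LA, up near HA) by a factor (default 5) when its TSS is within
50 kb of a DA summit; odds 1 gives exact independence, the null for the
coupling test. Profiles are a shared open backbone (30% of regions) plus
per-cluster specific regions, with every bit flipped with probability ε
(default 0.02; the recovery checks use ε = 0 and ε = 0.05 as their stated
conditions). Binary open/closed profiles match SCREEN-style annotations.

What the generators do **not** emulate: genomic sequence composition,
copy-number artefacts in screens, overdispersed fragment counts,
peak-width variation, correlated noise between samples, or continuous
accessibility signal. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the planted model, not
end-to-end fidelity to any particular real release.

# Problem sizes

The test suite and `scripts/acceptance.R` run the dependency arm at the
study's shape (25 lineages × 20 lines × 1,600 TFs; 20 and 10 seeds for the
null control respectively), the permutation scan at 500 null genes × 1,000
permutations × 10 seeds plus 50 power replicates, the consensus oracle on
100 instances of 200 peaks with planted collisions, and clustering recovery
on 60 samples × 6 clusters × 50 seeds. These sizes make the whole suite
complete in a couple of minutes on one CPU while keeping every check at the
cohort shape it is about.

# Known limitations

- The differential-accessibility engine itself is out of scope: `call_da()`
  thresholds an externally supplied fold-change/padj table.
- Gene capture has no gene-body or nearest-gene model beyond the strategy
  switch; distance-decay coupling is not modelled.
- Cluster biological annotation is a user concern; clusters are reported
  as `cluster_1 … cluster_k` in emission order.
- The FDR estimator is the study's own; it is conservative under the null
  (the calibration check) but is not a proven FDR-controlling procedure.
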