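---
title: "Models and methods behind dynbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynbind)
```

# The biological problem

Under replication stress — classically, release of G1-arrested budding
yeast into hydroxyurea (HU), which depletes dNTPs and stalls replication
forks — the DNA replication checkpoint kinase localizes genome-wide: at
stalled forks near fired replication origins, and, less expectedly, at the
promoters of a large fraction of genes. `dynbind` implements the
computational side of this analysis: from binned ChIP-seq coverage to
promoter-binding calls, differential (dynamic) binding between cell-cycle
stages, replication-origin firing classes, replication–transcription
conflict orientation statistics, and the integration of binding changes
with expression changes.

All coordinates in the package are 0-based and half-open; tracks live on a
fixed 25-bp grid (`genome_layout()`), the resolution at which enrichment
is computed.

# Normalization

For a bin $i$ with IP count $x_i$, input count $y_i$, and genome-wide
totals $T_x$, $T_y$, the **simple normalization** is the reciprocally
scaled log-ratio

$$ f_i = \log_2 \frac{(x_i + c)\, T_y}{(y_i + c)\, T_x}, $$

with pseudocount $c$ (default 1) added to both bin counts, not to totals.
At $c = 0$ this is the raw reciprocal-scaling formula and is *exactly*
invariant to rescaling either library; any $c > 0$ bounds the ratio at
empty bins at the cost of making that invariance asymptotic (the deviation
vanishes as counts grow). Replicates are each normalized against their own
input and then averaged per bin (`average_replicates()`).

Ongoing DNA synthesis elevates ChIP background around active origins. The
**origin-aware normalization** therefore partitions the genome into
origin-proximal bins — any bin intersecting $[\mathrm{center} - r,
\mathrm{center} + r]$, default $r = 5000$ bp — and the complement, and
applies the simple normalization independently in each partition with
partition-restricted totals. A consequence worth remembering: absolute
levels are then not comparable across the two partitions. A partition with
zero counts in either sample raises an explicit error rather than
producing silent infinities.

# Promoter scoring and binding specificity

The promoter is the 500-bp window upstream of the TSS (strand-aware,
clipped and flagged at chromosome edges); for peak annotation it is
extended 50 bp downstream. A gene's activity score is the overlap-weighted
mean of the enrichment track over its window — equivalently, the sum of
per-25-bp-window fold changes scaled by the window size. Clipped windows
are normalized by the width actually covered so edge genes are not
penalized.

Empirical significance of promoter binding compares each observed score
against `n_null` windows of the same width placed uniformly at random on
the genome (positions at bp resolution, kept inside chromosomes), with the
one-sided upper-tail add-one estimator $p = (1 + \#\{s_{null} \ge s\}) /
(1 + n_{null})$. The null construction is the package's own choice; it is
the simplest null drawn from the same signal distribution. On
structureless noise tracks the resulting p-values are uniform (the test
suite checks this by a KS test over 500 genes); note that on a *constant*
track every p is exactly 1 by the tie convention, which is why calibration
is stated for noise, not constants.

Binding specificity across promoters is summarized by the Lorenz curve of
sorted per-gene signal and its Gini index, computed as one minus twice the
trapezoidal area under the curve. This equals half the relative mean
absolute difference, which the tests exploit as an independent oracle. A
sequence-specific factor concentrated on few promoters scores high; a
broadly binding kinase scores low.

# Residual differential binding

Overall promoter activity differs between timepoints for reasons unrelated
to any one gene — protein levels, IP efficiency, batch. The differential
binding (DB) procedure therefore fits ordinary least squares of the HU
scores on the G1 scores over *all* genes and ranks genes by the absolute
residual from that global trend. Directionality is the residual's sign.
Points fixed by design:

* the regression is of HU on G1 (G1 as predictor); residuals differ under
  reversal, so the direction is part of the contract;
* before ranking, each sample's scores are scaled to unit maximum and
  genes with a scaled score below −0.075 in *either* compared sample are
  excluded (conservative reading of the minimal-signal filter; the
  scaling is per sample);
* ranking ties at the selection boundary break lexicographically by gene
  id, so selections are deterministic;
* the top-K lists (K = 1000 by default) from two independent experiments
  are intersected, ordered by the worse of the two ranks, to give the
  reproducible DB set.

Group-level binding dynamics (e.g. for annotated targets of the SBF
transcription factor) are tested by standardizing residuals to Z-scores
and comparing the group against the rest with a two-sided Wilcoxon
rank-sum test — exact when the combined size is at most 30, normal
approximation with continuity correction otherwise.

# Origin typing from replication signal

Replication incorporation (EdU-type) tracks score each origin by the mean
signal over ±2.5 kb of its center — well inside the ~10-kb extent of DNA
synthesis under HU, wide enough to average bin noise; the window is
configurable. An origin is **early** if its wild-type signal at the first
stressed timepoint (HU45) exceeds 2 (it fires despite an intact
checkpoint); otherwise **late** if the mean of its later-timepoint (HU90)
signals across checkpoint-deficient mutants exceeds 2 (`late_rule =
"all"` instead requires every mutant individually); otherwise
**inactive**. Early plus late origins form the active set, and the three
classes partition the origin universe by construction. Replication timing
is attached from per-kb timing windows when the nearest window center is
within 5 kb (ties to the lower coordinate), and origins whose center falls
inside a blacklist interval (hyper-ChIPable regions) are dropped before
heatmap analyses.

# Gene–origin geometry and conflict orientation

Each gene is related to the origin with the smallest TSS-to-center
distance on its chromosome (point-to-point, ties to the lower coordinate),
with exclusive distance categories <1 kb, 1–2 kb, 2–5 kb, and "none"
(nothing within 5 kb). A replication fork arriving at the gene travels
away from the origin center; if transcription points back toward the
center the pair is head-on (HO), otherwise co-directional (CD). The search
universe includes all annotated origins by default with the class
recorded per relation; `active_only = TRUE` restricts it, since reasonable
analyses differ on whether never-firing origins belong in the universe.

Down-regulation bias among differentially expressed genes is tabulated per
distance category, origin class, and orientation, and two contrasts among
genes with an origin within 5 kb are tested by two-sided Fisher's exact
test: late-origin versus early-origin genes, and HO versus CD genes.

# Integration statistics

* `fisher_exact_2x2()` — exact hypergeometric test; the two-sided p sums
  all tables (given the margins) whose probability does not exceed the
  observed one, the classical convention; the odds ratio is the sample
  $ad/bc$ (possibly infinite), not the conditional MLE.
* `tf_enrichment()` — upper-tail Fisher for over-representation of a TF's
  target genes in a selection. The gene universe is an explicit,
  required parameter; it is never inferred from the inputs, because
  published universes for the same organism differ and the background
  frequency moves with it.
* `db_de_correlation()` / `db_de_association()` — Spearman correlation of
  DB residuals with expression log2 fold changes, and a 2×2 direction
  association with Fisher's test; zero margins are errors naming the
  margin.
* `naive_de()` — a deliberately simple DE surrogate: median-of-ratios
  size factors, per-condition means of normalized counts, $\log_2((m_B +
  1)/(m_A + 1))$, significance by |log2FC| threshold. It performs no
  dispersion modelling and no hypothesis test, is labelled as a surrogate
  in its output, and exists so the pipeline runs self-contained;
  externally computed DE tables are accepted as first-class input
  wherever its output is.

Raw p-values are reported throughout (rank selection, not FDR control, is
the DB procedure's mechanism; the integration tests report single
contrasts).

# The synthetic-data generator

The generator (`sim_config()`, `generate_annotation()`,
`simulate_chip_tracks()`, `simulate_edu_track()`, `simulate_rna_counts()`)
defines the study conditions under which every downstream claim is tested.

**Genome and annotation.** Chromosomes of equal length; genes and origins
are placed in regular slots with uniform jitter, which guarantees
non-overlap and puts a floor on spacing. Origin slots reserve a margin of
`fork_extent/2 + 1500` bp, so adjacent centers are at least 13 kb apart —
a fired origin's 10-kb fork plateau can then never reach a neighbour's
±2.5-kb scoring window, making noise-free origin typing exact by
construction. Strands are balanced. Origin classes are allocated in exact
fractions (largest remainder), default 0.31/0.32/0.37
early/late/inactive, matching the observed genome-wide proportions.

**Counts.** All count tracks are negative binomial with mean--dispersion
parameterization (variance $\mu + d\mu^2$, Poisson at $d = 0$; default $d
= 0.05$). IP means are uniform background (`depth` per bin, default 50)
plus a rectangular promoter peak over the 500-bp upstream window —
per-gene amplitude drawn once from $U(0.5, 3) \times$ depth — plus a
plateau of `fork_ip_factor × depth` within `fork_extent` of each fired
origin. Planted DB genes multiply their amplitude by $2^{\pm
\mathrm{db\_effect}}$ at HU timepoints, with 75% of effects positive
(gains predominate in the real data). Per-timepoint amplitude multipliers
default to 1, so a zero-effect configuration is truly null; non-unit
values emulate the batch differences the residual regression exists to
absorb.

**EdU.** Background 0.2 with plateau 4 over ±`fork_extent` of fired
origins: early origins fire under HU in every genotype, late origins fire
only in checkpoint-deficient genotypes by HU90, inactive origins never,
nothing in G1.

**RNA.** Lognormal baselines (mean `depth`); planted DEGs shift by
$2^{\pm\mathrm{deg\_log2fc}}$ between G1 and HU. Genes within 5 kb of a
late origin receive an orientation-biased *signed* direction in
checkpoint-deficient cells — down with probability `ho_down_bias` (0.8)
for head-on genes and `cd_down_bias` (0.4) for co-directional genes, up
otherwise. A down-or-nothing mechanism was rejected: it would make every
significant near-origin DEG a down gene and erase the up/down contrast
the bias test measures. Half of the planted DEGs are drawn from the
planted DB genes with concordant sign so the binding–expression
association stages have signal to find.

**Determinism.** One integer seed; every stochastic step derives a
documented sub-stream (`seed·7919 + 104729·k mod 2³¹−1`) and restores the
caller's RNG state, so identical configurations are byte-identical and
user code interleaves freely.

**What it does not emulate.** Read-level artefacts (mappability, GC,
duplicates), fragment-size effects, sigmoidal fork-boundary decay (the
plateau is rectangular), correlated gene expression programs beyond the
planted effects, and hyper-ChIPable signal itself (the blacklist intervals
are placed but carry no extra signal). Passing tests therefore demonstrate
the *procedures* recover planted structure under realistic count noise —
not that any particular biological dataset will behave as cleanly.

# Numerical choices and degenerate inputs

* Overlap-weighted window means use an $O(1)$-per-query cumulative
  integral of the step-function track; fully covered bins contribute
  their value exactly, so bedGraph round trips are bit-identical.
* Metagene matrices use the w0 averaging dialect: positions outside the
  chromosome contribute zero at full weight. Origin matrices are never
  strand-aware; TSS matrices flip minus-strand rows so upstream is always
  left.
* Ties: nearest-origin and timing assignment resolve to the lower
  coordinate; selection ranks resolve lexicographically by gene id; rows
  with missing ordering keys sort last.
* Degenerate inputs raise early, specific errors: constant G1 scores
  (singular fit), zero-variance residuals (undefined Z-scores), all-zero
  Gini input, empty peak sets, zero-count partitions, zero-total samples,
  mismatched origin universes.

# Problem sizes used in the checks

The packaged test suite and `scripts/acceptance.R` exercise: a 2000-gene,
4 × 750-kb genome with 150 planted DB genes (|Δlog2| = 1, depth 50,
duplicate IP/input, two independent experiments, top-300 intersection, 10
seeds); 60 origins over 3 × 600 kb for typing under both noise regimes (10
seeds); 60 near-origin genes (30 HO / 30 CD) with 100 seeded runs for
bias-detection power and 1000 for null calibration — the exact type-I rate
of the discrete Fisher contrast there is 0.026, so the larger run count is
needed to estimate it meaningfully; 500 genes on a 600-kb noise genome
with 10⁴ null windows for p-value calibration; all 132,470 non-degenerate
2×2 tables with total ≤ 40 for Fisher oracle agreement; 1000 random
vectors for Gini oracle agreement; 100 random tracks for the normalization
invariants. These sizes were chosen as the smallest at which the measured
quantities are stable to the asserted precision.

# Known limitations

* Under the two-experiment intersection design there is an irreducible
  chance-overlap floor of non-planted genes: with $K$ selected per
  experiment and $m$ planted among $N$ genes, about $(K - m)^2 / (N - m)$
  non-planted genes enter the intersection even at perfect recovery —
  roughly 12 genes (≈7% of the recovered set) at the sizes above. Reported
  false-member rates should be read against that floor, which no
  generator with exchangeable per-gene noise can undercut.
* The empirical-p null ignores chromatin structure; on real data,
  accessibility and copy-number covariates would argue for a stratified
  null.
* `naive_de()` is a surrogate by design; effect-size estimates at low
  counts shrink toward zero because of the +1 pseudocount, and no
  significance calibration is claimed for it.
* The origin-aware normalization makes levels incomparable across the
  proximal/distal partition boundary; profiles spanning the boundary mix
  the two scales.
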