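# dynbind

Analysis of cell-cycle-dynamic binding of a replication-checkpoint kinase
at gene promoters, and of its interplay with replication-origin firing and
gene expression under replication stress.

When G1-arrested yeast cells are released into hydroxyurea (HU), the
checkpoint kinase appears genome-wide in ChIP-seq: at stalled replication
forks around fired origins, and at the promoters of a substantial fraction
of genes, where its binding changes as cells move from G1 into S phase.
`dynbind` is for computational biologists who want to run — or stress-test
on simulated data — the full analysis chain behind such a study:

* **Normalization** of binned (25-bp) IP/input coverage into log2
  enrichment, `log2(((ip + c)·T_input) / ((input + c)·T_ip))`, either
  genome-wide ("simple") or independently for origin-proximal (±5 kb) and
  distal bins ("origin-aware", which absorbs replication background).
* **Promoter scoring**: mean enrichment over the 500-bp window upstream of
  each TSS; empirical p-values against uniformly placed null windows;
  Lorenz/Gini binding specificity; peak-to-promoter (−500/+50) annotation.
* **Differential binding (DB)** by regression residuals: OLS of HU
  promoter scores on G1 scores across all genes, per-gene residual
  `r_g = y_g − (a + b·x_g)`, top-K selection by |r| after a minimal-signal
  filter (scaled score ≥ −0.075 with the sample maximum at 1), and
  intersection of two independent experiments.
* **Origin typing** from replication-incorporation (EdU) signal: early if
  the wild-type HU45 score exceeds 2, else late if the checkpoint-mutant
  HU90 mean exceeds 2, else inactive; timing assignment and blacklist
  filtering.
* **Replication–transcription conflicts**: nearest origin per gene,
  head-on (HO) vs co-directional (CD) orientation, and Fisher tests for
  downregulation bias near late origins.
* **Integration**: TF-target enrichment (Fisher, explicit gene universe),
  Spearman correlation and direction association between binding and
  expression changes, Wilcoxon group tests on DB residual Z-scores, and a
  clearly-labelled naive DE surrogate (external DE tables are accepted
  everywhere).
* **Profiles**: strand-aware metagene matrices around TSSs (±1 kb) and
  origins (±15 kb) with w0 averaging and keyed row ordering.
* A **synthetic-data generator** with planted ground truth (negative
  binomial counts, promoter peaks with planted G1→HU shifts, fork
  plateaus ~10 kb around fired origins, orientation-biased expression
  changes) so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(dynbind)

cfg <- sim_config(n_genes = 300, n_origins = 20, chrom_length = 400000,
                  n_db_genes = 30, n_deg = 50, seed = 11)
res <- run_pipeline(cfg, analysis_config(top_k = 100, n_null = 5000))

print(res$origin_classes)
#> origin_classification: 20 origins (13 active: 6 early, 7 late; 7 inactive), threshold 2

length(res$db_overlap)                 # genes in both top-100 DB selections
#> [1] 49
mean(names(res$annotation$truth$db_effects) %in% res$db_overlap)
#> [1] 0.8                              # 80% of planted DB genes recovered

attr(res$promoter_p, "n_significant")  # significant promoters at alpha 0.05
#> [1] 158

print(res$tf_enrichment)               # TF targets among the DB/DEG set
#> tf_enrichment: 15/23 selected are targets (65.22% vs 10.00% background), Fisher p = 6.57e-12

res$db_de_correlation$r                # binding change vs expression change
#> [1] 0.5117973

res$bias$contrasts[, c("contrast", "a_down", "a_up", "b_down", "b_up", "p")]
#>  contrast a_down a_up b_down b_up          p
#>  HO_vs_CD     13    2      6    6 0.08695652
```

Reading the output: 13 of 20 simulated origins fire under HU (6 in wild
type = early, 7 only in checkpoint mutants = late); the two-experiment
residual analysis recovers 80% of the planted dynamic-binding genes; the
planted TF-target structure surfaces as a 65% target frequency in the
DB/DEG set against a 10% background; binding and expression changes
correlate positively (Spearman r = 0.51); and among significant DEGs near
origins, 13/15 head-on genes are downregulated versus 6/12 co-directional
ones. With `outdir =` set, every table is written as TSV alongside a
provenance JSON (inputs, configuration, seed).

## Package layout

| Path | Contents |
| --- | --- |
| `R/simulate.R` | synthetic genomes, tracks, RNA counts, ground truth |
| `R/layout.R`, `R/io.R` | genome layout, binned tracks, bedGraph/BED/TSV/GFF3-lite I/O |
| `R/normalize.R` | simple and origin-aware log2 enrichment |
| `R/promoter.R` | promoter windows/scores, empirical p, Lorenz/Gini, peak annotation |
| `R/differential_binding.R` | residual regression, top-K selection, group tests |
| `R/origins.R` | EdU scoring, early/late/inactive typing, timing, blacklist |
| `R/gene_origin.R` | nearest origin, HO/CD orientation, downregulation bias |
| `R/integration_stats.R` | Fisher/Spearman/association statistics, DE surrogate |
| `R/profiles.R` | metagene matrices, average profiles, row ordering |
| `R/pipeline.R` | configuration and end-to-end orchestration |

The methods vignette (`vignettes/dynbind-methods.Rmd`) documents the
models, the generator's assumptions, numerical conventions, and known
limitations.
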