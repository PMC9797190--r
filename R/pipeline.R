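#' Analysis configuration: the pipeline's constants
#'
#' Collects every threshold the analysis uses, at its standard default:
#' 25-bp bins; 500-bp promoter scoring window with a 50-bp downstream
#' extension for peak annotation; 1-kb TSS and 15-kb origin flanks for
#' metagene matrices; 5-kb origin-proximal radius for origin-aware
#' normalization; EdU origin-typing threshold 2; residual top-K 1000 with
#' minimal scaled signal -0.075; gene-origin distance bins at 1/2/5 kb;
#' 5-kb replication-timing assignment ceiling; alpha 0.05.
#'
#' @param bin_width,promoter_upstream,peak_downstream,tss_flank,origin_flank
#'   Geometry in bp.
#' @param origin_radius Origin-aware normalization radius, bp.
#' @param edu_threshold Origin-typing signal threshold.
#' @param top_k,min_signal Residual selection size and scaled-signal floor.
#' @param dist_breaks Gene-origin distance category thresholds, bp.
#' @param timing_max_dist Timing assignment ceiling, bp.
#' @param alpha Significance level.
#' @param n_null Null windows for empirical promoter p-values.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 25, promoter_upstream = 500,
                            peak_downstream = 50, tss_flank = 1000,
                            origin_flank = 15000, origin_radius = 5000,
                            edu_threshold = 2, top_k = 1000,
                            min_signal = -0.075,
                            dist_breaks = c(1000, 2000, 5000),
                            timing_max_dist = 5000, alpha = 0.05,
                            n_null = 10000) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("bin_width", "promoter_upstream", "tss_flank",
                       "origin_flank", "n_null")]) <= 0))
    stop("geometry parameters must be positive")
  if (top_k <= 0) stop("top_k must be positive")
  structure(cfg, class = "analysis_config")
}

#' Average replicate enrichment for one condition
#'
#' Pairs each IP replicate of the given genotype and timepoint with its
#' matched input, normalizes each pair ([log2_enrichment()]) and averages
#' the replicates ([average_replicates()]).
#'
#' @param tracks Named list of count tracks (as from
#'   [simulate_chip_tracks()]).
#' @param design The [sample_design()] the tracks were generated from.
#' @param genotype,timepoint Condition selector.
#' @param cfg A [norm_config()].
#' @return A `log2fc` [binned_track()].
#' @export
condition_enrichment <- function(tracks, design, genotype, timepoint,
                                 cfg = norm_config()) {
  ip <- design[design$assay == "IP" & design$genotype == genotype &
                 design$timepoint == timepoint, , drop = FALSE]
  if (!nrow(ip)) stop("no IP samples for this condition")
  reps <- lapply(seq_len(nrow(ip)), function(i) {
    inp <- design$sample[design$assay == "input" &
                           design$genotype == genotype &
                           design$timepoint == timepoint &
                           design$replicate == ip$replicate[i]]
    if (!length(inp))
      stop(sprintf("no matched input for '%s'", ip$sample[i]))
    log2_enrichment(tracks[[ip$sample[i]]], tracks[[inp[1]]], cfg)
  })
  average_replicates(reps)
}

#' Residual differential-binding analysis between two score tables
#'
#' Fits the G1-to-HU regression, scales each sample to unit maximum,
#' applies the minimal-signal filter and returns the top-K selection
#' alongside the fit.
#'
#' @param g1,hu Named (by gene) promoter score vectors.
#' @param K,min_signal Selection parameters (see [select_top_db()]).
#' @return A list: `fit` ([fit_db_regression()]), `selection`
#'   ([select_top_db()]).
#' @export
run_db_analysis <- function(g1, hu, K = 1000, min_signal = -0.075) {
  fit <- fit_db_regression(g1, hu)
  sel <- select_top_db(fit, scale_to_unit_max(g1), scale_to_unit_max(hu),
                       K = K, min_signal = min_signal)
  list(fit = fit, selection = sel)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates two independent ChIP experiments (G1 and HU45, duplicate
#' IP/input), EdU tracks for origin typing, and RNA counts; then runs
#' normalization, promoter scoring, residual differential binding with
#' top-K intersection, origin classification with blacklist filtering,
#' gene-origin relations with the downregulation-bias contrasts, the DE
#' surrogate, TF-target enrichment, binding-expression correlation and
#' association, empirical promoter p-values, and metagene profiles.
#' Stage order, inputs and seeds are recorded in `provenance`.
#'
#' @param config A [sim_config()].
#' @param analysis An [analysis_config()].
#' @param outdir Optional directory; when given, tables, tracks and a
#'   provenance JSON are written there.
#' @return A list with the stage results (see element names).
#' @export
run_pipeline <- function(config = sim_config(), analysis = analysis_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(analysis, "analysis_config"))
  if (config$n_genes < 3) stop("pipeline requires at least 3 genes")
  stages <- character()
  tick <- function(name) stages <<- c(stages, name)

  tick("simulate")
  ann <- generate_annotation(config)
  design <- sample_design("WT", c("G1", "HU45"), c("IP", "input"), 1:2)
  tracks1 <- simulate_chip_tracks(ann, design, config,
                                  seed = derive_seed(config$seed, 11))
  tracks2 <- simulate_chip_tracks(ann, design, config,
                                  seed = derive_seed(config$seed, 12))

  tick("normalize")
  ncfg <- norm_config(origin_radius = analysis$origin_radius)
  fc <- lapply(list(exp1 = tracks1, exp2 = tracks2), function(tr)
    list(G1 = condition_enrichment(tr, design, "WT", "G1", ncfg),
         HU45 = condition_enrichment(tr, design, "WT", "HU45", ncfg)))

  tick("promoter_scores")
  scores <- lapply(fc, function(e) lapply(e, function(t) {
    s <- promoter_scores(t, ann$genes, upstream = analysis$promoter_upstream)
    stats::setNames(s$score, s$gene_id)
  }))

  tick("differential_binding")
  K <- min(analysis$top_k, config$n_genes)
  db <- lapply(scores, function(s)
    run_db_analysis(s$G1, s$HU45, K = K, min_signal = analysis$min_signal))
  db_overlap <- intersect_top_db(db$exp1$selection, db$exp2$selection)

  tick("origin_classes")
  edu_scores <- function(genotype, timepoint, k)
    origin_edu_score(simulate_edu_track(ann$origins, genotype, timepoint,
                                        config, ann$layout,
                                        seed = derive_seed(config$seed, k)),
                     ann$origins)
  classes <- classify_origins(
    edu_scores("WT", "HU45", 21),
    list(mutA = edu_scores("mutA", "HU90", 22),
         mutB = edu_scores("mutB", "HU90", 23)),
    threshold = analysis$edu_threshold)
  origins_called <- ann$origins[, c("origin_id", "chrom", "center")]
  origins_called$class <- as.character(classes$class[origins_called$origin_id])
  origins_kept <- filter_blacklist(origins_called, ann$blacklist)

  tick("gene_origin")
  relations <- nearest_origin(ann$genes, origins_kept,
                              breaks = analysis$dist_breaks)

  tick("expression")
  rna_design <- sample_design(c("WT", "mutA"), c("G1", "HU45"), "RNA", 1:3)
  rna <- simulate_rna_counts(ann, rna_design, config,
                             seed = derive_seed(config$seed, 31))
  # stage-dependent DE in wild type (G1 -> HU45): the comparison behind
  # the binding-expression integration
  wt_cols <- rna_design$genotype == "WT"
  de <- naive_de(rna[, wt_cols, drop = FALSE],
                 factor(rna_design$timepoint[wt_cols],
                        levels = c("G1", "HU45")))
  de_sig <- de[de$significant, , drop = FALSE]
  # checkpoint-mutant vs wild type under HU, where late origins fire: the
  # comparison behind the gene-origin downregulation bias
  hu_cols <- rna_design$timepoint == "HU45"
  de_mut <- naive_de(rna[, hu_cols, drop = FALSE],
                     factor(rna_design$genotype[hu_cols],
                            levels = c("WT", "mutA")))
  de_mut_sig <- de_mut[de_mut$significant, , drop = FALSE]
  bias <- if (nrow(de_mut_sig) >= 2)
    suppressWarnings(deg_origin_bias(relations,
                                     stats::setNames(de_mut_sig$direction,
                                                     de_mut_sig$gene_id)))
  else NULL

  tick("integration")
  tf_targets <- ann$genes$gene_id[ann$genes$tf_labels == "TF1"]
  db_deg <- intersect(db_overlap, de_sig$gene_id)
  tf <- if (length(db_deg))
    tf_enrichment(config$n_genes, tf_targets, db_deg) else NULL
  res1 <- stats::setNames(db$exp1$fit$table$residual,
                          db$exp1$fit$table$gene_id)
  lfc <- stats::setNames(de$log2fc, de$gene_id)
  corr <- if (length(db_deg) >= 3)
    db_de_correlation(res1[db_deg], lfc[db_deg]) else NULL
  group <- tryCatch(db_group_test(db$exp1$fit, tf_targets), error = function(e) NULL)
  promp <- empirical_promoter_p(fc$exp1$HU45, ann$genes,
                                upstream = analysis$promoter_upstream,
                                n_null = analysis$n_null,
                                seed = derive_seed(config$seed, 41),
                                alpha = analysis$alpha)
  counts_hu <- promoter_scores(tracks1[["WT_HU45_IP_rep1"]], ann$genes,
                               upstream = analysis$promoter_upstream)
  gini <- lorenz_gini(pmax(counts_hu$score, 0))

  tick("profiles")
  tss_mat <- signal_matrix(fc$exp1$HU45, ann$genes, analysis$tss_flank,
                           bin = analysis$bin_width, strand_aware = TRUE)
  ori_mat <- if (nrow(origins_kept))
    signal_matrix(fc$exp1$HU45, origins_kept, analysis$origin_flank,
                  bin = analysis$bin_width) else NULL

  result <- list(
    annotation = ann, design = design, enrichment = fc, scores = scores,
    db = db, db_overlap = db_overlap, origin_classes = classes,
    origins_kept = origins_kept, relations = relations, rna = rna, de = de,
    de_mut = de_mut, bias = bias, tf_enrichment = tf, db_deg = db_deg,
    db_de_correlation = corr, group_test = group,
    promoter_p = promp, gini = gini,
    tss_matrix = tss_mat, origin_matrix = ori_mat,
    provenance = list(stages = stages, seed = config$seed,
                      sim_config = unclass(config)[
                        !vapply(unclass(config), is.function, TRUE)],
                      analysis_config = unclass(analysis),
                      package_version = as.character(
                        utils::packageVersion("dynbind"))))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(ann, outdir, tracks = NULL, rna_counts = rna)
    write_bedgraph(fc$exp1$G1, file.path(outdir, "WT_G1_log2fc_exp1.bedgraph"))
    write_bedgraph(fc$exp1$HU45,
                   file.path(outdir, "WT_HU45_log2fc_exp1.bedgraph"))
    write_tsv(db$exp1$fit$table, file.path(outdir, "db_residuals_exp1.tsv"))
    write_tsv(data.frame(gene_id = db_overlap),
              file.path(outdir, "db_overlap.tsv"))
    write_tsv(data.frame(origin_id = names(classes$class),
                         class = as.character(classes$class)),
              file.path(outdir, "origin_classes.tsv"))
    write_tsv(relations, file.path(outdir, "gene_origin_relations.tsv"))
    write_tsv(as.data.frame(de), file.path(outdir, "de_surrogate.tsv"))
    write_tsv(as.data.frame(de_mut),
              file.path(outdir, "de_mut_surrogate.tsv"))
    if (!is.null(bias)) {
      write_tsv(bias$strata, file.path(outdir, "deg_origin_strata.tsv"))
      if (!is.null(bias$contrasts))
        write_tsv(bias$contrasts, file.path(outdir, "deg_origin_contrasts.tsv"))
    }
    jsonlite::write_json(result$provenance,
                         file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
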