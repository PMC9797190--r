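#' Simulation configuration
#'
#' Defines the synthetic study: a toy genome, gene and origin annotations,
#' and negative-binomial binned read counts for IP/input ChIP samples,
#' replication-incorporation (EdU) tracks, and RNA counts, all with known
#' planted ground truth. Defaults emulate the assayed conditions: cells
#' released from G1 into hydroxyurea and sampled at 45 and 90 minutes,
#' replication forks extending about 10 kb from fired origins, and origin
#' classes in roughly the 0.31/0.32/0.37 early/late/inactive proportions
#' observed genome-wide.
#'
#' @param n_chromosomes,chrom_length Genome shape; `chrom_length` must be
#'   divisible by `bin_width`.
#' @param n_genes,n_origins Number of annotated genes and origins.
#' @param fraction_early,fraction_late,fraction_inactive Origin class
#'   fractions, summing to 1.
#' @param n_db_genes Genes with a planted promoter-binding change.
#' @param db_effect Planted G1 to HU promoter amplitude shift, log2 units.
#' @param db_up_fraction Fraction of planted DB genes with increased
#'   binding (default 0.75, matching the observed predominance of gains).
#' @param fork_extent Fork signal half-extent from a fired origin center,
#'   bp (default 10000, the approximate extent of DNA synthesis in wild
#'   type under these conditions).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + d mu^2`); 0 gives Poisson counts.
#' @param depth Mean background reads per bin for ChIP/EdU tracks, and the
#'   mean per-gene count for RNA.
#' @param n_deg Genes with a planted genome-wide expression change.
#' @param deg_log2fc Planted expression log2 fold change magnitude.
#' @param ho_down_bias,cd_down_bias Probability that a gene within 5 kb of
#'   a late origin is planted as downregulated in checkpoint-deficient
#'   cells, for head-on and co-directional genes respectively.
#' @param amp_range Per-gene promoter binding amplitude range, as
#'   multiples of `depth`.
#' @param timepoint_scaling Named multipliers applied to all promoter
#'   amplitudes per timepoint; non-unit values emulate batch differences
#'   (protein level, IP efficiency) that the residual regression must
#'   absorb. Default is unit scaling.
#' @param edu_plateau,edu_background Mean EdU signal on/off the fork
#'   plateau (defaults 4 and 0.2; the origin-typing threshold is 2).
#' @param fork_ip_factor Fork-associated ChIP signal added within the fork
#'   extent of fired origins, as a multiple of `depth`.
#' @param genotypes Valid genotype labels; the first is wild type.
#' @param checkpoint_deficient Genotypes in which late origins fire.
#' @param bin_width Track bin width, bp (default 25).
#' @param seed Master integer seed; every stochastic draw derives a
#'   documented sub-stream from it, so identical configs give identical
#'   outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 300000,
                       n_genes = 200, n_origins = 20,
                       fraction_early = 0.31, fraction_late = 0.32,
                       fraction_inactive = 0.37,
                       n_db_genes = 20, db_effect = 1, db_up_fraction = 0.75,
                       fork_extent = 10000, nb_dispersion = 0.05,
                       depth = 50, n_deg = 40, deg_log2fc = 2,
                       ho_down_bias = 0.8, cd_down_bias = 0.4,
                       amp_range = c(0.5, 3),
                       timepoint_scaling = c(G1 = 1, HU45 = 1, HU90 = 1),
                       edu_plateau = 4, edu_background = 0.2,
                       fork_ip_factor = 1,
                       genotypes = c("WT", "mutA", "mutB"),
                       checkpoint_deficient = c("mutA", "mutB"),
                       bin_width = 25, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_chromosomes, chrom_length, n_genes, n_origins, n_db_genes,
              n_deg)
  if (any(counts < 0)) stop("counts must be nonnegative")
  fr <- c(fraction_early, fraction_late, fraction_inactive)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8)
    stop("origin class fractions must lie in [0,1] and sum to 1")
  if (chrom_length %% bin_width != 0)
    stop("chrom_length must be divisible by bin_width")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (depth < 0) stop("depth must be >= 0")
  if (n_db_genes > n_genes || n_deg > n_genes)
    stop("planted gene counts exceed n_genes")
  if (db_up_fraction < 0 || db_up_fraction > 1)
    stop("db_up_fraction must be in [0,1]")
  if (any(c(ho_down_bias, cd_down_bias) < 0) ||
      any(c(ho_down_bias, cd_down_bias) > 1))
    stop("down-bias probabilities must be in [0,1]")
  if (!all(checkpoint_deficient %in% genotypes))
    stop("checkpoint_deficient genotypes must be listed in genotypes")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d x %s bp genome, %d genes (%d DB, %d DEG), %d origins, seed %d\n",
    x$n_chromosomes, format(x$chrom_length, big.mark = ","), x$n_genes,
    x$n_db_genes, x$n_deg, x$n_origins, x$seed))
  invisible(x)
}

#' Build a sample design table
#'
#' One row per (genotype, timepoint, assay, replicate) combination;
#' tuples must be unique.
#'
#' @param genotypes,timepoints,assays,replicates Levels crossed by
#'   `expand.grid`.
#' @return A `data.frame` with a derived unique `sample` name column.
#' @export
sample_design <- function(genotypes = "WT", timepoints = c("G1", "HU45"),
                          assays = c("IP", "input"), replicates = 1:2) {
  d <- expand.grid(genotype = genotypes, timepoint = timepoints,
                   assay = assays, replicate = replicates,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  d$sample <- paste(d$genotype, d$timepoint, d$assay,
                    paste0("rep", d$replicate), sep = "_")
  if (anyDuplicated(d$sample)) stop("duplicate sample tuples in design")
  d
}

## exact largest-remainder allocation of n items over class fractions
allocate_classes <- function(n, fractions, labels) {
  base <- floor(fractions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(labels, times = base)
}

## split n items as evenly as possible over k groups
split_even <- function(n, k) diff(round(seq(0, n, length.out = k + 1)))

place_in_slots <- function(n, length, margin, what) {
  if (n == 0) return(numeric())
  w <- floor(length / n)
  if (w < 2 * margin)
    stop(sprintf("cannot place %d %s on a %g-bp chromosome without overlap",
                 n, what, length))
  (seq_len(n) - 1) * w + margin + floor(stats::runif(n) * (w - 2 * margin + 1))
}

#' Generate annotation, blacklist, and planted ground truth
#'
#' Places genes (balanced strands) and origins (non-overlapping centers)
#' in regular slots with random jitter, draws exact-fraction origin
#' classes, a blacklist of hyper-ChIPable-like intervals, and the planted
#' truth: signed DB effects, genome-wide DEG effects, orientation-biased
#' downregulation flags for genes near late origins, and a TF target
#' label enriched among DB genes.
#'
#' @param config A [sim_config()].
#' @return A list: `layout` ([genome_layout()]), `genes`, `origins`,
#'   `blacklist` (data frames), and `truth` (list with `db_effects`,
#'   `deg_effects`, `near_late`, `tf_targets`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- rep(config$chrom_length, config$n_chromosomes)
  names(lens) <- paste0("chr", seq_len(config$n_chromosomes))
  layout <- genome_layout(lens, config$bin_width)
  with_seed(derive_seed(config$seed, 1), {
    g_per <- split_even(config$n_genes, config$n_chromosomes)
    o_per <- split_even(config$n_origins, config$n_chromosomes)
    genes <- do.call(rbind, lapply(seq_along(lens), function(i) {
      tss <- place_in_slots(g_per[i], lens[i], 600, "genes")
      if (!length(tss)) return(NULL)
      data.frame(chrom = names(lens)[i], tss = tss,
                 stringsAsFactors = FALSE)
    }))
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    strands <- rep(c("+", "-"), length.out = nrow(genes))
    genes$strand <- strands[sample(nrow(genes))]
    ## adjacent origin centers end up >= 2 * margin apart; keeping that
    ## above fork_extent + edu scoring window means fired-origin plateaus
    ## cannot bleed into a neighbour's score, so noise-free typing is exact
    o_margin <- config$fork_extent / 2 + 1500
    origins <- do.call(rbind, lapply(seq_along(lens), function(i) {
      ctr <- place_in_slots(o_per[i], lens[i], o_margin, "origins")
      if (!length(ctr)) return(NULL)
      data.frame(chrom = names(lens)[i], center = ctr,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(origins))
      origins <- data.frame(chrom = character(), center = numeric())
    if (nrow(origins)) {
      origins$origin_id <- sprintf("ori%03d", seq_len(nrow(origins)))
      cls <- allocate_classes(nrow(origins),
                              c(config$fraction_early, config$fraction_late,
                                config$fraction_inactive),
                              c("early", "late", "inactive"))
      origins$class <- sample(cls)
      origins <- origins[, c("origin_id", "chrom", "center", "class")]
    }
    blacklist <- do.call(rbind, lapply(names(lens), function(cn) {
      s <- floor(stats::runif(2) * (lens[[cn]] - 1000))
      data.frame(chrom = cn, start = s, end = s + 1000,
                 stringsAsFactors = FALSE)
    }))

    ## planted truth
    db_genes <- sample(genes$gene_id, config$n_db_genes)
    db_sign <- ifelse(stats::runif(config$n_db_genes) < config$db_up_fraction,
                      1, -1)
    db_effects <- stats::setNames(db_sign * config$db_effect, db_genes)

    late <- origins[origins$class %in% "late", , drop = FALSE]
    near_late <- if (nrow(late)) {
      rel <- nearest_origin(genes, late)
      rel <- rel[!is.na(rel$distance) & rel$distance < 5000, , drop = FALSE]
      if (nrow(rel)) {
        dirs <- plant_deg_directions(rel, config,
                                     seed = derive_seed(config$seed, 4))
        stats::setNames(dirs$direction, dirs$gene_id)
      } else stats::setNames(character(), character())
    } else stats::setNames(character(), character())

    ## half the DEGs are drawn from the DB genes with concordant sign,
    ## emulating the coupling between promoter-binding change and
    ## expression change; the rest are independent with random sign
    deg_pool <- setdiff(genes$gene_id, names(near_late))
    from_db_pool <- intersect(db_genes, deg_pool)
    n_from_db <- min(length(from_db_pool), floor(config$n_deg / 2))
    deg_db <- sample(from_db_pool, n_from_db)
    deg_free <- sample(setdiff(deg_pool, deg_db),
                       min(config$n_deg - n_from_db,
                           length(setdiff(deg_pool, deg_db))))
    deg_genes <- c(deg_db, deg_free)
    deg_sign <- c(sign(db_effects[deg_db]),
                  ifelse(stats::runif(length(deg_free)) < 0.5, 1, -1))
    deg_effects <- stats::setNames(unname(deg_sign) * config$deg_log2fc,
                                   deg_genes)

    n_tf <- max(5, round(0.1 * nrow(genes)))
    from_db <- sample(db_genes, min(length(db_genes), round(0.6 * n_tf)))
    rest <- sample(setdiff(genes$gene_id, from_db),
                   max(0, n_tf - length(from_db)))
    tf_targets <- sort(c(from_db, rest))
    genes$tf_labels <- ifelse(genes$gene_id %in% tf_targets, "TF1", "")
    genes$cluster <- sample(1:5, nrow(genes), replace = TRUE)
    genes <- genes[, c("gene_id", "chrom", "tss", "strand", "tf_labels",
                       "cluster")]

    list(layout = layout, genes = genes, origins = origins,
         blacklist = blacklist,
         truth = list(db_effects = db_effects, deg_effects = deg_effects,
                      near_late = near_late, tf_targets = tf_targets))
  })
}

#' Plant orientation-biased expression directions
#'
#' For genes with a late origin within 5 kb of the TSS, the planted
#' expression direction under checkpoint deficiency is `down` with
#' probability `ho_down_bias` (head-on) or `cd_down_bias`
#' (co-directional), and `up` otherwise; all other genes are drawn 50/50.
#'
#' @param relations A [nearest_origin()] table (against late origins, or
#'   with `origin_class` annotated).
#' @param config A [sim_config()] supplying the bias probabilities.
#' @param seed Integer seed for the draw.
#' @return A `data.frame` `gene_id`, `direction`.
#' @export
plant_deg_directions <- function(relations, config, seed = config$seed) {
  near <- !is.na(relations$distance) & relations$distance < 5000 &
    relations$origin_class %in% "late"
  p_down <- rep(0.5, nrow(relations))
  ho <- near & relations$orientation %in% "HO"
  cd <- near & relations$orientation %in% "CD"
  p_down[ho] <- config$ho_down_bias
  p_down[cd] <- config$cd_down_bias
  p_down[near & !ho & !cd] <- mean(c(config$ho_down_bias,
                                     config$cd_down_bias))
  with_seed(seed, data.frame(
    gene_id = relations$gene_id,
    direction = ifelse(stats::runif(nrow(relations)) < p_down, "down", "up"),
    stringsAsFactors = FALSE))
}

## negative-binomial draw with Poisson limit at zero dispersion
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

## per-chromosome deposition of window signal onto track bins:
## adds amount[i] (per-bp density over [start, end)) * overlap to bins
deposit <- function(acc, bw, start, end, amount) {
  start <- pmax(start, 0); end <- pmin(end, length(acc) * bw)
  keep <- end > start
  if (!any(keep)) return(acc)
  start <- start[keep]; end <- end[keep]; amount <- amount[keep]
  b0 <- floor(start / bw)
  b1 <- floor((end - 1) / bw)
  nspan <- b1 - b0 + 1
  bins <- rep(b0, nspan) + sequence(nspan) - 1
  ov <- pmin(rep(end, nspan), (bins + 1) * bw) -
    pmax(rep(start, nspan), bins * bw)
  add <- rowsum(rep(amount, nspan) * ov / bw, bins)
  idx <- as.integer(rownames(add)) + 1L
  acc[idx] <- acc[idx] + add[, 1]
  acc
}

fired_origins <- function(origins, genotype, timepoint, config) {
  if (!genotype %in% config$genotypes)
    stop(sprintf("unknown genotype '%s'", genotype))
  if (timepoint == "G1" || !nrow(origins)) return(origins[0, , drop = FALSE])
  deficient <- genotype %in% config$checkpoint_deficient
  fire <- origins$class == "early" |
    (origins$class == "late" & deficient & timepoint == "HU90")
  origins[fire, , drop = FALSE]
}

#' Simulate binned ChIP-seq count tracks
#'
#' IP tracks are negative-binomial counts around a mean of uniform
#' background (`depth` per bin), a rectangular promoter peak over the
#' 500-bp window upstream of each TSS (per-gene amplitude drawn once from
#' `amp_range * depth`, scaled by the timepoint factor, and shifted by
#' `2^db_effect` at HU timepoints for planted DB genes), and a
#' fork-associated plateau within `fork_extent` of each fired origin.
#' Input tracks are background only. Every IP sample must have a matched
#' input (same genotype, timepoint, replicate).
#'
#' @param ann A [generate_annotation()] result.
#' @param design A [sample_design()] table with IP/input assays.
#' @param config The [sim_config()].
#' @param seed Master seed (defaults to `config$seed`); per-sample
#'   sub-streams are derived from it.
#' @return Named list of count [binned_track()]s, one per design row.
#' @export
simulate_chip_tracks <- function(ann, design, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ip_rows <- design[design$assay == "IP", , drop = FALSE]
  for (i in seq_len(nrow(ip_rows))) {
    match_in <- design$assay == "input" &
      design$genotype == ip_rows$genotype[i] &
      design$timepoint == ip_rows$timepoint[i] &
      design$replicate == ip_rows$replicate[i]
    if (!any(match_in))
      stop(sprintf("no matched input for IP sample '%s'", ip_rows$sample[i]))
  }
  layout <- ann$layout
  bw <- layout$bin_width
  genes <- ann$genes
  win <- promoter_window(genes$tss, genes$strand,
                         layout$chrom_lengths[genes$chrom], upstream = 500)
  amp <- with_seed(derive_seed(seed, 2),
                   stats::runif(nrow(genes), config$amp_range[1],
                                config$amp_range[2]) * config$depth)
  scaling <- config$timepoint_scaling
  tracks <- vector("list", nrow(design))
  names(tracks) <- design$sample
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    if (!row$genotype %in% config$genotypes)
      stop(sprintf("unknown genotype '%s'", row$genotype))
    tracks[[i]] <- with_seed(derive_seed(seed, 100 + i), {
      vals <- lapply(names(layout$chrom_lengths), function(cn) {
        nb <- ceiling(layout$chrom_lengths[[cn]] / bw)
        mu <- rep(config$depth, nb)
        if (row$assay == "IP") {
          gi <- which(genes$chrom == cn)
          if (length(gi)) {
            a <- amp[gi] * scaling[[row$timepoint]]
            planted <- match(genes$gene_id[gi], names(ann$truth$db_effects))
            eff <- ifelse(is.na(planted), 0, ann$truth$db_effects[planted])
            if (row$timepoint != "G1") a <- a * 2^eff
            mu <- deposit(mu, bw, win$start[gi], win$end[gi], a)
          }
          fired <- fired_origins(ann$origins, row$genotype, row$timepoint,
                                 config)
          if (nrow(fired)) {
            fc <- fired[fired$chrom == cn, , drop = FALSE]
            if (nrow(fc))
              mu <- deposit(mu, bw, fc$center - config$fork_extent,
                            fc$center + config$fork_extent,
                            rep(config$fork_ip_factor * config$depth,
                                nrow(fc)))
          }
        }
        rnb(length(mu), mu, config$nb_dispersion)
      })
      names(vals) <- names(layout$chrom_lengths)
      binned_track(vals, layout, kind = "counts")
    })
  }
  tracks
}

#' Simulate a replication-incorporation (EdU) track
#'
#' Mean signal is `edu_background` everywhere plus an `edu_plateau`
#' plateau within `fork_extent` of each origin that fires for the given
#' genotype and timepoint: early origins fire under HU in every genotype,
#' late origins fire only in checkpoint-deficient genotypes by HU90, and
#' inactive origins never fire; nothing fires in G1.
#'
#' @param origins Origin `data.frame` with planted `class`.
#' @param genotype,timepoint Condition simulated.
#' @param config The [sim_config()].
#' @param layout A [genome_layout()] for the track.
#' @param noise Draw negative-binomial noise around the mean (default);
#'   `FALSE` returns the exact mean track.
#' @param seed Integer seed.
#' @return An `edu` [binned_track()].
#' @export
simulate_edu_track <- function(origins, genotype, timepoint, config, layout,
                               noise = TRUE, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  fired <- fired_origins(origins, genotype, timepoint, config)
  bw <- layout$bin_width
  make <- function() {
    vals <- lapply(names(layout$chrom_lengths), function(cn) {
      nb <- ceiling(layout$chrom_lengths[[cn]] / bw)
      mu <- rep(config$edu_background, nb)
      fc <- fired[fired$chrom == cn, , drop = FALSE]
      if (nrow(fc))
        mu <- deposit(mu, bw, fc$center - config$fork_extent,
                      fc$center + config$fork_extent,
                      rep(config$edu_plateau, nrow(fc)))
      if (noise) rnb(length(mu), mu, config$nb_dispersion) else mu
    })
    names(vals) <- names(layout$chrom_lengths)
    binned_track(vals, layout, kind = "edu")
  }
  if (noise) with_seed(seed, make()) else make()
}

#' Simulate RNA count tables
#'
#' Gene baseline means are lognormal around `depth`; planted DEGs shift
#' by `deg_log2fc` between G1 and HU conditions; genes near late origins
#' additionally shift by the planted orientation-biased direction (down
#' with probability `ho_down_bias`/`cd_down_bias`) in
#' checkpoint-deficient genotypes under HU. Counts are negative binomial.
#'
#' @param ann A [generate_annotation()] result.
#' @param design A [sample_design()] table with `assay == "RNA"` rows and
#'   at least one replicate per (genotype, timepoint) condition.
#' @param config The [sim_config()].
#' @param seed Master seed.
#' @return Integer matrix, genes x RNA samples.
#' @export
simulate_rna_counts <- function(ann, design, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rna <- design[design$assay == "RNA", , drop = FALSE]
  if (!nrow(rna)) stop("design contains no RNA samples")
  genes <- ann$genes
  base <- with_seed(derive_seed(seed, 3),
                    config$depth * exp(stats::rnorm(nrow(genes), 0, 0.5) -
                                         0.125))
  deg <- ann$truth$deg_effects
  near <- ann$truth$near_late
  counts <- matrix(0L, nrow(genes), nrow(rna),
                   dimnames = list(genes$gene_id, rna$sample))
  for (j in seq_len(nrow(rna))) {
    row <- rna[j, ]
    if (!row$genotype %in% config$genotypes)
      stop(sprintf("unknown genotype '%s'", row$genotype))
    mu <- base
    if (row$timepoint != "G1") {
      i <- match(names(deg), genes$gene_id)
      mu[i] <- mu[i] * 2^deg
      if (row$genotype %in% config$checkpoint_deficient && length(near)) {
        i <- match(names(near), genes$gene_id)
        shift <- ifelse(near == "down", -1, 1) * abs(config$deg_log2fc)
        mu[i] <- mu[i] * 2^shift
      }
    }
    counts[, j] <- with_seed(derive_seed(seed, 500 + j),
                             rnb(length(mu), mu, config$nb_dispersion))
  }
  counts
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genes.tsv`, `origins.tsv`, `blacklist.bed`, one bedGraph per
#' track, `rna_counts.tsv` and `truth.json` under `dir`.
#'
#' @param ann A [generate_annotation()] result.
#' @param dir Output directory (created if needed).
#' @param tracks Optional named list of [binned_track()]s.
#' @param rna_counts Optional RNA count matrix.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(ann, dir, tracks = NULL, rna_counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(ann$genes, file.path(dir, "genes.tsv"))
  write_tsv(ann$origins, file.path(dir, "origins.tsv"))
  con <- file(file.path(dir, "blacklist.bed"), "wb")
  writeLines(sprintf("%s\t%d\t%d", ann$blacklist$chrom,
                     as.integer(ann$blacklist$start),
                     as.integer(ann$blacklist$end)), con, sep = "\n")
  close(con)
  for (nm in names(tracks))
    write_bedgraph(tracks[[nm]], file.path(dir, paste0(nm, ".bedgraph")))
  if (!is.null(rna_counts))
    write_tsv(data.frame(gene_id = rownames(rna_counts), rna_counts,
                         check.names = FALSE),
              file.path(dir, "rna_counts.tsv"))
  jsonlite::write_json(
    list(db_effects = as.list(ann$truth$db_effects),
         deg_effects = as.list(ann$truth$deg_effects),
         near_late = as.list(ann$truth$near_late),
         tf_targets = ann$truth$tf_targets),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
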