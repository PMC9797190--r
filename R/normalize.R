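#' Normalization settings
#'
#' @param pseudocount Added to both IP and input bin counts before the log
#'   ratio (not to library totals), bounding the ratio at empty bins. With
#'   `pseudocount = 0` the raw reciprocal-scaling formula is recovered,
#'   which is exactly invariant to library scaling but undefined on empty
#'   bins; any positive value trades that exactness for boundedness.
#' @param origin_radius Half-width in bp of the origin-proximal region used
#'   by [origin_aware_normalize()] (default 5000: the region within 5000 bp
#'   upstream and downstream of each origin center).
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(pseudocount = 1, origin_radius = 5000) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (origin_radius < 0) stop("origin_radius must be >= 0")
  structure(list(pseudocount = pseudocount, origin_radius = origin_radius),
            class = "norm_config")
}

## core per-partition computation; totals are over raw counts of the bins
## in `mask` (a logical list parallel to the track values).
log2_ratio_masked <- function(ip, input, mask, pseudocount, label) {
  t_ip <- sum(unlist(Map(function(v, m) sum(v[m]), ip$values, mask)))
  t_in <- sum(unlist(Map(function(v, m) sum(v[m]), input$values, mask)))
  if (t_ip <= 0 || t_in <= 0)
    stop(sprintf("degenerate partition '%s': zero total counts in %s", label,
                 if (t_ip <= 0) "IP" else "input"))
  c <- pseudocount
  out <- Map(function(vi, vn, m) {
    r <- numeric(length(vi))
    r[m] <- log2(((vi[m] + c) * t_in) / ((vn[m] + c) * t_ip))
    r
  }, ip$values, input$values, mask)
  out
}

#' Simple log2 IP/input enrichment
#'
#' Per 25-bp bin, the log2 fold change of IP over input with the two
#' samples reciprocally scaled by each other's genome-wide total read
#' count: `log2(((ip + c) * T_input) / ((input + c) * T_ip))` with
#' pseudocount `c`. Totals are computed over raw counts.
#'
#' @param ip,input Count [binned_track()]s sharing a layout.
#' @param cfg A [norm_config()].
#' @return A `log2fc` [binned_track()].
#' @export
log2_enrichment <- function(ip, input, cfg = norm_config()) {
  stopifnot(inherits(ip, "binned_track"), inherits(input, "binned_track"))
  check_same_layout(ip, input)
  mask <- lapply(ip$values, function(v) rep(TRUE, length(v)))
  vals <- log2_ratio_masked(ip, input, mask, cfg$pseudocount, "genome")
  binned_track(vals, ip$layout, kind = "log2fc")
}

#' Average replicate enrichment tracks
#'
#' Per-bin arithmetic mean of one or more log2 enrichment tracks (each
#' replicate is normalized against its own input first, then averaged).
#'
#' @param tracks Non-empty list of `log2fc` [binned_track()]s sharing a
#'   layout.
#' @return A `log2fc` [binned_track()].
#' @export
average_replicates <- function(tracks) {
  if (!length(tracks)) stop("no tracks to average")
  for (t in tracks) stopifnot(inherits(t, "binned_track"))
  if (length(tracks) > 1)
    for (t in tracks[-1]) check_same_layout(tracks[[1]], t)
  vals <- lapply(names(tracks[[1]]$values), function(cn) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[cn]])) / length(tracks)
  })
  names(vals) <- names(tracks[[1]]$values)
  binned_track(vals, tracks[[1]]$layout, kind = "log2fc")
}

## logical per-chromosome mask of bins whose interval intersects
## [center - radius, center + radius] for any origin
origin_proximal_mask <- function(layout, origins, radius) {
  bw <- layout$bin_width
  nb <- layout_n_bins(layout)
  names(nb) <- names(layout$chrom_lengths)
  mask <- lapply(names(layout$chrom_lengths), function(cn) {
    m <- rep(FALSE, nb[[cn]])
    sub <- origins[origins$chrom == cn, , drop = FALSE]
    for (ctr in sub$center) {
      # bin [i*bw, (i+1)*bw) intersects closed [ctr - r, ctr + r]
      lo <- max(0L, floor((ctr - radius) / bw))
      hi <- min(nb[[cn]] - 1L, floor((ctr + radius) / bw))
      if (hi >= lo) m[(lo + 1L):(hi + 1L)] <- TRUE
    }
    m
  })
  names(mask) <- names(layout$chrom_lengths)
  mask
}

#' Origin-aware log2 enrichment normalization
#'
#' Accounts for the elevated background around replication origins caused
#' by ongoing DNA synthesis: the genome is partitioned into origin-proximal
#' bins (any bin intersecting `[center - radius, center + radius]` for any
#' origin) and the complement, and the simple normalization is applied
#' independently within each partition using partition-restricted library
#' totals. Absolute levels are therefore not comparable across the two
#' partitions.
#'
#' @inheritParams log2_enrichment
#' @param origins Origin annotation `data.frame` (`chrom`, `center`).
#' @return A `log2fc` [binned_track()].
#' @export
origin_aware_normalize <- function(ip, input, origins, cfg = norm_config()) {
  stopifnot(inherits(ip, "binned_track"), inherits(input, "binned_track"))
  check_same_layout(ip, input)
  if (nrow(origins) == 0)
    return(log2_enrichment(ip, input, cfg))
  prox <- origin_proximal_mask(ip$layout, origins, cfg$origin_radius)
  dist <- lapply(prox, `!`)
  v1 <- log2_ratio_masked(ip, input, prox, cfg$pseudocount, "origin-proximal")
  v2 <- log2_ratio_masked(ip, input, dist, cfg$pseudocount, "origin-distal")
  vals <- Map(function(a, b, m) ifelse(m, a, b), v1, v2, prox)
  binned_track(vals, ip$layout, kind = "log2fc")
}
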