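#' Strand-aware promoter window
#'
#' For scoring, the promoter is the 500-bp window upstream of the TSS; for
#' peak annotation it is extended 50 bp downstream. On the `+` strand the
#' window is `[tss - upstream, tss + downstream)`; on the `-` strand it is
#' mirrored to `[tss - downstream, tss + upstream)`. Windows are clipped at
#' chromosome bounds and flagged.
#'
#' @param tss TSS position(s), 0-based bp.
#' @param strand `"+"` or `"-"`, recycled.
#' @param chrom_length Chromosome length(s) in bp, recycled.
#' @param upstream,downstream Window extent in bp (defaults 500 and 0).
#' @return A `data.frame` with `start`, `end`, `clipped`.
#' @export
promoter_window <- function(tss, strand, chrom_length,
                            upstream = 500, downstream = 0) {
  n <- max(length(tss), length(strand), length(chrom_length))
  tss <- rep_len(tss, n); strand <- rep_len(strand, n)
  chrom_length <- rep_len(chrom_length, n)
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  cs <- pmax(start, 0); ce <- pmin(end, chrom_length)
  data.frame(start = cs, end = ce, clipped = cs != start | ce != end)
}

#' Promoter activity scores
#'
#' Per gene, the overlap-weighted mean of track values over its promoter
#' window (the per-25-bp-window fold changes summed and scaled by the
#' window size). Windows clipped at a chromosome edge are normalised by
#' the width actually covered; genes whose window vanishes entirely are
#' scored `NA` and reported via the `"missing"` attribute.
#'
#' @param track A `log2fc` [binned_track()].
#' @param genes Gene annotation `data.frame` (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param upstream,downstream Promoter extent in bp (defaults 500, 0).
#' @return A `data.frame` `gene_id`, `score`, `clipped`, with attribute
#'   `"missing"` listing unscorable genes.
#' @export
promoter_scores <- function(track, genes, upstream = 500, downstream = 0) {
  stopifnot(inherits(track, "binned_track"))
  win <- promoter_window(genes$tss, genes$strand,
                         track$layout$chrom_lengths[genes$chrom],
                         upstream, downstream)
  score <- window_mean(track, genes$chrom, win$start, win$end)
  out <- data.frame(gene_id = genes$gene_id, score = score,
                    clipped = win$clipped, stringsAsFactors = FALSE)
  missing <- out$gene_id[is.na(out$score)]
  if (length(missing))
    warning(sprintf("%d gene(s) with empty promoter window: %s",
                    length(missing), paste(missing, collapse = ", ")))
  attr(out, "missing") <- missing
  out
}

#' Empirical p-values for promoter binding
#'
#' The observed promoter score of each gene is compared against a null of
#' `n_null` windows of the same width placed uniformly at random on the
#' genome (positions drawn at bp resolution, kept fully inside
#' chromosomes). One-sided upper-tail with add-one correction:
#' `p = (1 + #[null >= obs]) / (1 + n_null)`.
#'
#' @inheritParams promoter_scores
#' @param n_null Number of null windows (>= 100).
#' @param seed Integer seed making the null draw reproducible.
#' @param alpha Significance level for the reported significant count.
#' @return A `data.frame` `gene_id`, `score`, `p`, with attributes
#'   `"n_significant"` and `"alpha"`.
#' @export
empirical_promoter_p <- function(track, genes, upstream = 500,
                                 n_null = 10000, seed = 1, alpha = 0.05) {
  if (n_null < 100) stop("n_null must be >= 100")
  lens <- track$layout$chrom_lengths
  ok <- lens >= upstream
  if (!any(ok)) stop("genome shorter than the promoter window")
  obs <- promoter_scores(track, genes, upstream = upstream, downstream = 0)
  null_scores <- with_seed(seed, {
    w <- (lens - upstream)[ok]
    chrom <- sample(names(lens)[ok], n_null, replace = TRUE,
                    prob = (w + 1) / sum(w + 1))
    start <- floor(stats::runif(n_null) * (lens[chrom] - upstream + 1))
    window_mean(track, chrom, start, start + upstream)
  })
  p <- vapply(obs$score, function(s) {
    if (is.na(s)) return(NA_real_)
    (1 + sum(null_scores >= s)) / (1 + n_null)
  }, 0)
  out <- data.frame(gene_id = obs$gene_id, score = obs$score, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "n_significant") <- sum(p <= alpha, na.rm = TRUE)
  attr(out, "alpha") <- alpha
  out
}

#' Lorenz curve and Gini index of binding specificity
#'
#' Quantifies how concentrated a nonnegative per-promoter signal is across
#' genes: values are sorted ascending, the Lorenz curve is the cumulative
#' share of signal against the cumulative share of genes, and the Gini
#' index is one minus twice the trapezoidal area under the curve. This
#' equals half the relative mean absolute difference,
#' `sum|xi - xj| / (2 n^2 mean)`. A factor binding a small set of
#' promoters strongly (a sequence-specific TF) scores high; a broadly
#' distributed binder scores low.
#'
#' @param values Nonnegative per-gene signal (length >= 2, not all zero).
#' @return A list of class `lorenz_result`: `x`, `y` (curve points from
#'   (0,0) to (1,1)) and `gini`.
#' @export
lorenz_gini <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(values < 0)) stop("values must be nonnegative")
  tot <- sum(values)
  if (tot == 0) stop("Gini undefined for all-zero input")
  v <- sort(values)
  n <- length(v)
  x <- c(0, seq_len(n) / n)
  y <- c(0, cumsum(v) / tot)
  area <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  structure(list(x = x, y = y, gini = 1 - 2 * area), class = "lorenz_result")
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat("Lorenz curve over", length(x$x) - 1, "units; Gini =",
      format(x$gini, digits = 4), "\n")
  invisible(x)
}

#' Annotate peaks relative to promoters
#'
#' Labels each peak `promoter` if it intersects any strand-aware
#' promoter window (default -500/+50 bp around the TSS), else `gene body`
#' if gene extents are annotated (an `end` column in `genes`) and the peak
#' intersects one, else `other`. Precedence is promoter > gene body >
#' other for peaks spanning both.
#'
#' @param peaks Interval `data.frame` (`chrom`, `start`, `end`), 0-based
#'   half-open; must be non-empty.
#' @param genes Gene annotation; gene-body calls require an `end` column
#'   giving the gene end (bp beyond the TSS-side start).
#' @param layout A [genome_layout()].
#' @param upstream,downstream Promoter extent around the TSS (500/50).
#' @return A `data.frame` of peaks with a `category` column; attribute
#'   `"promoter_fraction"` is the fraction of peaks labelled promoter.
#' @export
annotate_peaks <- function(peaks, genes, layout, upstream = 500,
                           downstream = 50) {
  if (nrow(peaks) == 0) stop("promoter fraction undefined: no peaks")
  win <- promoter_window(genes$tss, genes$strand,
                         layout$chrom_lengths[genes$chrom],
                         upstream, downstream)
  win$chrom <- genes$chrom
  has_body <- "end" %in% names(genes)
  if (has_body) {
    body_start <- pmin(genes$tss, genes$end)
    body_end <- pmax(genes$tss, genes$end)
  }
  category <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- win$chrom == peaks$chrom[i]
    hit <- same & win$start < peaks$end[i] & win$end > peaks$start[i]
    if (any(hit)) return("promoter")
    if (has_body) {
      gsame <- genes$chrom == peaks$chrom[i]
      ghit <- gsame & body_start < peaks$end[i] & body_end > peaks$start[i]
      if (any(ghit)) return("gene body")
    }
    "other"
  }, "")
  out <- cbind(peaks, category = category)
  attr(out, "promoter_fraction") <- mean(category == "promoter")
  out
}
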