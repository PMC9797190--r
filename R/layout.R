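#' Genome layout: chromosome lengths and a fixed bin width
#'
#' A `genome_layout` fixes the coordinate system for every track and
#' annotation in the pipeline: an ordered set of chromosomes with lengths in
#' bp, and the bin width at which coverage tracks are stored (25 bp by
#' default, the resolution at which enrichment is computed per window).
#' All coordinates in the package are 0-based, half-open.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_width Bin width in bp (default 25).
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 10000, chr2 = 5000))
#' @export
genome_layout <- function(chrom_lengths, bin_width = 25) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names in layout")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number")
  structure(
    list(chrom_lengths = chrom_lengths, bin_width = as.numeric(bin_width)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_lengths), "chromosome(s),",
      "bin width", x$bin_width, "bp, total",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  invisible(x)
}

## number of bins per chromosome: ceil(len / bin_width)
layout_n_bins <- function(layout) {
  as.integer(ceiling(layout$chrom_lengths / layout$bin_width))
}

#' Binned genome signal track
#'
#' Fixed-bin-width per-chromosome value vectors, the carrier for raw counts,
#' log2 IP/input enrichment, or replication-incorporation (EdU) signal.
#'
#' @param values Named list of numeric vectors, one per chromosome of
#'   `layout`, with `ceiling(length / bin_width)` entries each.
#' @param layout A [genome_layout()].
#' @param kind Value semantics: `"counts"` (nonnegative), `"log2fc"`
#'   (finite), or `"edu"` (nonnegative).
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, layout, kind = c("counts", "log2fc", "edu")) {
  kind <- match.arg(kind)
  stopifnot(inherits(layout, "genome_layout"))
  nb <- layout_n_bins(layout)
  chroms <- names(layout$chrom_lengths)
  if (!setequal(names(values), chroms))
    stop("track chromosomes do not match layout")
  values <- values[chroms]
  for (i in seq_along(chroms)) {
    v <- values[[i]]
    if (length(v) != nb[i])
      stop(sprintf("track '%s' has %d bins, layout requires %d",
                   chroms[i], length(v), nb[i]))
    if (kind %in% c("counts", "edu") && any(v < 0, na.rm = TRUE))
      stop(sprintf("negative %s values on '%s'", kind, chroms[i]))
    if (kind == "log2fc" && any(!is.finite(v)))
      stop(sprintf("non-finite log2fc values on '%s'", chroms[i]))
  }
  structure(list(values = values, layout = layout, kind = kind),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track [", x$kind, "]: ", length(x$values),
      " chromosome(s), ", sum(lengths(x$values)), " bins of ",
      x$layout$bin_width, " bp\n", sep = "")
  invisible(x)
}

check_same_layout <- function(a, b) {
  la <- a$layout; lb <- b$layout
  if (la$bin_width != lb$bin_width ||
      !identical(la$chrom_lengths, lb$chrom_lengths))
    stop("tracks do not share a genome layout")
  invisible(TRUE)
}

## Windowed integrals over a binned track.
##
## For one chromosome's bin values, returns the integral of the step
## function over [0, p) for each position p, where the last bin may be
## truncated by the chromosome end. O(1) per query after one cumsum.
track_integral_fun <- function(values, bin_width, chrom_length) {
  n <- length(values)
  starts <- (seq_len(n) - 1) * bin_width
  widths <- pmin(bin_width, chrom_length - starts)
  cum <- c(0, cumsum(values * widths))
  function(p) {
    p <- pmin(pmax(p, 0), chrom_length)
    k <- pmin(floor(p / bin_width), n - 1)
    frac <- pmin(p - k * bin_width, widths[k + 1])
    cum[k + 1] + values[k + 1] * frac
  }
}

## Overlap-weighted window sums over a track, vectorised over windows.
## Returns per-window: the integral of the track over the in-chromosome
## part of [start, end), and the covered width in bp.
window_sums <- function(track, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  out_sum <- numeric(length(start))
  covered <- numeric(length(start))
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    v <- track$values[[cn]]
    if (is.null(v)) stop(sprintf("chromosome '%s' absent from track", cn))
    L <- track$layout$chrom_lengths[[cn]]
    I <- track_integral_fun(v, track$layout$bin_width, L)
    s <- pmax(start[idx], 0); e <- pmin(end[idx], L)
    w <- pmax(e - s, 0)
    out_sum[idx] <- ifelse(w > 0, I(e) - I(s), 0)
    covered[idx] <- w
  }
  list(sum = out_sum, covered = covered)
}

## Overlap-weighted mean over the covered part of each window (clipped
## windows are normalised by the width actually covered). NA if nothing
## is covered.
window_mean <- function(track, chrom, start, end) {
  ws <- window_sums(track, chrom, start, end)
  ifelse(ws$covered > 0, ws$sum / ws$covered, NA_real_)
}
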