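#' Metagene signal matrix around anchors
#'
#' Rows are anchors (TSSs or origin centers), columns flank bins of width
#' `bin` spanning `[anchor - flank, anchor + flank)`. Each entry is the
#' overlap-weighted mean of the track over its bin, with portions outside
#' the chromosome contributing 0 at full weight (the `w0` averaging
#' dialect: missing data count as zero, they are not dropped). With
#' `strand_aware = TRUE` rows of `-` strand anchors are reversed so that
#' upstream is always on the left; origin matrices should never be
#' strand-aware.
#'
#' @param track A [binned_track()].
#' @param anchors `data.frame` with `chrom`, a position column (`tss` or
#'   `center`), an id column (`gene_id` or `origin_id`), and `strand` when
#'   `strand_aware`.
#' @param flank Half-window in bp; must be a multiple of `bin`.
#' @param bin Column bin width in bp (default 25).
#' @param strand_aware Reverse rows of `-` strand anchors.
#' @return A numeric matrix of class `signal_matrix` (anchors x bins) with
#'   row names from the id column; attributes `flank`, `bin`.
#' @export
signal_matrix <- function(track, anchors, flank, bin = 25,
                          strand_aware = FALSE) {
  stopifnot(inherits(track, "binned_track"))
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  pos_col <- intersect(c("tss", "center", "pos"), names(anchors))[1]
  if (is.na(pos_col)) stop("anchors need a 'tss', 'center' or 'pos' column")
  id_col <- intersect(c("gene_id", "origin_id", "id"), names(anchors))[1]
  ids <- if (!is.na(id_col)) anchors[[id_col]] else
    paste0("anchor", seq_len(nrow(anchors)))
  ncol <- as.integer(2 * flank / bin)
  n <- nrow(anchors)
  offsets <- (seq_len(ncol) - 1) * bin - flank
  chrom <- rep(anchors$chrom, each = ncol)
  start <- rep(anchors[[pos_col]], each = ncol) + rep(offsets, n)
  ws <- window_sums(track, chrom, start, start + bin)
  m <- matrix(ws$sum / bin, nrow = n, ncol = ncol, byrow = TRUE,
              dimnames = list(ids, NULL))
  if (strand_aware) {
    if (!"strand" %in% names(anchors))
      stop("strand_aware requires a strand column")
    neg <- anchors$strand == "-"
    m[neg, ] <- m[neg, ncol:1, drop = FALSE]
  }
  structure(m, flank = flank, bin = bin, class = c("signal_matrix", "matrix"))
}

#' Column-wise average profile of a signal matrix
#'
#' @param m A [signal_matrix()] (or any matrix) with at least one row.
#' @return Numeric vector of per-column means.
#' @export
average_profile <- function(m) {
  if (nrow(m) == 0) stop("empty signal matrix")
  colMeans(unclass(m))
}

#' Order signal-matrix rows by an external key
#'
#' Stable sort of rows by a per-anchor key — replication timing for origin
#' matrices (ascending), or expression log2FC for TSS matrices (use
#' `decreasing = TRUE`), optionally within blocks (e.g. coexpression
#' clusters) whose boundaries are preserved. Missing keys sort last
#' within their block.
#'
#' @param m A [signal_matrix()].
#' @param key Numeric vector, one value per row (in row order).
#' @param decreasing Sort descending within blocks.
#' @param blocks Optional block labels, one per row; block order follows
#'   first appearance.
#' @return The reordered matrix.
#' @export
order_rows <- function(m, key, decreasing = FALSE, blocks = NULL) {
  if (length(key) != nrow(m)) stop("one key per row required")
  k <- if (decreasing) -xtfrm(key) else xtfrm(key)
  if (is.null(blocks)) {
    ord <- order(k, na.last = TRUE)
  } else {
    if (length(blocks) != nrow(m)) stop("one block label per row required")
    b <- match(blocks, unique(blocks))
    ord <- order(b, k, na.last = TRUE)
  }
  out <- m[ord, , drop = FALSE]
  attributes(out)$flank <- attr(m, "flank")
  attributes(out)$bin <- attr(m, "bin")
  class(out) <- class(m)
  out
}
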