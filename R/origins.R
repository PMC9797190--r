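#' Per-origin replication (EdU) signal
#'
#' Mean track value over `[center - window, center + window)`, clipped at
#' chromosome edges and normalised by the covered width — the per-origin
#' statistic thresholded by [classify_origins()]. The default +/- 2.5 kb
#' window sits well inside the ~10 kb fork extent under replication
#' stress, averaging out bin noise.
#'
#' @param track An `edu` [binned_track()].
#' @param origins Origin `data.frame` (`origin_id`, `chrom`, `center`).
#' @param window Half-width in bp (default 2500).
#' @return Named numeric vector of per-origin scores.
#' @export
origin_edu_score <- function(track, origins, window = 2500) {
  stopifnot(inherits(track, "binned_track"))
  s <- window_mean(track, origins$chrom, origins$center - window,
                   origins$center + window)
  names(s) <- origins$origin_id
  s
}

#' Classify origins as early, late, or inactive
#'
#' An origin is *early* if its replication signal in wild type at the
#' first timepoint under replication stress (HU45) exceeds the threshold
#' (fires despite an intact checkpoint); otherwise *late* if the average
#' of its later-timepoint (HU90) signals across checkpoint-deficient
#' mutants exceeds the threshold (fires only when the checkpoint fails;
#' with `late_rule = "all"` every mutant must individually exceed it);
#' otherwise *inactive*. Early and late origins together are the active
#' set.
#'
#' @param wt_first Named per-origin scores, wild type, first timepoint.
#' @param mutant_later Named list (one element per checkpoint-deficient
#'   genotype) of per-origin scores at the later timepoint.
#' @param threshold Signal threshold (default 2).
#' @param late_rule `"mean"` (default; threshold on the mutant average) or
#'   `"all"` (threshold in each mutant separately).
#' @return A list of class `origin_classification`: `class` (named factor
#'   early/late/inactive), `scores` (matrix of inputs), `threshold`;
#'   `active` gives the active origin ids.
#' @export
classify_origins <- function(wt_first, mutant_later, threshold = 2,
                             late_rule = c("mean", "all")) {
  late_rule <- match.arg(late_rule)
  if (!length(mutant_later)) stop("need at least one mutant genotype")
  ids <- names(wt_first)
  if (is.null(ids)) stop("scores must be named by origin id")
  for (g in names(mutant_later)) {
    miss <- setdiff(ids, names(mutant_later[[g]]))
    if (length(miss) || length(mutant_later[[g]]) != length(ids))
      stop(sprintf("origin universe mismatch for genotype '%s'", g))
  }
  mut <- do.call(cbind, lapply(mutant_later, function(s) s[ids]))
  early <- wt_first > threshold
  late_stat <- if (late_rule == "mean") rowMeans(mut) else
    apply(mut, 1, min)
  late <- !early & late_stat > threshold
  cls <- ifelse(early, "early", ifelse(late, "late", "inactive"))
  cls <- factor(cls, levels = c("early", "late", "inactive"))
  names(cls) <- ids
  structure(list(class = cls,
                 scores = cbind(wt_first = wt_first[ids], mut),
                 threshold = threshold,
                 active = ids[cls != "inactive"]),
            class = "origin_classification")
}

#' @export
print.origin_classification <- function(x, ...) {
  tb <- table(x$class)
  cat(sprintf(
    "origin_classification: %d origins (%d active: %d early, %d late; %d inactive), threshold %g\n",
    length(x$class), length(x$active), tb[["early"]], tb[["late"]],
    tb[["inactive"]], x$threshold))
  invisible(x)
}

#' Assign replication timing to origins
#'
#' From per-window (default 1-kb) replication-timing values, each origin
#' receives the timing of the window whose center is closest to the origin
#' center, provided the distance is no more than `max_dist`; otherwise
#' timing is missing. Equidistant windows resolve to the lower coordinate.
#'
#' @param origins Origin `data.frame` (`origin_id`, `chrom`, `center`).
#' @param timing `data.frame` with `chrom`, `center` (window center, bp)
#'   and `timing` (minutes).
#' @param max_dist Maximum assignment distance in bp (default 5000).
#' @return Named numeric vector of timings (NA where unassigned).
#' @export
assign_timing <- function(origins, timing, max_dist = 5000) {
  out <- rep(NA_real_, nrow(origins))
  names(out) <- origins$origin_id
  for (cn in unique(origins$chrom)) {
    tw <- timing[timing$chrom == cn, , drop = FALSE]
    if (!nrow(tw)) next
    tw <- tw[order(tw$center), , drop = FALSE]
    oi <- which(origins$chrom == cn)
    for (i in oi) {
      d <- abs(tw$center - origins$center[i])
      j <- which(d == min(d))[1]  # ties: lower coordinate (sorted)
      if (d[j] <= max_dist) out[i] <- tw$timing[j]
    }
  }
  out
}

#' Remove blacklisted origins
#'
#' Drops origins whose center point (`[center, center + 1)`, optionally
#' padded) intersects any blacklist interval — e.g. hyper-ChIPable
#' regions enriched in ChIP regardless of antibody. Half-open semantics:
#' a center touching an interval end is retained.
#'
#' @param origins Origin `data.frame`.
#' @param blacklist Interval `data.frame` (`chrom`, `start`, `end`).
#' @param pad Padding in bp around the center point (default 0).
#' @return The retained rows of `origins`.
#' @export
filter_blacklist <- function(origins, blacklist, pad = 0) {
  if (!nrow(blacklist) || !nrow(origins)) return(origins)
  drop <- vapply(seq_len(nrow(origins)), function(i) {
    b <- blacklist[blacklist$chrom == origins$chrom[i], , drop = FALSE]
    any(b$start < origins$center[i] + 1 + pad &
          b$end > origins$center[i] - pad)
  }, TRUE)
  origins[!drop, , drop = FALSE]
}
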