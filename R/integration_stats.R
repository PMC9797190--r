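#' A 2x2 contingency table
#'
#' Cell `a` counts units both in the selection and in the gene set of
#' interest; `b` and `c` the off-diagonal memberships; `d` the remainder.
#'
#' @param a,b,c,d Nonnegative integer counts, total > 0.
#' @return A list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (sum(cells) == 0) stop("empty contingency table")
  structure(as.list(cells), class = "contingency_2x2")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed one — the classical
#' convention. The reported odds ratio is the sample odds ratio
#' `ad / bc` (may be `Inf`), not the conditional MLE.
#'
#' @param t A [contingency_2x2()].
#' @param sided `"two"` or `"greater"` (upper tail on cell `a`).
#' @return A list: `p`, `odds_ratio`, `table`.
#' @export
fisher_exact_2x2 <- function(t, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  stopifnot(inherits(t, "contingency_2x2"))
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate margins: a zero row or column total")
  alt <- if (sided == "two") "two.sided" else "greater"
  p <- stats::fisher.test(m, alternative = alt)$p.value
  or <- (t$a * t$d) / (t$b * t$c)
  list(p = p, odds_ratio = or, table = t)
}

#' Transcription-factor target enrichment in a gene selection
#'
#' Tests whether a TF's annotated target genes are over-represented in a
#' selection (e.g. the DB/DEG set) relative to the genome universe, by an
#' upper-tail Fisher's exact test. Also reports the target frequency
#' inside the selection and in the background, in percent.
#'
#' @param universe Size of the gene universe (explicit, never inferred).
#' @param targets Character vector of TF target gene ids (within the
#'   universe).
#' @param selection Non-empty character vector of selected gene ids.
#' @return A list of class `tf_enrichment`: `table`
#'   ([contingency_2x2()]), `overlap`, `freq_selection_pct`,
#'   `freq_background_pct`, `p`, `odds_ratio`.
#' @export
tf_enrichment <- function(universe, targets, selection) {
  if (!length(selection)) stop("empty selection")
  targets <- unique(targets); selection <- unique(selection)
  if (length(targets) > universe || length(selection) > universe)
    stop("targets/selection larger than the universe")
  a <- length(intersect(targets, selection))
  b <- length(targets) - a
  c <- length(selection) - a
  d <- universe - a - b - c
  tb <- contingency_2x2(a, b, c, d)
  ft <- fisher_exact_2x2(tb, sided = "greater")
  structure(list(table = tb, overlap = a,
                 freq_selection_pct = 100 * a / length(selection),
                 freq_background_pct = 100 * length(targets) / universe,
                 p = ft$p, odds_ratio = ft$odds_ratio),
            class = "tf_enrichment")
}

#' @export
print.tf_enrichment <- function(x, ...) {
  cat(sprintf(
    "tf_enrichment: %d/%d selected are targets (%.2f%% vs %.2f%% background), Fisher p = %.3g\n",
    x$overlap, x$table$a + x$table$c, x$freq_selection_pct,
    x$freq_background_pct, x$p))
  invisible(x)
}

#' Correlation of binding changes with expression changes
#'
#' Spearman rank correlation between per-gene DB residuals and expression
#' log2 fold changes over the shared gene set; average ranks on ties,
#' exact p for n <= 10, t-approximation otherwise.
#'
#' @param residuals Named numeric vector of DB residuals.
#' @param log2fc Named numeric vector of expression log2FC.
#' @return A list: `r`, `p`, `n`.
#' @export
db_de_correlation <- function(residuals, log2fc) {
  shared <- intersect(names(residuals), names(log2fc))
  if (length(shared) < 3) stop("need at least 3 shared genes")
  ct <- suppressWarnings(
    stats::cor.test(residuals[shared], log2fc[shared], method = "spearman",
                    exact = length(shared) <= 10))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Association between binding and expression direction
#'
#' 2x2 table of DB direction (up/down) against DE direction (up/down)
#' over shared genes, with a two-sided Fisher's exact test. A zero margin
#' (e.g. no down-DB gene) is an error naming the margin.
#'
#' @param db_direction,de_direction Named character vectors with values
#'   `"up"`/`"down"`.
#' @return A list: `table` ([contingency_2x2()]), `p`, `odds_ratio`.
#' @export
db_de_association <- function(db_direction, de_direction) {
  shared <- intersect(names(db_direction), names(de_direction))
  db <- db_direction[shared]; de <- de_direction[shared]
  keep <- db %in% c("up", "down") & de %in% c("up", "down")
  db <- db[keep]; de <- de[keep]
  if (!length(db)) stop("no shared genes with up/down directions")
  margins <- c("DB up" = sum(db == "up"), "DB down" = sum(db == "down"),
               "DE up" = sum(de == "up"), "DE down" = sum(de == "down"))
  zero <- names(margins)[margins == 0]
  if (length(zero))
    stop(sprintf("zero margin: %s", paste(zero, collapse = ", ")))
  tb <- contingency_2x2(sum(db == "up" & de == "up"),
                        sum(db == "up" & de == "down"),
                        sum(db == "down" & de == "up"),
                        sum(db == "down" & de == "down"))
  ft <- fisher_exact_2x2(tb, sided = "two")
  list(table = tb, p = ft$p, odds_ratio = ft$odds_ratio)
}

#' Naive differential expression surrogate
#'
#' A deliberately simple DE caller used where an external engine's table
#' is not supplied: median-of-ratios size factors (geometric-mean
#' reference over samples, genes with a zero reference excluded from the
#' factor computation), per-condition means of normalized counts, and
#' `log2FC = log2((mean_B + 1) / (mean_A + 1))`. A gene is flagged
#' significant when `|log2FC| >= lfc_threshold`. No dispersion modelling
#' or testing is performed; outputs carry a `surrogate` marker, and
#' externally computed DE tables are accepted everywhere this output is.
#'
#' @param counts Integer matrix, genes x samples, with row and column
#'   names.
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels; fold change is level 2 over level 1.
#' @param lfc_threshold Absolute log2FC cutoff for the significance flag
#'   (default 1).
#' @return A `data.frame` of class `de_result`: `gene_id`, `base_mean`,
#'   `log2fc`, `significant`, `direction` (`up`/`down`/`ns`); attributes
#'   `"size_factors"`, `"excluded"` (all-zero genes), `"surrogate" = TRUE`.
#' @export
naive_de <- function(counts, condition, lfc_threshold = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(colSums(counts) == 0)) stop("sample with zero total counts")
  condition <- as.factor(condition)
  if (nlevels(condition) != 2 || length(condition) != ncol(counts))
    stop("condition must give exactly two levels across the samples")
  all_zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[all_zero]
  work <- counts[!all_zero, , drop = FALSE]
  log_geo <- rowMeans(log(work))
  use <- is.finite(log_geo)  # genes with any zero drop out of the reference
  if (!any(use)) stop("no gene usable for size-factor estimation")
  sf <- apply(work[use, , drop = FALSE], 2, function(col)
    stats::median(col / exp(log_geo[use])))
  norm <- sweep(work, 2, sf, "/")
  ma <- rowMeans(norm[, condition == levels(condition)[1], drop = FALSE])
  mb <- rowMeans(norm[, condition == levels(condition)[2], drop = FALSE])
  lfc <- log2((mb + 1) / (ma + 1))
  sig <- abs(lfc) >= lfc_threshold
  out <- data.frame(gene_id = rownames(work),
                    base_mean = (ma + mb) / 2, log2fc = lfc,
                    significant = sig,
                    direction = ifelse(!sig, "ns",
                                       ifelse(lfc > 0, "up", "down")),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "size_factors") <- sf
  attr(out, "excluded") <- excluded
  attr(out, "surrogate") <- TRUE
  class(out) <- c("de_result", class(out))
  out
}
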