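#' Scale promoter scores to unit maximum
#'
#' Divides every score by the sample's maximum, so the minimal-signal
#' filter threshold (-0.075 by default elsewhere) is expressed on a scale
#' where the strongest promoter is 1. Scaling is per sample.
#'
#' @param scores Numeric vector of per-gene scores; the maximum must be
#'   positive.
#' @return Scaled scores (negatives preserved).
#' @export
scale_to_unit_max <- function(scores) {
  m <- max(scores, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("cannot scale: maximum score is not > 0")
  scores / m
}

#' Regression-residual differential binding
#'
#' Overall promoter activity differs between timepoints for batch reasons
#' (protein levels, IP efficiency), so raw score differences are not
#' comparable. An ordinary least squares line of the later-timepoint
#' scores (`y`, e.g. HU45) on the G1 scores (`x`) over all genes captures
#' that global trend; each gene's residual `y - (a + b x)` measures its
#' deviation from it, i.e. its differential (dynamic) binding.
#'
#' @param x,y Named-by-gene or plain numeric score vectors (G1 and HU);
#'   equal length >= 3, `x` not constant.
#' @param gene_id Gene identifiers (defaults to `names(x)`).
#' @return A list of class `db_fit`: `slope`, `intercept`, and `table`, a
#'   `data.frame` with `gene_id`, `x`, `y`, `fitted`, `residual`,
#'   `abs_rank` (1 = largest `|residual|`, ties broken by gene id) and
#'   `direction` (sign of the residual).
#' @export
fit_db_regression <- function(x, y, gene_id = names(x)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 genes")
  if (is.null(gene_id)) gene_id <- paste0("g", seq_along(x))
  if (stats::sd(x) == 0) stop("singular fit: x scores are constant")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  fitted <- co[[1]] + co[[2]] * x
  res <- y - fitted
  ord <- order(-abs(res), gene_id)
  abs_rank <- integer(length(res))
  abs_rank[ord] <- seq_along(res)
  tab <- data.frame(gene_id = gene_id, x = x, y = y, fitted = fitted,
                    residual = res, abs_rank = abs_rank,
                    direction = sign(res), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(slope = co[[2]], intercept = co[[1]], table = tab),
            class = "db_fit")
}

#' @export
print.db_fit <- function(x, ...) {
  cat(sprintf("db_fit: %d genes, y = %.4g + %.4g x\n",
              nrow(x$table), x$intercept, x$slope))
  invisible(x)
}

#' Select top differentially bound genes
#'
#' Genes whose unit-max-scaled score falls below `min_signal` in either
#' compared sample are excluded (conservative low-signal filter), the
#' remainder are ranked by absolute residual descending (ties broken by
#' gene id, lexicographic), and the first `K` are returned.
#'
#' @param fit A [fit_db_regression()] result.
#' @param scaled_x,scaled_y Unit-max-scaled scores (see
#'   [scale_to_unit_max()]), in `fit$table` gene order.
#' @param K Number of genes to select (default 1000).
#' @param min_signal Scaled-score floor (default -0.075).
#' @return A list of class `db_selection`: `genes` (ordered top-K ids),
#'   `table` (their rows of the residual table, with `passes_filter` for
#'   all genes retained in the `full` element), `K`, `min_signal`.
#' @export
select_top_db <- function(fit, scaled_x, scaled_y, K = 1000,
                          min_signal = -0.075) {
  stopifnot(inherits(fit, "db_fit"))
  if (K <= 0) stop("K must be positive")
  tab <- fit$table
  if (length(scaled_x) != nrow(tab) || length(scaled_y) != nrow(tab))
    stop("scaled scores must match the residual table")
  tab$passes_filter <- scaled_x >= min_signal & scaled_y >= min_signal
  kept <- tab[tab$passes_filter, , drop = FALSE]
  kept <- kept[order(-abs(kept$residual), kept$gene_id), , drop = FALSE]
  sel <- utils::head(kept, K)
  structure(list(genes = sel$gene_id, table = sel, full = tab, K = K,
                 min_signal = min_signal),
            class = "db_selection")
}

#' @export
print.db_selection <- function(x, ...) {
  cat(sprintf("db_selection: %d of top-%d genes (min scaled signal %.3g)\n",
              length(x$genes), x$K, x$min_signal))
  invisible(x)
}

#' Intersect two top-DB selections
#'
#' Genes called in both experiments, ordered by the worse (maximum) of
#' their two within-selection ranks — the reproducible DB set.
#'
#' @param sel_a,sel_b [select_top_db()] results.
#' @return Character vector of shared gene ids.
#' @export
intersect_top_db <- function(sel_a, sel_b) {
  stopifnot(inherits(sel_a, "db_selection"), inherits(sel_b, "db_selection"))
  common <- intersect(sel_a$genes, sel_b$genes)
  if (!length(common)) return(character())
  ra <- match(common, sel_a$genes)
  rb <- match(common, sel_b$genes)
  common[order(pmax(ra, rb), common)]
}

#' Group test on differential-binding residuals
#'
#' Standardizes residuals to Z-scores over all genes and compares a gene
#' group (e.g. SBF targets) against the rest by a two-sided Wilcoxon
#' rank-sum test (exact when the combined size is at most 30, normal
#' approximation with continuity correction otherwise).
#'
#' @param fit A [fit_db_regression()] result.
#' @param group Character vector of gene ids; non-empty, proper subset.
#' @return A list: `z` (named Z-scores for all genes), `in_group` logical,
#'   `p` (Wilcoxon two-sided), `group_median_z`, `rest_median_z`.
#' @export
db_group_test <- function(fit, group) {
  stopifnot(inherits(fit, "db_fit"))
  tab <- fit$table
  in_group <- tab$gene_id %in% group
  if (!any(in_group)) stop("group contains no annotated genes")
  if (all(in_group)) stop("group must be a proper subset of all genes")
  s <- stats::sd(tab$residual)
  if (s == 0) stop("Z-scores undefined: residuals have zero variance")
  z <- (tab$residual - mean(tab$residual)) / s
  names(z) <- tab$gene_id
  n <- nrow(tab)
  wt <- stats::wilcox.test(z[in_group], z[!in_group],
                           alternative = "two.sided",
                           exact = n <= 30, correct = TRUE)
  list(z = z, in_group = in_group, p = wt$p.value,
       group_median_z = stats::median(z[in_group]),
       rest_median_z = stats::median(z[!in_group]))
}
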