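# Fixtures are built in code: tiny layouts, tracks and annotations, plus
# independent oracles used to freeze expected values.

toy_layout <- function(lens = c(chr1 = 1000), bw = 25) {
  genome_layout(lens, bin_width = bw)
}

const_track <- function(value, layout, kind = "log2fc") {
  nb <- ceiling(layout$chrom_lengths / layout$bin_width)
  vals <- lapply(nb, function(n) rep(value, n))
  names(vals) <- names(layout$chrom_lengths)
  binned_track(vals, layout, kind = kind)
}

track_from <- function(values, layout, kind = "counts") {
  if (!is.list(values)) values <- stats::setNames(list(values),
                                                  names(layout$chrom_lengths)[1])
  binned_track(values, layout, kind = kind)
}

make_genes <- function(tss, strand = "+", chrom = "chr1",
                       id = sprintf("g%03d", seq_along(tss))) {
  data.frame(gene_id = id, chrom = chrom, tss = tss,
             strand = rep_len(strand, length(tss)), stringsAsFactors = FALSE)
}

make_origins <- function(center, chrom = "chr1", class = NA_character_,
                         id = sprintf("ori%03d", seq_along(center))) {
  data.frame(origin_id = id, chrom = rep_len(chrom, length(center)),
             center = center, class = rep_len(class, length(center)),
             stringsAsFactors = FALSE)
}

## --- independent oracles -------------------------------------------------

## Gini as half the relative mean absolute difference: sum|xi-xj|/(2 n^2 mu)
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

## Spearman for tie-free inputs via 1 - 6 sum(d^2) / (n(n^2-1))
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## closed-form OLS of y on x
ols_closed_form <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  list(slope = b, intercept = a, residuals = y - (a + b * x))
}

## Fisher two-sided p by full enumeration over the conditional
## distribution (log-binomial coefficients; no dhyper, no fisher.test)
fisher_enum_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[x == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

## mean promoter IP count for a gene in a track list (counts kind)
promoter_count_mean <- function(track, gene) {
  w <- promoter_window(gene$tss, gene$strand,
                       track$layout$chrom_lengths[gene$chrom])
  window_mean <- getFromNamespace("window_mean", "dynbind")
  window_mean(track, gene$chrom, w$start, w$end)
}
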