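#' Read a bedGraph file onto a genome layout
#'
#' Records are resampled onto the layout's fixed-width bins by
#' coverage-weighted mean, with uncovered positions treated as value 0
#' (coverage semantics). Input intervals must not overlap; records may be
#' unsorted. Coordinates are 0-based, half-open (bedGraph native).
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @param layout A [genome_layout()].
#' @param kind Value semantics for the resulting track (default `"counts"`
#'   for raw coverage; use `"log2fc"` for enrichment tracks).
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, layout, kind = "counts") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  bad <- setdiff(unique(df$chrom), names(layout$chrom_lengths))
  if (length(bad))
    stop(sprintf("bedGraph chromosome(s) absent from layout: %s",
                 paste(bad, collapse = ", ")))
  if (any(df$end <= df$start))
    stop("bedGraph records with end <= start")
  if (any(df$end > layout$chrom_lengths[df$chrom]))
    stop("bedGraph records extend beyond chromosome bounds")
  bw <- layout$bin_width
  nb <- layout_n_bins(layout)
  names(nb) <- names(layout$chrom_lengths)
  values <- lapply(names(layout$chrom_lengths), function(cn) {
    sub <- df[df$chrom == cn, , drop = FALSE]
    acc <- numeric(nb[[cn]])
    if (nrow(sub)) {
      sub <- sub[order(sub$start), , drop = FALSE]
      if (any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop(sprintf("overlapping bedGraph intervals on '%s'", cn))
      b0 <- floor(sub$start / bw)
      b1 <- floor((sub$end - 1) / bw)
      nspan <- b1 - b0 + 1
      bins <- rep(b0, nspan) + sequence(nspan) - 1
      starts <- rep(sub$start, nspan)
      ends <- rep(sub$end, nspan)
      vals <- rep(sub$value, nspan)
      ov <- pmin(ends, (bins + 1) * bw) - pmax(starts, bins * bw)
      L <- layout$chrom_lengths[[cn]]
      eff <- pmin(bw, L - bins * bw)  # last bin may be truncated
      # weight by the fraction of each bin covered; a fully covered bin
      # contributes its value exactly (bit-identical round trips)
      sums <- rowsum(vals * (ov / eff), bins)
      idx <- as.integer(rownames(sums)) + 1L
      acc[idx] <- sums[, 1]
    }
    acc
  })
  names(values) <- names(layout$chrom_lengths)
  binned_track(values, layout, kind = kind)
}

#' Write a binned track as bedGraph
#'
#' Consecutive equal-valued bins are merged into one record and zero runs
#' are omitted (gaps read back as 0). Output is 0-based half-open, tab
#' separated, LF line endings, full precision (round-trips exactly for
#' bin-aligned data).
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  bw <- track$layout$bin_width
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    L <- track$layout$chrom_lengths[[cn]]
    r <- rle(v)
    endbin <- cumsum(r$lengths)
    startbin <- endbin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    lines <- sprintf("%s\t%.17g\t%.17g\t%.17g", cn,
                     startbin[keep] * bw, pmin(endbin[keep] * bw, L),
                     r$values[keep])
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

stop_with_rows <- function(msg, rows) {
  stop(sprintf("%s (line%s %s)", msg, if (length(rows) > 1) "s" else "",
               paste(rows, collapse = ", ")), call. = FALSE)
}

#' Read a gene annotation table
#'
#' Tab-separated with header; required columns `gene_id`, `chrom`, `tss`
#' (0-based bp), `strand` (`+`/`-`); optional `tf_labels` (comma-separated
#' transcription-factor target labels), `cluster` (coexpression cluster
#' label), and `end` (gene end, enabling gene-body peak annotation).
#' Invalid rows are reported with their line numbers.
#'
#' @param path Path to the TSV.
#' @param layout A [genome_layout()].
#' @return A `data.frame` with one validated row per gene.
#' @export
read_gene_table <- function(path, layout) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("gene table lacks column(s): %s", paste(miss, collapse = ", ")))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  if (anyDuplicated(df$gene_id))
    stop_with_rows("duplicated gene_id", line[duplicated(df$gene_id)])
  bad <- which(!df$chrom %in% names(layout$chrom_lengths))
  if (length(bad)) stop_with_rows("unknown chromosome in gene table", line[bad])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stop_with_rows("strand must be '+' or '-'", line[bad])
  bad <- which(df$tss < 0 | df$tss >= layout$chrom_lengths[df$chrom])
  if (length(bad)) stop_with_rows("TSS outside chromosome bounds", line[bad])
  df
}

#' Read an origin annotation table
#'
#' Tab-separated with header; required columns `origin_id`, `chrom`,
#' `center` (0-based bp); optional `timing` (replication timing, minutes)
#' and `class` (`early`/`late`/`inactive`).
#'
#' @inheritParams read_gene_table
#' @return A validated `data.frame` of origins.
#' @export
read_origin_table <- function(path, layout) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("origin_id", "chrom", "center")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("origin table lacks column(s): %s", paste(miss, collapse = ", ")))
  line <- seq_len(nrow(df)) + 1L
  if (anyDuplicated(df$origin_id))
    stop_with_rows("duplicated origin_id", line[duplicated(df$origin_id)])
  bad <- which(!df$chrom %in% names(layout$chrom_lengths))
  if (length(bad)) stop_with_rows("unknown chromosome in origin table", line[bad])
  bad <- which(df$center < 0 | df$center >= layout$chrom_lengths[df$chrom])
  if (length(bad)) stop_with_rows("origin center outside chromosome", line[bad])
  if ("class" %in% names(df)) {
    bad <- which(!is.na(df$class) & !df$class %in% c("early", "late", "inactive"))
    if (length(bad)) stop_with_rows("origin class must be early/late/inactive",
                                    line[bad])
  }
  df
}

#' Read a BED3/BED6 interval file
#'
#' No header; 0-based half-open intervals validated against the layout.
#' Used for blacklists (hyper-ChIPable regions) and externally called
#' peaks.
#'
#' @inheritParams read_gene_table
#' @return A `data.frame` with `chrom`, `start`, `end` (plus `name`,
#'   `score`, `strand` when present).
#' @export
read_bed <- function(path, layout) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fill = TRUE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  line <- seq_len(nrow(df))
  bad <- which(df$end <= df$start)
  if (length(bad)) stop_with_rows("BED interval with end <= start", line[bad])
  bad <- which(!df$chrom %in% names(layout$chrom_lengths))
  if (length(bad)) stop_with_rows("unknown chromosome in BED", line[bad])
  bad <- which(df$start < 0 | df$end > layout$chrom_lengths[df$chrom])
  if (length(bad)) stop_with_rows("BED interval outside chromosome", line[bad])
  df
}

#' Minimal GFF3 gene reader
#'
#' Extracts `gene` features only, converting to the package's 0-based TSS
#' convention: `start - 1` for `+` strand genes, `end - 1` for `-` strand.
#' The gene id is taken from the `ID=` attribute. This deliberately avoids
#' full GFF3 attribute semantics; use [read_gene_table()] for anything
#' richer.
#'
#' @inheritParams read_gene_table
#' @return A gene `data.frame` as from [read_gene_table()].
#' @export
read_gff3_genes <- function(path, layout) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 9]
  f <- f[vapply(f, function(x) x[3] == "gene", TRUE)]
  if (!length(f)) return(data.frame(gene_id = character(), chrom = character(),
                                    tss = numeric(), strand = character()))
  att <- vapply(f, function(x) x[9], "")
  id <- sub(".*ID=([^;]+).*", "\\1", att)
  strand <- vapply(f, function(x) x[7], "")
  start1 <- as.numeric(vapply(f, function(x) x[4], ""))
  end1 <- as.numeric(vapply(f, function(x) x[5], ""))
  df <- data.frame(gene_id = id,
                   chrom = vapply(f, function(x) x[1], ""),
                   tss = ifelse(strand == "+", start1 - 1, end1 - 1),
                   strand = strand, stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  read_gene_table(tf, layout)
}

#' Write a data frame as a deterministic TSV
#'
#' Tab-separated, no quoting, LF line endings, fixed column order — the
#' writer used for every tabular output of the pipeline.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
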