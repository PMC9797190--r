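#' Relate genes to their nearest replication origin
#'
#' For each gene, the origin with minimal `|TSS - center|` on the same
#' chromosome (ties toward the lower-coordinate origin), together with the
#' replication-fork/transcription orientation (see [orientation()]), the
#' origin class when annotated, and a distance category with exclusive
#' bins `<1kb`, `1-2kb`, `2-5kb`, and `none` (no origin within 5 kb, or no
#' origin on the chromosome).
#'
#' @param genes Gene annotation `data.frame` (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param origins Origin `data.frame` (`origin_id`, `chrom`, `center`,
#'   optional `class`).
#' @param active_only If `TRUE`, restrict the search universe to origins
#'   with class `early` or `late`.
#' @param breaks Distance-category thresholds in bp (default
#'   `c(1000, 2000, 5000)`).
#' @return A `data.frame`: `gene_id`, `origin_id`, `distance`,
#'   `orientation` (`HO`/`CD`/`NA`), `origin_class`, `category`.
#' @export
nearest_origin <- function(genes, origins, active_only = FALSE,
                           breaks = c(1000, 2000, 5000)) {
  if (active_only) {
    if (!"class" %in% names(origins))
      stop("active_only requires an origin 'class' column")
    origins <- origins[origins$class %in% c("early", "late"), , drop = FALSE]
  }
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id,
                    origin_id = NA_character_, distance = NA_real_,
                    orientation = NA_character_,
                    origin_class = NA_character_,
                    category = "none", stringsAsFactors = FALSE)
  has_class <- "class" %in% names(origins)
  for (cn in unique(genes$chrom)) {
    oc <- origins[origins$chrom == cn, , drop = FALSE]
    if (!nrow(oc)) next
    oc <- oc[order(oc$center), , drop = FALSE]
    gi <- which(genes$chrom == cn)
    for (i in gi) {
      d <- abs(oc$center - genes$tss[i])
      j <- which(d == min(d))[1]  # tie -> lower coordinate (sorted)
      out$origin_id[i] <- oc$origin_id[j]
      out$distance[i] <- d[j]
      out$orientation[i] <- orientation(genes$tss[i], genes$strand[i],
                                        oc$center[j])
      if (has_class) out$origin_class[i] <- as.character(oc$class[j])
    }
  }
  d <- out$distance
  out$category <- ifelse(is.na(d) | d >= breaks[3], "none",
                  ifelse(d < breaks[1], "<1kb",
                  ifelse(d < breaks[2], "1-2kb", "2-5kb")))
  out
}

#' Gene-origin orientation: head-on or co-directional
#'
#' A replication fork arriving at a gene from a nearby origin travels away
#' from the origin center. If the gene's transcription direction opposes
#' that fork (transcription points toward the origin center) the pair is
#' head-on (`HO`); if it matches, co-directional (`CD`). A gene whose TSS
#' coincides with the center has no defined orientation (`NA`).
#'
#' @param tss TSS position(s), bp.
#' @param strand `"+"` or `"-"`.
#' @param center Origin center position(s), bp (same chromosome).
#' @return Character vector of `"HO"`, `"CD"`, or `NA`.
#' @export
orientation <- function(tss, strand, center) {
  fork_dir <- sign(tss - center)           # fork moves away from center
  tx_dir <- ifelse(strand == "+", 1, -1)
  ifelse(fork_dir == 0, NA_character_,
         ifelse(fork_dir == tx_dir, "CD", "HO"))
}

#' Down-regulation bias of expression changes near origins
#'
#' Among differentially expressed genes, tabulates up/down counts and
#' proportions by nearest-origin distance category, origin class, and
#' orientation, and tests two contrasts among genes with an origin within
#' 5 kb by two-sided Fisher's exact test: late- versus early-origin genes,
#' and head-on versus co-directional genes. Empty strata skip their
#' contrast with a warning.
#'
#' @param relations A [nearest_origin()] table.
#' @param de Named character vector or `data.frame` (`gene_id`,
#'   `direction`) with directions `"up"`/`"down"`; other values ignored.
#' @param max_dist Distance ceiling for the contrasts (default 5000 bp).
#' @return A list of class `deg_origin_bias`: `strata` (long count/
#'   proportion table) and `contrasts` (`data.frame` with counts, odds
#'   ratio and Fisher p per contrast).
#' @export
deg_origin_bias <- function(relations, de, max_dist = 5000) {
  if (is.data.frame(de)) {
    dir <- de$direction
    names(dir) <- de$gene_id
  } else dir <- de
  dir <- dir[dir %in% c("up", "down")]
  miss <- setdiff(names(dir), relations$gene_id)
  if (length(miss))
    stop(sprintf("DE gene(s) absent from relations: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  rel <- relations[match(names(dir), relations$gene_id), , drop = FALSE]
  rel$direction <- unname(dir)

  strata <- do.call(rbind, lapply(
    c(category = "category", origin_class = "origin_class",
      orientation = "orientation"),
    function(col) {
      lv <- unique(rel[[col]][!is.na(rel[[col]])])
      do.call(rbind, lapply(lv, function(s) {
        sub <- rel[!is.na(rel[[col]]) & rel[[col]] == s, , drop = FALSE]
        data.frame(stratum_type = col, stratum = s,
                   n_down = sum(sub$direction == "down"),
                   n_up = sum(sub$direction == "up"),
                   prop_down = mean(sub$direction == "down"),
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(strata) <- NULL

  near <- rel[!is.na(rel$distance) & rel$distance < max_dist, , drop = FALSE]
  contrast <- function(name, in_a, in_b, label_a, label_b) {
    a <- near[in_a, , drop = FALSE]; b <- near[in_b, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) {
      warning(sprintf("contrast '%s' skipped: empty stratum", name))
      return(NULL)
    }
    tb <- contingency_2x2(sum(a$direction == "down"),
                          sum(a$direction == "up"),
                          sum(b$direction == "down"),
                          sum(b$direction == "up"))
    ft <- fisher_exact_2x2(tb, sided = "two")
    data.frame(contrast = name, group_a = label_a, group_b = label_b,
               a_down = tb$a, a_up = tb$b, b_down = tb$c, b_up = tb$d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  }
  contrasts <- rbind(
    contrast("late_vs_early",
             !is.na(near$origin_class) & near$origin_class == "late",
             !is.na(near$origin_class) & near$origin_class == "early",
             "late", "early"),
    contrast("HO_vs_CD",
             !is.na(near$orientation) & near$orientation == "HO",
             !is.na(near$orientation) & near$orientation == "CD",
             "HO", "CD"))
  structure(list(strata = strata, contrasts = contrasts, max_dist = max_dist),
            class = "deg_origin_bias")
}

#' @export
print.deg_origin_bias <- function(x, ...) {
  cat("deg_origin_bias (< ", x$max_dist, " bp contrasts):\n", sep = "")
  if (!is.null(x$contrasts)) print(x$contrasts, row.names = FALSE)
  invisible(x)
}
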