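test_that("Fisher 2x2 matches enumeration on worked examples", {
  even <- fisher_exact_2x2(contingency_2x2(10, 10, 10, 10))
  expect_equal(even$p, 1)
  expect_equal(even$odds_ratio, 1)
  diag3 <- fisher_exact_2x2(contingency_2x2(3, 0, 0, 3))
  expect_equal(diag3$p, 0.1)  # 2 * (1 / C(6,3))
  expect_equal(diag3$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(contingency_2x2(0, 0, 3, 3)),
               "degenerate margins")
  expect_error(contingency_2x2(-1, 1, 1, 1), "nonnegative")
})

test_that("Fisher 2x2 equals the enumeration oracle on random tables", {
  set.seed(51)
  for (i in 1:300) {
    repeat {
      cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(4)))
      m <- matrix(cells, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    got <- fisher_exact_2x2(contingency_2x2(cells[1], cells[2],
                                            cells[3], cells[4]))$p
    expect_equal(got, fisher_enum_two_sided(cells[1], cells[2],
                                            cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("TF-target enrichment arithmetic is exact", {
  universe <- 6604
  targets <- sprintf("t%04d", 1:81)
  selection <- c(targets[1:36], sprintf("s%04d", 1:200))
  enr <- tf_enrichment(universe, targets, selection)
  expect_equal(enr$overlap, 36)
  expect_equal(round(enr$freq_selection_pct, 2), 15.25)
  expect_equal(enr$freq_background_pct, 100 * 81 / 6604)
  expect_equal(unlist(enr$table), c(a = 36, b = 45, c = 200, d = 6323))
  expect_lt(enr$p, 1e-15)

  # disjoint targets: no enrichment signal
  none <- tf_enrichment(1000, sprintf("t%d", 1:30), sprintf("s%d", 1:50))
  expect_equal(none$freq_selection_pct, 0)
  expect_gt(none$p, 0.5)
  # selection identical to targets
  all_in <- tf_enrichment(1000, sprintf("t%d", 1:30), sprintf("t%d", 1:30))
  expect_equal(all_in$freq_selection_pct, 100)
  expect_error(tf_enrichment(1000, "t1", character()), "empty selection")
})

test_that("Spearman correlation follows the rank formula", {
  r1 <- db_de_correlation(c(a = 1, b = 2, c = 3), c(a = 10, b = 20, c = 30))
  expect_equal(r1$r, 1)
  r2 <- db_de_correlation(c(a = 1, b = 2, c = 3), c(a = 30, b = 10, c = 20))
  expect_equal(r2$r, -0.5)
  expect_equal(r2$r, spearman_formula(c(1, 2, 3), c(30, 10, 20)))
  set.seed(52)
  x <- rnorm(25); y <- rnorm(25)
  names(x) <- names(y) <- paste0("g", 1:25)
  expect_equal(db_de_correlation(x, y)$r, spearman_formula(x, y))
  expect_error(db_de_correlation(c(a = 1, b = 2), c(a = 1, b = 2)),
               "at least 3")
})

test_that("binding-expression direction association matches enumeration", {
  up20 <- setNames(rep(c("up", "down"), each = 20), paste0("g", 1:40))
  conc <- db_de_association(up20, up20)
  expect_equal(conc$p, fisher_enum_two_sided(20, 0, 0, 20), tolerance = 1e-12)
  expect_lt(conc$p, 1e-9)

  indep <- db_de_association(
    setNames(rep(c("up", "down"), each = 20), paste0("g", 1:40)),
    setNames(rep(c("up", "down"), 20), paste0("g", 1:40)))
  expect_equal(indep$p, 1)

  # one discordant gene among ten concordant pairs
  db <- setNames(rep(c("up", "down"), each = 5), paste0("g", 1:10))
  de <- db; de[10] <- "up"
  got <- db_de_association(db, de)
  expect_equal(got$p, fisher_enum_two_sided(5, 0, 1, 4), tolerance = 1e-12)

  allup <- setNames(rep("up", 4), paste0("g", 1:4))
  expect_error(db_de_association(allup, up20[1:4]), "zero margin: DB down")
})

test_that("naive DE surrogate normalizes by median-of-ratios", {
  counts <- matrix(c(10, 100, 50, 20, 200, 100), ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  de <- naive_de(counts, c("A", "B"))
  sf <- attr(de, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)  # sample2 = 2 x sample1
  expect_equal(de$log2fc, rep(0, 3))
  expect_true(all(de$direction == "ns"))

  # unit size factors: log2FC = log2((mean+1)/(mean+1)) with pseudocount 1
  counts2 <- rbind(matrix(100, 11, 2), c(10, 40))
  rownames(counts2) <- paste0("g", 1:12)
  de2 <- naive_de(counts2, c("A", "B"))
  expect_equal(attr(de2, "size_factors"), c(1, 1), ignore_attr = TRUE)
  expect_equal(de2$log2fc[12], log2(41 / 11))
  expect_equal(de2$direction[12], "up")

  # all-zero genes are excluded and reported
  counts3 <- rbind(counts, g0 = c(0, 0))
  de3 <- naive_de(counts3, c("A", "B"))
  expect_equal(attr(de3, "excluded"), "g0")
  expect_false("g0" %in% de3$gene_id)
  expect_true(attr(de3, "surrogate"))

  expect_error(naive_de(cbind(c(1, 0), c(0, 0)), c("A", "B")), "zero total")
  expect_error(naive_de(counts, c("A", "B", "C")), "two levels")
})

test_that("naive DE recovers planted fold changes and is null-safe", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 600000, n_genes = 400,
                    n_origins = 0, n_db_genes = 0, n_deg = 50,
                    deg_log2fc = 2, depth = 200, seed = 99)
  ann <- generate_annotation(cfg)
  design <- sample_design("WT", c("G1", "HU45"), "RNA", 1:3)
  counts <- simulate_rna_counts(ann, design, cfg)
  de <- naive_de(counts, ifelse(grepl("G1", colnames(counts)), "G1", "HU"))
  planted <- ann$truth$deg_effects
  est <- setNames(de$log2fc, de$gene_id)[names(planted)]
  # signed recovery: median estimate of the planted effect within +/- 0.3
  expect_lt(abs(median(est * sign(planted)) - 2), 0.3)

  null_cfg <- sim_config(n_chromosomes = 1, chrom_length = 600000,
                         n_genes = 400, n_origins = 0, n_db_genes = 0,
                         n_deg = 0, depth = 200, seed = 100)
  nc <- simulate_rna_counts(generate_annotation(null_cfg), design, null_cfg,
                            seed = 100)
  nde <- naive_de(nc, ifelse(grepl("G1", colnames(nc)), "G1", "HU"))
  expect_lte(mean(nde$significant), 0.01)
})
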