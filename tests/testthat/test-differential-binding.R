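test_that("unit-max scaling divides by the sample maximum", {
  expect_equal(scale_to_unit_max(c(2, 4)), c(0.5, 1))
  expect_equal(scale_to_unit_max(c(3, 3, 3)), c(1, 1, 1))
  expect_equal(scale_to_unit_max(c(-1, 4)), c(-0.25, 1))
  expect_error(scale_to_unit_max(c(-2, -1)), "maximum")
})

test_that("residual regression matches the closed-form OLS oracle", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  fit <- fit_db_regression(x, y, gene_id = paste0("g", 1:4))
  oracle <- ols_closed_form(x, y)
  expect_equal(fit$slope, 2.3)
  expect_equal(fit$intercept, -0.5)
  expect_equal(fit$table$residual, c(0.2, -0.1, -0.4, 0.3))
  expect_equal(fit$table$residual, oracle$residuals)
  expect_equal(fit$table$abs_rank, order(order(-abs(oracle$residuals))))

  # perfect fit leaves zero residuals
  expect_equal(fit_db_regression(x, 2 * x)$table$residual, rep(0, 4))
  # shifting y moves the intercept only
  shifted <- fit_db_regression(x, y + 5)
  expect_equal(shifted$table$residual, fit$table$residual)
  expect_equal(shifted$intercept, fit$intercept + 5)

  expect_error(fit_db_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(fit_db_regression(1:2, 1:2), "at least 3")
})

test_that("top-DB selection filters, ranks by |residual|, breaks ties by id", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  fit <- fit_db_regression(x, y, gene_id = paste0("g", 1:4))
  sel <- select_top_db(fit, scale_to_unit_max(x), scale_to_unit_max(y), K = 1)
  expect_equal(sel$genes, "g3")  # residual -0.4 has the largest magnitude

  # the largest-|residual| gene is excluded when below the signal floor
  sx <- scale_to_unit_max(x); sx[3] <- -0.2
  sel2 <- select_top_db(fit, sx, scale_to_unit_max(y), K = 1)
  expect_equal(sel2$genes, "g4")
  expect_false(sel2$full$passes_filter[3])

  # K beyond the pool saturates
  sel3 <- select_top_db(fit, scale_to_unit_max(x), scale_to_unit_max(y),
                        K = 100)
  expect_equal(sort(sel3$genes), paste0("g", 1:4))
  expect_error(select_top_db(fit, sx, sx, K = 0), "positive")

  # exact |residual| ties resolve lexicographically by gene id
  xt <- c(0, 1, 2, 3); e <- c(1, -1, -1, 1)
  ft <- fit_db_regression(xt, xt + e, gene_id = c("d", "c", "b", "a"))
  expect_equal(ft$table$residual, e)
  st <- select_top_db(ft, rep(1, 4), rep(1, 4), K = 2)
  expect_equal(st$genes, c("a", "b"))
})

test_that("selection intersection orders by the worse rank", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  fit <- fit_db_regression(x, y, gene_id = paste0("g", 1:4))
  s <- scale_to_unit_max(x)
  full <- select_top_db(fit, s, s, K = 4)
  expect_equal(intersect_top_db(full, full), full$genes)
  top2 <- select_top_db(fit, s, s, K = 2)
  expect_equal(sort(intersect_top_db(full, top2)), sort(top2$genes))

  other <- fit_db_regression(x, c(9, 6, 4, 2), gene_id = paste0("h", 1:4))
  expect_equal(intersect_top_db(select_top_db(other, s, s, K = 4), full),
               character())
})

test_that("selection is invariant to gene order permutation", {
  set.seed(14)
  x <- rnorm(50, 5); y <- 1.2 * x + rnorm(50, 0, 0.3)
  ids <- sprintf("g%02d", 1:50)
  fit <- fit_db_regression(x, y, gene_id = ids)
  sel <- select_top_db(fit, scale_to_unit_max(x), scale_to_unit_max(y), K = 10)
  perm <- sample(50)
  fitp <- fit_db_regression(x[perm], y[perm], gene_id = ids[perm])
  selp <- select_top_db(fitp, scale_to_unit_max(x[perm]),
                        scale_to_unit_max(y[perm]), K = 10)
  expect_equal(sel$genes, selp$genes)
})

test_that("group residual test standardizes and uses exact Wilcoxon", {
  xt <- c(0, 1, 2, 3)
  e <- c(1, -1, -1, 1) + 0.1 * c(-1, 3, -3, 1)  # distinct, orthogonal to fit
  fit <- fit_db_regression(xt, xt + e, gene_id = paste0("g", 1:4))
  expect_equal(fit$table$residual, e, tolerance = 1e-12)
  res <- db_group_test(fit, c("g3", "g2"))  # the two lowest residuals
  expect_equal(res$p, 1 / 3)  # exact: 2 of C(4,2)=6 assignments as extreme
  expect_equal(mean(res$z), 0, tolerance = 1e-12)
  expect_equal(sd(res$z), 1, tolerance = 1e-12)

  expect_error(db_group_test(fit, character()), "no annotated")
  expect_error(db_group_test(fit, paste0("g", 1:4)), "proper subset")
  flat <- fit_db_regression(xt, 2 * xt)
  expect_error(db_group_test(flat, "g1"), "zero variance")
})

test_that("planted binding changes are recovered by the two-experiment
           intersection with faithful signs", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 375000, n_genes = 500,
                    n_origins = 0, n_db_genes = 40, db_effect = 1,
                    depth = 50, n_deg = 0, seed = 77)
  ann <- generate_annotation(cfg)
  design <- sample_design("WT", c("G1", "HU45"), c("IP", "input"), 1:2)
  run_exp <- function(seed) {
    tr <- simulate_chip_tracks(ann, design, cfg, seed = seed)
    g1 <- condition_enrichment(tr, design, "WT", "G1")
    hu <- condition_enrichment(tr, design, "WT", "HU45")
    sg <- promoter_scores(g1, ann$genes)
    sh <- promoter_scores(hu, ann$genes)
    run_db_analysis(setNames(sg$score, sg$gene_id),
                    setNames(sh$score, sh$gene_id), K = 80)
  }
  stats <- sapply(1:3, function(s) {
    a <- run_exp(1000 + s); b <- run_exp(2000 + s)
    ov <- intersect_top_db(a$selection, b$selection)
    planted <- names(ann$truth$db_effects)
    rec <- intersect(ov, planted)
    dirs <- setNames(a$fit$table$direction, a$fit$table$gene_id)
    c(recovery = mean(planted %in% ov),
      false = mean(!ov %in% planted),
      sign = mean(sign(ann$truth$db_effects[rec]) == dirs[rec]))
  })
  expect_gte(median(stats["recovery", ]), 0.8)
  expect_gte(median(stats["sign", ]), 0.95)
  # false members cannot fall below the chance-overlap floor of the two
  # independent top-K lists; bound them loosely above it
  expect_lte(median(stats["false", ]), 0.2)
})
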