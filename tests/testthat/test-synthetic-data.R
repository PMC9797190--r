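test_that("annotation generation is deterministic and respects bounds", {
  cfg <- sim_config(n_genes = 50, n_origins = 10, seed = 7)
  a <- generate_annotation(cfg)
  b <- generate_annotation(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$genes), 50)
  expect_true(all(a$genes$tss >= 0 &
                    a$genes$tss < cfg$chrom_length))
  expect_equal(sum(a$genes$strand == "+"), 25)  # balanced strands
  expect_equal(nrow(a$origins), 10)
  # non-overlapping centers with a wide guard interval
  for (cn in unique(a$origins$chrom)) {
    ctr <- sort(a$origins$center[a$origins$chrom == cn])
    if (length(ctr) > 1) expect_true(all(diff(ctr) >= 2 * 6500))
  }
  expect_equal(length(a$truth$db_effects), cfg$n_db_genes)
  expect_true(all(names(a$truth$db_effects) %in% a$genes$gene_id))
})

test_that("degenerate fractions and infeasible density are handled", {
  cfg <- sim_config(fraction_early = 1, fraction_late = 0,
                    fraction_inactive = 0, n_origins = 12, seed = 3)
  ann <- generate_annotation(cfg)
  expect_true(all(ann$origins$class == "early"))
  expect_error(sim_config(fraction_early = 0.6, fraction_late = 0.6,
                          fraction_inactive = -0.2), "sum to 1")
  dense <- sim_config(n_chromosomes = 1, chrom_length = 10000, n_genes = 50,
                      n_db_genes = 0, n_deg = 0, n_origins = 0)
  expect_error(generate_annotation(dense), "cannot place")
})

test_that("ChIP tracks are deterministic, layout-shaped and null at depth 0", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 100000, n_genes = 20,
                    n_origins = 4, n_db_genes = 4, n_deg = 0, seed = 5)
  ann <- generate_annotation(cfg)
  design <- sample_design("WT", c("G1", "HU45"), c("IP", "input"), 1)
  t1 <- simulate_chip_tracks(ann, design, cfg)
  t2 <- simulate_chip_tracks(ann, design, cfg)
  expect_identical(t1, t2)
  expect_equal(length(t1), nrow(design))
  expect_equal(lengths(t1[[1]]$values), c(chr1 = 4000))

  zero <- sim_config(n_chromosomes = 1, chrom_length = 100000, n_genes = 20,
                     n_origins = 4, n_db_genes = 4, n_deg = 0, depth = 0,
                     seed = 5)
  tz <- simulate_chip_tracks(generate_annotation(zero), design, zero)
  expect_true(all(vapply(tz, function(t) all(t$values$chr1 == 0), TRUE)))

  no_input <- design[design$assay == "IP", ]
  expect_error(simulate_chip_tracks(ann, no_input, cfg), "no matched input")
  bad <- design; bad$genotype <- "nosuch"
  expect_error(simulate_chip_tracks(ann, bad, cfg), "unknown genotype")
})

test_that("planted DB genes shift promoter counts between G1 and HU", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 60000, n_genes = 10,
                    n_origins = 0, n_db_genes = 3, db_effect = 1,
                    db_up_fraction = 1, n_deg = 0, depth = 30, seed = 13)
  ann <- generate_annotation(cfg)
  design <- sample_design("WT", c("G1", "HU45"), c("IP", "input"), 1)
  planted <- ann$genes[ann$genes$gene_id %in% names(ann$truth$db_effects), ]
  others <- ann$genes[!ann$genes$gene_id %in% names(ann$truth$db_effects), ]
  set.seed(101)
  diffs <- replicate(50, {
    tr <- simulate_chip_tracks(ann, design, cfg,
                               seed = sample.int(1e6, 1))
    hu <- sapply(seq_len(nrow(planted)), function(i)
      promoter_count_mean(tr$WT_HU45_IP_rep1, planted[i, ]))
    g1 <- sapply(seq_len(nrow(planted)), function(i)
      promoter_count_mean(tr$WT_G1_IP_rep1, planted[i, ]))
    on <- sapply(seq_len(nrow(others)), function(i)
      promoter_count_mean(tr$WT_HU45_IP_rep1, others[i, ]) -
        promoter_count_mean(tr$WT_G1_IP_rep1, others[i, ]))
    c(planted = mean(hu - g1), others = mean(on))
  })
  # planted amplitudes double at HU; unplanted genes stay flat
  expect_gt(mean(diffs["planted", ]), 0)
  expect_gt(mean(diffs["planted", ]), mean(diffs["others", ]) + 5)
  expect_lt(abs(mean(diffs["others", ])), 3)
})

test_that("EdU tracks fire the right origins per genotype and timepoint", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 200000, n_genes = 10,
                    n_origins = 10, n_db_genes = 2, n_deg = 2, seed = 23)
  ann <- generate_annotation(cfg)
  sc <- function(g, tp, noise = FALSE, seed = 1) origin_edu_score(
    simulate_edu_track(ann$origins, g, tp, cfg, ann$layout, noise = noise,
                       seed = seed), ann$origins)
  late <- ann$origins$class == "late"
  early <- ann$origins$class == "early"

  g1 <- sc("WT", "G1")
  expect_true(all(abs(g1 - cfg$edu_background) < 1e-9))  # no firing in G1
  wt45 <- sc("WT", "HU45")
  expect_true(all(abs(wt45[late] - cfg$edu_background) < 1e-9))
  expect_true(all(wt45[early] > 2))
  mut90 <- sc("mutA", "HU90")
  expect_true(all(mut90[late] > 2))
  # Monte-Carlo mean of noisy late-origin scores sits near the plateau
  set.seed(102)
  noisy <- rowMeans(replicate(20, sc("mutA", "HU90", noise = TRUE,
                                     seed = sample.int(1e6, 1))))
  expect_true(all(noisy[late] > 2))
  expect_error(sc("nosuch", "HU90"), "unknown genotype")
})

test_that("RNA counts are deterministic with planted effects in place", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 300000, n_genes = 150,
                    n_origins = 10, n_db_genes = 10, n_deg = 20,
                    deg_log2fc = 0, ho_down_bias = 0, cd_down_bias = 0,
                    depth = 100, seed = 55)
  ann <- generate_annotation(cfg)
  design <- sample_design(c("WT", "mutA"), c("G1", "HU45"), "RNA", 1:2)
  r1 <- simulate_rna_counts(ann, design, cfg)
  r2 <- simulate_rna_counts(ann, design, cfg)
  expect_identical(r1, r2)
  expect_equal(dim(r1), c(150, nrow(design)))

  # with all planted effects at zero the surrogate calls nothing
  hu <- grepl("HU45", colnames(r1))
  de <- naive_de(r1[, hu], factor(c("WT", "mutA")[1 +
                   grepl("mutA", colnames(r1)[hu])], c("WT", "mutA")))
  expect_lte(mean(de$significant), 0.02)
  expect_error(simulate_rna_counts(ann, design[design$assay == "IP", ],
                                   cfg), "no RNA samples")
})

test_that("planted direction draws follow the orientation bias", {
  rel <- data.frame(gene_id = sprintf("g%03d", 1:300), origin_id = "o",
                    distance = 2000,
                    orientation = rep(c("HO", "CD"), 150),
                    origin_class = "late",
                    category = "2-5kb", stringsAsFactors = FALSE)
  cfg <- sim_config(ho_down_bias = 0.9, cd_down_bias = 0.1)
  d <- plant_deg_directions(rel, cfg, seed = 61)
  ho_down <- mean(d$direction[rel$orientation == "HO"] == "down")
  cd_down <- mean(d$direction[rel$orientation == "CD"] == "down")
  expect_gt(ho_down, 0.8)
  expect_lt(cd_down, 0.2)
  expect_identical(d, plant_deg_directions(rel, cfg, seed = 61))
})

test_that("simulated datasets write to plain-text files and read back", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 100000, n_genes = 20,
                    n_origins = 4, n_db_genes = 2, n_deg = 2, seed = 71)
  ann <- generate_annotation(cfg)
  design <- sample_design("WT", "G1", c("IP", "input"), 1)
  tracks <- simulate_chip_tracks(ann, design, cfg)
  dir <- withr::local_tempdir()
  write_simulation(ann, dir, tracks = tracks)
  expect_true(all(file.exists(file.path(dir, c("genes.tsv", "origins.tsv",
                                               "blacklist.bed",
                                               "truth.json")))))
  genes <- read_gene_table(file.path(dir, "genes.tsv"), ann$layout)
  expect_equal(genes$tss, ann$genes$tss)
  back <- read_bedgraph(file.path(dir, "WT_G1_IP_rep1.bedgraph"), ann$layout)
  expect_equal(back$values, tracks$WT_G1_IP_rep1$values)
})
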