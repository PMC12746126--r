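# Synthetic tissue and microregion generators: determinism, planted
# parameter recovery, and structural guarantees.

test_that("identical config and seed give byte-identical tables", {
  cfg <- tissue_config(n_cells = 1200, seed = 5)
  s1 <- generate_tissue(cfg)
  s2 <- generate_tissue(cfg)
  expect_identical(s1$cells, s2$cells)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cell_table(s1$cells, f1); write_cell_table(s2$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generate_tissue(tissue_config(n_cells = 1200, seed = 6))
  expect_false(identical(s1$cells, s3$cells))
})

test_that("planted tumor fraction is recovered at binomial accuracy", {
  sim <- generate_tissue(simple_tissue_config(0.6, 10000, seed = 3))
  f <- mean(sim$cells$true_class == "Tumor")
  expect_lt(abs(f - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
})

test_that("class fraction recovery holds across seeds (4-SD band)", {
  for (seed in 1:20) {
    sim <- generate_tissue(simple_tissue_config(0.3, 2000, seed = seed))
    f <- mean(sim$cells$true_class == "Tumor")
    expect_lt(abs(f - 0.3), 4 * sqrt(0.3 * 0.7 / 2000))
  }
})

test_that("vessel cells lie inside the configured corridor", {
  path <- rbind(c(100, 1700), c(900, 1850))
  spec <- list(list(domain_id = "A", bounds = c(0, 0, 1000, 2000),
                    nests = list(list(center = c(500, 500), radius = 250)),
                    tumor_fraction = 0.3, immune_mix = default_immune_mix(),
                    necrosis = FALSE,
                    vessels = list(list(path = path, halfwidth = 10,
                                        n_cells = 80))))
  sim <- generate_tissue(tissue_config(n_cells = 1000,
                                       field_size = c(1000, 2000),
                                       domain_specs = spec, seed = 2))
  ves <- sim$cells[sim$cells$true_class == "Endothelial", c("x", "y")]
  expect_gt(nrow(ves), 0)
  d <- apply(as.matrix(ves), 1, oracle_path_dist, path = path)
  expect_true(all(d <= 10 + 1e-9))
})

test_that("invalid configurations are rejected", {
  expect_error(tissue_config(n_cells = 0, seed = 1), "positive count")
  bad <- default_domain_specs()
  bad[[1]]$immune_mix <- c(Treg = 0.5, Macrophage = 0.2)  # sums to 0.7
  expect_error(tissue_config(domain_specs = bad, seed = 1), "sum to 1")
  expect_error(tissue_config(seed = 1, cellcycle_mix = c(neutral = 0.5, g1s = 0.6)),
               "sum to 1")
  expect_error(tissue_config(n_cells = 100),
               "seed")
  mm <- default_marker_model()
  mm$pos_meanlog[3] <- mm$neg_meanlog[3] - 1
  expect_error(tissue_config(marker_model = mm, seed = 1),
               "positive component")
})

test_that("true gates recover true positivity labels (gate separability)", {
  sim <- generate_tissue(tissue_config(n_cells = 3000, seed = 8))
  g <- apply_gates(sim$cells, sim$truth$gates)
  agree <- vapply(colnames(sim$truth$positivity), function(m)
    mean(g[[paste0("pos_", m)]] == sim$truth$positivity[, m]), 0)
  expect_true(all(agree >= 0.95))
  # per-cell: all markers of >= 95% of cells called correctly
  all_ok <- rowMeans(sapply(colnames(sim$truth$positivity), function(m)
    g[[paste0("pos_", m)]] == sim$truth$positivity[, m])) == 1
  expect_gte(mean(all_ok), 0.90)
})

test_that("necrotic zones are debris-flagged and locally sparse", {
  sim <- generate_tissue(tissue_config(n_cells = 10000, seed = 13))
  necro <- sim$cells$true_region == "necrotic"
  expect_gte(sum(necro), 3)  # the zone is small but not empty at this seed
  expect_true(all(sim$cells$debris[necro]))
  dens <- local_knn_density(sim$cells[, c("x", "y")], k = 10)
  expect_lt(median(dens[necro]), median(dens[sim$cells$true_region == "distal"]))
})

test_that("microregion counts are deterministic and respect gene sets", {
  specs <- make_correlated_mr_specs(n_tumor = 5, n_peritumoral = 5, seed = 4)
  m1 <- generate_mr_counts(mr_specs = specs, seed = 21)
  m2 <- generate_mr_counts(mr_specs = specs, seed = 21)
  expect_identical(m1$counts, m2$counts)
  expect_true(all(m1$counts >= 0))
  expect_true(all(m1$counts == floor(m1$counts)))
  expect_equal(dim(m1$counts), c(1000L, 10L))
  # unknown gene set / unknown gene errors
  bad <- specs
  bad[[1]]$activity <- c(NOPE = 1)
  expect_error(generate_mr_counts(mr_specs = bad, seed = 1), "unknown gene set")
  uni <- default_gene_universe(200)
  uni$gene_sets$BAD <- c("not_a_gene")
  expect_error(generate_mr_counts(mr_specs = specs, seed = 1, universe = uni),
               "unknown gene")
})

test_that("zero latent activity leaves set genes indistinguishable", {
  specs <- lapply(1:50, function(i)
    list(mr_id = sprintf("MR%02d", i), domain = "A", compartment = "tumor",
         activity = c(SIG_A = 0)))
  mr <- generate_mr_counts(n_genes = 400, mr_specs = specs, seed = 17,
                           universe = default_gene_universe(400))
  in_set <- rownames(mr$counts) %in% mr$truth$gene_sets$SIG_A
  gene_means <- rowMeans(mr$counts)
  p <- rank_compare(gene_means[in_set], gene_means[!in_set])$p
  expect_gt(p, 0.01)
})

test_that("a planted x4 mean shift separates active and inactive MRs", {
  specs <- c(
    lapply(1:20, function(i) list(mr_id = sprintf("A%02d", i), domain = "A",
                                  compartment = "tumor", activity = c(SIG_A = 1))),
    lapply(1:20, function(i) list(mr_id = sprintf("I%02d", i), domain = "A",
                                  compartment = "tumor", activity = c(SIG_A = 0))))
  mr <- generate_mr_counts(mr_specs = specs, seed = 9)
  expr <- log_transform(size_factor_normalize(mr$counts)$normalized)
  sc <- ssgsea(expr, mr$truth$gene_sets["SIG_A"])
  active <- rep(c(TRUE, FALSE), each = 20)
  auc <- (sum(outer(sc[1, active], sc[1, !active], ">")) +
          0.5 * sum(outer(sc[1, active], sc[1, !active], "=="))) / 400
  expect_gte(auc, 0.9)
})
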