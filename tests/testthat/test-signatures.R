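# Normalization, ssGSEA, score scaling, stratified correlation, rank test.

test_that("size factors follow median-of-ratios", {
  m <- matrix(c(10, 30, 20, 60), nrow = 2)  # genes x MRs [[10,20],[30,60]]
  sf <- size_factor_normalize(m)
  expect_equal(unname(sf$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf$normalized[, 1]), c(10, 30) * sqrt(2), tolerance = 1e-12)
  # identical columns -> unit size factors
  m2 <- matrix(rpois(40, 20) + 1, nrow = 10, ncol = 4)
  m2 <- m2[, c(1, 1, 1, 1)]
  expect_equal(unname(size_factor_normalize(m2)$size_factors), rep(1, 4))
  # scale equivariance: doubling one MR doubles its size factor relative to
  # the others and leaves relative normalized counts unchanged (the shared
  # geometric-mean reference absorbs a common factor of 2^(1/m))
  set.seed(4)
  m3 <- matrix(rpois(200, 30) + 1, nrow = 50)
  n3 <- size_factor_normalize(m3)
  m4 <- m3; m4[, 2] <- m4[, 2] * 2
  n4 <- size_factor_normalize(m4)
  expect_equal(n4$size_factors[2] / n4$size_factors[1],
               2 * n3$size_factors[2] / n3$size_factors[1], tolerance = 1e-12)
  expect_equal(n4$normalized, n3$normalized * 2^(1 / 4), tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rnbinom(600, mu = 50, size = 2) + 1, nrow = 100)
  ours <- size_factor_normalize(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # DESeq2 medians log-ratios rather than ratios; agreement is ~0.1%
  expect_equal(unname(ours), unname(ref), tolerance = 2e-3)
})

test_that("normalization rejects degenerate input", {
  expect_error(size_factor_normalize(matrix(1:3, ncol = 1)), "at least 2")
  m <- matrix(c(0, 1, 1, 0), nrow = 2)  # every gene has a zero somewhere
  expect_error(size_factor_normalize(m), "nonzero counts")
})

test_that("log transform is log10 with +1 pseudocount", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(99), 2)
  expect_equal(log_transform(9), 1)
  expect_error(log_transform(-1), "non-negative")
})

test_that("ssGSEA matches the literal running-sum oracle", {
  set.seed(42)
  for (rep in 1:10) {
    ng <- sample(10:50, 1)
    expr <- setNames(round(rexp(ng, 0.1), 3), sprintf("g%02d", seq_len(ng)))
    set_genes <- sample(names(expr), sample(2:(ng - 2), 1))
    got <- ssgsea(matrix(expr, ncol = 1, dimnames = list(names(expr), "s")),
                  list(S = set_genes))[1, 1]
    expect_equal(got, oracle_ssgsea(expr, set_genes), tolerance = 1e-9)
  }
  # ties: duplicate values still match the oracle
  expr <- setNames(c(5, 5, 3, 3, 1, 8), sprintf("g%d", 1:6))
  expect_equal(ssgsea(matrix(expr, ncol = 1, dimnames = list(names(expr), "s")),
                      list(S = c("g1", "g5")))[1, 1],
               oracle_ssgsea(expr, c("g1", "g5")), tolerance = 1e-9)
})

test_that("ssGSEA is deterministic and monotone in member rank", {
  expr <- matrix(c(6, 5, 4, 3, 2, 1, 6, 5, 4, 3, 2, 1), ncol = 2,
                 dimnames = list(sprintf("g%d", 1:6), c("a", "b")))
  sc <- ssgsea(expr, list(S = c("g2", "g4")))
  expect_equal(sc[1, "a"], sc[1, "b"])  # identical vectors, identical scores
  # move a member from last rank to first: score strictly increases
  lo <- setNames(c(6, 5, 4, 3, 2, 1), sprintf("g%d", 1:6))
  hi <- setNames(c(6, 5, 4, 3, 2, 7), sprintf("g%d", 1:6))  # g6 now ranks 1st
  s_lo <- ssgsea(matrix(lo, ncol = 1, dimnames = list(names(lo), "s")),
                 list(S = c("g3", "g6")))[1, 1]
  s_hi <- ssgsea(matrix(hi, ncol = 1, dimnames = list(names(hi), "s")),
                 list(S = c("g3", "g6")))[1, 1]
  expect_gt(s_hi, s_lo)
  expect_error(ssgsea(expr, list(S = c("nope"))), "no genes")
  expect_error(ssgsea(expr, list(S = rownames(expr))), "every gene")
})

test_that("score scaling handles constant rows", {
  sc <- rbind(a = c(2, 4, 6), b = c(1, 1, 1))
  mm <- scale_scores(sc, "minmax")
  expect_equal(unname(mm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(mm["b", ]), rep(0.5, 3))
  z <- scale_scores(sc, "zscore")
  expect_equal(mean(z["a", ]), 0)
  expect_equal(sd(z["a", ]), 1)
  expect_equal(unname(z["b", ]), rep(0, 3))
})

test_that("stratified Pearson correlation and p-values", {
  res <- stratified_correlation(c(1, 2, 3), c(2, 4, 6), rep("s", 3))
  expect_equal(res$r, 1)
  res2 <- stratified_correlation(c(1, 2, 3), c(6, 4, 2), rep("s", 3))
  expect_equal(res2$r, -1)
  # construct n = 10 with exact r = 0.632; p ~ 0.0499 two-sided at 8 df
  x <- 1:10
  e <- resid(lm(rnorm(10) ~ x))
  y <- 0.632 * scale(x)[, 1] + sqrt(1 - 0.632^2) * scale(e)[, 1]
  res3 <- stratified_correlation(x, y, rep("s", 10))
  expect_equal(res3$r, 0.632, tolerance = 1e-10)
  expect_equal(res3$p, 2 * pt(-0.632 * sqrt(8 / (1 - 0.632^2)), 8),
               tolerance = 1e-12)
  expect_lt(abs(res3$p - 0.0499), 2e-4)
  # degenerate strata
  res4 <- stratified_correlation(c(1, 2, 3, 1, 1, 1), c(1, 3, 5, 2, 3, 1),
                                 rep(c("ok", "flat"), each = 3))
  expect_true(is.na(res4$r[res4$stratum == "flat"]))
  expect_match(res4$flag[res4$stratum == "flat"], "zero variance")
  res5 <- stratified_correlation(1:2, 2:3, c("s", "s"))
  expect_match(res5$flag, "n < 3")
  # BH option adds an adjusted column
  res6 <- stratified_correlation(c(1, 2, 3, 1, 3, 2), c(2, 4, 6, 5, 1, 9),
                                 rep(c("a", "b"), each = 3), adjust = "BH")
  expect_true("p_adj" %in% names(res6))
})

test_that("Mann-Whitney U: exact small-sample p and symmetry", {
  res <- rank_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2/C(6,3)
  expect_equal(res$method, "exact")
  # identical tied groups: tie-corrected normal path, p = 1
  res2 <- rank_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$p, 1)
  # label swap: U -> n1*n2 - U, identical p
  a <- c(0.3, 1.8, 2.2, 5); b <- c(0.9, 3.1, 4.4)
  r1 <- rank_compare(a, b); r2 <- rank_compare(b, a)
  expect_equal(r1$U + r2$U, length(a) * length(b))
  expect_equal(r1$p, r2$p)
  expect_error(rank_compare(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p matches full enumeration for n <= 8", {
  set.seed(77)
  vals <- sample(100, 8)  # distinct values, no ties
  for (n1 in 1:7) {
    a <- vals[seq_len(n1)]; b <- vals[(n1 + 1):8]
    expect_equal(rank_compare(a, b)$p, oracle_mwu_exact(a, b),
                 tolerance = 1e-12, label = paste("split", n1))
  }
  # and for a smaller combined n with a different draw
  v2 <- sample(50, 6)
  expect_equal(rank_compare(v2[1:2], v2[3:6])$p,
               oracle_mwu_exact(v2[1:2], v2[3:6]), tolerance = 1e-12)
})

test_that("GMT round trip preserves gene sets", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g9", "g2"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
  writeLines("BAD\tonly_two_fields", path)
  expect_error(read_gmt(path), "malformed")
})
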