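test_that("coefficient of variation follows sd/mean with n-1 denominator", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_identical(coefficient_of_variation(c(0, 0, 0)), Inf)
  expect_error(coefficient_of_variation(3), "at least 2")
  # scale invariance
  x <- rexp(20)
  expect_equal(coefficient_of_variation(7.7 * x),
               coefficient_of_variation(x), tolerance = 1e-12)
})

test_that("fold change from the mean is a plain scale-invariant ratio", {
  pp <- pathway_profile(matrix(c(1, 2, 3), 3, 1,
                               dimnames = list(paste0("S", 1:3), "P1")))
  expect_equal(unname(fold_change_from_mean(pp, "P1")), c(0.5, 1, 1.5))
  pp2 <- pathway_profile(matrix(c(2, 4, 6), 3, 1,
                                dimnames = list(paste0("S", 1:3), "P1")))
  expect_equal(fold_change_from_mean(pp2, "P1"),
               fold_change_from_mean(pp, "P1"))
  expect_equal(unname(fold_change_from_mean(pp, "P1", log2 = TRUE)),
               log2(c(0.5, 1, 1.5)))
  const <- pathway_profile(matrix(2, 3, 1,
                                  dimnames = list(paste0("S", 1:3), "P1")))
  expect_true(all(fold_change_from_mean(const, "P1") == 1))
  zero <- pathway_profile(matrix(0, 3, 1,
                                 dimnames = list(paste0("S", 1:3), "P1")))
  expect_error(fold_change_from_mean(zero, "P1"), "zero mean")
})

test_that("Bray-Curtis distances match the formula and vegan", {
  vals <- matrix(c(1, 0,
                   0, 1,
                   2, 2,
                   1, 1), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("S", 1:4), c("a", "b")))
  d <- bray_curtis_matrix(gene_profile(vals))
  expect_equal(d["S1", "S2"], 1)
  expect_equal(d["S3", "S4"], 1 / 3)
  expect_equal(d["S3", "S3"], 0)

  set.seed(5)
  big <- matrix(rexp(15 * 12), 15,
                dimnames = list(sprintf("S%02d", 1:15), sprintf("K%02d", 1:12)))
  d2 <- bray_curtis_matrix(gene_profile(big))
  # independent oracle: naive per-pair loop
  for (i in 1:14) for (j in (i + 1):15) {
    expected <- 1 - 2 * sum(pmin(big[i, ], big[j, ])) / (sum(big[i, ]) + sum(big[j, ]))
    expect_equal(unname(d2[i, j]), expected, tolerance = 1e-12)
  }
  expect_true(all(d2 >= 0 & d2 <= 1))
  skip_if_not_installed("vegan")
  expect_equal(unname(unclass(d2)),
               unname(as.matrix(vegan::vegdist(big, method = "bray"))),
               tolerance = 1e-12)
})

test_that("negative pair fraction counts anticorrelated pairs", {
  vals <- matrix(c(1, 2, 3,
                   3, 2, 1), ncol = 2,
                 dimnames = list(paste0("S", 1:3), c("a", "b")))
  expect_equal(negative_pair_fraction(gene_profile(vals)), 1)

  same <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2,
                 dimnames = list(paste0("S", 1:3), c("a", "b")))
  expect_equal(negative_pair_fraction(gene_profile(same)), 0)

  const <- matrix(c(1, 2, 3, 2, 2, 2), ncol = 2,
                  dimnames = list(paste0("S", 1:3), c("a", "b")))
  expect_error(suppressMessages(negative_pair_fraction(gene_profile(const))),
               "fewer than 2")
})

test_that("negative pair fraction matches the null correlation tail", {
  # independent genes: P(r < -0.3) at n = 200 from the exact t transform
  n <- 200
  t_crit <- -0.3 * sqrt((n - 2) / (1 - 0.09))
  p_null <- pt(t_crit, df = n - 2)
  set.seed(31)
  fracs <- replicate(10, {
    vals <- matrix(abs(rnorm(n * 10, 10)), n,
                   dimnames = list(sprintf("S%03d", 1:n), sprintf("K%02d", 1:10)))
    negative_pair_fraction(gene_profile(vals), r_threshold = -0.3)
  })
  n_pairs <- 45 * 10
  expect_lt(abs(mean(fracs) - p_null), 3 * sqrt(p_null * (1 - p_null) / n_pairs))
})

test_that("mantel test returns exact results in degenerate configurations", {
  set.seed(8)
  vals <- matrix(rexp(8 * 10), 8,
                 dimnames = list(sprintf("S%02d", 1:8), sprintf("K%02d", 1:10)))
  d1 <- bray_curtis_matrix(gene_profile(vals))
  out <- mantel_test(d1, d1, n_perm = 199, seed = 1)
  expect_equal(out$r, 1)
  expect_equal(out$p, 1 / 200)

  # positive affine transform leaves r = 1; p reproducible with a seed
  d2 <- distance_matrix(unclass(d1) * 2.5 + (1 - diag(8)) * 0.01)
  out2 <- mantel_test(d1, d2, n_perm = 199, seed = 1)
  expect_equal(out2$r, 1)
  expect_identical(mantel_test(d1, d2, n_perm = 99, seed = 7)$p,
                   mantel_test(d1, d2, n_perm = 99, seed = 7)$p)

  ids <- rownames(d1)
  d3 <- unclass(d1); dimnames(d3) <- list(letters[1:8], letters[1:8])
  expect_error(mantel_test(d1, distance_matrix(d3), 99), "different sample IDs")
  expect_error(mantel_test(d1, d1, n_perm = 10), "at least 99")
})

test_that("mantel statistic agrees with vegan on the same matrices", {
  skip_if_not_installed("vegan")
  set.seed(9)
  a <- matrix(rexp(10 * 8), 10,
              dimnames = list(sprintf("S%02d", 1:10), sprintf("K%02d", 1:8)))
  b <- matrix(rexp(10 * 8), 10,
              dimnames = list(sprintf("S%02d", 1:10), sprintf("K%02d", 1:8)))
  d1 <- bray_curtis_matrix(gene_profile(a))
  d2 <- bray_curtis_matrix(gene_profile(b))
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(unclass(d1)), as.dist(unclass(d2)),
                       permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("scheme variation comparison reports CoV ratios and a paired test", {
  set.seed(10)
  vals <- matrix(rexp(12 * 6) + 10, 12,
                 dimnames = list(sprintf("S%02d", 1:12), sprintf("P%02d", 1:6)))
  a <- pathway_profile(vals)
  ident <- compare_scheme_variation(a, a)
  expect_true(all(ident$report$cov_ratio == 1))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  # doubling one feature's spread about its mean doubles its CoV
  v2 <- vals
  v2[, 3] <- mean(vals[, 3]) + 2 * (vals[, 3] - mean(vals[, 3]))
  expect_true(all(v2[, 3] > 0))
  b <- pathway_profile(v2)
  cmp <- compare_scheme_variation(a, b)
  expect_equal(cmp$report$cov_ratio[cmp$report$feature == "P03"], 2,
               tolerance = 1e-12)
  expect_equal(cmp$report$cov_ratio[cmp$report$feature == "P01"], 1)

  few <- pathway_profile(vals[, 1:2])
  expect_error(compare_scheme_variation(a, few), "fewer than 3")
})

test_that("marker normalization unmasks planted variation relative to relative normalization", {
  w <- simulate_world(seed = 6)
  hits <- vapply(1:20, function(s) {
    sim <- simulate_profiles(w, n_samples = 15, noise_cv = 0,
                             genome_size_spread = 2, seed = s)
    std <- suppressWarnings(suppressMessages(run_pipeline(
      sim$profile, w$map, pipeline_config("standard"))))
    rev <- suppressWarnings(suppressMessages(run_pipeline(
      sim$profile, w$map,
      pipeline_config("custom", normalization = "single_copy",
                      scheme = "fractional"),
      markers = w$markers)))
    cmp <- compare_scheme_variation(std$pathways, rev$pathways)
    vp <- intersect(w$variable_pathways, cmp$report$feature)
    all(cmp$report$cov_ratio[cmp$report$feature %in% vp] > 1)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
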