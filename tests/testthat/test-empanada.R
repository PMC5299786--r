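test_that("gene classification partitions the mapped genes", {
  cls <- classify_genes(toy_map())
  expect_identical(cls$shared, "KO1")
  expect_identical(sort(cls$nonshared), c("KO2", "KO3"))

  all_single <- pathway_map(c("a", "b"), c("P1", "P2"))
  expect_length(classify_genes(all_single)$shared, 0)

  all_multi <- pathway_map(c("a", "a", "b", "b"), c("P1", "P2", "P1", "P2"))
  cls2 <- classify_genes(all_multi)
  expect_length(cls2$nonshared, 0)
  p <- toy_profile(matrix(c(1, 2), 1, dimnames = list("S1", c("a", "b"))))
  # no non-shared genes -> no support basis for any pathway
  expect_error(suppressWarnings(
    map_to_pathways(p, all_multi, "empanada", min_nonshared = 0,
                    min_mean_rel_abundance = 0)),
    "support")
})

test_that("eligibility uses map-level non-shared counts and mean relative abundance", {
  genes <- sprintf("K%02d", 1:21)
  map <- pathway_map(c(genes[1:10], genes[11:19], genes[20], genes[20], genes[21]),
                     c(rep("P1", 10), rep("P2", 9), "P1", "P2", "P3"))
  vals <- matrix(rep(1, 21), 1, dimnames = list("S1", genes))
  p <- gene_profile(vals)
  # P1 has 10 non-shared genes, P2 only 9, P3 has 1
  expect_identical(eligible_pathways(p, map, min_nonshared = 10,
                                     min_mean_rel_abundance = 1e-4), "P1")
  expect_identical(eligible_pathways(p, map, min_nonshared = 0,
                                     min_mean_rel_abundance = 0),
                   c("P1", "P2", "P3"))
  # abundance threshold: P3 holds 1/21 of the total, exclude it
  expect_identical(eligible_pathways(p, map, min_nonshared = 0,
                                     min_mean_rel_abundance = 0.1),
                   c("P1", "P2"))
})

test_that("pathway support is the mean of present non-shared genes", {
  map <- pathway_map(c("a", "b", "c", "c"), c("P1", "P1", "P1", "P2"))
  vals <- matrix(c(2, 4, 10,
                   0, 0, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  p <- gene_profile(vals)
  sup <- suppressWarnings(pathway_support(p, map))
  expect_equal(unname(sup[, "P1"]), c(3, 0)) # mean of a, b; shared c excluded
  expect_false("P2" %in% colnames(sup))      # no non-shared gene in profile
})

test_that("the three mapping schemes follow their definitions on a worked example", {
  # shared gene KO1 in P1+P2; non-shared KO2 (P1: support source) and KO3 (P2)
  map <- toy_map()
  vals <- matrix(c(3, 2, 1), 1, dimnames = list("S1", c("KO1", "KO2", "KO3")))
  p <- gene_profile(vals)

  frac <- map_to_pathways(p, map, "fractional", 0, 0)
  expect_equal(unname(frac$values[1, c("P1", "P2")]), c(2 + 1.5, 1 + 1.5))

  comp <- map_to_pathways(p, map, "complete", 0, 0)
  expect_equal(unname(comp$values[1, c("P1", "P2")]), c(2 + 3, 1 + 3))

  # supports: P1 = 2, P2 = 1 -> KO1 contributes 2 to P1, 1 to P2
  emp <- map_to_pathways(p, map, "empanada", 0, 0)
  expect_equal(unname(emp$values[1, c("P1", "P2")]), c(2 + 2, 1 + 1))
})

test_that("vectorized empanada equals the brute-force oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_mapping_instance(n_samples = sample(2:20, 1),
                                    n_genes = sample(10:50, 1),
                                    n_pathways = sample(2:8, 1),
                                    seed = seed)
    thr_ns <- sample(0:2, 1)
    thr_ab <- sample(c(0, 1e-3), 1)
    oracle <- brute_force_empanada(inst$profile, inst$map, thr_ns, thr_ab)
    if (is.null(oracle)) next
    got <- suppressWarnings(suppressMessages(
      map_to_pathways(inst$profile, inst$map, "empanada", thr_ns, thr_ab)))
    expect_identical(sort(colnames(got$values)), sort(colnames(oracle)))
    expect_lt(max(abs(got$values[, colnames(oracle)] - oracle)), 1e-9)
  }
})

test_that("fractional and empanada schemes conserve mapped abundance", {
  for (seed in 26:35) {
    inst <- random_mapping_instance(12, 30, 5, seed)
    for (scheme in c("fractional", "empanada")) {
      out <- suppressWarnings(suppressMessages(
        map_to_pathways(inst$profile, inst$map, scheme, 0, 0)))
      mapped <- unique(inst$map$gene[inst$map$pathway %in% colnames(out$values)])
      mapped <- intersect(mapped, colnames(inst$profile$values))
      expect_equal(rowSums(out$values),
                   rowSums(inst$profile$values[, mapped, drop = FALSE]),
                   tolerance = 1e-9)
    }
  }
})

test_that("scheme dominance and limit equivalences hold", {
  for (seed in 36:40) {
    inst <- random_mapping_instance(8, 25, 4, seed)
    frac <- suppressWarnings(suppressMessages(
      map_to_pathways(inst$profile, inst$map, "fractional", 0, 0)))
    comp <- suppressWarnings(suppressMessages(
      map_to_pathways(inst$profile, inst$map, "complete", 0, 0)))
    shared_cols <- intersect(colnames(frac$values), colnames(comp$values))
    expect_true(all(comp$values[, shared_cols] - frac$values[, shared_cols]
                    >= -1e-12))
  }

  # equal supports in a sample make empanada collapse to fractional there
  map <- toy_map()
  vals <- matrix(c(3, 5, 5), 1, dimnames = list("S1", c("KO1", "KO2", "KO3")))
  p <- gene_profile(vals)
  emp <- map_to_pathways(p, map, "empanada", 0, 0)
  frac <- map_to_pathways(p, map, "fractional", 0, 0)
  expect_equal(emp$values, frac$values, tolerance = 1e-12)
})

test_that("zero support triggers the uniform fractional fallback, not an error", {
  map <- toy_map()
  # sample S2 has zero abundance for both support genes
  vals <- matrix(c(3, 2, 1,
                   4, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("KO1", "KO2", "KO3")))
  p <- gene_profile(vals)
  expect_message(emp <- map_to_pathways(p, map, "empanada", 0, 0),
                 "fallback")
  expect_equal(unname(emp$values["S2", c("P1", "P2")]), c(2, 2))
})

test_that("mapping is sample-specific with no cross-sample leakage", {
  inst <- random_mapping_instance(10, 30, 5, 99)
  out <- suppressWarnings(suppressMessages(
    map_to_pathways(inst$profile, inst$map, "empanada", 0, 0)))
  perm <- sample(nrow(inst$profile$values))
  p2 <- gene_profile(inst$profile$values[perm, , drop = FALSE])
  out2 <- suppressWarnings(suppressMessages(
    map_to_pathways(p2, inst$map, "empanada", 0, 0)))
  expect_equal(out2$values, out$values[rownames(out2$values), ],
               tolerance = 1e-12)
})
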