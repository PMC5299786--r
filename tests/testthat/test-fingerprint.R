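# small deterministic cohort used across the fingerprint tests
fp_cohort <- function(n_ind = 6, n_genes = 40, boost = 10, seed = 1) {
  set.seed(seed)
  inds <- sprintf("I%02d", seq_len(n_ind))
  genes <- sprintf("K%03d", seq_len(n_genes))
  base <- rlnorm(n_genes)
  vals <- matrix(rep(base, each = n_ind), n_ind,
                 dimnames = list(paste0(inds, "_V1"), genes))
  # give individual i private genes (i-1)*ng/n + 1 ...
  per <- n_genes %/% n_ind
  sig <- split(genes[seq_len(per * n_ind)], rep(inds, each = per))[inds]
  for (i in seq_along(inds)) vals[i, sig[[i]]] <- vals[i, sig[[i]]] * boost
  meta <- sample_metadata(c(paste0(inds, "_V1"), paste0(inds, "_V2")),
                          rep(inds, 2), rep(1:2, each = n_ind))
  v2 <- vals
  rownames(v2) <- paste0(inds, "_V2")
  list(visit1 = gene_profile(vals), visit2 = gene_profile(v2),
       meta = meta, signatures = sig)
}

test_that("codes pick strict-argmax genes ranked by specificity ratio", {
  vals <- matrix(c(10, 5, 1,    # g1: max A, ratio 2
                   8, 4, 0,     # g2: max A, ratio 2
                   3, 3, 1,     # g3: tie for max -> excluded
                   0, 0, 2,     # g4: max C, second-highest 0 -> Inf ratio
                   1, 6, 2,     # g5: max B, ratio 3
                   3, 7, 19),   # g6: max C, ratio 19/7; equalizes row sums
                 nrow = 3,
                 dimnames = list(c("A_V1", "B_V1", "C_V1"), paste0("g", 1:6)))
  stopifnot(length(unique(rowSums(vals))) == 1L) # raw comparisons survive
  meta <- sample_metadata(rownames(vals), c("A", "B", "C"), 1L)
  codes <- suppressWarnings(build_codes(gene_profile(vals), meta, k = 2))
  expect_identical(sort(codes$A$gene), c("g1", "g2"))
  expect_identical(codes$B$gene, "g5")
  expect_identical(codes$C$gene, c("g4", "g6")) # Inf ratio ranks first
  expect_identical(codes$C$ratio[1], Inf)
  # g3 (tied max) is in no code
  expect_false("g3" %in% unlist(lapply(codes, `[[`, "gene")))
})

test_that("codes are pairwise disjoint and bounded by k", {
  coh <- fp_cohort(n_ind = 8, n_genes = 64, seed = 3)
  codes <- suppressWarnings(build_codes(coh$visit1, coh$meta, k = 5))
  genes <- unlist(lapply(codes, `[[`, "gene"))
  expect_false(anyDuplicated(genes) > 0)
  expect_true(all(vapply(codes, nrow, integer(1)) <= 5))
})

test_that("agreement scores count strict visit-2 maxima per code gene", {
  coh <- fp_cohort(seed = 4)
  codes <- suppressWarnings(build_codes(coh$visit1, coh$meta, k = 3))
  scores <- suppressWarnings(agreement_scores(codes, coh$visit2, coh$meta))
  # visit2 == visit1, so each individual's own sample collects its code size
  for (i in names(codes))
    expect_equal(scores[paste0(i, "_V2"), i], nrow(codes[[i]]))
  # score bound: no entry exceeds the owner's code size
  expect_true(all(t(scores) <= vapply(codes, nrow, integer(1))))
  # column sums bounded by union code size
  expect_lte(sum(scores), sum(vapply(codes, nrow, integer(1))))
})

test_that("identification is perfect on a noise-free repeated cohort", {
  coh <- fp_cohort(seed = 5)
  codes <- suppressWarnings(build_codes(coh$visit1, coh$meta, k = 4))
  res <- suppressWarnings(identify_individuals(codes, coh$visit2, coh$meta))
  expect_equal(res$accuracy, 1)
  expect_true(all(res$assignments$correct))
})

test_that("identification is invariant to rescaling a visit-2 sample", {
  coh <- fp_cohort(seed = 6)
  codes <- suppressWarnings(build_codes(coh$visit1, coh$meta, k = 4))
  v2 <- coh$visit2$values
  v2[2, ] <- v2[2, ] * 50 # depth change; relative normalization removes it
  res <- suppressWarnings(identify_individuals(
    codes, gene_profile(v2), coh$meta))
  expect_equal(res$accuracy, 1)
})

test_that("a tie in visit-2 maxima skips the gene; assignment ties are unassigned", {
  vals <- matrix(c(4, 1,
                   1, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A_V1", "B_V1"), c("g1", "g2")))
  meta <- sample_metadata(c("A_V1", "B_V1", "A_V2", "B_V2"),
                          rep(c("A", "B"), 2), rep(1:2, each = 2))
  codes <- suppressWarnings(build_codes(gene_profile(vals), meta, k = 1))
  # visit2 where both samples are identical: every gene ties -> all scores 0
  v2 <- matrix(1, 2, 2, dimnames = list(c("A_V2", "B_V2"), c("g1", "g2")))
  scores <- agreement_scores(codes, gene_profile(v2), meta)
  expect_true(all(scores == 0))
  res <- identify_individuals(codes, gene_profile(v2), meta)
  expect_true(all(is.na(res$assignments$assigned_individual)))
  expect_equal(res$accuracy, 0)
})

test_that("accuracy sweep spans code sizes and is 1 everywhere on clean data", {
  coh <- fp_cohort(seed = 7)
  sweep <- suppressWarnings(accuracy_sweep(coh$visit1, coh$visit2, coh$meta,
                                           k_values = 1:5))
  expect_identical(sweep$k, 1:5)
  expect_true(all(sweep$accuracy == 1))
  expect_error(accuracy_sweep(coh$visit1, coh$visit2, coh$meta,
                              k_values = integer()), "non-empty")
})

test_that("planted signatures survive noise and null cohorts identify at chance", {
  w <- simulate_world(n_genes = 900, seed = 5)
  coh <- simulate_two_visit_cohort(w, n_individuals = 36,
                                   signature_strength = 5, noise_cv = 0.1,
                                   seed = 2)
  codes <- suppressWarnings(build_codes(coh$visit1, coh$meta, k = 20))
  expect_length(codes, 36)
  expect_true(all(vapply(codes, nrow, integer(1)) == 20))
  res <- suppressWarnings(identify_individuals(codes, coh$visit2, coh$meta))
  expect_gte(res$accuracy, 0.9)

  # no signal: mean accuracy compatible with 1/n guessing
  accs <- vapply(1:10, function(s) {
    ch <- simulate_two_visit_cohort(w, n_individuals = 36,
                                    signature_strength = 0, noise_cv = 0.2,
                                    seed = s)
    cd <- suppressWarnings(build_codes(ch$visit1, ch$meta, k = 20))
    suppressWarnings(identify_individuals(cd, ch$visit2, ch$meta))$accuracy
  }, numeric(1))
  p0 <- 1 / 36
  expect_lt(abs(mean(accs) - p0), 3 * sqrt(p0 * (1 - p0) / (10 * 36)))
})
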