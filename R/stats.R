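#' Coefficient of variation
#'
#' Standard deviation (n-1 denominator) divided by the mean — the package's
#' measure of between-sample functional variability. Scale-invariant:
#' `coefficient_of_variation(c * x)` equals `coefficient_of_variation(x)`
#' for any `c > 0`.
#'
#' @param values Numeric vector of non-negative values, length >= 2.
#' @return Non-negative real; `Inf` when the mean is zero (undefined CoV
#'   sentinel).
#' @export
coefficient_of_variation <- function(values) {
  if (!is.numeric(values))
    stop("`values` must be numeric", call. = FALSE)
  .cov_vector(values, "sample")
}

#' Per-sample fold change from the mean abundance
#'
#' The ratio of each sample's abundance of one feature to the across-sample
#' mean abundance of that feature (optionally log2-transformed).
#'
#' @param profile A `pathway_profile` or `gene_profile`.
#' @param feature Feature (column) ID.
#' @param log2 Return log2 fold changes instead of plain ratios.
#' @return Named numeric vector over samples.
#' @export
fold_change_from_mean <- function(profile, feature, log2 = FALSE) {
  stopifnot(inherits(profile, "pathway_profile") || inherits(profile, "gene_profile"))
  if (!feature %in% colnames(profile$values))
    stop("feature '", feature, "' not present in the profile", call. = FALSE)
  x <- profile$values[, feature]
  m <- mean(x)
  if (m <= 0)
    stop("feature '", feature, "' has zero mean abundance", call. = FALSE)
  fc <- x / m
  if (log2) base::log2(fc) else fc
}

#' Bray-Curtis distance matrix between samples
#'
#' `d(i, j) = 1 - 2 * sum(pmin(x_i, x_j)) / (sum(x_i) + sum(x_j))` over
#' features, the standard abundance-based dissimilarity for community
#' profiles; values lie in \[0, 1\].
#'
#' @param profile A `gene_profile` or `pathway_profile` with a positive
#'   total in every sample.
#' @return A samples x samples [distance_matrix()].
#' @export
bray_curtis_matrix <- function(profile) {
  stopifnot(inherits(profile, "pathway_profile") || inherits(profile, "gene_profile"))
  x <- profile$values
  totals <- rowSums(x)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[totals == 0], collapse = ", "), call. = FALSE)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    if (i < n) {
      js <- (i + 1L):n
      mins <- colSums(pmin(t(x[js, , drop = FALSE]), x[i, ]))
      dij <- 1 - 2 * mins / (totals[i] + totals[js])
      d[i, js] <- dij
      d[js, i] <- dij
    }
  }
  d[d < 0] <- 0 # guard FP underflow
  distance_matrix(d)
}

#' Fraction of negatively correlated gene-family pairs
#'
#' Among a set of member gene families (e.g. the genes annotated to one
#' pathway), computes the fraction of unordered pairs whose Pearson
#' correlation across samples falls below `r_threshold`. A substantial
#' negative fraction indicates alternative functional strategies within the
#' group rather than a cohesive co-varying unit. Genes with zero variance
#' are excluded (their correlation is undefined); the count is reported via
#' `message()`.
#'
#' @param profile A [gene_profile()] with >= 3 samples.
#' @param members Character vector of member gene IDs (default: all genes).
#' @param r_threshold Correlation threshold (default -0.3).
#' @return Fraction in \[0, 1\].
#' @export
negative_pair_fraction <- function(profile, members = NULL, r_threshold = -0.3) {
  stopifnot(inherits(profile, "gene_profile"))
  if (nrow(profile$values) < 3L)
    stop("need at least 3 samples to estimate correlations", call. = FALSE)
  if (is.null(members)) members <- colnames(profile$values)
  members <- intersect(members, colnames(profile$values))
  x <- profile$values[, members, drop = FALSE]
  vars <- apply(x, 2L, stats::var)
  n_const <- sum(vars == 0)
  if (n_const > 0L) {
    message("negative_pair_fraction: excluded ", n_const,
            " zero-variance gene(s)")
    x <- x[, vars > 0, drop = FALSE]
  }
  if (ncol(x) < 2L)
    stop("fewer than 2 genes with nonzero variance", call. = FALSE)
  r <- stats::cor(x)
  ut <- r[upper.tri(r)]
  mean(ut < r_threshold)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' permutation p-value obtained by jointly permuting the rows and columns
#' of `d2`: `p = (1 + #permutations with r* >= r) / (1 + n_perm)`. The +1
#' correction means the p-value is never exactly zero.
#'
#' @param d1,d2 [distance_matrix()] objects over the same IDs (`d2` is
#'   aligned to `d1`'s ID order).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return List with elements `r`, `p` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"))
  if (n_perm < 99) stop("`n_perm` must be at least 99", call. = FALSE)
  ids <- rownames(d1)
  if (!setequal(ids, rownames(d2)))
    stop("distance matrices are over different sample IDs", call. = FALSE)
  m1 <- .dm_values(d1)
  m2 <- .dm_values(d2)[ids, ids]
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- stats::cor(v1, m2[ut])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- nrow(m1)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm <- stats::cor(v1, m2[p, p][ut])
    if (r_perm >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = as.integer(n_perm))
}

#' Compare per-feature variation between two pathway profiles
#'
#' Computes the coefficient of variation of every shared feature under two
#' processing schemes (e.g. relative vs single-copy normalization, or
#' fractional vs support-based mapping), the per-feature CoV ratio B/A, and
#' a paired test across features of whether scheme B changes variation
#' overall.
#'
#' @param profile_a,profile_b `pathway_profile` objects over (mostly) the
#'   same features; the intersection is used, with a warning when features
#'   are dropped. At least 3 shared features are required.
#' @param test `"t"` for a paired Student t test on per-feature CoV values
#'   (default) or `"wilcoxon"` for an unpaired rank-sum test (appropriate
#'   when the two profiles cover different aggregate definitions).
#' @return List with elements `report` (data frame: `feature`, `cov_a`,
#'   `cov_b`, `cov_ratio`), `statistic`, `p.value`, `method`.
#' @export
compare_scheme_variation <- function(profile_a, profile_b,
                                     test = c("t", "wilcoxon")) {
  stopifnot(inherits(profile_a, "pathway_profile") || inherits(profile_a, "gene_profile"),
            inherits(profile_b, "pathway_profile") || inherits(profile_b, "gene_profile"))
  test <- match.arg(test)
  fa <- colnames(profile_a$values)
  fb <- colnames(profile_b$values)
  shared <- intersect(fa, fb)
  if (test == "t" && length(shared) < 3L)
    stop("fewer than 3 shared features between the two profiles", call. = FALSE)
  if (!setequal(fa, fb))
    warning(length(fa) + length(fb) - 2L * length(shared),
            " feature(s) present in only one profile dropped from pairing",
            call. = FALSE)
  cov_a <- apply(profile_a$values[, shared, drop = FALSE], 2L, .cov_vector)
  cov_b <- apply(profile_b$values[, shared, drop = FALSE], 2L, .cov_vector)
  report <- data.frame(feature = shared, cov_a = unname(cov_a),
                       cov_b = unname(cov_b),
                       cov_ratio = unname(cov_b / cov_a),
                       stringsAsFactors = FALSE)
  finite <- is.finite(cov_a) & is.finite(cov_b)
  a <- cov_a[finite]
  b <- cov_b[finite]
  if (test == "t") {
    if (isTRUE(all.equal(a, b, tolerance = 1e-12))) {
      statistic <- 0
      p <- 1
    } else {
      tt <- stats::t.test(b, a, paired = TRUE)
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    }
    method <- "paired t test on per-feature CoV"
  } else {
    # unpaired comparison uses every feature of each profile, not just the
    # shared ones (the aggregate definitions may differ entirely)
    a <- apply(profile_a$values, 2L, .cov_vector)
    b <- apply(profile_b$values, 2L, .cov_vector)
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    wt <- stats::wilcox.test(b, a, exact = FALSE)
    statistic <- unname(wt$statistic)
    p <- wt$p.value
    method <- "Wilcoxon rank-sum test on per-feature CoV"
  }
  list(report = report, statistic = statistic, p.value = p, method = method)
}
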