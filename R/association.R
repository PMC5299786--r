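#' Case/control association of each pathway
#'
#' Two-sided Wilcoxon rank-sum test of each pathway's abundance between
#' case and control samples, with Benjamini-Hochberg adjustment across
#' pathways. The reported association score is the tie-corrected
#' standardized rank-sum z statistic, positive when the pathway is enriched
#' in cases. Being rank-based, p-values are invariant to any monotone
#' per-pathway transform of the abundances.
#'
#' @param profile A [pathway_profile()] (or `gene_profile`).
#' @param meta A [sample_metadata()] with a `group` column covering the
#'   profile's samples; both groups need >= 2 samples.
#' @return An `association_result` data frame with columns `pathway`,
#'   `statistic`, `p`, `q` and `direction`
#'   (`enriched_in_case` / `depleted_in_case` / `none`).
#' @export
pathway_association <- function(profile, meta) {
  stopifnot(inherits(profile, "pathway_profile") || inherits(profile, "gene_profile"))
  stopifnot(inherits(meta, "sample_metadata"))
  if (is.null(meta$group))
    stop("metadata has no `group` column", call. = FALSE)
  samples <- rownames(profile$values)
  grp <- meta$group[match(samples, meta$sample_id)]
  if (anyNA(grp))
    stop("group label missing for sample(s): ",
         paste(utils::head(samples[is.na(grp)], 5), collapse = ", "),
         call. = FALSE)
  n_case <- sum(grp == "case")
  n_ctrl <- sum(grp == "control")
  if (n_case < 2L || n_ctrl < 2L)
    stop("need at least 2 samples in each of case and control", call. = FALSE)
  res <- t(apply(profile$values, 2L, function(x) {
    .ranksum_one(x[grp == "case"], x[grp == "control"])
  }))
  out <- data.frame(pathway = colnames(profile$values),
                    statistic = res[, "z"], p = res[, "p"],
                    q = stats::p.adjust(res[, "p"], method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$direction <- ifelse(out$statistic > 0, "enriched_in_case",
                          ifelse(out$statistic < 0, "depleted_in_case", "none"))
  class(out) <- c("association_result", "data.frame")
  out
}

# signed standardized rank-sum z (ties corrected) + two-sided Wilcoxon p
.ranksum_one <- function(case, ctrl) {
  n1 <- length(case)
  n2 <- length(ctrl)
  r <- rank(c(case, ctrl))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  p <- suppressWarnings(
    stats::wilcox.test(case, ctrl, alternative = "two.sided")$p.value)
  c(z = z, p = p)
}

#' Compare association results between two processing pipelines
#'
#' Quantifies the overall consistency of disease-association scores
#' produced by two pipelines (Pearson correlation of the signed statistics
#' over shared pathways) and lists the pathways that cross the FDR
#' significance boundary in exactly one pipeline — the "hidden association"
#' pattern in which a revised pipeline reveals disease links that standard
#' processing masks (or vice versa).
#'
#' @param res_a,res_b `association_result` objects sharing >= 3 pathways.
#' @param q_threshold FDR boundary (default 0.05).
#' @return List with `r` (Pearson correlation of statistics), `only_in_a`
#'   and `only_in_b` (pathways significant in exactly one result), and
#'   `shared_pathways`.
#' @export
compare_pipelines <- function(res_a, res_b, q_threshold = 0.05) {
  stopifnot(inherits(res_a, "association_result"),
            inherits(res_b, "association_result"))
  shared <- intersect(res_a$pathway, res_b$pathway)
  if (length(shared) < 3L)
    stop("fewer than 3 shared pathways between the two results", call. = FALSE)
  sa <- res_a$statistic[match(shared, res_a$pathway)]
  sb <- res_b$statistic[match(shared, res_b$pathway)]
  qa <- res_a$q[match(shared, res_a$pathway)]
  qb <- res_b$q[match(shared, res_b$pathway)]
  sig_a <- shared[qa < q_threshold]
  sig_b <- shared[qb < q_threshold]
  list(r = stats::cor(sa, sb),
       only_in_a = setdiff(sig_a, sig_b),
       only_in_b = setdiff(sig_b, sig_a),
       shared_pathways = shared)
}
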