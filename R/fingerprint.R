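#' Build functional metagenomic codes from first-visit profiles
#'
#' For each individual, the candidate markers are the gene families for
#' which that individual's first-visit sample has the strictly highest
#' relative abundance among all individuals. Candidates are ranked by the
#' ratio of the individual's abundance to the second-highest abundance
#' (a second-highest of zero ranks as infinitely specific, ordered among
#' such genes by own abundance then gene ID), and the top `k` form the
#' individual's code. Codes are pairwise disjoint by construction: a gene
#' has at most one strict maximum. An individual with fewer than `k`
#' candidates receives a shorter code with a warning.
#'
#' @param visit1 A [gene_profile()] with exactly one sample per individual
#'   (relative normalization is applied internally).
#' @param meta A [sample_metadata()] covering the samples of `visit1`.
#' @param k Code size (default 20).
#' @return A `metagenomic_codes` object: named list of per-individual data
#'   frames with columns `gene` and `ratio`, plus attribute `k`.
#' @export
build_codes <- function(visit1, meta, k = 20) {
  stopifnot(inherits(visit1, "gene_profile"), inherits(meta, "sample_metadata"))
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  samples <- rownames(visit1$values)
  ind <- meta$individual_id[match(samples, meta$sample_id)]
  if (anyNA(ind))
    stop("metadata missing for sample(s): ",
         paste(utils::head(samples[is.na(ind)], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ind))
    stop("more than one first-visit sample for individual(s): ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "), call. = FALSE)
  if (length(ind) < 2L)
    stop("need at least 2 individuals to build codes", call. = FALSE)
  rel <- relative_normalize(visit1)$values
  codes <- lapply(seq_along(ind), function(i) {
    x_i <- rel[i, ]
    others <- rel[-i, , drop = FALSE]
    second <- apply(others, 2L, max)
    cand <- which(x_i > second) # strict maximum; ties excluded everywhere
    if (length(cand) == 0L)
      return(data.frame(gene = character(), ratio = numeric(),
                        stringsAsFactors = FALSE))
    ratio <- x_i[cand] / second[cand] # 0 second-highest -> Inf
    g <- names(x_i)[cand]
    ord <- order(-ratio, -x_i[cand], g)
    top <- utils::head(ord, k)
    data.frame(gene = g[top], ratio = unname(ratio[top]),
               stringsAsFactors = FALSE)
  })
  names(codes) <- ind
  short <- ind[vapply(codes, nrow, integer(1)) < k]
  if (length(short))
    warning("individual(s) with fewer than k = ", k, " candidate genes: ",
            paste(short, collapse = ", "), call. = FALSE)
  all_genes <- unlist(lapply(codes, `[[`, "gene"), use.names = FALSE)
  stopifnot(!anyDuplicated(all_genes)) # disjointness by strict-argmax
  structure(codes, k = as.integer(k), class = "metagenomic_codes")
}

#' @export
print.metagenomic_codes <- function(x, ...) {
  cat("<metagenomic_codes> ", length(x), " individuals, k = ", attr(x, "k"),
      ", union size ", sum(vapply(x, nrow, integer(1))), "\n", sep = "")
  invisible(x)
}

#' Agreement scores between second-visit samples and first-visit codes
#'
#' For every marker gene in the union of the codes, the second-visit sample
#' with the strictly highest relative abundance of that gene earns one
#' point toward the individual whose code contains the gene. A tie for the
#' maximum scores no point. Each sample's score against an individual is
#' therefore bounded by that individual's code size.
#'
#' @param codes A `metagenomic_codes` object from [build_codes()].
#' @param visit2 A [gene_profile()] of second-visit samples (relative
#'   normalization applied internally). Code genes absent from the profile
#'   are skipped with a warning.
#' @param meta A [sample_metadata()] covering the samples of `visit2`.
#' @return Integer matrix, second-visit samples x individuals.
#' @export
agreement_scores <- function(codes, visit2, meta) {
  stopifnot(inherits(codes, "metagenomic_codes"),
            inherits(visit2, "gene_profile"),
            inherits(meta, "sample_metadata"))
  rel <- relative_normalize(visit2)$values
  samples <- rownames(rel)
  owners <- rep(names(codes), vapply(codes, nrow, integer(1)))
  genes <- unlist(lapply(codes, `[[`, "gene"), use.names = FALSE)
  present <- genes %in% colnames(rel)
  if (any(!present)) {
    warning(sum(!present), " code gene(s) absent from the second-visit ",
            "profile skipped", call. = FALSE)
    owners <- owners[present]
    genes <- genes[present]
  }
  scores <- matrix(0L, nrow = length(samples), ncol = length(codes),
                   dimnames = list(samples, names(codes)))
  if (length(genes) == 0L) return(scores)
  sub <- rel[, genes, drop = FALSE]
  for (j in seq_along(genes)) {
    x <- sub[, j]
    top <- which(x == max(x))
    if (length(top) == 1L) # strict maximum required
      scores[top, owners[j]] <- scores[top, owners[j]] + 1L
  }
  scores
}

#' Identify individuals from second-visit samples
#'
#' Assigns each second-visit sample to the individual with which it has the
#' highest agreement score; a tied maximum leaves the sample unassigned
#' (counted incorrect). Accuracy is the fraction of samples assigned to
#' their true individual.
#'
#' @inheritParams agreement_scores
#' @return An `identification_result` list with elements `assignments`
#'   (data frame: `sample_id`, `true_individual`, `assigned_individual`,
#'   `agreement_score`, `correct`) and `accuracy`.
#' @export
identify_individuals <- function(codes, visit2, meta) {
  scores <- agreement_scores(codes, visit2, meta)
  samples <- rownames(scores)
  truth <- meta$individual_id[match(samples, meta$sample_id)]
  assigned <- character(length(samples))
  best <- integer(length(samples))
  for (i in seq_along(samples)) {
    s <- scores[i, ]
    top <- which(s == max(s))
    best[i] <- max(s)
    assigned[i] <- if (length(top) == 1L) colnames(scores)[top] else NA_character_
  }
  correct <- !is.na(assigned) & assigned == truth
  res <- list(assignments = data.frame(sample_id = samples,
                                       true_individual = truth,
                                       assigned_individual = assigned,
                                       agreement_score = best,
                                       correct = correct,
                                       stringsAsFactors = FALSE),
              accuracy = mean(correct))
  class(res) <- "identification_result"
  res
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result> ", sum(x$assignments$correct), " of ",
      nrow(x$assignments), " samples correctly identified (accuracy ",
      sprintf("%.3f", x$accuracy), ")\n", sep = "")
  invisible(x)
}

#' Identification accuracy across code sizes
#'
#' Rebuilds codes and evaluates identification for every requested code
#' size. Accuracy is not guaranteed to be monotone in `k`, so the full
#' table is reported.
#'
#' @param visit1,visit2 First- and second-visit [gene_profile()] objects.
#' @param meta A [sample_metadata()] covering both visits.
#' @param k_values Integer vector of code sizes (default `1:20`).
#' @return Data frame with columns `k` and `accuracy`.
#' @export
accuracy_sweep <- function(visit1, visit2, meta, k_values = 1:20) {
  if (length(k_values) == 0L)
    stop("`k_values` must be non-empty", call. = FALSE)
  acc <- vapply(k_values, function(k) {
    codes <- suppressWarnings(build_codes(visit1, meta, k = k))
    suppressWarnings(identify_individuals(codes, visit2, meta))$accuracy
  }, numeric(1))
  data.frame(k = as.integer(k_values), accuracy = acc)
}
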