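#' Aggregate definition: named groups of gene families
#'
#' @param members Named list mapping aggregate IDs to non-empty character
#'   vectors of gene IDs. For the `cooccurrence` basis the groups must form
#'   a partition of the clustered gene set.
#' @param basis `"pathway"` (annotation-based, possibly overlapping) or
#'   `"cooccurrence"` (genome co-occurrence clusters, a partition).
#' @return An object of class `aggregate_definition`.
#' @export
aggregate_definition <- function(members, basis = c("pathway", "cooccurrence")) {
  basis <- match.arg(basis)
  if (length(members) == 0L || is.null(names(members)) ||
      any(!nzchar(names(members))))
    stop("`members` must be a non-empty named list", call. = FALSE)
  if (anyDuplicated(names(members)))
    stop("duplicate aggregate IDs", call. = FALSE)
  sizes <- lengths(members)
  if (any(sizes == 0L))
    stop("empty aggregate(s): ",
         paste(names(members)[sizes == 0L], collapse = ", "), call. = FALSE)
  members <- lapply(members, function(g) unique(as.character(g)))
  if (basis == "cooccurrence") {
    all_genes <- unlist(members, use.names = FALSE)
    if (anyDuplicated(all_genes))
      stop("cooccurrence aggregates must be disjoint", call. = FALSE)
  }
  structure(list(members = members, basis = basis),
            class = "aggregate_definition")
}

#' @export
print.aggregate_definition <- function(x, ...) {
  cat("<aggregate_definition> ", length(x$members), " ", x$basis,
      " aggregates over ", length(unique(unlist(x$members, use.names = FALSE))),
      " gene families\n", sep = "")
  invisible(x)
}

#' Build pathway-basis aggregates from an association map
#'
#' @param map A [pathway_map()].
#' @return An [aggregate_definition()] with `basis = "pathway"` (groups may
#'   overlap: shared genes appear in every pathway they map to).
#' @export
pathway_aggregates <- function(map) {
  stopifnot(inherits(map, "pathway_map"))
  if (nrow(map) == 0L) stop("pathway map is empty", call. = FALSE)
  aggregate_definition(split(map$gene, map$pathway), basis = "pathway")
}

#' Jaccard distance between gene families across genomes
#'
#' Presence is copy number > 0. The similarity of two gene families is the
#' fraction of genomes carrying both out of genomes carrying at least one;
#' the returned value is the Jaccard distance 1 - similarity, as required by
#' distance-based clustering.
#'
#' @param content A [genome_content()]. Genes present in no genome are
#'   excluded with a warning (their union with any partner may be empty).
#' @return A genes x genes [distance_matrix()] with entries in \[0, 1\].
#' @export
jaccard_distance <- function(content) {
  stopifnot(inherits(content, "genome_content"))
  pres <- content$copies > 0
  storage.mode(pres) <- "double"
  n_g <- colSums(pres)
  if (any(n_g == 0)) {
    warning(sum(n_g == 0), " gene(s) present in no genome excluded from ",
            "co-occurrence distances", call. = FALSE)
    pres <- pres[, n_g > 0, drop = FALSE]
    n_g <- n_g[n_g > 0]
  }
  if (ncol(pres) < 1L)
    stop("no genes present in any genome", call. = FALSE)
  inter <- crossprod(pres)
  uni <- outer(n_g, n_g, `+`) - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  d <- (d + t(d)) / 2 # enforce exact symmetry against FP noise
  distance_matrix(d)
}

#' Genome co-occurrence aggregates by complete-linkage clustering
#'
#' Cuts a complete-linkage dendrogram of the gene-gene Jaccard distances
#' into exactly `n_aggregates` groups. Gene families that co-occur in the
#' same genomes form cohesive genome functional units, an annotation-free
#' alternative to pathway-based grouping. Genes are ordered
#' lexicographically before clustering so results are deterministic across
#' platforms.
#'
#' @param dist A genes x genes [distance_matrix()] (e.g. from
#'   [jaccard_distance()]).
#' @param n_aggregates Number of clusters, between 1 and the number of
#'   genes. A natural default is the number of distinct pathways in the
#'   annotation map being compared against.
#' @return An [aggregate_definition()] with `basis = "cooccurrence"`;
#'   aggregate IDs are `CA001`, `CA002`, ... in order of each cluster's
#'   lexicographically smallest member.
#' @export
cooccurrence_aggregates <- function(dist, n_aggregates) {
  stopifnot(inherits(dist, "distance_matrix"))
  n <- nrow(dist)
  if (!is.numeric(n_aggregates) || length(n_aggregates) != 1L ||
      n_aggregates < 1 || n_aggregates > n)
    stop("`n_aggregates` must be between 1 and the number of genes (", n, ")",
         call. = FALSE)
  ord <- order(rownames(dist))
  d <- .dm_values(dist)[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, k = as.integer(n_aggregates))
  groups <- split(names(cl), cl)
  first <- vapply(groups, function(g) min(g), character(1))
  groups <- groups[order(first)]
  names(groups) <- sprintf("CA%03d", seq_along(groups))
  aggregate_definition(groups, basis = "cooccurrence")
}

#' Sum gene-family abundances over aggregates
#'
#' The abundance of an aggregate in a sample is the sum of the abundances
#' of its member gene families present in the profile. Under the pathway
#' basis a shared gene is counted fully in every aggregate containing it
#' (uniform complete mapping); see [map_to_pathways()] for fractional and
#' support-based alternatives.
#'
#' @param profile A [gene_profile()].
#' @param agg An [aggregate_definition()].
#' @return A [pathway_profile()] (samples x aggregates, `scheme = "sum"`).
#'   Profile genes belonging to no aggregate are ignored; their count is
#'   reported via `message()`.
#' @export
aggregate_abundance <- function(profile, agg) {
  stopifnot(inherits(profile, "gene_profile"),
            inherits(agg, "aggregate_definition"))
  genes <- colnames(profile$values)
  vals <- vapply(agg$members, function(members) {
    cols <- intersect(members, genes)
    if (length(cols) == 0L)
      return(rep(0, nrow(profile$values)))
    rowSums(profile$values[, cols, drop = FALSE])
  }, numeric(nrow(profile$values)))
  if (nrow(profile$values) == 1L)
    vals <- matrix(vals, nrow = 1L, dimnames = list(rownames(profile$values),
                                                    names(agg$members)))
  else rownames(vals) <- rownames(profile$values)
  unassigned <- setdiff(genes, unlist(agg$members, use.names = FALSE))
  message("aggregate_abundance: ", length(unassigned),
          " profile gene(s) belong to no aggregate")
  pathway_profile(vals, scheme = "sum", basis = agg$basis)
}
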