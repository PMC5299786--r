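#' Construct a sample-by-gene abundance profile
#'
#' A `gene_profile` is the central data structure of the package: a dense
#' numeric matrix of non-negative gene-family (KO-style) abundances with
#' samples in rows and gene families in columns, plus a record of how the
#' values were normalized.
#'
#' @param values Numeric matrix, samples x genes, with unique row names
#'   (sample IDs) and unique column names (gene-family IDs). Values must be
#'   finite and non-negative; missing values are rejected.
#' @param normalization One of `"raw"` (e.g. mapped read counts),
#'   `"relative"` (each sample row sums to 1) or `"copy_number"` (values on
#'   the average-copies-per-genome scale produced by
#'   [single_copy_normalize()]).
#' @return An object of class `gene_profile` with elements `values` and
#'   `normalization`.
#' @seealso [relative_normalize()], [single_copy_normalize()],
#'   [read_gene_profile()]
#' @export
gene_profile <- function(values, normalization = c("raw", "relative", "copy_number")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .check_profile_matrix(values, what = "gene")
  if (normalization == "relative") {
    sums <- rowSums(values)
    if (any(abs(sums - 1) > 1e-9)) {
      bad <- rownames(values)[which.max(abs(sums - 1))]
      stop("normalization 'relative' requires each sample row to sum to 1; sample '",
           bad, "' sums to ", format(sums[bad]), call. = FALSE)
    }
  }
  structure(list(values = values, normalization = normalization),
            class = "gene_profile")
}

#' Construct a sample-by-pathway abundance profile
#'
#' @param values Numeric matrix, samples x pathways (or aggregates), with
#'   unique dimnames; non-negative and finite.
#' @param scheme Mapping scheme that produced the values: `"fractional"`,
#'   `"complete"`, `"empanada"`, or `"sum"` for plain aggregate summation.
#' @param basis Whether columns are annotation pathways or genome
#'   co-occurrence aggregates.
#' @return An object of class `pathway_profile`.
#' @export
pathway_profile <- function(values,
                            scheme = c("fractional", "complete", "empanada", "sum"),
                            basis = c("pathway", "cooccurrence")) {
  scheme <- match.arg(scheme)
  basis <- match.arg(basis)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .check_profile_matrix(values, what = "pathway")
  structure(list(values = values, scheme = scheme, basis = basis),
            class = "pathway_profile")
}

.check_profile_matrix <- function(values, what = "gene") {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("profile matrix must have sample row names and ", what,
         " column names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate ", what, " IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values))
    stop("profile contains missing values", call. = FALSE)
  if (any(!is.finite(values)))
    stop("profile contains non-finite values", call. = FALSE)
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample '", rownames(values)[idx[1]],
         "', ", what, " '", colnames(values)[idx[2]], "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gene_profile <- function(x, ...) {
  cat("<gene_profile> ", nrow(x$values), " samples x ", ncol(x$values),
      " gene families (normalization: ", x$normalization, ")\n", sep = "")
  invisible(x)
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat("<pathway_profile> ", nrow(x$values), " samples x ", ncol(x$values),
      " ", x$basis, " aggregates (scheme: ", x$scheme, ")\n", sep = "")
  invisible(x)
}

#' Sample and feature identifiers of a profile
#'
#' @param x A `gene_profile` or `pathway_profile`.
#' @return Character vector of sample IDs / feature IDs.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Construct a gene-family to pathway association map
#'
#' Associations are a many-to-many relation: a gene family mapped to two or
#' more pathways is *shared*, one mapped to exactly one pathway is
#' *non-shared*. Exact duplicate pairs are removed with a warning.
#'
#' @param gene Character vector of gene-family IDs.
#' @param pathway Character vector of pathway IDs, same length.
#' @return A `pathway_map`: a data frame with columns `gene` and `pathway`.
#' @export
pathway_map <- function(gene, pathway) {
  gene <- as.character(gene)
  pathway <- as.character(pathway)
  if (length(gene) != length(pathway))
    stop("`gene` and `pathway` must have the same length", call. = FALSE)
  if (length(gene) == 0L) {
    map <- data.frame(gene = character(), pathway = character(),
                      stringsAsFactors = FALSE)
    class(map) <- c("pathway_map", "data.frame")
    return(map)
  }
  key <- paste(gene, pathway, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate gene-pathway association(s) removed", call. = FALSE)
    keep <- !duplicated(key)
    gene <- gene[keep]
    pathway <- pathway[keep]
  }
  map <- data.frame(gene = gene, pathway = pathway, stringsAsFactors = FALSE)
  class(map) <- c("pathway_map", "data.frame")
  map
}

#' Construct a genome-by-gene copy-number matrix
#'
#' @param copies Non-negative integer-valued matrix, genomes x genes, with
#'   unique dimnames.
#' @return An object of class `genome_content`.
#' @export
genome_content <- function(copies) {
  copies <- as.matrix(copies)
  if (is.null(rownames(copies)) || is.null(colnames(copies)))
    stop("copy-number matrix must have genome row names and gene column names",
         call. = FALSE)
  if (anyDuplicated(rownames(copies)) || anyDuplicated(colnames(copies)))
    stop("duplicate genome or gene IDs in copy-number matrix", call. = FALSE)
  if (anyNA(copies) || any(!is.finite(copies)))
    stop("copy-number matrix contains missing or non-finite values", call. = FALSE)
  if (any(copies < 0))
    stop("copy-number matrix contains negative values", call. = FALSE)
  if (any(abs(copies - round(copies)) > 1e-8))
    stop("copy numbers must be integer-valued", call. = FALSE)
  storage.mode(copies) <- "double"
  structure(list(copies = copies), class = "genome_content")
}

#' @export
print.genome_content <- function(x, ...) {
  cat("<genome_content> ", nrow(x$copies), " genomes x ", ncol(x$copies),
      " gene families\n", sep = "")
  invisible(x)
}

#' Construct a universal single-copy marker gene set
#'
#' @param gene_ids Non-empty character vector of gene-family IDs expected to
#'   be present in single copy in every bacterial genome.
#' @return An object of class `marker_set` (a character vector).
#' @export
marker_set <- function(gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  gene_ids <- gene_ids[nzchar(gene_ids)]
  if (length(gene_ids) == 0L)
    stop("marker set must contain at least one gene-family ID", call. = FALSE)
  structure(gene_ids, class = "marker_set")
}

#' Construct sample metadata
#'
#' @param sample_id,individual_id Character vectors.
#' @param visit Integer visit index (>= 1) per sample.
#' @param group Optional factor/character with levels `case`/`control`.
#' @return A `sample_metadata` data frame keyed by `sample_id`.
#' @export
sample_metadata <- function(sample_id, individual_id, visit = 1L, group = NULL) {
  sample_id <- as.character(sample_id)
  individual_id <- as.character(individual_id)
  visit <- as.integer(visit)
  n <- length(sample_id)
  if (length(individual_id) != n)
    stop("`individual_id` must match `sample_id` in length", call. = FALSE)
  visit <- rep_len(visit, n)
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs in metadata", call. = FALSE)
  if (any(is.na(visit)) || any(visit < 1L))
    stop("`visit` must be an integer >= 1", call. = FALSE)
  if (anyDuplicated(paste(individual_id, visit)))
    stop("(individual_id, visit) pairs must be unique", call. = FALSE)
  meta <- data.frame(sample_id = sample_id, individual_id = individual_id,
                     visit = visit, stringsAsFactors = FALSE)
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != n)
      stop("`group` must match `sample_id` in length", call. = FALSE)
    if (!all(group %in% c("case", "control", NA)))
      stop("`group` values must be 'case' or 'control'", call. = FALSE)
    meta$group <- group
  }
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Validate and construct a distance matrix
#'
#' @param values Square numeric matrix with matching row/column names,
#'   symmetric to 1e-12, zero diagonal, non-negative.
#' @return The validated matrix with class `distance_matrix`.
#' @export
distance_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values)))
    stop("distance matrix must have identical row and column names", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("distances must be non-negative and non-missing", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix is not symmetric (tolerance 1e-12)", call. = FALSE)
  if (any(diag(values) != 0))
    stop("distance matrix diagonal must be exactly zero", call. = FALSE)
  class(values) <- c("distance_matrix", "matrix", "array")
  values
}

# internal: strip class for arithmetic
.dm_values <- function(d) {
  v <- unclass(d)
  class(v) <- NULL
  matrix(as.numeric(v), nrow = nrow(d), dimnames = dimnames(d))
}
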