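#' Copy-number coefficient of variation of one gene family across genomes
#'
#' Genomes in which the gene is absent count as copy number zero, so a low
#' CoV implies the gene is both ubiquitous and at near-constant copy number
#' ("genome-prevalent"). Returns `Inf` when the mean copy number is zero.
#'
#' @param content A [genome_content()].
#' @param gene_id Gene-family ID (must be a column of `content`).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param include_absent Include absent genomes as zeros (default `TRUE`).
#' @return Non-negative real (or `Inf` for an all-zero column).
#' @export
copy_number_cov <- function(content, gene_id,
                            sd_type = c("sample", "population"),
                            include_absent = TRUE) {
  stopifnot(inherits(content, "genome_content"))
  sd_type <- match.arg(sd_type)
  if (!gene_id %in% colnames(content$copies))
    stop("gene '", gene_id, "' not present in the copy-number matrix",
         call. = FALSE)
  x <- content$copies[, gene_id]
  if (!include_absent) x <- x[x > 0]
  .cov_vector(x, sd_type)
}

.cov_vector <- function(x, sd_type = "sample") {
  n <- length(x)
  if (n < 2L)
    stop("coefficient of variation requires at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) return(Inf)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  s / m
}

#' Identify genome-prevalent gene families
#'
#' Flags gene families whose copy-number CoV across a set of genomes falls
#' below a threshold (default 1.5). Such genes are close to constant-copy
#' across genomes and therefore carry little between-sample information;
#' excluding them from profiles exposes inter-individual differences that
#' they would otherwise dilute. Applying the same operation to a
#' gut-dwelling genome subset yields "gut genome-prevalent" genes.
#'
#' @param content A [genome_content()] with at least 2 genomes.
#' @param threshold CoV cutoff; genes with CoV strictly below it are
#'   flagged prevalent.
#' @param sd_type,include_absent Passed to [copy_number_cov()].
#' @param label Free-text label for the genome set (e.g. `"all"`, `"gut"`).
#' @return A `prevalent_gene_report` data frame with columns `gene`, `cov`,
#'   `prevalent`, and attributes `threshold` and `label`.
#' @export
identify_prevalent <- function(content, threshold = 1.5,
                               sd_type = c("sample", "population"),
                               include_absent = TRUE,
                               label = "all") {
  stopifnot(inherits(content, "genome_content"))
  sd_type <- match.arg(sd_type)
  if (nrow(content$copies) < 2L)
    stop("prevalence CoV is undefined for fewer than 2 genomes", call. = FALSE)
  covs <- vapply(colnames(content$copies), function(g) {
    x <- content$copies[, g]
    if (!include_absent) x <- x[x > 0]
    if (length(x) < 2L) return(Inf)
    .cov_vector(x, sd_type)
  }, numeric(1))
  report <- data.frame(gene = colnames(content$copies),
                       cov = unname(covs),
                       prevalent = unname(covs < threshold),
                       stringsAsFactors = FALSE)
  attr(report, "threshold") <- threshold
  attr(report, "label") <- label
  class(report) <- c("prevalent_gene_report", "data.frame")
  report
}

#' Remove a set of gene families from a profile
#'
#' @param profile A [gene_profile()].
#' @param exclude Character vector of gene IDs to drop (e.g. the prevalent
#'   genes of [identify_prevalent()]); IDs absent from the profile are
#'   ignored with a warning.
#' @return The filtered `gene_profile` (sample order preserved); the number
#'   of removed genes is reported via `message()`.
#' @export
filter_genes <- function(profile, exclude) {
  stopifnot(inherits(profile, "gene_profile"))
  if (inherits(exclude, "prevalent_gene_report"))
    exclude <- exclude$gene[exclude$prevalent]
  exclude <- unique(as.character(exclude))
  genes <- colnames(profile$values)
  absent <- setdiff(exclude, genes)
  if (length(absent))
    warning(length(absent), " excluded gene(s) not present in the profile",
            call. = FALSE)
  keep <- setdiff(genes, exclude)
  message("filter_genes: removed ", length(genes) - length(keep), " of ",
          length(genes), " gene families")
  if (length(keep) == 0L) {
    warning("all gene families removed; returning an empty-gene profile",
            call. = FALSE)
    out <- profile
    out$values <- profile$values[, 0, drop = FALSE]
    return(out)
  }
  out <- profile
  out$values <- profile$values[, keep, drop = FALSE]
  # a relative profile no longer sums to 1 after filtering
  if (profile$normalization == "relative") out$normalization <- "raw"
  gene_profile(out$values, normalization = out$normalization)
}
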