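#' Read a delimited abundance matrix into a gene profile
#'
#' Expects a dense delimited table with one header row and one leading ID
#' column. By default genes are rows and samples are columns (the common
#' layout of public KO tables); set `orientation = "genes_in_columns"` for
#' the transposed layout. Lines starting with `#` are treated as comments
#' (used for provenance headers written by [run_pipeline()]).
#'
#' Empty cells, ragged rows, duplicate IDs and negative values are hard
#' errors: silent zero-filling can mask upstream problems and the matrices
#' this package consumes are dense.
#'
#' @param path Path to a `.tsv`/`.csv` file (delimiter auto-detected from
#'   the extension, tab otherwise).
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @param delim Optional delimiter override (single character).
#' @return A [gene_profile()] with `normalization = "raw"`.
#' @export
read_gene_profile <- function(path,
                              orientation = c("genes_in_rows", "genes_in_columns"),
                              delim = NULL) {
  orientation <- match.arg(orientation)
  m <- .read_matrix(path, delim)
  if (orientation == "genes_in_rows") m <- t(m)
  gene_profile(m, normalization = "raw")
}

#' Write a profile to a delimited file
#'
#' Values are written with 15 significant digits so that
#' `read_gene_profile(write_profile(p))` reproduces `p` to 1e-12 relative
#' tolerance.
#'
#' @param profile A `gene_profile` or `pathway_profile`.
#' @param path Output path; delimiter auto-detected from the extension.
#' @param orientation Layout to write (features in rows by default).
#' @param header Optional character vector of comment lines (without the
#'   leading `#`) written before the table.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path,
                          orientation = c("genes_in_rows", "genes_in_columns"),
                          header = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(profile, "gene_profile") || inherits(profile, "pathway_profile"))
  m <- profile$values
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("refusing to write a profile with zero samples or zero features",
         call. = FALSE)
  if (orientation == "genes_in_rows") m <- t(m)
  sep <- .delim_for(path, NULL)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  id_label <- if (orientation == "genes_in_rows") "feature_id" else "sample_id"
  writeLines(paste(c(id_label, colnames(m)), collapse = sep), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])), collapse = sep)
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a two-column gene-to-pathway association table
#'
#' @param path Two-column delimited file (`gene_id`, `pathway_id`), no
#'   header required; a header line whose first field is `gene` or
#'   `gene_id` is skipped. Repeated identical pairs are deduplicated with a
#'   warning; lines without exactly two fields are hard errors.
#' @param delim Optional delimiter override.
#' @return A [pathway_map()].
#' @export
read_pathway_map <- function(path, delim = NULL) {
  sep <- .delim_for(path, delim)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(pathway_map(character(), character()))
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop("pathway map line ", lineno[which(nf != 2L)[1]],
         " does not have exactly 2 fields", call. = FALSE)
  gene <- vapply(fields, `[[`, character(1), 1L)
  pway <- vapply(fields, `[[`, character(1), 2L)
  if (tolower(gene[1]) %in% c("gene", "gene_id", "ko")) {
    gene <- gene[-1]
    pway <- pway[-1]
  }
  pathway_map(gene, pway)
}

#' Read a genome-by-gene copy-number matrix
#'
#' @inheritParams read_gene_profile
#' @param orientation `"genes_in_columns"` (default: genomes are rows) or
#'   `"genes_in_rows"`.
#' @return A [genome_content()].
#' @export
read_genome_content <- function(path,
                                orientation = c("genes_in_columns", "genes_in_rows"),
                                delim = NULL) {
  orientation <- match.arg(orientation)
  m <- .read_matrix(path, delim)
  if (orientation == "genes_in_rows") m <- t(m)
  genome_content(m)
}

#' Read a one-column marker gene list
#'
#' @param path Text file with one gene-family ID per line; `#` comments and
#'   blank lines ignored.
#' @return A [marker_set()].
#' @export
read_marker_set <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  marker_set(lines)
}

#' Read a sample metadata table
#'
#' @param path Delimited file with header columns `sample_id`,
#'   `individual_id`, `visit` and optionally `group`.
#' @param delim Optional delimiter override.
#' @return A [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  sep <- .delim_for(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  required <- c("sample_id", "individual_id", "visit")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sample_metadata(df$sample_id, df$individual_id, df$visit,
                  group = if ("group" %in% names(df)) df$group else NULL)
}

#' Write an aggregate definition as a two-column table
#'
#' @param agg An [aggregate_definition()].
#' @param path Output path (two columns: `aggregate_id`, `gene_id`).
#' @return `path`, invisibly.
#' @export
write_aggregates <- function(agg, path) {
  stopifnot(inherits(agg, "aggregate_definition"))
  sep <- .delim_for(path, NULL)
  rows <- unlist(lapply(names(agg$members), function(a) {
    paste(a, agg$members[[a]], sep = sep)
  }))
  writeLines(c(paste("aggregate_id", "gene_id", sep = sep), rows), path)
  invisible(path)
}

# ---- internals ---------------------------------------------------------

.delim_for <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Dense numeric matrix reader with precise error reporting: header row of
# column IDs, leading ID column, no missing cells, no ragged rows.
.read_matrix <- function(path, delim = NULL) {
  sep <- .delim_for(path, delim)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L)
    stop("matrix file '", path, "' must contain a header and at least one data row",
         call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  col_ids <- header[-1]
  if (length(col_ids) == 0L)
    stop("matrix file '", path, "' has no data columns", call. = FALSE)
  if (anyDuplicated(col_ids))
    stop("duplicate column IDs in '", path, "': ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "),
         call. = FALSE)
  body <- fields[-1]
  nf <- lengths(body)
  expected <- length(col_ids) + 1L
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1]
    stop("ragged row at line ", lineno[-1][bad], " of '", path, "': expected ",
         expected, " fields, found ", nf[bad], call. = FALSE)
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids))
    stop("duplicate row IDs in '", path, "': ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  cells <- vapply(body, function(f) f[-1], character(length(col_ids)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  empty <- !nzchar(trimws(cells))
  dim(empty) <- dim(cells) # nzchar drops dims
  if (any(empty)) {
    idx <- which(empty, arr.ind = TRUE)[1, ]
    stop("empty cell at row '", row_ids[idx[1]], "', column '",
         col_ids[idx[2]], "' of '", path, "'", call. = FALSE)
  }
  m <- suppressWarnings(matrix(as.numeric(cells), nrow = length(row_ids)))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", cells[idx[1], idx[2]], "' at row '",
         row_ids[idx[1]], "', column '", col_ids[idx[2]], "' of '", path, "'",
         call. = FALSE)
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative value at row '", row_ids[idx[1]], "', column '",
         col_ids[idx[2]], "' of '", path, "'", call. = FALSE)
  }
  dimnames(m) <- list(row_ids, col_ids)
  m
}
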