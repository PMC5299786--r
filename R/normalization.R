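#' Relative (total-sum) normalization
#'
#' Divides each sample row by its total so that gene-family abundances read
#' as relative abundances. Depth-independent, but confounded by the average
#' genome size of the community: samples dominated by large genomes spread
#' the same sequencing effort over more genes, shrinking every relative
#' abundance and masking true copy-number variation.
#'
#' @param profile A [gene_profile()].
#' @return A `gene_profile` with `normalization = "relative"`; each sample
#'   row sums to 1.
#' @export
relative_normalize <- function(profile) {
  stopifnot(inherits(profile, "gene_profile"))
  totals <- rowSums(profile$values)
  if (any(totals == 0)) {
    bad <- rownames(profile$values)[totals == 0]
    stop("cannot relative-normalize all-zero sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gene_profile(profile$values / totals, normalization = "relative")
}

#' Single-copy marker-gene normalization
#'
#' Uses a set of universal single-copy marker gene families as a per-sample
#' yardstick: every abundance is divided by a robust center of the sample's
#' marker abundances. Since each marker occurs exactly once per genome, its
#' abundance tracks the number of genomes sequenced, so normalized values
#' read as the average copy number of each gene family per genome in the
#' community. Unlike relative normalization this is insensitive both to
#' sequencing depth and to average genome size.
#'
#' Markers absent from the profile contribute nothing to the center (they
#' are treated as annotation gaps, not zeros); if fewer than half of the
#' markers are present a warning is emitted. A sample whose marker center is
#' zero has no usable yardstick and is a hard error.
#'
#' @param profile A [gene_profile()].
#' @param markers A [marker_set()] (or character vector) of single-copy
#'   marker gene-family IDs.
#' @param center Robust center of marker abundances per sample: `"median"`
#'   (default) or `"trimmed_mean"`.
#' @param trim Trim fraction for `center = "trimmed_mean"`.
#' @return A `gene_profile` with `normalization = "copy_number"`. With
#'   `center = "median"`, the median of the post-normalization marker values
#'   is 1 in every sample by construction.
#' @export
single_copy_normalize <- function(profile, markers,
                                  center = c("median", "trimmed_mean"),
                                  trim = 0.1) {
  stopifnot(inherits(profile, "gene_profile"))
  center <- match.arg(center)
  markers <- unique(as.character(markers))
  if (length(markers) == 0L)
    stop("marker set is empty", call. = FALSE)
  present <- intersect(markers, colnames(profile$values))
  if (length(present) == 0L)
    stop("none of the ", length(markers),
         " marker gene families are present in the profile", call. = FALSE)
  if (length(present) < 0.5 * length(markers))
    warning("only ", length(present), " of ", length(markers),
            " marker gene families found in the profile", call. = FALSE)
  mvals <- profile$values[, present, drop = FALSE]
  centers <- apply(mvals, 1L, function(x) {
    if (center == "median") stats::median(x) else mean(x, trim = trim)
  })
  if (any(centers <= 0)) {
    bad <- rownames(profile$values)[centers <= 0]
    stop("zero marker signal in sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gene_profile(profile$values / centers, normalization = "copy_number")
}
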