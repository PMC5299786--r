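#' Classify mapped gene families as shared or non-shared
#'
#' A gene family associated with two or more pathways is *shared*; one
#' associated with exactly one pathway is *non-shared*. Non-shared genes
#' are unambiguous evidence for their pathway and anchor the support-based
#' mapping scheme.
#'
#' @param map A non-empty [pathway_map()].
#' @return List with character vectors `shared` and `nonshared` (a
#'   partition of the mapped genes).
#' @export
classify_genes <- function(map) {
  stopifnot(inherits(map, "pathway_map"))
  if (nrow(map) == 0L) stop("pathway map is empty", call. = FALSE)
  deg <- table(map$gene)
  list(shared = sort(names(deg)[deg >= 2L]),
       nonshared = sort(names(deg)[deg == 1L]))
}

#' Pathways eligible for support-based mapping
#'
#' A pathway is retained iff it has at least `min_nonshared` non-shared
#' gene families in the annotation map (a property of the database, not of
#' the profile) and its mean relative abundance across samples, under
#' uniform fractional mapping of the relative-normalized profile, exceeds
#' `min_mean_rel_abundance`.
#'
#' @param profile A [gene_profile()] (any normalization; relative
#'   abundances are computed internally).
#' @param map A [pathway_map()].
#' @param min_nonshared Minimum count of non-shared genes (default 10).
#' @param min_mean_rel_abundance Minimum overall mean relative abundance
#'   (default 0.0005, i.e. 0.05\%).
#' @return Character vector of eligible pathway IDs (possibly empty).
#' @export
eligible_pathways <- function(profile, map, min_nonshared = 10,
                              min_mean_rel_abundance = 5e-4) {
  stopifnot(inherits(profile, "gene_profile"), inherits(map, "pathway_map"))
  if (nrow(map) == 0L) stop("pathway map is empty", call. = FALSE)
  stopifnot(min_nonshared >= 0, min_mean_rel_abundance >= 0)
  cls <- classify_genes(map)
  ns_count <- table(map$pathway[map$gene %in% cls$nonshared])
  pathways <- sort(unique(map$pathway))
  n_nonshared <- as.integer(ns_count[pathways])
  n_nonshared[is.na(n_nonshared)] <- 0L
  rel <- relative_normalize(profile)
  frac <- .map_linear(rel$values, map, scheme = "fractional")
  mean_ab <- colMeans(frac)[pathways]
  mean_ab[is.na(mean_ab)] <- 0
  pathways[n_nonshared >= min_nonshared & mean_ab > min_mean_rel_abundance]
}

#' Per-sample pathway support values
#'
#' The support of a pathway in a sample is the mean abundance of the
#' pathway's non-shared gene families present in the profile — an unbiased
#' estimate of the pathway's presence that is untouched by multi-pathway
#' mapping ambiguity. Pathways with no non-shared gene present in the
#' profile are excluded with a warning.
#'
#' @param profile A [gene_profile()].
#' @param map A [pathway_map()].
#' @param pathways Optional subset of pathway IDs to score (default: all).
#' @return Numeric matrix, samples x pathways.
#' @export
pathway_support <- function(profile, map, pathways = NULL) {
  stopifnot(inherits(profile, "gene_profile"), inherits(map, "pathway_map"))
  cls <- classify_genes(map)
  if (is.null(pathways)) pathways <- sort(unique(map$pathway))
  genes <- colnames(profile$values)
  sup <- vapply(pathways, function(p) {
    ns <- intersect(map$gene[map$pathway == p & map$gene %in% cls$nonshared],
                    genes)
    if (length(ns) == 0L) return(rep(NA_real_, nrow(profile$values)))
    rowMeans(profile$values[, ns, drop = FALSE])
  }, numeric(nrow(profile$values)))
  if (nrow(profile$values) == 1L)
    sup <- matrix(sup, nrow = 1L, dimnames = list(rownames(profile$values),
                                                  pathways))
  else rownames(sup) <- rownames(profile$values)
  drop_p <- colnames(sup)[colSums(is.na(sup)) > 0]
  if (length(drop_p)) {
    warning(length(drop_p), " pathway(s) with no non-shared gene in the ",
            "profile excluded from support: ",
            paste(utils::head(drop_p, 5), collapse = ", "), call. = FALSE)
    sup <- sup[, setdiff(colnames(sup), drop_p), drop = FALSE]
  }
  sup
}

#' Map gene-family abundances to pathway abundances
#'
#' Converts a sample x gene profile into a sample x pathway profile under
#' one of three schemes for distributing the abundance of *shared* gene
#' families (genes associated with several pathways):
#'
#' * `fractional` — uniform split: each of a gene's pathways receives
#'   `value / degree`.
#' * `complete` — the full value is added to every associated pathway.
#' * `empanada` — sample-specific, support-based split: the value is
#'   partitioned among the gene's pathways proportionally to each
#'   pathway's support in that sample ([pathway_support()]). The pathway
#'   abundance is then the sum of these partial contributions plus the
#'   entire abundances of the pathway's non-shared genes.
#'
#' Eligibility ([eligible_pathways()]) is applied before mapping and a
#' shared gene's degree counts only its eligible pathways, so that total
#' abundance of genes with at least one eligible pathway is conserved under
#' the `fractional` and `empanada` schemes; set
#' `keep_ineligible_in_degree = TRUE` to split over the full annotation
#' degree instead (breaking conservation). A shared gene whose eligible
#' pathways all have zero support in a sample falls back to a uniform
#' fractional split for that gene and sample (reported via `message()`).
#'
#' @param profile A [gene_profile()] in any normalization state.
#' @param map A [pathway_map()].
#' @param scheme `"fractional"`, `"complete"` or `"empanada"`.
#' @param min_nonshared,min_mean_rel_abundance Eligibility thresholds, see
#'   [eligible_pathways()].
#' @param keep_ineligible_in_degree Use the full annotation degree when
#'   splitting shared genes (default `FALSE`).
#' @return A [pathway_profile()], samples x eligible pathways.
#' @export
map_to_pathways <- function(profile, map,
                            scheme = c("fractional", "complete", "empanada"),
                            min_nonshared = 10, min_mean_rel_abundance = 5e-4,
                            keep_ineligible_in_degree = FALSE) {
  stopifnot(inherits(profile, "gene_profile"), inherits(map, "pathway_map"))
  scheme <- match.arg(scheme)
  elig <- eligible_pathways(profile, map, min_nonshared, min_mean_rel_abundance)
  if (length(elig) == 0L)
    stop("no pathway passes the eligibility filter", call. = FALSE)
  cls <- classify_genes(map)
  map_e <- map[map$pathway %in% elig, , drop = FALSE]
  if (nrow(map_e) == 0L)
    stop("no gene maps to an eligible pathway", call. = FALSE)

  vals <- profile$values
  genes <- colnames(vals)
  samples <- rownames(vals)

  if (scheme != "empanada") {
    full_deg <- if (keep_ineligible_in_degree) table(map$gene) else NULL
    out <- .map_linear(vals, map_e, scheme = scheme, full_degree = full_deg)
    out <- out[, elig[elig %in% colnames(out)], drop = FALSE]
    return(pathway_profile(out, scheme = scheme, basis = "pathway"))
  }

  # empanada: non-shared genes contribute fully; shared genes split by
  # per-sample support ratios over their eligible pathways.
  # pathways whose non-shared genes are all absent from the profile (e.g.
  # removed by prevalence filtering) have no support basis and are dropped
  # by pathway_support with a warning; restrict mapping to the rest
  sup <- pathway_support(profile, map, pathways = elig)
  elig <- intersect(elig, colnames(sup))
  if (length(elig) == 0L)
    stop("no eligible pathway has computable support", call. = FALSE)
  map_e <- map_e[map_e$pathway %in% elig, , drop = FALSE]

  out <- matrix(0, nrow = length(samples), ncol = length(elig),
                dimnames = list(samples, elig))
  ns_map <- map_e[map_e$gene %in% cls$nonshared & map_e$gene %in% genes, ,
                  drop = FALSE]
  for (p in unique(ns_map$pathway)) {
    cols <- ns_map$gene[ns_map$pathway == p]
    out[, p] <- out[, p] + rowSums(vals[, cols, drop = FALSE])
  }

  sh_map <- map_e[map_e$gene %in% cls$shared & map_e$gene %in% genes, ,
                  drop = FALSE]
  assoc <- split(sh_map$pathway, sh_map$gene)
  n_fallback <- 0L
  for (g in names(assoc)) {
    pws <- assoc[[g]]
    deg <- if (keep_ineligible_in_degree) sum(map$gene == g) else length(pws)
    s_g <- sup[, pws, drop = FALSE]
    denom <- rowSums(s_g)
    w <- s_g / denom
    zero <- denom == 0
    if (any(zero)) {
      n_fallback <- n_fallback + sum(zero)
      w[zero, ] <- 1 / length(pws)
    }
    if (keep_ineligible_in_degree && deg > length(pws)) {
      # weights renormalized over eligible pathways still sum to 1; with
      # the full-degree flag the uniform fallback splits over deg instead
      w[zero, ] <- 1 / deg
    }
    out[, pws] <- out[, pws] + vals[, g] * w
  }
  if (n_fallback > 0L)
    message("map_to_pathways: uniform fallback used for ", n_fallback,
            " shared gene/sample combination(s) with zero support")
  pathway_profile(out, scheme = "empanada", basis = "pathway")
}

# Linear (sample-independent) mapping schemes via a gene x pathway weight
# matrix: fractional = 1/degree, complete = 1.
.map_linear <- function(vals, map, scheme = c("fractional", "complete"),
                        full_degree = NULL) {
  scheme <- match.arg(scheme)
  map <- map[map$gene %in% colnames(vals), , drop = FALSE]
  pathways <- sort(unique(map$pathway))
  genes <- sort(unique(map$gene))
  if (length(genes) == 0L)
    return(matrix(0, nrow = nrow(vals), ncol = 0,
                  dimnames = list(rownames(vals), character())))
  w <- matrix(0, nrow = length(genes), ncol = length(pathways),
              dimnames = list(genes, pathways))
  w[cbind(map$gene, map$pathway)] <- 1
  if (scheme == "fractional") {
    deg <- if (is.null(full_degree)) rowSums(w)
           else as.numeric(full_degree[genes])
    w <- w / deg
  }
  vals[, genes, drop = FALSE] %*% w
}
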