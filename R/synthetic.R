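#' Simulate a synthetic microbial world
#'
#' Builds a seed-deterministic collection of bacterial genomes, a
#' gene-to-pathway annotation, and a universal single-copy marker set, with
#' planted structure that every downstream stage can be validated against:
#'
#' * **Markers** (`M...`): copy number exactly 1 in every genome.
#' * **Background block**: present in every genome at copy 1 — these are
#'   genome-prevalent by construction (copy-number CoV 0).
#' * **Six ordinary blocks**: each genome carries a small number of blocks
#'   (two for "small" genomes, one for "large" ones), so block genes
#'   co-occur perfectly across genomes and are recoverable as
#'   co-occurrence aggregates; their ~25% genome coverage gives a
#'   copy-number CoV well above the 1.5 prevalence cutoff.
#' * **One restricted block**: carried only by the "large" half of the
#'   genomes. Together with the profile simulator's genome-size spread,
#'   these genes are the planted size-confounded variable genes whose
#'   variation relative normalization dampens.
#'
#' Every genome carries background plus exactly two equal-size blocks, so
#' all genomes have identical total gene content; genome-size differences
#' are introduced only by [simulate_profiles()]'s `genome_size_spread`.
#'
#' Pathways are contiguous block-ordered slices of the non-marker genes
#' (markers are left unannotated), and a `shared_fraction` of non-marker
#' genes receives one extra random pathway association, making it shared.
#'
#' @param n_genomes Number of genomes (even, >= 4).
#' @param n_genes Total gene families including markers.
#' @param n_pathways Number of pathways in the annotation map.
#' @param n_markers Number of universal single-copy markers (>= 1).
#' @param shared_fraction Fraction of non-marker genes mapped to a second
#'   pathway.
#' @param presence_noise Probability of flipping each non-marker
#'   presence/absence cell (used to stress co-occurrence recovery).
#' @param seed Integer seed; identical seeds give bit-identical worlds.
#' @return A `synthetic_world` list with elements `content`
#'   ([genome_content()]), `map` ([pathway_map()]), `markers`
#'   ([marker_set()]), and ground-truth fields `block_of` (gene -> block
#'   label), `cooccurrence_truth` (gene -> planted cluster label, markers
#'   and background share one label), `is_large` (per genome),
#'   `variable_genes` (the restricted block), `variable_pathways`,
#'   `background_genes`, `primary_pathway` (gene -> first pathway) and
#'   `default_affected_pathway` (an ordinary-block pathway suitable for
#'   planting case/control effects).
#' @export
simulate_world <- function(n_genomes = 40, n_genes = 220, n_pathways = 10,
                           n_markers = 10, shared_fraction = 0.25,
                           presence_noise = 0, seed = 1) {
  if (n_markers < 1) stop("`n_markers` must be >= 1", call. = FALSE)
  n_nm <- n_genes - n_markers
  n_groups <- 8L # background + 6 ordinary + 1 restricted
  if (n_nm < n_groups)
    stop("`n_genes` too small: need at least ", n_markers + n_groups,
         " genes for ", n_markers, " markers", call. = FALSE)
  if (n_genomes < 4 || n_genomes %% 2 != 0)
    stop("`n_genomes` must be an even number >= 4", call. = FALSE)
  if (n_pathways < 1 || n_pathways > n_nm)
    stop("`n_pathways` out of range", call. = FALSE)

  .with_seed(seed, {
    marker_ids <- sprintf("M%03d", seq_len(n_markers))
    gene_ids <- sprintf("K%05d", seq_len(n_nm))
    genome_ids <- sprintf("G%03d", seq_len(n_genomes))
    is_large <- seq_len(n_genomes) > n_genomes / 2

    block_size <- n_nm %/% n_groups
    sizes <- rep(block_size, n_groups)
    sizes[1] <- sizes[1] + n_nm %% n_groups # background absorbs remainder
    labels <- c("background", paste0("B", 1:6), "restricted")
    block_of <- rep(labels, sizes)
    names(block_of) <- gene_ids

    copies <- matrix(0, nrow = n_genomes, ncol = n_nm,
                     dimnames = list(genome_ids, gene_ids))
    copies[, block_of == "background"] <- 1
    ordinary <- paste0("B", 1:6)
    for (g in seq_len(n_genomes)) {
      carried <- if (is_large[g]) c(sample(ordinary, 1L), "restricted")
                 else sample(ordinary, 2L)
      copies[g, block_of %in% carried] <- 1
    }
    if (presence_noise > 0) {
      flips <- matrix(stats::runif(length(copies)) < presence_noise,
                      nrow = n_genomes)
      copies[flips] <- 1 - copies[flips]
    }
    marker_copies <- matrix(1, nrow = n_genomes, ncol = n_markers,
                            dimnames = list(genome_ids, marker_ids))
    content <- genome_content(cbind(marker_copies, copies))

    # block-ordered contiguous pathway slices over non-marker genes
    pathway_ids <- sprintf("P%03d", seq_len(n_pathways))
    slice <- sort(rep_len(seq_len(n_pathways), n_nm))
    primary <- pathway_ids[slice]
    names(primary) <- gene_ids
    n_shared <- if (n_pathways >= 2) floor(shared_fraction * n_nm) else 0L
    shared_genes <- if (n_shared > 0) sample(gene_ids, n_shared) else character()
    extra <- vapply(shared_genes, function(g) {
      sample(setdiff(pathway_ids, primary[g]), 1L)
    }, character(1))
    map <- pathway_map(c(gene_ids, shared_genes), c(unname(primary), unname(extra)))

    truth <- block_of
    truth[block_of == "background"] <- "universal"
    truth <- c(stats::setNames(rep("universal", n_markers), marker_ids), truth)

    # a pathway counts as "variable" if most of its primary genes are in
    # the restricted block; default affected pathway is ordinary-block pure
    frac_restricted <- vapply(pathway_ids, function(p) {
      mean(block_of[names(primary)[primary == p]] == "restricted")
    }, numeric(1))
    frac_ordinary <- vapply(pathway_ids, function(p) {
      mean(block_of[names(primary)[primary == p]] %in% ordinary)
    }, numeric(1))
    structure(list(
      content = content, map = map, markers = marker_set(marker_ids),
      block_of = block_of, cooccurrence_truth = truth, is_large = is_large,
      variable_genes = gene_ids[block_of == "restricted"],
      background_genes = gene_ids[block_of == "background"],
      variable_pathways = pathway_ids[frac_restricted > 0.5],
      primary_pathway = primary,
      default_affected_pathway = pathway_ids[which.max(frac_ordinary)],
      seed = seed), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$content$copies), " genomes x ",
      ncol(x$content$copies), " gene families, ",
      length(unique(x$map$pathway)), " pathways, ",
      length(x$markers), " markers (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate gene-family abundance profiles from a synthetic world
#'
#' Each sample is a weighted mixture of the world's genomes (Dirichlet
#' taxa weights). The true average copy number of gene `j` in sample `s`
#' is `sum_g w_gs * c_gj`; the simulated read-space abundance is
#' `depth * true_copy / average_genome_size`, mirroring how shotgun
#' sequencing spreads a fixed read budget over the community's total gene
#' content. `genome_size_spread` inflates the background-gene copies of
#' the "large" half of the genomes by `1 + spread`, so average genome size
#' varies with community composition — the confound that relative
#' normalization cannot remove but single-copy marker normalization can.
#' Multiplicative lognormal noise with coefficient of variation `noise_cv`
#' (mean 1) is applied last.
#'
#' @param world A [simulate_world()] result.
#' @param n_samples Number of samples.
#' @param depth Total abundance scale (read budget) per sample.
#' @param noise_cv CV of the multiplicative lognormal noise (0 = noise
#'   free).
#' @param genome_size_spread Background copy inflation of large genomes
#'   (0 = all genomes identical in size).
#' @param alpha Dirichlet concentration of taxa weights.
#' @param seed Integer seed.
#' @return A list with `profile` ([gene_profile()], raw), `true_copy`
#'   (samples x genes true average copy numbers), `weights` (samples x
#'   genomes), and `avg_genome_size` (per sample).
#' @export
simulate_profiles <- function(world, n_samples = 30, depth = 1e6,
                              noise_cv = 0, genome_size_spread = 0,
                              alpha = 0.5, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  .with_seed(seed, {
    copies <- world$content$copies
    n_genomes <- nrow(copies)
    w <- matrix(stats::rgamma(n_samples * n_genomes, shape = alpha),
                nrow = n_samples)
    w <- w / rowSums(w)
    dimnames(w) <- list(sprintf("S%03d", seq_len(n_samples)),
                        rownames(copies))
    c_eff <- copies
    if (genome_size_spread > 0)
      c_eff[world$is_large, world$background_genes] <-
        c_eff[world$is_large, world$background_genes] * (1 + genome_size_spread)
    true_copy <- w %*% c_eff
    gsize <- rowSums(true_copy)
    reads <- depth * true_copy / gsize
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- matrix(stats::rlnorm(length(reads), meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog), nrow = n_samples)
      reads <- reads * noise
    }
    list(profile = gene_profile(reads, normalization = "raw"),
         true_copy = true_copy, weights = w, avg_genome_size = gsize)
  })
}

#' Simulate a two-visit cohort with planted individual signatures
#'
#' Every individual shares a common lognormal baseline abundance profile;
#' each receives `n_signature` private non-marker genes whose abundance is
#' multiplied by `1 + signature_strength`. Both visits are independent
#' multiplicative-lognormal-noise realizations of the individual's mean
#' profile, so with `noise_cv = 0` the two visits are identical and with
#' `signature_strength = 0` no individual signal exists.
#'
#' @param world A [simulate_world()] result (supplies the gene universe).
#' @param n_individuals Number of individuals (>= 2); requires
#'   `n_individuals * n_signature` non-marker genes.
#' @param signature_strength Fold boost of signature genes (0 = null).
#' @param noise_cv Within-individual multiplicative noise CV.
#' @param n_signature Signature genes per individual (default 20).
#' @param seed Integer seed.
#' @return List with `visit1`, `visit2` ([gene_profile()]s), `meta`
#'   ([sample_metadata()] over both visits) and `signatures` (named list of
#'   each individual's planted genes).
#' @export
simulate_two_visit_cohort <- function(world, n_individuals = 36,
                                      signature_strength = 5, noise_cv = 0.1,
                                      n_signature = 20, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (n_individuals < 2) stop("`n_individuals` must be >= 2", call. = FALSE)
  genes <- colnames(world$content$copies)
  nm <- setdiff(genes, as.character(world$markers))
  if (length(nm) < n_individuals * n_signature)
    stop("world has too few non-marker genes for ", n_individuals,
         " individuals with ", n_signature, " signature genes each",
         call. = FALSE)
  .with_seed(seed, {
    inds <- sprintf("I%03d", seq_len(n_individuals))
    base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
    names(base) <- genes
    sig_pool <- sample(nm, n_individuals * n_signature)
    signatures <- split(sig_pool, rep(inds, each = n_signature))[inds]
    mean_prof <- matrix(rep(base, each = n_individuals),
                        nrow = n_individuals,
                        dimnames = list(inds, genes))
    for (i in inds)
      mean_prof[i, signatures[[i]]] <-
        mean_prof[i, signatures[[i]]] * (1 + signature_strength)
    draw <- function(visit) {
      vals <- mean_prof
      if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        vals <- vals * matrix(stats::rlnorm(length(vals), -sdlog^2 / 2, sdlog),
                              nrow = n_individuals)
      }
      rownames(vals) <- paste0(inds, "_V", visit)
      gene_profile(vals, normalization = "raw")
    }
    visit1 <- draw(1L)
    visit2 <- draw(2L)
    meta <- sample_metadata(
      sample_id = c(rownames(visit1$values), rownames(visit2$values)),
      individual_id = rep(inds, 2L),
      visit = rep(c(1L, 2L), each = n_individuals))
    list(visit1 = visit1, visit2 = visit2, meta = meta,
         signatures = signatures)
  })
}

#' Simulate a case/control cohort with a planted pathway effect
#'
#' Builds community profiles as in [simulate_profiles()], multiplies the
#' true copy numbers of the genes of `affected_pathways` by `effect` in
#' case samples, and optionally plants a genome-size confound: with
#' `confound_genome_size = TRUE` the background-gene copies of each case
#' sample are rescaled so that the sample's total genome size grows by
#' exactly `effect`, which cancels the planted enrichment under relative
#' normalization (the affected pathway's relative abundance matches the
#' controls) while leaving marker-based copy numbers — and hence the
#' revised pipeline — fully exposed to it.
#'
#' @param world A [simulate_world()] result.
#' @param n_case,n_control Group sizes.
#' @param affected_pathways Pathway IDs to perturb (default: the world's
#'   `default_affected_pathway`).
#' @param effect Multiplicative effect in cases (1 = null).
#' @param confound_genome_size Plant the genome-size confound.
#' @param noise_cv,alpha,depth As in [simulate_profiles()].
#' @param seed Integer seed.
#' @return List with `profile` ([gene_profile()]), `meta`
#'   ([sample_metadata()] with case/control groups), `affected_pathways`
#'   and `affected_genes`.
#' @export
simulate_case_control <- function(world, n_case = 20, n_control = 20,
                                  affected_pathways = NULL, effect = 2,
                                  confound_genome_size = FALSE,
                                  noise_cv = 0.1, alpha = 0.5, depth = 1e6,
                                  seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (effect < 0) stop("`effect` must be >= 0", call. = FALSE)
  if (is.null(affected_pathways))
    affected_pathways <- world$default_affected_pathway
  aff_genes <- unique(world$map$gene[world$map$pathway %in% affected_pathways])
  if (length(aff_genes) == 0L)
    stop("no genes map to the affected pathway(s)", call. = FALSE)
  .with_seed(seed, {
    copies <- world$content$copies
    n <- n_case + n_control
    w <- matrix(stats::rgamma(n * nrow(copies), shape = alpha), nrow = n)
    w <- w / rowSums(w)
    tc <- w %*% copies
    dimnames(tc) <- list(c(sprintf("CASE%03d", seq_len(n_case)),
                           sprintf("CTRL%03d", seq_len(n_control))),
                         colnames(copies))
    is_case <- seq_len(n) <= n_case
    g0 <- rowSums(tc)
    tc[is_case, aff_genes] <- tc[is_case, aff_genes] * effect
    if (confound_genome_size) {
      # scale only background genes outside the affected pathway, so every
      # affected-pathway member is multiplied by exactly `effect` while
      # total genome size also grows by exactly `effect` in cases
      bg <- setdiff(world$background_genes, aff_genes)
      if (length(bg) == 0L)
        stop("no background genes left to carry the genome-size confound",
             call. = FALSE)
      bg_tot <- rowSums(tc[, bg, drop = FALSE])
      g1 <- rowSums(tc)
      f <- (effect * g0 - (g1 - bg_tot)) / bg_tot
      f[!is_case] <- 1
      if (any(f <= 0))
        stop("genome-size confound infeasible for this effect size",
             call. = FALSE)
      tc[, bg] <- tc[, bg] * f
    }
    gsize <- rowSums(tc)
    reads <- depth * tc / gsize
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      reads <- reads * matrix(stats::rlnorm(length(reads), -sdlog^2 / 2, sdlog),
                              nrow = n)
    }
    meta <- sample_metadata(sample_id = rownames(tc),
                            individual_id = rownames(tc),
                            visit = 1L,
                            group = ifelse(is_case, "case", "control"))
    list(profile = gene_profile(reads, normalization = "raw"),
         meta = meta, affected_pathways = affected_pathways,
         affected_genes = aff_genes)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
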