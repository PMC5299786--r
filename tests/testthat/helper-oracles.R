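# Independent oracles and tiny fixtures shared across the suite. The
# oracle implementations deliberately use naive elementwise loops, written
# separately from the package's vectorized code paths.

toy_profile <- function(vals = NULL) {
  if (is.null(vals))
    vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("KO1", "KO2", "KO3")))
  gene_profile(vals)
}

toy_map <- function() {
  pathway_map(c("KO1", "KO1", "KO2", "KO3"), c("P1", "P2", "P1", "P2"))
}

# naive per-gene / per-sample support-based mapping, mirroring the written
# definition: eligibility, support from non-shared genes present, shared
# abundance partitioned by support ratio, uniform fallback at zero support
brute_force_empanada <- function(profile, map, min_nonshared = 10,
                                 min_mean_rel_abundance = 5e-4) {
  vals <- profile$values
  gene_paths <- split(map$pathway, map$gene)
  deg <- lengths(gene_paths)
  nonshared <- names(deg)[deg == 1L]
  pathways <- sort(unique(map$pathway))
  rel <- vals / rowSums(vals)

  elig <- character()
  for (p in pathways) {
    genes_p <- unique(map$gene[map$pathway == p])
    ns_count <- sum(genes_p %in% nonshared)
    tot <- 0
    for (s in rownames(vals)) {
      for (g in genes_p)
        if (g %in% colnames(vals)) tot <- tot + rel[s, g] / deg[[g]]
    }
    if (ns_count >= min_nonshared && tot / nrow(vals) > min_mean_rel_abundance)
      elig <- c(elig, p)
  }
  ns_genes_of <- function(p)
    intersect(unique(map$gene[map$pathway == p]) [
      unique(map$gene[map$pathway == p]) %in% nonshared], colnames(vals))
  elig <- elig[vapply(elig, function(p) length(ns_genes_of(p)) > 0, logical(1))]
  if (length(elig) == 0L) return(NULL)

  out <- matrix(0, nrow(vals), length(elig),
                dimnames = list(rownames(vals), elig))
  for (s in rownames(vals)) {
    support <- vapply(elig, function(p) mean(vals[s, ns_genes_of(p)]),
                      numeric(1))
    for (g in intersect(names(gene_paths), colnames(vals))) {
      pws <- intersect(gene_paths[[g]], elig)
      if (length(pws) == 0L) next
      if (g %in% nonshared) {
        out[s, pws] <- out[s, pws] + vals[s, g]
      } else {
        sup <- support[pws]
        w <- if (sum(sup) > 0) sup / sum(sup) else rep(1 / length(pws), length(pws))
        out[s, pws] <- out[s, pws] + vals[s, g] * w
      }
    }
  }
  out
}

# random small mapping instance for oracle comparisons
random_mapping_instance <- function(n_samples, n_genes, n_pathways, seed) {
  set.seed(seed)
  genes <- sprintf("K%03d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  pws <- sprintf("P%02d", seq_len(n_pathways))
  k <- sample(seq_len(min(3L, n_pathways)), n_genes, replace = TRUE)
  assoc_g <- rep(genes, k)
  assoc_p <- unlist(lapply(k, function(kk) sample(pws, kk)))
  vals <- matrix(stats::rexp(n_samples * n_genes), n_samples,
                 dimnames = list(samples, genes))
  vals[stats::runif(length(vals)) < 0.1] <- 0
  list(profile = gene_profile(vals), map = pathway_map(assoc_g, assoc_p))
}

# planted-block presence/absence matrix: each block gets an independent
# random genome membership pattern, genes inherit their block's pattern,
# then a fraction of cells is bit-flipped
planted_block_content <- function(n_genomes = 40, n_genes = 100,
                                  n_blocks = 5, flip = 0.05, seed = 1) {
  set.seed(seed)
  membership <- matrix(stats::runif(n_genomes * n_blocks) < 0.5, n_genomes)
  block_of <- rep(seq_len(n_blocks), length.out = n_genes)
  pres <- membership[, block_of]
  flips <- matrix(stats::runif(n_genomes * n_genes) < flip, n_genomes)
  pres[flips] <- !pres[flips]
  m <- matrix(as.numeric(pres), n_genomes,
              dimnames = list(sprintf("G%03d", seq_len(n_genomes)),
                              sprintf("K%03d", seq_len(n_genes))))
  list(content = genome_content(m),
       truth = stats::setNames(block_of, colnames(m)))
}

# adjusted Rand index between two labelings (pair-counting form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_comb <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n_comb
  (sum_comb - expected) / ((sum_a + sum_b) / 2 - expected)
}

# cluster labels (named by gene) from an aggregate definition
aggregate_labels <- function(agg) {
  lab <- rep(names(agg$members), lengths(agg$members))
  names(lab) <- unlist(agg$members, use.names = FALSE)
  lab
}
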