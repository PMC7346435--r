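# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately use brute-force constructions (explicit sums,
# double loops, naive agglomeration) so they stay independent of the
# implementation paths they check.

toy_dataset <- function(tpm, id = "TOY", species = "human", ...) {
  expression_dataset(tpm, id, species, ...)
}

# Dataset with gene-indexed TPM rows replicated identically.
dataset_from_means <- function(means, n_rep = 3L, id = "TOY",
                               species = "human") {
  m <- matrix(rep(means, n_rep), ncol = n_rep,
              dimnames = list(names(means), paste0("r", seq_len(n_rep))))
  expression_dataset(m, id, species)
}

# calls object without running thresholds, for direct quantile tests
calls_from_summary <- function(summary_tpm, id = "TOY", species = "human") {
  structure(list(dataset_id = id, species = species,
                 expressed = names(summary_tpm),
                 highly_expressed = character(0),
                 summary_tpm = summary_tpm,
                 tpm_threshold = 1, z_threshold = 1.5),
            class = "expression_calls")
}

# The hand-built 4-pair toy mapping: A genes in quantiles (1,1,2,2),
# B genes in (1,2,1,2), one-to-one pairs a_i <-> b_i.
toy_four_pair_map <- function() {
  qa_a <- assign_quantiles(
    calls_from_summary(c(a1 = 40, a2 = 30, a3 = 20, a4 = 10),
                       id = "A1", species = "human"), n_quantiles = 2L)
  qa_b <- assign_quantiles(
    calls_from_summary(c(b1 = 40, b3 = 30, b2 = 20, b4 = 10),
                       id = "B1", species = "zebrafish"), n_quantiles = 2L)
  om <- orthology_map(paste0("a", 1:4), paste0("b", 1:4), rep(1L, 4),
                      "human", "zebrafish")
  build_quantile_mapping(qa_a, qa_b, om)
}

# Exhaustive hypergeometric upper tail computed from binomial
# coefficients, never from phyper().
hyper_tail_oracle <- function(hits, list_size, set_size, universe_size) {
  ks <- hits:min(list_size, set_size)
  if (hits > min(list_size, set_size)) return(0)
  sum(choose(set_size, ks) * choose(universe_size - set_size, list_size - ks)) /
    choose(universe_size, list_size)
}

# Naive double-loop "expressed" caller.
expressed_oracle <- function(tpm, threshold = 1) {
  out <- character(0)
  for (g in rownames(tpm)) {
    ok <- TRUE
    for (j in seq_len(ncol(tpm))) if (!(tpm[g, j] > threshold)) ok <- FALSE
    if (ok) out <- c(out, g)
  }
  out
}

# Naive UPGMA agglomeration over a distance matrix: returns merge
# heights and the leaf partition after each merge.
upgma_oracle <- function(dmat) {
  clusters <- as.list(rownames(dmat))
  heights <- numeric(0)
  partitions <- list()
  d <- dmat
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        # average linkage: mean pairwise distance between members
        dd <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Partition of leaves after each hclust merge, for comparison with the
# oracle above.
hclust_partitions <- function(hc) {
  n <- length(hc$labels)
  member <- as.list(hc$labels)
  names(member) <- NULL
  nodes <- vector("list", n - 1L)
  active <- lapply(seq_len(n), function(i) hc$labels[[i]])
  out <- list()
  for (m in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0) hc$labels[[-k]] else nodes[[k]]
    nodes[[m]] <- c(pick(hc$merge[m, 1L]), pick(hc$merge[m, 2L]))
    active <- Filter(function(s) !all(s %in% nodes[[m]]), active)
    active[[length(active) + 1L]] <- nodes[[m]]
    out[[m]] <- lapply(active, sort)
  }
  out
}

# canonical form of a partition (order-independent)
canon_partition <- function(p) {
  sorted <- lapply(p, sort)
  keys <- vapply(sorted, paste, character(1), collapse = ",")
  sorted[order(keys)]
}
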