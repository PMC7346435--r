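# Between-sample similarity on a chosen gene set: row normalization,
# UPGMA clustering with Pearson-correlation distance, PCA, and the
# ANOSIM / adonis (PERMANOVA) permutation tests with an exact
# enumeration mode for small designs.

#' Row-normalize a signal matrix
#'
#' Scales each row (gene) to mean 0 and SD 1 across samples, the usual
#' preprocessing before correlation-based clustering so that each gene
#' contributes its expression profile shape, not its magnitude.
#'
#' @param mat Numeric matrix, genes x samples.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return Matrix of the same shape with zero row means and unit row SDs.
#' @export
row_normalize <- function(mat, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.matrix(mat) || !is.numeric(mat))
    oq_validation_error("'mat' must be a numeric matrix")
  mu <- rowMeans(mat)
  centered <- mat - mu
  denom <- if (sd_type == "sample") ncol(mat) - 1L else ncol(mat)
  sdv <- sqrt(rowSums(centered^2) / denom)
  zero <- which(sdv == 0)
  if (length(zero)) {
    nm <- rownames(mat)[zero[1L]] %||% as.character(zero[1L])
    oq_abort(sprintf("zero-variance row '%s': cannot row-normalize", nm),
             "orthoquant_degenerate_error")
  }
  centered / sdv
}

#' UPGMA clustering of samples with Pearson-correlation distance
#'
#' Agglomerates the sample columns with average linkage (UPGMA) on the
#' distance d(i, j) = 1 - Pearson(i, j). The distance is the plain
#' 1 - r (range 0..2), so perfectly anti-correlated samples sit at
#' height 2; this affects heights only, never the topology.
#'
#' @param mat Numeric matrix, genes x samples (typically
#'   row-normalized log TPM).
#' @return An object of class `hclust` over the sample columns.
#' @export
upgma_cluster <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2L)
    oq_validation_error("need a matrix with at least 2 sample columns")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    oq_abort(sprintf("constant sample column '%s': correlation undefined",
                     colnames(mat)[which(sds == 0)[1L]] %||% which(sds == 0)[1L]),
             "orthoquant_degenerate_error")
  d <- stats::as.dist(1 - stats::cor(mat))
  stats::hclust(d, method = "average")
}

#' Export a dendrogram in Newick format
#' @param hc An `hclust` object.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PCA scores and explained-variance fractions for samples
#'
#' Centered (not scaled) principal components analysis of the samples.
#' Sign of each component follows the `stats::prcomp` convention and is
#' arbitrary: duplicated analyses agree up to sign.
#'
#' @param mat Numeric matrix, genes x samples; PCA is performed over
#'   the sample columns.
#' @param n_components Number of components to return, or `NULL` for
#'   all components up to the matrix rank.
#' @return List with `scores` (samples x components),
#'   `variance_fraction` (per retained component, of total variance),
#'   and `rank`.
#' @export
pca_scores <- function(mat, n_components = 2L) {
  if (!is.matrix(mat) || ncol(mat) < 2L)
    oq_validation_error("need a matrix with at least 2 sample columns")
  p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > p$sdev[1L] * 1e-8)
  if (is.null(n_components)) n_components <- rank
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > rank)
    oq_validation_error(sprintf(
      "n_components = %d exceeds the matrix rank (%d)", n_components, rank))
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       variance_fraction = varfrac[seq_len(n_components)],
       rank = rank)
}

# All distinct arrangements of a label multiset (used by the exact
# permutation mode). Returns a matrix, one arrangement per row.
multiset_permutations <- function(labels) {
  labels <- sort(labels)
  out <- list()
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      recurse(remaining[-i], c(acc, u))
    }
  }
  recurse(labels, character(0))
  do.call(rbind, out)
}

n_distinct_assignments <- function(groups) {
  tab <- table(groups)
  exp(lgamma(length(groups) + 1) - sum(lgamma(tab + 1)))
}

# Shared permutation machinery for ANOSIM / adonis. statistic_fun maps
# a grouping vector to the statistic; larger values mean stronger
# separation, and the permutation p-value is one-sided.
permutation_p <- function(groups, statistic_fun, n_permutations, seed,
                          max_exhaustive) {
  observed <- statistic_fun(groups)
  n_exact <- n_distinct_assignments(groups)
  if (n_exact <= max_exhaustive) {
    perms <- multiset_permutations(as.character(groups))
    stats_all <- apply(perms, 1L, statistic_fun)
    p <- sum(stats_all >= observed - 1e-12) / nrow(perms)
    list(statistic = observed, p_value = p, mode = "exhaustive",
         n_permutations = nrow(perms))
  } else {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      if (statistic_fun(sample(groups)) >= observed - 1e-12)
        exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_permutations + 1)
    list(statistic = observed, p_value = p, mode = "permutation",
         n_permutations = n_permutations)
  }
}

check_grouping <- function(d, groups) {
  n <- attr(d, "Size")
  if (length(groups) != n)
    oq_validation_error("'groups' length must match the distance matrix size")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) oq_validation_error("need at least 2 groups")
  if (any(tab < 2L))
    oq_validation_error(sprintf("group '%s' has fewer than 2 samples",
                                names(tab)[tab < 2L][1L]))
  groups
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances
#' exceed within-group distances. With M = n(n-1)/2 pairwise
#' distances ranked jointly (average ranks on ties),
#' R = (mean between-group rank - mean within-group rank) / (M/2),
#' so R is 1 when every between-group distance exceeds every
#' within-group distance and about 0 under no group structure. The
#' p-value is one-sided: the fraction of group relabelings with R at
#' least as large as observed. When the number of distinct label
#' arrangements is at most `max_exhaustive` the test enumerates them
#' all (exact p, minimum 1/#arrangements); otherwise it draws
#' `n_permutations` random relabelings and uses
#' (1 + #exceedances) / (n_permutations + 1).
#'
#' @param d A `dist` object or symmetric distance matrix over samples.
#' @param groups Group label per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation draw (ignored in
#'   exhaustive mode). The caller's RNG state is restored on exit.
#' @param max_exhaustive Threshold on the number of distinct label
#'   arrangements below which exact enumeration replaces sampling.
#' @return Object of class `permutation_test_result` with
#'   `statistic_name = "ANOSIM R"`, `statistic`, `p_value`, `mode`,
#'   `n_permutations`, `seed`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999L, seed = 1L,
                        max_exhaustive = 10000L) {
  d <- stats::as.dist(d)
  groups <- check_grouping(d, groups)
  rk <- rank(as.vector(d))
  n <- attr(d, "Size")
  M <- n * (n - 1) / 2
  stat <- function(g) {
    # as.dist() coerces the logical mask to 0/1, hence the explicit
    # comparison before indexing
    same_g <- as.vector(stats::as.dist(outer(g, g, `==`))) > 0
    (mean(rk[!same_g]) - mean(rk[same_g])) / (M / 2)
  }
  res <- permutation_p(groups, stat, n_permutations, seed, max_exhaustive)
  structure(list(statistic_name = "ANOSIM R", statistic = res$statistic,
                 p_value = res$p_value, mode = res$mode,
                 n_permutations = res$n_permutations, seed = seed),
            class = "permutation_test_result")
}

#' adonis / PERMANOVA one-way test on a distance matrix
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components (the Gower-centered partition:
#' SS_total = sum of squared distances / n, SS_within summed per group
#' with its own size) and reports R^2 = SS_between / SS_total with a
#' one-sided permutation p-value, exactly as in the one-factor
#' PERMANOVA. Exhaustive enumeration applies as in [anosim_test()].
#'
#' @inheritParams anosim_test
#' @return Object of class `permutation_test_result` with
#'   `statistic_name = "adonis R2"`.
#' @export
adonis_test <- function(d, groups, n_permutations = 999L, seed = 1L,
                        max_exhaustive = 10000L) {
  d <- stats::as.dist(d)
  groups <- check_grouping(d, groups)
  dm2 <- as.matrix(d)^2
  n <- attr(d, "Size")
  ss_total <- sum(dm2[upper.tri(dm2)]) / n
  stat <- function(g) {
    ss_within <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      sub <- dm2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    (ss_total - ss_within) / ss_total
  }
  res <- permutation_p(groups, stat, n_permutations, seed, max_exhaustive)
  structure(list(statistic_name = "adonis R2", statistic = res$statistic,
                 p_value = res$p_value, mode = res$mode,
                 n_permutations = res$n_permutations, seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("<permutation_test_result> %s = %.4f, p = %.4g (%s, %d %s)\n",
              x$statistic_name, x$statistic, x$p_value, x$mode,
              x$n_permutations,
              if (x$mode == "exhaustive") "arrangements" else "permutations"))
  invisible(x)
}
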