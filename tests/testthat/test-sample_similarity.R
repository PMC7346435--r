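test_that("row normalization yields zero means and unit SDs, idempotently", {
  v <- matrix(c(1, 2, 3), 1, dimnames = list("g1", paste0("s", 1:3)))
  n1 <- row_normalize(v)
  expect_equal(mean(n1), 0)
  expect_equal(sd(n1[1, ]), 1)

  set.seed(8)
  m <- matrix(rnorm(450, 5, 3), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:9)))
  nm <- row_normalize(m)
  expect_equal(unname(rowMeans(nm)), rep(0, 50), tolerance = 1e-12)
  expect_equal(unname(apply(nm, 1, sd)), rep(1, 50), tolerance = 1e-12)
  expect_equal(row_normalize(nm), nm, tolerance = 1e-12)

  m[3, ] <- 7
  err <- tryCatch(row_normalize(m), error = function(e) e)
  expect_s3_class(err, "orthoquant_degenerate_error")
  expect_match(conditionMessage(err), "g03")
})

test_that("identical samples merge first at height zero", {
  set.seed(14)
  base <- rnorm(30)
  m <- cbind(s1 = base, s2 = base, s3 = rnorm(30))
  hc <- upgma_cluster(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
})

test_that("UPGMA merge order and heights match naive agglomeration", {
  set.seed(25)
  for (rep in 1:5) {
    m <- matrix(rnorm(4 * 20), 20, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    m[, 2] <- m[, 1] + rnorm(20, 0, 0.3)   # force some structure
    d <- 1 - cor(m)
    oracle <- upgma_oracle(d)
    hc <- upgma_cluster(m)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-10)
    got <- hclust_partitions(hc)
    for (i in seq_along(got))
      expect_equal(canon_partition(got[[i]]),
                   canon_partition(oracle$partitions[[i]]))
  }
})

test_that("cophenetic distances satisfy the ultrametric three-point condition", {
  set.seed(26)
  m <- matrix(rnorm(6 * 25), 25, 6, dimnames = list(NULL, paste0("s", 1:6)))
  hc <- upgma_cluster(m)
  cp <- as.matrix(stats::cophenetic(hc))
  n <- ncol(cp)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(cp[i, j], max(cp[i, k], cp[k, j]) + 1e-10)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("constant sample columns are rejected for correlation distance", {
  m <- cbind(s1 = rnorm(10), s2 = rep(2, 10))
  expect_error(upgma_cluster(m), class = "orthoquant_degenerate_error")
})

test_that("PCA recovers collinear structure and matches an eigen oracle", {
  t_vals <- seq(-2, 2, length.out = 5)
  m <- rbind(g1 = 3 * t_vals, g2 = -1 * t_vals, g3 = 0.5 * t_vals)
  colnames(m) <- paste0("s", 1:5)
  p <- pca_scores(m, 1)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)

  set.seed(33)
  m2 <- matrix(rnorm(9 * 40), 40, 9, dimnames = list(NULL, paste0("s", 1:9)))
  p2 <- pca_scores(m2, n_components = NULL)
  ev <- eigen(stats::cov(t(m2)), symmetric = TRUE)$values
  expect_equal(p2$variance_fraction,
               (ev / sum(ev))[seq_along(p2$variance_fraction)],
               tolerance = 1e-10)
  expect_true(all(diff(p2$variance_fraction) <= 1e-12))
  expect_error(pca_scores(m2, 100), class = "orthoquant_validation_error")
})

test_that("duplicated analyses give identical scores up to sign", {
  set.seed(34)
  m <- matrix(rnorm(5 * 30), 30, 5, dimnames = list(NULL, paste0("s", 1:5)))
  p1 <- pca_scores(m, 2)
  p2 <- pca_scores(m[sample(30), ], 2)   # row order must not matter
  for (j in 1:2)
    expect_true(isTRUE(all.equal(p1$scores[, j], p2$scores[, j],
                                 tolerance = 1e-8)) ||
                isTRUE(all.equal(p1$scores[, j], -p2$scores[, j],
                                 tolerance = 1e-8)))
})

test_that("ANOSIM reaches 1 for perfect separation and ~0 under the null", {
  set.seed(51)
  x <- rbind(matrix(rnorm(6, 0, 0.1), 3), matrix(rnorm(6, 20, 0.1), 3))
  g <- rep(c("A", "B"), each = 3)
  res <- anosim_test(dist(x), g)
  expect_equal(res$statistic, 1)
  expect_equal(res$mode, "exhaustive")
  expect_gte(res$p_value, 1 / 20)

  null_r <- replicate(30, {
    xs <- matrix(rnorm(16), 8, 2)
    anosim_test(dist(xs), rep(c("A", "B"), each = 4),
                max_exhaustive = 0, n_permutations = 99)$statistic
  })
  expect_lt(abs(mean(null_r)), 0.15)
})

test_that("ANOSIM and adonis match vegan on a shared fixture", {
  skip_if_not_installed("vegan")
  set.seed(52)
  x <- matrix(rnorm(18), 9, 2)
  x[4:6, ] <- x[4:6, ] + 2.5
  x[7:9, 1] <- x[7:9, 1] + 5
  g <- rep(c("A", "B", "C"), each = 3)
  d <- dist(x)
  expect_equal(anosim_test(d, g)$statistic,
               unname(vegan::anosim(d, factor(g), permutations = 2)$statistic),
               tolerance = 1e-12)
  expect_equal(adonis_test(d, g)$statistic,
               vegan::adonis2(d ~ g, permutations = 2)$R2[1],
               tolerance = 1e-12)
})

test_that("permutation p agrees with exhaustive enumeration on small designs", {
  set.seed(53)
  for (setup in list(list(n = 6, g = rep(c("A", "B"), each = 3)),
                     list(n = 9, g = rep(c("A", "B", "C"), each = 3)))) {
    x <- matrix(rnorm(setup$n * 2), setup$n, 2)
    x[setup$g == "A", ] <- x[setup$g == "A", ] + 1.5
    d <- dist(x)
    for (fn in list(anosim_test, adonis_test)) {
      exact <- fn(d, setup$g)
      expect_equal(exact$mode, "exhaustive")
      mc <- fn(d, setup$g, n_permutations = 999, seed = 99,
               max_exhaustive = 0)
      expect_equal(mc$mode, "permutation")
      expect_lt(abs(mc$p_value - exact$p_value), 2 / sqrt(999))
    }
  }
})

test_that("the 9-sample 3-group design bounds the exact p from below", {
  x <- rbind(matrix(rnorm(6, 0, 0.05), 3), matrix(rnorm(6, 10, 0.05), 3),
             matrix(rnorm(6, 20, 0.05), 3))
  g <- rep(c("A", "B", "C"), each = 3)
  res <- anosim_test(dist(x), g)
  expect_equal(res$n_permutations, 1680L)
  expect_gte(res$p_value, 1 / 1680)
  # the statistic is invariant to permuting group NAMES, so the 3! = 6
  # relabelings of the observed partition all tie with it: the smallest
  # achievable p is 6/1680 = 1/280
  expect_equal(res$p_value, 6 / 1680)
})

test_that("adonis R2 equals the classical Euclidean trace ratio", {
  set.seed(54)
  x <- matrix(rnorm(9 * 4), 9, 4)
  g <- rep(c("A", "B", "C"), each = 3)
  res <- adonis_test(dist(x), g)
  # brute-force one-way MANOVA decomposition on coordinates
  grand <- colMeans(x)
  ss_total <- sum(sweep(x, 2, grand)^2)
  ss_within <- sum(vapply(unique(g), function(lv) {
    xs <- x[g == lv, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
  expect_equal(res$statistic, (ss_total - ss_within) / ss_total,
               tolerance = 1e-12)
  expect_gte(res$statistic, 0)
  expect_lte(res$statistic, 1)
})

test_that("both tests are invariant to sample order and distance scaling", {
  set.seed(55)
  x <- matrix(rnorm(8 * 3), 8, 3)
  g <- rep(c("A", "B"), each = 4)
  d <- dist(x)
  perm <- sample(8)
  d_perm <- as.dist(as.matrix(d)[perm, perm])
  expect_equal(anosim_test(d, g)$statistic,
               anosim_test(d_perm, g[perm])$statistic, tolerance = 1e-12)
  expect_equal(adonis_test(d, g)$statistic,
               adonis_test(d * 7.3, g)$statistic, tolerance = 1e-12)
  expect_equal(anosim_test(d, g)$statistic,
               anosim_test(d * 7.3, g)$statistic, tolerance = 1e-12)
})

test_that("both statistics increase with between-group separation", {
  set.seed(56)
  base <- matrix(rnorm(9 * 3), 9, 3)
  g <- rep(c("A", "B", "C"), each = 3)
  shifts <- c(0.5, 1.5, 4, 10)
  stats_r <- vapply(shifts, function(s) {
    x <- base + outer(as.numeric(factor(g)) * s, rep(1, 3))
    anosim_test(dist(x), g)$statistic
  }, numeric(1))
  stats_r2 <- vapply(shifts, function(s) {
    x <- base + outer(as.numeric(factor(g)) * s, rep(1, 3))
    adonis_test(dist(x), g)$statistic
  }, numeric(1))
  expect_true(all(diff(stats_r) >= -1e-10))
  expect_true(all(diff(stats_r2) >= -1e-10))
})

test_that("groups with one sample are rejected", {
  d <- dist(matrix(rnorm(8), 4, 2))
  expect_error(anosim_test(d, c("A", "A", "B", "C")),
               class = "orthoquant_validation_error")
})
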