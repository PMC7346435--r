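test_that("quantile assignment splits balanced blocks with extras first", {
  tpm10 <- setNames(seq(100, 10, by = -10), paste0("g", 1:10))
  qa <- assign_quantiles(calls_from_summary(tpm10), 10)
  expect_equal(unname(qa$quantile_of[paste0("g", 1:10)]), 1:10)
  expect_equal(qa$quantile_of[["g1"]], 1L)  # highest TPM -> quantile 1

  tpm25 <- setNames(100 - seq_len(25), sprintf("g%02d", 1:25))
  qa25 <- assign_quantiles(calls_from_summary(tpm25), 10)
  expect_equal(as.integer(table(qa25$quantile_of)),
               c(3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L))
  # contiguity: quantile of a higher-TPM gene is never larger
  ord <- names(sort(-tpm25))
  expect_true(all(diff(qa25$quantile_of[ord]) >= 0))
})

test_that("TPM ties at quantile boundaries break deterministically by gene ID", {
  tpm <- setNames(c(10, 9, 5, 5, 1), c("gE", "gD", "gB", "gA", "gC"))
  qa1 <- assign_quantiles(calls_from_summary(tpm), 5)
  qa2 <- assign_quantiles(calls_from_summary(tpm[sample(names(tpm))]), 5)
  expect_equal(qa1$quantile_of[names(qa1$quantile_of)],
               qa2$quantile_of[names(qa1$quantile_of)])
  # tie at the 3rd/4th block boundary: gA (alphabetically first) wins
  expect_lt(qa1$quantile_of[["gA"]], qa1$quantile_of[["gB"]])
})

test_that("assignment refuses fewer expressed genes than quantiles", {
  expect_error(assign_quantiles(calls_from_summary(c(g1 = 2, g2 = 1)), 10),
               class = "orthoquant_validation_error")
})

test_that("per-quantile average TPM is the mean of member summaries", {
  tpm <- setNames(c(40, 30, 20, 10), paste0("g", 1:4))
  qa <- assign_quantiles(calls_from_summary(tpm), 2)
  expect_equal(unname(qa$avg_tpm), c(35, 15))
})

test_that("a dataset mapped to itself is exactly diagonal", {
  set.seed(13)
  tpm <- setNames(rexp(60, 0.01) + 1, sprintf("g%02d", 1:60))
  qa <- assign_quantiles(calls_from_summary(tpm), 10)
  qm <- build_quantile_mapping(qa, qa, om = NULL)
  grid <- qm$counts[1:10, 1:10]
  expect_equal(unname(diag(grid)), rep(6L, 10))
  expect_equal(sum(grid) - sum(diag(grid)), 0L)
  expect_equal(sum(qm$counts[11, ]) + sum(qm$counts[, 11]), 0L)
})

test_that("the hand-built 4-pair map reproduces hand enumeration", {
  qm <- toy_four_pair_map()
  grid <- qm$counts[1:2, 1:2]
  expect_equal(unname(grid), matrix(1L, 2, 2))
  expect_equal(sum(qm$counts), 4L)
})

test_that("many-to-many pairs contribute one count per pair but one gene", {
  qa_a <- assign_quantiles(calls_from_summary(
    c(a1 = 50, a2 = 10), id = "A1", species = "human"), 2)
  qa_b <- assign_quantiles(calls_from_summary(
    c(b1 = 50, b2 = 10), id = "B1", species = "zebrafish"), 2)
  om <- orthology_map(c("a1", "a1"), c("b1", "b2"), c(1L, 1L),
                      "human", "zebrafish")
  qm <- build_quantile_mapping(qa_a, qa_b, om)
  expect_equal(qm$counts[1, 1], 1L)
  expect_equal(qm$counts[1, 2], 1L)
  summ <- quantile_map_gene_summary(qm)
  a1_rows <- summ[summ$side == "row" & summ$category == "grid", "n_genes"]
  expect_equal(a1_rows, 1L)  # a1 counted once at unique-gene level
  # a2 has no ortholog -> column n+2
  expect_equal(qm$counts[2, 4], 1L)
})

test_that("margin rows separate unexpressed-ortholog from no-ortholog genes", {
  qa_a <- assign_quantiles(calls_from_summary(
    c(a1 = 50, a2 = 40, a3 = 30, a4 = 20), id = "A1", species = "human"), 2)
  qa_b <- assign_quantiles(calls_from_summary(
    c(b1 = 50, b9 = 10), id = "B1", species = "zebrafish"), 2)
  om <- orthology_map(c("a1", "a2", "a3"), c("b1", "bGone", "b2"),
                      c(1L, 1L, 0L), "human", "zebrafish")
  qm <- build_quantile_mapping(qa_a, qa_b, om)
  # a1-b1 lands in the grid; a2's only HC ortholog is unexpressed;
  # a3's ortholog is low-confidence so a3 counts as no-ortholog; a4 too
  expect_equal(qm$counts[1, 1], 1L)
  expect_equal(qm$counts[1, 3], 1L)   # a2: quantile 1, col n+1
  expect_equal(qm$counts[2, 4], 2L)   # a3, a4: quantile 2, col n+2
  # column-side: b9 expressed, no HC ortholog -> row n+2
  expect_equal(qm$counts[4, 2], 1L)
})

test_that("grid counts conserve the number of doubly expressed HC pairs", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 120
    tpm_a <- setNames(rexp(n, 0.01) + 1.01, sprintf("a%03d", 1:n))
    tpm_b <- setNames(rexp(n, 0.01) + 1.01, sprintf("b%03d", 1:n))
    qa <- assign_quantiles(calls_from_summary(tpm_a, "A1", "human"), 10)
    qb <- assign_quantiles(calls_from_summary(tpm_b, "B1", "zebrafish"), 10)
    ga <- sprintf("a%03d", sample(n + 40, 150, replace = TRUE))
    gb <- sprintf("b%03d", sample(n + 40, 150, replace = TRUE))
    conf <- rbinom(150, 1, 0.6)
    om <- orthology_map(ga, gb, conf, "human", "zebrafish")
    qm <- build_quantile_mapping(qa, qb, om)
    hc <- om$pairs[om$pairs$confidence == 1, ]
    expected_pairs <- sum(hc$gene_a %in% names(tpm_a) &
                          hc$gene_b %in% names(tpm_b))
    expect_equal(sum(qm$counts[1:10, 1:10]), expected_pairs)
    # each expressed row gene falls in exactly one unique-gene category
    expect_equal(length(qm$gene_categories$row), n)
    expect_true(all(qm$gene_categories$row %in%
                    c("grid", "ortholog_unexpressed", "no_ortholog")))
  }
})

test_that("species mismatch between assignments and orthology errors", {
  qa <- assign_quantiles(calls_from_summary(
    c(a1 = 2, a2 = 3), id = "A1", species = "human"), 2)
  qb <- assign_quantiles(calls_from_summary(
    c(b1 = 2, b2 = 3), id = "B1", species = "zebrafish"), 2)
  om <- orthology_map("a1", "b1", 1L, "mouse", "zebrafish")
  expect_error(build_quantile_mapping(qa, qb, om),
               class = "orthoquant_validation_error")
  expect_error(build_quantile_mapping(qa, qb, om = NULL),
               class = "orthoquant_validation_error")
})

test_that("region enrichment reports the uniform expectation", {
  # N pairs spread over the grid: a single cell expects N/100
  set.seed(17)
  n <- 600
  tpm_a <- setNames(rexp(n) + 1.01, sprintf("a%03d", 1:n))
  tpm_b <- setNames(rexp(n) + 1.01, sprintf("b%03d", 1:n))
  qa <- assign_quantiles(calls_from_summary(tpm_a, "A1", "human"), 10)
  qb <- assign_quantiles(calls_from_summary(tpm_b, "B1", "zebrafish"), 10)
  om <- orthology_map(names(tpm_a), names(tpm_b), rep(1L, n),
                      "human", "zebrafish")
  qm <- build_quantile_mapping(qa, qb, om)
  re <- region_enrichment(qm, 1, 1)
  expect_equal(re$expected, n / 100)
  re33 <- region_enrichment(qm, 1:3, 1:3)
  expect_equal(re33$expected, n * 9 / 100)
  expect_equal(re33$n_mapped, n)
})

test_that("one-sided region p equals the exhaustive hypergeometric tail", {
  qm <- toy_four_pair_map()
  re <- region_enrichment(qm, 1, 1, alternative = "greater")
  oracle <- hyper_tail_oracle(re$observed,
                              list_size = sum(qm$counts[1, 1:2]),
                              set_size = sum(qm$counts[1:2, 1]),
                              universe_size = re$n_mapped)
  expect_equal(re$p_value, oracle, tolerance = 1e-12)

  set.seed(23)
  n <- 40
  tpm_a <- setNames(rexp(n) + 1.01, sprintf("a%03d", 1:n))
  tpm_b <- setNames(tpm_a + rnorm(n, 0, 0.2), sprintf("b%03d", 1:n))
  qa <- assign_quantiles(calls_from_summary(tpm_a, "A1", "human"), 4)
  qb <- assign_quantiles(calls_from_summary(pmax(tpm_b, 1.01), "B1",
                                            "zebrafish"), 4)
  om <- orthology_map(names(tpm_a), names(tpm_b), rep(1L, n),
                      "human", "zebrafish")
  qm2 <- build_quantile_mapping(qa, qb, om)
  re2 <- region_enrichment(qm2, 1, 1, alternative = "greater")
  grid <- qm2$counts[1:4, 1:4]
  oracle2 <- hyper_tail_oracle(grid[1, 1], sum(grid[1, ]), sum(grid[, 1]),
                               sum(grid))
  expect_equal(re2$p_value, oracle2, tolerance = 1e-12)
})

test_that("region enrichment validates its region", {
  qm <- toy_four_pair_map()
  expect_error(region_enrichment(qm, integer(0), 1),
               class = "orthoquant_validation_error")
  expect_error(region_enrichment(qm, 1, 3),
               class = "orthoquant_validation_error")  # margins excluded
})

test_that("region enrichment is invariant to replicate order upstream", {
  set.seed(41)
  m <- matrix(rexp(300, 0.05) + 1.01, nrow = 100,
              dimnames = list(sprintf("a%03d", 1:100), paste0("r", 1:3)))
  ds1 <- toy_dataset(m, id = "A1")
  ds2 <- toy_dataset(m[, c(3, 1, 2)], id = "A1")
  mb <- matrix(rexp(300, 0.05) + 1.01, nrow = 100,
               dimnames = list(sprintf("b%03d", 1:100), paste0("r", 1:3)))
  dsb <- toy_dataset(mb, id = "B1", species = "zebrafish")
  om <- orthology_map(rownames(m), rownames(mb), rep(1L, 100),
                      "human", "zebrafish")
  qb <- assign_quantiles(expression_calls(dsb), 5)
  re1 <- region_enrichment(build_quantile_mapping(
    assign_quantiles(expression_calls(ds1), 5), qb, om), 1:2, 1:2)
  re2 <- region_enrichment(build_quantile_mapping(
    assign_quantiles(expression_calls(ds2), 5), qb, om), 1:2, 1:2)
  expect_equal(re1$p_value, re2$p_value)
  expect_equal(re1$observed, re2$observed)
})

test_that("reference projection restricts counts to the listed row genes", {
  qm <- toy_four_pair_map()
  all_ref <- reference_gene_list(paste0("a", 1:4))
  proj <- project_reference_list(qm, all_ref)
  expect_equal(proj$counts, qm$counts)

  disjoint <- project_reference_list(qm, reference_gene_list("zz"))
  expect_equal(sum(disjoint$counts), 0L)

  some <- project_reference_list(qm, reference_gene_list(c("a1", "a4")))
  expect_equal(sum(some$counts), 2L)
  expect_equal(some$counts[1, 1], 1L)
  expect_equal(some$counts[2, 2], 1L)
  expect_equal(some$projection$n_ortholog_expressed, 2L)
})
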