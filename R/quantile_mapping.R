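# The extended quantile-mapping matrix: expressed genes of each dataset
# are binned into expression deciles, and high-confidence ortholog pairs
# are cross-tabulated by their (row-quantile, column-quantile). Two
# margin rows/columns extend the n x n grid:
#   index n+1 — genes expressed on one side with a high-confidence
#               ortholog on the other side, none of which is expressed
#               there;
#   index n+2 — genes expressed on one side with no high-confidence
#               ortholog at all.
# In same-species mode genes are matched by identity, margin n+1 holds
# genes expressed in only one of the two datasets, and n+2 is unused.

#' Assign expressed genes to expression quantiles
#'
#' Genes are ranked by summary TPM in decreasing order and split into
#' `n_quantiles` contiguous blocks: quantile 1 holds the most highly
#' expressed genes. When the number of genes is not divisible by
#' `n_quantiles`, the earlier (higher-expression) quantiles receive the
#' extra genes, so block sizes differ by at most one with larger blocks
#' first. Ties in TPM are broken by gene ID (increasing), making the
#' assignment deterministic.
#'
#' @param calls An [expression_calls()] object (its `summary_tpm` is
#'   used for ranking).
#' @param n_quantiles Number of quantiles (default 10).
#' @return Object of class `quantile_assignment`: `dataset_id`,
#'   `n_quantiles`, `quantile_of` (named integer vector over expressed
#'   genes), `summary_tpm`, and `avg_tpm` (mean summary TPM per
#'   quantile).
#' @export
assign_quantiles <- function(calls, n_quantiles = 10L) {
  stopifnot(inherits(calls, "expression_calls"))
  n_quantiles <- as.integer(n_quantiles)
  if (n_quantiles < 1L) oq_validation_error("'n_quantiles' must be >= 1")
  tpm <- calls$summary_tpm
  N <- length(tpm)
  if (N < n_quantiles)
    oq_validation_error(sprintf(
      "only %d expressed gene(s) for %d quantiles", N, n_quantiles))
  ord <- order(-tpm, names(tpm), method = "radix")
  sizes <- rep(N %/% n_quantiles, n_quantiles)
  extra <- N %% n_quantiles
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- rep.int(seq_len(n_quantiles), sizes)
  quantile_of <- integer(N)
  quantile_of[ord] <- q
  names(quantile_of) <- names(tpm)
  avg_tpm <- vapply(split(tpm[ord], q), mean, numeric(1))
  structure(list(dataset_id = calls$dataset_id,
                 species = calls$species,
                 n_quantiles = n_quantiles,
                 quantile_of = quantile_of,
                 summary_tpm = tpm,
                 avg_tpm = avg_tpm),
            class = "quantile_assignment")
}

#' @export
print.quantile_assignment <- function(x, ...) {
  cat(sprintf("<quantile_assignment> %s: %d genes in %d quantiles\n",
              x$dataset_id, length(x$quantile_of), x$n_quantiles))
  invisible(x)
}

#' Build the extended quantile-mapping matrix between two datasets
#'
#' In cross-species mode the counting unit of the `n x n` grid is the
#' high-confidence ortholog pair: each pair with both genes expressed
#' contributes one count at (row-gene quantile, column-gene quantile),
#' so a gene with several expressed orthologs contributes to several
#' cells. The margin cells count genes: a row-expressed gene in
#' quantile q whose high-confidence orthologs are all unexpressed in
#' the column dataset counts at (q, n+1); one with no high-confidence
#' ortholog counts at (q, n+2); symmetrically, column-side genes fill
#' rows n+1 and n+2. In same-species mode genes are matched by
#' identity; genes expressed in only one dataset fill margin n+1 and
#' margin n+2 stays empty.
#'
#' @param qa_row,qa_col [assign_quantiles()] results for the row and
#'   column datasets. Both must use the same `n_quantiles`.
#' @param om An [orthology_map()] for cross-species mode (only its
#'   confidence-1 pairs are used), or `NULL` for same-species mode.
#'   The map's species must match the two assignments: the row dataset
#'   on the A side and the column dataset on the B side.
#' @return Object of class `quantile_mapping` with fields `counts`
#'   (`(n+2) x (n+2)` integer matrix), `members` (list keyed
#'   `"r,c"` of data frames `gene_row`/`gene_col`), `avg_tpm_row`,
#'   `avg_tpm_col`, `mode`, `n_quantiles`, dataset labels, and
#'   `gene_categories`: per-side factors classifying each expressed
#'   gene as `grid`, `ortholog_unexpressed` or `no_ortholog`
#'   (`unique_to_dataset` in same-species mode).
#' @export
build_quantile_mapping <- function(qa_row, qa_col, om = NULL) {
  stopifnot(inherits(qa_row, "quantile_assignment"),
            inherits(qa_col, "quantile_assignment"))
  if (qa_row$n_quantiles != qa_col$n_quantiles)
    oq_validation_error("row and column assignments use different n_quantiles")
  n <- qa_row$n_quantiles
  dimn <- c(as.character(seq_len(n)), "no_expr_ortholog", "no_ortholog")
  row_genes <- names(qa_row$quantile_of)
  col_genes <- names(qa_col$quantile_of)

  if (is.null(om)) {
    if (!identical(qa_row$species, qa_col$species))
      oq_validation_error("same-species mode requires matching species labels")
    mode <- "same-species"
    common <- intersect(row_genes, col_genes)
    only_row <- setdiff(row_genes, col_genes)
    only_col <- setdiff(col_genes, row_genes)
    ent_r <- c(qa_row$quantile_of[common], qa_row$quantile_of[only_row],
               rep(n + 1L, length(only_col)))
    ent_c <- c(qa_col$quantile_of[common], rep(n + 1L, length(only_row)),
               qa_col$quantile_of[only_col])
    ent_gr <- c(common, only_row, rep(NA_character_, length(only_col)))
    ent_gc <- c(common, rep(NA_character_, length(only_row)), only_col)
    row_cat <- ifelse(row_genes %in% common, "grid", "unique_to_dataset")
    col_cat <- ifelse(col_genes %in% common, "grid", "unique_to_dataset")
  } else {
    stopifnot(inherits(om, "orthology_map"))
    if (!identical(qa_row$species, om$species_a) ||
        !identical(qa_col$species, om$species_b))
      oq_validation_error(sprintf(
        "species mismatch: assignments are (%s, %s) but orthology map is (%s, %s)",
        qa_row$species, qa_col$species, om$species_a, om$species_b))
    mode <- "cross-species"
    hc <- om$pairs[om$pairs$confidence == 1L, , drop = FALSE]
    both <- hc$gene_a %in% row_genes & hc$gene_b %in% col_genes
    grid_pairs <- hc[both, , drop = FALSE]
    a_with_orth <- unique(hc$gene_a)
    b_with_orth <- unique(hc$gene_b)
    row_cat <- ifelse(row_genes %in% grid_pairs$gene_a, "grid",
               ifelse(row_genes %in% a_with_orth, "ortholog_unexpressed",
                      "no_ortholog"))
    col_cat <- ifelse(col_genes %in% grid_pairs$gene_b, "grid",
               ifelse(col_genes %in% b_with_orth, "ortholog_unexpressed",
                      "no_ortholog"))
    m_row_ou <- row_genes[row_cat == "ortholog_unexpressed"]
    m_row_no <- row_genes[row_cat == "no_ortholog"]
    m_col_ou <- col_genes[col_cat == "ortholog_unexpressed"]
    m_col_no <- col_genes[col_cat == "no_ortholog"]
    ent_r <- c(unname(qa_row$quantile_of[grid_pairs$gene_a]),
               unname(qa_row$quantile_of[m_row_ou]),
               unname(qa_row$quantile_of[m_row_no]),
               rep(n + 1L, length(m_col_ou)), rep(n + 2L, length(m_col_no)))
    ent_c <- c(unname(qa_col$quantile_of[grid_pairs$gene_b]),
               rep(n + 1L, length(m_row_ou)), rep(n + 2L, length(m_row_no)),
               unname(qa_col$quantile_of[m_col_ou]),
               unname(qa_col$quantile_of[m_col_no]))
    ent_gr <- c(grid_pairs$gene_a, m_row_ou, m_row_no,
                rep(NA_character_, length(m_col_ou) + length(m_col_no)))
    ent_gc <- c(grid_pairs$gene_b,
                rep(NA_character_, length(m_row_ou) + length(m_row_no)),
                m_col_ou, m_col_no)
  }
  counts <- matrix(0L, n + 2L, n + 2L, dimnames = list(dimn, dimn))
  members <- list()
  if (length(ent_r)) {
    counts[] <- tabulate((ent_c - 1L) * (n + 2L) + ent_r, nbins = (n + 2L)^2)
    long <- data.frame(gene_row = ent_gr, gene_col = ent_gc,
                       stringsAsFactors = FALSE)
    members <- split(long, paste0(ent_r, ",", ent_c))
    members <- lapply(members, function(df) { rownames(df) <- NULL; df })
  }
  names(row_cat) <- row_genes
  names(col_cat) <- col_genes
  structure(
    list(row_dataset = qa_row$dataset_id,
         col_dataset = qa_col$dataset_id,
         n_quantiles = n,
         mode = mode,
         counts = counts,
         members = members,
         avg_tpm_row = qa_row$avg_tpm,
         avg_tpm_col = qa_col$avg_tpm,
         gene_categories = list(row = row_cat, col = col_cat)),
    class = "quantile_mapping")
}

#' @export
print.quantile_mapping <- function(x, ...) {
  n <- x$n_quantiles
  grid_total <- sum(x$counts[seq_len(n), seq_len(n)])
  cat(sprintf(
    "<quantile_mapping> %s (rows) vs %s (cols), %s mode: %d %s in the %dx%d grid\n",
    x$row_dataset, x$col_dataset, x$mode, grid_total,
    if (x$mode == "cross-species") "ortholog pairs" else "genes", n, n))
  invisible(x)
}

#' Long-format member table of a quantile mapping
#'
#' One line per mapped pair (or per margin gene), giving the row and
#' column index and the gene IDs on both sides (`NA` for the absent
#' side of margin cells).
#'
#' @param qm A `quantile_mapping`.
#' @return A data frame with columns `row`, `col`, `gene_row`,
#'   `gene_col`, `summary_tpm_row`, `summary_tpm_col`.
#' @export
quantile_map_members <- function(qm) {
  stopifnot(inherits(qm, "quantile_mapping"))
  keys <- names(qm$members)
  if (!length(keys))
    return(data.frame(row = integer(0), col = integer(0),
                      gene_row = character(0), gene_col = character(0),
                      summary_tpm_row = numeric(0),
                      summary_tpm_col = numeric(0)))
  rc <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  out <- do.call(rbind, lapply(seq_along(keys), function(i) {
    df <- qm$members[[i]]
    data.frame(row = as.integer(rc[i, 1L]), col = as.integer(rc[i, 2L]),
               df, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$row, out$col, out$gene_row, out$gene_col,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique-gene category counts of a quantile mapping
#'
#' Summarizes each side's expressed genes into the three mutually
#' exclusive categories used in the mapping (grid / ortholog present
#' but unexpressed / no high-confidence ortholog).
#'
#' @param qm A `quantile_mapping`.
#' @return Data frame with one row per (side, category).
#' @export
quantile_map_gene_summary <- function(qm) {
  stopifnot(inherits(qm, "quantile_mapping"))
  do.call(rbind, lapply(c("row", "col"), function(side) {
    tab <- table(qm$gene_categories[[side]])
    data.frame(side = side,
               dataset = if (side == "row") qm$row_dataset else qm$col_dataset,
               category = names(tab), n_genes = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
}

#' Fisher enrichment of a rectangular region of the quantile grid
#'
#' Over the N pairs mapped into the `n x n` quantile grid (margins
#' excluded), tests whether the region `rows x cols` holds more pairs
#' than expected if row and column quantile membership were
#' independent. The 2x2 table is (in region rows and region cols; in
#' rows, not cols; not rows, in cols; neither), tested with Fisher's
#' exact test. The uniform expectation `N * |rows| * |cols| / n^2` is
#' reported alongside.
#'
#' @param qm A `quantile_mapping`.
#' @param rows,cols Integer sets of quantile indices in `1..n`.
#' @param alternative `"two.sided"` (default) or `"greater"`
#'   (over-representation only).
#' @return Object of class `region_enrichment`: `observed`, `expected`,
#'   `odds_ratio` (cross-product estimate), `p_value`, the 2x2
#'   `table`, and the region definition.
#' @export
region_enrichment <- function(qm, rows, cols,
                              alternative = c("two.sided", "greater")) {
  stopifnot(inherits(qm, "quantile_mapping"))
  alternative <- match.arg(alternative)
  n <- qm$n_quantiles
  rows <- unique(as.integer(rows)); cols <- unique(as.integer(cols))
  if (!length(rows) || !length(cols))
    oq_validation_error("region must contain at least one row and one column")
  if (any(rows < 1L | rows > n) || any(cols < 1L | cols > n))
    oq_validation_error(sprintf(
      "region indices must lie in 1..%d (quantile cells only)", n))
  grid <- qm$counts[seq_len(n), seq_len(n), drop = FALSE]
  N <- sum(grid)
  if (N == 0L) oq_abort("no pairs mapped into the quantile grid",
                        "orthoquant_degenerate_error")
  a <- sum(grid[rows, cols])
  b <- sum(grid[rows, -cols, drop = FALSE])
  c_ <- sum(grid[-rows, cols, drop = FALSE])
  d <- N - a - b - c_
  tab <- matrix(c(a, c_, b, d), 2L, 2L,
                dimnames = list(in_rows = c("yes", "no"),
                                in_cols = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  or <- (a * d) / (b * c_)
  structure(list(rows = rows, cols = cols,
                 observed = as.integer(a),
                 expected = N * length(rows) * length(cols) / n^2,
                 odds_ratio = or,
                 p_value = p,
                 n_mapped = as.integer(N),
                 table = tab,
                 alternative = alternative),
            class = "region_enrichment")
}

#' @export
print.region_enrichment <- function(x, ...) {
  cat(sprintf(
    "<region_enrichment> rows {%s} x cols {%s}: observed %d, expected %.2f, OR %.2f, p = %.3g\n",
    paste(x$rows, collapse = ","), paste(x$cols, collapse = ","),
    x$observed, x$expected, x$odds_ratio, x$p_value))
  invisible(x)
}

#' Restrict a quantile mapping to a reference gene list
#'
#' Keeps only the pairs (and margin entries) whose row-side gene is in
#' the reference list and recomputes all counts. Used e.g. to locate
#' externally defined oocyte-specific genes on the mapping.
#'
#' @param qm A `quantile_mapping`.
#' @param ref A [reference_gene_list()] of row-species gene IDs.
#' @return A `quantile_mapping` restricted to the reference genes, with
#'   an extra `projection` field reporting per-category counts of the
#'   reference genes (`n_reference`, `n_expressed_row`,
#'   `n_with_ortholog`, `n_ortholog_expressed`).
#' @export
project_reference_list <- function(qm, ref) {
  stopifnot(inherits(qm, "quantile_mapping"),
            inherits(ref, "reference_gene_list"))
  out <- qm
  n <- qm$n_quantiles
  out$counts[] <- 0L
  out$members <- list()
  for (key in names(qm$members)) {
    df <- qm$members[[key]]
    rc <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    keep <- if (rc[1L] > n) rep(FALSE, nrow(df)) else df$gene_row %in% ref$genes
    # rows n+1/n+2 hold column-side genes; a row-gene reference cannot
    # select them, so they are dropped from the projection.
    if (any(keep)) {
      out$members[[key]] <- df[keep, , drop = FALSE]
      out$counts[rc[1L], rc[2L]] <- sum(keep)
    }
  }
  row_cat <- qm$gene_categories$row
  in_ref <- names(row_cat) %in% ref$genes
  out$gene_categories$row <- row_cat[in_ref]
  grid_cols <- out$counts[seq_len(n), seq_len(n), drop = FALSE]
  expressed_ref <- names(row_cat)[in_ref]
  with_orth <- sum(row_cat[in_ref] %in% c("grid", "ortholog_unexpressed"))
  out$projection <- list(
    reference = ref$name,
    n_reference = length(ref$genes),
    n_expressed_row = length(expressed_ref),
    n_with_ortholog = with_orth,
    n_ortholog_expressed = sum(row_cat[in_ref] == "grid"))
  out
}
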