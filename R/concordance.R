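# Extraction and ranking of "highly concordant orthologous genes":
# high-confidence ortholog pairs whose members sit in the top-k
# expression quantiles of both species, intersected across the row-side
# (e.g. human) datasets and ranked by grand-mean TPM over every
# replicate of every dataset.

#' Row-side genes of the top k x k region of a quantile mapping
#'
#' Returns the unique row-dataset gene IDs of the ortholog pairs that
#' fall in rows 1..k and columns 1..k of the quantile grid, i.e. genes
#' expressed in the top `k/n` fraction in both datasets through at
#' least one high-confidence ortholog. In the many-to-many case a gene
#' qualifies as soon as ANY of its expressed high-confidence orthologs
#' places a pair in the region.
#'
#' @param qm A `quantile_mapping`.
#' @param k Region size in quantiles (default 3, i.e. the top 30% with
#'   10 quantiles).
#' @return Character vector of row-side gene IDs.
#' @export
top_region_genes <- function(qm, k = 3L) {
  stopifnot(inherits(qm, "quantile_mapping"))
  k <- as.integer(k)
  if (k < 1L || k > qm$n_quantiles)
    oq_validation_error(sprintf("'k' must lie in 1..%d", qm$n_quantiles))
  keys <- names(qm$members)
  if (!length(keys)) return(character(0))
  rc <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  sel <- as.integer(rc[, 1L]) <= k & as.integer(rc[, 2L]) <= k
  genes <- unlist(lapply(qm$members[sel], `[[`, "gene_row"),
                  use.names = FALSE)
  sort(unique(genes[!is.na(genes)]))
}

#' Intersect per-dataset concordant gene sets and rank by grand-mean TPM
#'
#' Takes the top-region gene sets obtained from several quantile
#' mappings (one per row-side dataset against the common column-side
#' dataset), intersects them, and ranks the intersection by the average
#' TPM over all replicates of all supplied datasets. For a dataset of
#' the other species the gene's signal is taken from its expressed
#' high-confidence orthologs: when several qualify, their TPMs are
#' averaged replicate-wise first (gene-level average), then pooled, and
#' the gene is flagged `multi_ortholog`.
#'
#' @param sets Named list of character vectors: per-dataset concordant
#'   row-side gene sets (names are dataset IDs).
#' @param datasets List of [expression_dataset()] objects covering every
#'   dataset whose replicates enter the grand mean (typically the
#'   row-side datasets plus the column-side dataset).
#' @param om [orthology_map()] used to fetch ortholog signal in
#'   datasets of the other species (only confidence-1 pairs are used).
#'   May be `NULL` when all datasets share the genes' species.
#' @param species Species of the genes in `sets` (default: species of
#'   the first dataset containing them).
#' @param tpm_threshold Expression cutoff used to decide which
#'   orthologs "qualify" as expressed contributors (default 1).
#' @return Object of class `concordance_result`: `per_dataset` (the
#'   input sets), `intersection`, `overlap_percent` (of the smallest
#'   set, rounded half away from zero), and `ranking` — a data frame
#'   (rank, gene, avg_tpm, multi_ortholog) sorted by `avg_tpm`
#'   decreasing with ties broken by gene ID.
#' @export
intersect_and_rank <- function(sets, datasets, om = NULL, species = NULL,
                               tpm_threshold = 1.0) {
  if (!length(sets)) oq_validation_error("need at least one gene set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    oq_validation_error("'sets' must be a named list of gene sets")
  inter <- Reduce(intersect, sets)
  smallest <- min(lengths(sets))
  overlap_pct <- if (length(sets) > 1L)
    round_half_up(100 * length(inter) / smallest) else 100
  species <- species %||% datasets[[1L]]$species
  hc <- if (!is.null(om)) om$pairs[om$pairs$confidence == 1L, , drop = FALSE]

  gene_signal <- function(g) {
    vals <- numeric(0); multi <- FALSE
    for (ds in datasets) {
      if (identical(ds$species, species)) {
        if (g %in% ds$genes) vals <- c(vals, ds$tpm[g, ])
        # a human gene absent from the other human dataset simply
        # contributes nothing from it
      } else {
        if (is.null(hc))
          oq_validation_error(
            "orthology map required for datasets of the other species")
        orth <- if (identical(om$species_a, species))
          hc$gene_b[hc$gene_a == g] else hc$gene_a[hc$gene_b == g]
        orth <- unique(orth[orth %in% ds$genes])
        orth <- orth[rowSums(ds$tpm[orth, , drop = FALSE] > tpm_threshold) ==
                       ncol(ds$tpm)]
        if (!length(orth))
          oq_abort(sprintf(
            "gene '%s' has no expressed high-confidence ortholog in dataset '%s'",
            g, ds$dataset_id), "orthoquant_validation_error")
        if (length(orth) > 1L) multi <- TRUE
        vals <- c(vals, colMeans(ds$tpm[orth, , drop = FALSE]))
      }
    }
    list(mean = mean(vals), multi = multi)
  }

  sig <- lapply(inter, gene_signal)
  ranking <- data.frame(
    gene = inter,
    avg_tpm = vapply(sig, `[[`, numeric(1), "mean"),
    multi_ortholog = vapply(sig, `[[`, logical(1), "multi"),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$avg_tpm, ranking$gene,
                           method = "radix"), , drop = FALSE]
  ranking <- data.frame(rank = seq_len(nrow(ranking)), ranking,
                        row.names = NULL)
  structure(list(per_dataset = sets,
                 intersection = inter,
                 overlap_percent = overlap_pct,
                 ranking = ranking),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> %d concordant gene(s) across %d set(s) (%g%% of the smallest set)\n",
    length(x$intersection), length(x$per_dataset), x$overlap_percent))
  if (nrow(x$ranking)) print(utils::head(x$ranking, 5L))
  invisible(x)
}

#' Cross-reference a concordance ranking with a reference gene list
#'
#' Returns the members of the ranking that appear in the reference
#' list, preserving the ranking order (e.g. to flag genes with a known
#' epigenetic function).
#'
#' @param result A `concordance_result`.
#' @param ref A [reference_gene_list()].
#' @return The subset of `result$ranking` whose genes are in `ref`.
#' @export
cross_reference <- function(result, ref) {
  stopifnot(inherits(result, "concordance_result"),
            inherits(ref, "reference_gene_list"))
  out <- result$ranking[result$ranking$gene %in% ref$genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
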