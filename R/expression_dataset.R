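#' Construct an expression dataset
#'
#' An `expression_dataset` holds a gene-by-replicate matrix of TPM
#' (transcripts per million) values for one study, together with a short
#' dataset label, the species, and optional per-gene biotype annotations.
#' TPM is a relative abundance measure: within each replicate the values
#' nominally sum to one million.
#'
#' @param tpm Numeric matrix, genes in rows, replicates in columns. Row
#'   names are gene IDs (required, unique); column names are replicate IDs
#'   (generated as `rep1..repK` when absent). All values must be finite
#'   and non-negative.
#' @param dataset_id Short label, e.g. `"H1"` or `"ZF"`.
#' @param species Species label, e.g. `"human"`.
#' @param gene_types Optional named character vector mapping gene IDs to
#'   biotype labels (e.g. `"protein_coding"`). Every name must be a gene
#'   of the dataset.
#' @return An object of class `expression_dataset` with fields
#'   `dataset_id`, `species`, `genes`, `replicates`, `tpm`, `gene_types`.
#' @examples
#' m <- matrix(c(5, 0, 2, 6, 1, 2), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
#' ds <- expression_dataset(m, "TOY", "human")
#' ds$genes
#' @export
expression_dataset <- function(tpm, dataset_id, species, gene_types = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm))
    oq_validation_error("'tpm' must be a numeric matrix")
  if (is.null(rownames(tpm)))
    oq_validation_error("'tpm' must have gene IDs as row names")
  if (ncol(tpm) < 1L)
    oq_validation_error("dataset must have at least one replicate")
  if (is.null(colnames(tpm)))
    colnames(tpm) <- paste0("rep", seq_len(ncol(tpm)))
  genes <- rownames(tpm)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    oq_validation_error(sprintf("duplicate gene ID(s): %s",
                                paste(unique(dup), collapse = ", ")))
  bad <- which(!is.finite(tpm) | tpm < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    oq_validation_error(sprintf(
      "negative or non-finite TPM at gene '%s', replicate '%s'",
      genes[bad[1L, 1L]], colnames(tpm)[bad[1L, 2L]]))
  }
  if (!is.null(gene_types)) {
    if (is.null(names(gene_types)))
      oq_validation_error("'gene_types' must be a named character vector")
    unknown <- setdiff(names(gene_types), genes)
    if (length(unknown))
      oq_validation_error(sprintf(
        "gene_types refer to unknown gene(s): %s",
        paste(utils::head(unknown, 5L), collapse = ", ")))
    gene_types <- as.character(gene_types) |> stats::setNames(names(gene_types))
  }
  structure(
    list(dataset_id = as.character(dataset_id),
         species = as.character(species),
         genes = genes,
         replicates = colnames(tpm),
         tpm = tpm,
         gene_types = gene_types),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s (%s): %d genes x %d replicates\n",
              x$dataset_id, x$species, length(x$genes), length(x$replicates)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$tpm)
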