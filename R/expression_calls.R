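# Gene-status calls on TPM matrices: "expressed" (TPM above a threshold
# in every replicate) and "highly expressed" (replicate-wise z-score of
# log TPM among expressed genes above a threshold in a minimum number of
# replicates), plus TPM-distribution summaries.

#' Call expressed genes
#'
#' A gene is "expressed" in a dataset when its TPM is strictly greater
#' than `tpm_threshold` in every replicate.
#'
#' @param ds An [expression_dataset()].
#' @param tpm_threshold TPM cutoff (default 1; the comparison is strict).
#' @return Character vector of expressed gene IDs, in dataset order.
#' @export
call_expressed <- function(ds, tpm_threshold = 1.0) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is_scalar_number(tpm_threshold) || tpm_threshold < 0)
    oq_validation_error("'tpm_threshold' must be a non-negative number")
  ok <- rowSums(ds$tpm > tpm_threshold) == ncol(ds$tpm)
  ds$genes[ok]
}

#' Call highly expressed genes
#'
#' Within each replicate independently, z-scores are computed over the
#' log TPM values of the expressed genes only (mean and SD taken over
#' the expressed genes of that replicate). A gene is "highly expressed"
#' when its z-score exceeds `z_threshold` in at least `min_replicates`
#' replicates. The log base does not affect z-scores; log2 is used.
#'
#' @param ds An [expression_dataset()].
#' @param expressed Character vector of expressed gene IDs (subset of
#'   the dataset's genes), typically from [call_expressed()]. Since all
#'   expressed genes have TPM above 1, no pseudocount is needed.
#' @param z_threshold z-score cutoff (default 1.5, strict comparison).
#' @param min_replicates Minimum number of replicates in which the
#'   cutoff must be exceeded. Default `ceiling(2/3 * n_replicates)`,
#'   the 2-of-3 rule generalized to other designs.
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n) for the per-replicate SD.
#' @return Character vector of highly expressed gene IDs.
#' @export
call_highly_expressed <- function(ds, expressed, z_threshold = 1.5,
                                  min_replicates = NULL,
                                  sd_type = c("sample", "population")) {
  stopifnot(inherits(ds, "expression_dataset"))
  sd_type <- match.arg(sd_type)
  if (is.null(min_replicates))
    min_replicates <- as.integer(ceiling(2 / 3 * ncol(ds$tpm)))
  unknown <- setdiff(expressed, ds$genes)
  if (length(unknown))
    oq_validation_error(sprintf("expressed genes not in dataset: %s",
                                paste(utils::head(unknown, 5), collapse = ", ")))
  if (length(expressed) < 2L)
    oq_validation_error("need at least 2 expressed genes to compute z-scores")
  lt <- log2(ds$tpm[expressed, , drop = FALSE])
  mu <- colMeans(lt)
  n <- nrow(lt)
  ss <- colSums(sweep(lt, 2L, mu)^2)
  sdv <- sqrt(ss / if (sd_type == "sample") n - 1 else n)
  if (any(sdv == 0))
    oq_abort(sprintf("zero SD of log TPM in replicate '%s': degenerate dataset",
                     colnames(lt)[which(sdv == 0)[1L]]),
             "orthoquant_degenerate_error")
  z <- sweep(sweep(lt, 2L, mu), 2L, sdv, `/`)
  hits <- rowSums(z > z_threshold) >= min_replicates
  expressed[hits]
}

#' Expression calls for a dataset
#'
#' Convenience wrapper bundling [call_expressed()] and
#' [call_highly_expressed()] with the per-gene mean TPM used downstream
#' for quantile ranking.
#'
#' @inheritParams call_expressed
#' @inheritParams call_highly_expressed
#' @param summary_fun How replicate TPMs are summarized per gene for
#'   ranking: `"mean"` (arithmetic, default) or `"geometric"`.
#' @return An object of class `expression_calls`: list with
#'   `dataset_id`, `expressed`, `highly_expressed`, `summary_tpm`
#'   (named vector over expressed genes) and the thresholds used.
#' @export
expression_calls <- function(ds, tpm_threshold = 1.0, z_threshold = 1.5,
                             min_replicates = NULL,
                             sd_type = c("sample", "population"),
                             summary_fun = c("mean", "geometric")) {
  summary_fun <- match.arg(summary_fun)
  sd_type <- match.arg(sd_type)
  expressed <- call_expressed(ds, tpm_threshold)
  highly <- call_highly_expressed(ds, expressed, z_threshold,
                                  min_replicates, sd_type)
  m <- ds$tpm[expressed, , drop = FALSE]
  summary_tpm <- if (summary_fun == "mean") rowMeans(m)
                 else 2^rowMeans(log2(m))
  structure(
    list(dataset_id = ds$dataset_id,
         species = ds$species,
         expressed = expressed,
         highly_expressed = highly,
         summary_tpm = summary_tpm,
         tpm_threshold = tpm_threshold,
         z_threshold = z_threshold),
    class = "expression_calls")
}

#' @export
print.expression_calls <- function(x, ...) {
  cat(sprintf("<expression_calls> %s: %d expressed, %d highly expressed\n",
              x$dataset_id, length(x$expressed), length(x$highly_expressed)))
  invisible(x)
}

#' Per-replicate TPM distribution over fixed intervals
#'
#' Counts genes per TPM interval per replicate. With the default edges
#' `c(0, 1, 10, 100)` the bins are the five-interval scheme
#' `{0}`, `(0,1)`, `[1,10)`, `[10,100)`, `[100,Inf)`: a dedicated bin
#' for exact zeros, then left-closed intervals from each edge.
#'
#' @param ds An [expression_dataset()].
#' @param bin_edges Strictly increasing non-negative numeric vector
#'   starting at 0. The first bin is exact zeros; subsequent bins are
#'   `(0, e2)`, `[e2, e3)`, ..., `[e_last, Inf)`.
#' @return Object of class `tpm_distribution`: counts matrix (bins x
#'   replicates), bin labels, and the fraction matrix.
#' @export
tpm_distribution <- function(ds, bin_edges = c(0, 1, 10, 100)) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    oq_validation_error("'bin_edges' must be strictly increasing")
  if (bin_edges[1L] != 0)
    oq_validation_error("'bin_edges' must start at 0 (zero-TPM bin)")
  inner <- bin_edges[-1L]
  labels <- c("0",
              sprintf("(0,%g)", inner[1L]),
              if (length(inner) > 1L)
                sprintf("[%g,%g)", inner[-length(inner)], inner[-1L]),
              sprintf("[%g,Inf)", inner[length(inner)]))
  counts <- apply(ds$tpm, 2L, function(v) {
    zero <- sum(v == 0)
    cuts <- c(0, inner, Inf)
    tab <- tabulate(findInterval(v[v > 0], cuts), nbins = length(cuts) - 1L)
    c(zero, tab)
  })
  rownames(counts) <- labels
  structure(list(dataset_id = ds$dataset_id,
                 bin_edges = bin_edges,
                 counts = counts,
                 fractions = sweep(counts, 2L, colSums(counts), `/`)),
            class = "tpm_distribution")
}

#' @export
print.tpm_distribution <- function(x, ...) {
  cat(sprintf("<tpm_distribution> %s\n", x$dataset_id))
  print(x$counts)
  invisible(x)
}
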