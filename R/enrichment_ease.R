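# Gene-set over-representation with Fisher's exact test and the EASE
# score: Fisher's one-sided p recomputed after removing one hit from
# the category, which penalizes categories supported by very few genes
# (a single-gene category can never be significant). Bonferroni
# correction over the tested sets is reported alongside.

check_margins <- function(hits, list_size, set_size, universe_size) {
  vals <- c(hits, list_size, set_size, universe_size)
  if (any(vals < 0) || any(vals != floor(vals)))
    oq_validation_error("all counts must be non-negative integers")
  if (hits > list_size || hits > set_size ||
      list_size > universe_size || set_size > universe_size)
    oq_validation_error(sprintf(
      "inconsistent 2x2 margins: hits=%d, list=%d, set=%d, universe=%d",
      hits, list_size, set_size, universe_size))
}

#' One-sided Fisher over-representation p-value
#'
#' Hypergeometric upper tail P(X >= hits) for drawing `list_size` genes
#' from a universe of `universe_size` of which `set_size` belong to the
#' category.
#'
#' @param hits Category genes in the analyzed list.
#' @param list_size Size of the analyzed list.
#' @param set_size Category size within the universe.
#' @param universe_size Universe size.
#' @return p-value in (0, 1].
#' @export
fisher_overrep <- function(hits, list_size, set_size, universe_size) {
  check_margins(hits, list_size, set_size, universe_size)
  stats::phyper(hits - 1, set_size, universe_size - set_size, list_size,
                lower.tail = FALSE)
}

#' EASE score (one-removed Fisher over-representation p-value)
#'
#' [fisher_overrep()] with the hit count replaced by
#' `max(hits - 1, 0)`, margins unchanged. Always at least as large as
#' the Fisher p-value, and exactly 1 for categories with 0 or 1 hits.
#'
#' @inheritParams fisher_overrep
#' @return p-value in (0, 1].
#' @export
ease_score <- function(hits, list_size, set_size, universe_size) {
  check_margins(hits, list_size, set_size, universe_size)
  fisher_overrep(max(hits - 1, 0), list_size, set_size, universe_size)
}

#' Gene-set over-representation analysis with EASE scoring
#'
#' Scores every set of the collection that shares at least one gene
#' with the analyzed list. Significance is called on the raw EASE score
#' at `threshold` (0.05 by default); a Bonferroni-corrected EASE score
#' over the number of tested sets is reported and can be used as the
#' criterion instead.
#'
#' @param gene_list Character vector of genes to test.
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param universe Character vector of background genes. Default: the
#'   union of all collection members and the analyzed list.
#' @param threshold Significance cutoff on the chosen criterion.
#' @param criterion `"ease"` (raw EASE score, default) or
#'   `"bonferroni"` (Bonferroni-corrected EASE).
#' @return Data frame of class `enrichment_result`, one row per tested
#'   set, sorted by EASE score then set name: `set_name`, `hits`,
#'   `list_size`, `set_size`, `universe_size`, `fisher_p`,
#'   `ease_score`, `bonferroni_ease`, `significant`.
#' @export
enrich <- function(gene_list, collection, universe = NULL, threshold = 0.05,
                   criterion = c("ease", "bonferroni")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(as.character(gene_list))
  if (is.null(universe))
    universe <- unique(c(unlist(lapply(collection, `[[`, "genes"),
                                use.names = FALSE), gene_list))
  universe <- unique(as.character(universe))
  if (!length(universe)) oq_validation_error("empty universe")
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    oq_validation_error(sprintf("gene list not contained in universe (%s, ...)",
                                outside[1L]))
  gene_list <- intersect(gene_list, universe)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$genes, universe)
    hits <- length(intersect(members, gene_list))
    if (hits == 0L) return(NULL)
    data.frame(set_name = nm, hits = hits,
               list_size = length(gene_list),
               set_size = length(members),
               universe_size = length(universe),
               fisher_p = fisher_overrep(hits, length(gene_list),
                                         length(members), length(universe)),
               ease_score = ease_score(hits, length(gene_list),
                                       length(members), length(universe)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set_name = character(0), hits = integer(0),
                      list_size = integer(0), set_size = integer(0),
                      universe_size = integer(0), fisher_p = numeric(0),
                      ease_score = numeric(0), bonferroni_ease = numeric(0),
                      significant = logical(0))
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$bonferroni_ease <- pmin(1, out$ease_score * nrow(out))
  crit <- if (criterion == "ease") out$ease_score else out$bonferroni_ease
  out$significant <- crit <= threshold
  out <- out[order(out$ease_score, out$set_name, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}
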