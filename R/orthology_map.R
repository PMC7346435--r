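#' Construct a cross-species orthology map
#'
#' The orthology relation between two species is many-to-many: one gene
#' in species A may be orthologous to several genes in species B and
#' vice versa. Each pair carries a binary confidence flag (1 = high,
#' 0 = low), mirroring Ensembl's orthology-confidence classification.
#' Duplicate (gene_a, gene_b) pairs are removed, keeping the first.
#'
#' @param gene_a,gene_b Character vectors of equal length: paired gene
#'   IDs in species A and species B.
#' @param confidence Integer vector in {0, 1}, same length.
#' @param species_a,species_b Species labels.
#' @return An object of class `orthology_map` with a `pairs` data frame
#'   (`gene_a`, `gene_b`, `confidence`) and the species labels.
#' @export
orthology_map <- function(gene_a, gene_b, confidence,
                          species_a = "A", species_b = "B") {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b) ||
      length(gene_a) != length(confidence))
    oq_validation_error("gene_a, gene_b and confidence must have equal length")
  if (length(confidence) && !all(confidence %in% c(0L, 1L)))
    oq_validation_error("orthology confidence must be 0 or 1")
  keep <- !duplicated(paste(gene_a, gene_b, sep = "\r"))
  pairs <- data.frame(gene_a = gene_a[keep], gene_b = gene_b[keep],
                      confidence = as.integer(confidence)[keep],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 species_a = as.character(species_a),
                 species_b = as.character(species_b)),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  s <- orthology_summary(x)
  cat(sprintf(
    "<orthology_map> %s vs %s: %d pair(s), %d %s gene(s), %d %s gene(s), %d high-confidence\n",
    x$species_a, x$species_b, s$n_pairs, s$n_genes_a, x$species_a,
    s$n_genes_b, x$species_b, s$n_high_confidence))
  invisible(x)
}

#' Summary counts for an orthology map
#'
#' @param om An [orthology_map()].
#' @return List with `n_pairs`, `n_genes_a`, `n_genes_b`,
#'   `n_high_confidence`.
#' @export
orthology_summary <- function(om) {
  stopifnot(inherits(om, "orthology_map"))
  list(n_pairs = nrow(om$pairs),
       n_genes_a = length(unique(om$pairs$gene_a)),
       n_genes_b = length(unique(om$pairs$gene_b)),
       n_high_confidence = sum(om$pairs$confidence == 1L))
}

#' Keep only high-confidence ortholog pairs
#'
#' Retains pairs with confidence 1; the many-to-many structure is
#' preserved (no collapsing to one-to-one). Idempotent.
#'
#' @param om An [orthology_map()].
#' @return An [orthology_map()] with only confidence-1 pairs.
#' @export
filter_high_confidence <- function(om) {
  stopifnot(inherits(om, "orthology_map"))
  keep <- om$pairs$confidence == 1L
  orthology_map(om$pairs$gene_a[keep], om$pairs$gene_b[keep],
                om$pairs$confidence[keep], om$species_a, om$species_b)
}

#' Orthologs of a gene
#'
#' Genes absent from the map return an empty set rather than an error:
#' expression matrices and orthology tables typically come from
#' different gene universes.
#'
#' @param om An [orthology_map()].
#' @param gene A gene ID.
#' @param direction `"a_to_b"` (query a species-A gene) or `"b_to_a"`.
#' @return Character vector of ortholog IDs (possibly empty).
#' @export
orthologs_of <- function(om, gene, direction = c("a_to_b", "b_to_a")) {
  stopifnot(inherits(om, "orthology_map"))
  direction <- match.arg(direction)
  p <- om$pairs
  if (direction == "a_to_b") unique(p$gene_b[p$gene_a == gene])
  else unique(p$gene_a[p$gene_b == gene])
}
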