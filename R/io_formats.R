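# Readers and writers for the tabular artifacts of the pipeline:
# TPM matrices, GMT gene sets, reference gene lists and quantile-map
# exports. All formats are plain TSV/GMT text; decimal separator is ".",
# encoding UTF-8, and both LF and CRLF line endings are accepted.

#' Read a gene-by-replicate TPM matrix
#'
#' Expects a tab-separated file with a header row of replicate IDs, the
#' first column holding gene IDs, and a numeric body of TPM values.
#'
#' @param path Path to the TSV file.
#' @param dataset_id,species Labels attached to the resulting dataset.
#' @param strip_id_version If `TRUE`, trailing Ensembl-style version
#'   suffixes (`".NN"`) are removed from gene IDs before validation.
#'   Off by default: gene IDs are treated as opaque case-sensitive
#'   strings, and stripping must be an explicit choice.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dataset_id, species,
                                   strip_id_version = FALSE) {
  if (!file.exists(path)) oq_abort(sprintf("file not found: %s", path),
                                   "orthoquant_io_error")
  header <- readLines(path, n = 1L)
  if (!length(header) || !grepl("\t", header))
    oq_parse_error(sprintf("malformed header (no tab separator) in %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    oq_parse_error("expression matrix needs a gene column and >=1 replicate")
  ids <- df[[1L]]
  if (strip_id_version) ids <- sub("\\.\\d+$", "", ids)
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(NULL, colnames(body))))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad))
    oq_validation_error(sprintf(
      "non-numeric TPM value '%s' at gene '%s', column '%s'",
      body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
      colnames(body)[bad[1L, 2L]]))
  rownames(num) <- ids
  expression_dataset(num, dataset_id = dataset_id, species = species)
}

#' Write a TPM matrix in the format read_expression_matrix() expects
#'
#' @param ds An [expression_dataset()].
#' @param path Output path.
#' @param gene_col Name used for the gene-ID header column.
#' @export
write_expression_matrix <- function(ds, path, gene_col = "gene_id") {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(ds$genes, ds$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member gene IDs, all
#' tab-separated. Duplicate members within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: a named list of sets, each a list
#'   with `description` and `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) oq_abort(sprintf("file not found: %s", path),
                                   "orthoquant_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      oq_parse_error(sprintf("GMT line %d has %d field(s); need name, description and >=1 member",
                             i, length(fields)))
    nm <- fields[[1L]]
    if (nm %in% names(sets))
      oq_parse_error(sprintf("duplicate gene-set name '%s' at line %d", nm, i))
    sets[[nm]] <- list(description = fields[[2L]],
                       genes = unique(fields[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s)\n", length(x)))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a reference gene list
#'
#' A named list of unique gene IDs, used e.g. to project externally
#' defined gene sets (oocyte-specific genes, epigenetic-factor genes)
#' onto the quantile mapping or the concordant-gene ranking.
#'
#' @param genes Character vector of gene IDs (duplicates are dropped).
#' @param name Label for the list.
#' @export
reference_gene_list <- function(genes, name = "reference") {
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  genes <- unique(genes)
  if (!length(genes)) oq_validation_error("reference gene list is empty")
  structure(list(name = as.character(name), genes = genes),
            class = "reference_gene_list")
}

#' Read a one-gene-per-line reference list
#' @param path Path to a plain-text file, one gene ID per line.
#' @param name Label for the list (default: file name without extension).
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) oq_abort(sprintf("file not found: %s", path),
                                   "orthoquant_io_error")
  genes <- readLines(path, warn = FALSE)
  genes <- sub("\r$", "", genes)
  reference_gene_list(genes, name %||% tools::file_path_sans_ext(basename(path)))
}

#' Export a quantile mapping as a TSV pair
#'
#' Writes two files: `<prefix>_counts.tsv`, the full
#' `(n+2) x (n+2)` count matrix (zero cells written as `0`, never
#' blank), and `<prefix>_members.tsv`, a long-format table with one line
#' per mapped pair or margin gene: row index, column index, row-side and
#' column-side gene IDs (`NA` on the missing side for margin cells) and
#' the per-gene summary TPMs. Re-reading the counts file with
#' [read_quantile_map_counts()] reproduces the count matrix exactly.
#'
#' @param qm A `quantile_mapping` (see [build_quantile_mapping()]).
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_quantile_map <- function(qm, prefix) {
  stopifnot(inherits(qm, "quantile_mapping"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) oq_abort(sprintf("directory does not exist: %s", dir),
                                 "orthoquant_io_error")
  counts_path <- paste0(prefix, "_counts.tsv")
  members_path <- paste0(prefix, "_members.tsv")
  cm <- data.frame(row = rownames(qm$counts), qm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cm, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long <- quantile_map_members(qm)
  utils::write.table(long, members_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, members = members_path))
}

#' Read back a quantile-map count matrix written by write_quantile_map()
#' @param path Path to the `*_counts.tsv` file.
#' @return Integer matrix with the original dimnames.
#' @export
read_quantile_map_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Read an orthology table
#'
#' Expects a tab-separated file with a header and three columns: gene ID
#' in species A, gene ID in species B, and a binary orthology-confidence
#' flag (1 = high, 0 = low), in the style of a BioMart homolog export.
#' Duplicate (gene_a, gene_b) pairs are dropped with the first
#' occurrence retained.
#'
#' @param path Path to the TSV file.
#' @param species_a,species_b Species labels for the two columns.
#' @param confidence_col Name of the confidence column (default: third
#'   column whatever its header).
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path, species_a = "A", species_b = "B",
                           confidence_col = NULL) {
  if (!file.exists(path)) oq_abort(sprintf("file not found: %s", path),
                                   "orthoquant_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L)
    return(orthology_map(character(0), character(0), integer(0),
                         species_a, species_b))
  if (ncol(df) < 3L && is.null(confidence_col))
    oq_parse_error("orthology table needs columns gene_a, gene_b, confidence")
  conf_col <- confidence_col %||% colnames(df)[3L]
  if (!conf_col %in% colnames(df))
    oq_parse_error(sprintf("confidence column '%s' not found", conf_col))
  conf <- suppressWarnings(as.numeric(df[[conf_col]]))
  if (anyNA(conf) || !all(conf %in% c(0, 1)))
    oq_validation_error("orthology confidence must be 0 or 1")
  orthology_map(df[[1L]], df[[2L]], as.integer(conf), species_a, species_b)
}

#' Write an orthology map as TSV
#' @param om An [orthology_map()].
#' @param path Output path.
#' @export
write_orthology <- function(om, path) {
  stopifnot(inherits(om, "orthology_map"))
  utils::write.table(om$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
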