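# End-to-end orchestration: expression calls -> orthology -> quantile
# maps -> region enrichment -> concordant genes -> sample similarity ->
# over-representation, from a single config, with per-stage logging and
# a run manifest (config snapshot, seed, checksums of every output).

#' Pairwise overlap table for named gene sets
#'
#' For every pair of sets reports the intersection size and the overlap
#' percentage relative to the SMALLER set, rounded half away from zero
#' to an integer percent (the convention behind "~N%" overlap figures).
#'
#' @param sets Named list of character vectors (>= 2 non-empty sets).
#' @return Data frame: `set1`, `set2`, `size1`, `size2`, `n_common`,
#'   `overlap_percent`.
#' @export
summarize_overlaps <- function(sets) {
  if (length(sets) < 2L) oq_validation_error("need at least two sets")
  if (is.null(names(sets))) oq_validation_error("'sets' must be named")
  if (any(lengths(sets) == 0L))
    oq_validation_error(sprintf("set '%s' is empty",
                                names(sets)[lengths(sets) == 0L][1L]))
  combos <- utils::combn(names(sets), 2L)
  do.call(rbind, apply(combos, 2L, function(nm) {
    a <- unique(sets[[nm[1L]]]); b <- unique(sets[[nm[2L]]])
    common <- length(intersect(a, b))
    data.frame(set1 = nm[1L], set2 = nm[2L],
               size1 = length(a), size2 = length(b), n_common = common,
               overlap_percent = round_half_up(
                 100 * common / min(length(a), length(b))),
               stringsAsFactors = FALSE)
  }))
}

pipeline_defaults <- function() {
  list(tpm_threshold = 1.0, z_threshold = 1.5, n_quantiles = 10L, k = 3L,
       n_permutations = 999L, seed = 1L, enrichment_threshold = 0.05)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      oq_abort(sprintf("config file not found: %s", config),
               "orthoquant_io_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) oq_validation_error("config must be a list or a YAML path")
  params <- utils::modifyList(pipeline_defaults(), config$parameters %||% list())
  config$parameters <- params
  if (is.null(config$output_dir))
    oq_validation_error("config must set 'output_dir'")
  if (is.null(config$simulate)) {
    if (is.null(config$datasets) || !length(config$datasets))
      oq_validation_error("config must list 'datasets' or set 'simulate'")
    for (d in config$datasets) {
      for (fld in c("path", "id", "species"))
        if (is.null(d[[fld]]))
          oq_validation_error(sprintf("every dataset needs '%s'", fld))
      if (!file.exists(d$path))
        oq_abort(sprintf("dataset file not found: %s", d$path),
                 "orthoquant_io_error")
    }
    if (is.null(config$orthology))
      oq_validation_error("config must set 'orthology' (path to the pair table)")
    if (!file.exists(config$orthology))
      oq_abort(sprintf("orthology file not found: %s", config$orthology),
               "orthoquant_io_error")
  }
  for (fld in c("gene_sets", "reference_list")) {
    if (!is.null(config[[fld]]) && !file.exists(config[[fld]]))
      oq_abort(sprintf("%s file not found: %s", fld, config[[fld]]),
               "orthoquant_io_error")
  }
  config
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[orthoquant:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full cross-species concordance pipeline
#'
#' Executes, in dependency order: expression calls per dataset,
#' orthology loading, quantile assignment, cross-species quantile maps
#' of each species-A dataset against the species-B dataset plus the
#' same-species map between the two species-A datasets, top-region
#' Fisher enrichment, concordant-gene extraction and ranking, sample
#' similarity on the concordant genes (UPGMA, PCA, ANOSIM, adonis;
#' overall and pairwise), and, when a GMT file is configured, EASE
#' over-representation of the concordant genes. Every stage writes its
#' table under `output_dir` and the run ends with a `MANIFEST.yaml`
#' holding the config snapshot, package version, seed and MD5 checksum
#' of every output file. A failing stage aborts with the stage name.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   `output_dir`; either `simulate` (arguments for [sim_config()]) or
#'   `datasets` (list of `path`/`id`/`species`) plus `orthology` (TSV
#'   path); optional `gene_sets` (GMT path), `reference_list` (gene
#'   list path), and `parameters` (`tpm_threshold`, `z_threshold`,
#'   `n_quantiles`, `k`, `n_permutations`, `seed`,
#'   `enrichment_threshold`).
#' @param verbose Emit per-stage log messages (default TRUE).
#' @return Invisibly, a list with the in-memory stage results
#'   (`calls`, `orthology`, `maps`, `enrichment`, `concordance`,
#'   `similarity`, `overrepresentation`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  config <- read_pipeline_config(config)
  p <- config$parameters
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      oq_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               "orthoquant_pipeline_error")
    })
  }

  # -- stage: data -----------------------------------------------------
  if (!is.null(config$simulate)) {
    stage_log(verbose, "data", "simulating study (seed %s)",
              config$simulate$seed %||% p$seed)
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% p$seed
    study <- run_stage("data", simulate_study(do.call(sim_config, sim_args)))
    datasets <- study$datasets
    om <- study$orthology
    for (id in names(datasets))
      write_expression_matrix(datasets[[id]],
                              file.path(out_dir, paste0("tpm_", id, ".tsv")))
    write_orthology(om, file.path(out_dir, "orthology.tsv"))
  } else {
    datasets <- run_stage("data", {
      ds <- lapply(config$datasets, function(d)
        read_expression_matrix(d$path, d$id, d$species))
      stats::setNames(ds, vapply(config$datasets, `[[`, character(1), "id"))
    })
    species <- vapply(datasets, `[[`, character(1), "species")
    om <- run_stage("data", read_orthology(
      config$orthology,
      species_a = species[[which(duplicated(species))[1L]]],
      species_b = species[[which(!species %in% species[duplicated(species)])[1L]]]))
  }
  species <- vapply(datasets, `[[`, character(1), "species")
  a_ids <- names(datasets)[species == om$species_a]
  b_ids <- names(datasets)[species == om$species_b]
  if (length(a_ids) != 2L || length(b_ids) != 1L)
    oq_abort("pipeline expects two species-A datasets and one species-B dataset",
             "orthoquant_pipeline_error")
  b_id <- b_ids[[1L]]

  # -- stage: calls ----------------------------------------------------
  calls <- run_stage("calls", lapply(datasets, expression_calls,
                                     tpm_threshold = p$tpm_threshold,
                                     z_threshold = p$z_threshold))
  for (id in names(calls)) {
    cl <- calls[[id]]
    df <- data.frame(gene_id = datasets[[id]]$genes,
                     mean_tpm = rowMeans(datasets[[id]]$tpm),
                     expressed = datasets[[id]]$genes %in% cl$expressed,
                     highly_expressed = datasets[[id]]$genes %in%
                       cl$highly_expressed)
    utils::write.table(df, file.path(out_dir, paste0("calls_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log(verbose, "calls", "%s: %d expressed, %d highly expressed",
              id, length(cl$expressed), length(cl$highly_expressed))
  }

  # -- stage: quantile maps -------------------------------------------
  hc <- filter_high_confidence(om)
  qa <- lapply(calls, assign_quantiles, n_quantiles = p$n_quantiles)
  maps <- run_stage("quantile_map", {
    m <- list()
    for (id in a_ids)
      m[[paste0(id, "_vs_", b_id)]] <-
        build_quantile_mapping(qa[[id]], qa[[b_id]], hc)
    m[[paste0(a_ids[1L], "_vs_", a_ids[2L])]] <-
      build_quantile_mapping(qa[[a_ids[1L]]], qa[[a_ids[2L]]], om = NULL)
    m
  })
  for (nm in names(maps))
    write_quantile_map(maps[[nm]], file.path(out_dir, paste0("qm_", nm)))

  # -- stage: region enrichment ---------------------------------------
  ksel <- seq_len(p$k)
  enr <- run_stage("enrichment", do.call(rbind, lapply(
    names(maps)[seq_along(a_ids)], function(nm) {
      re <- region_enrichment(maps[[nm]], ksel, ksel)
      data.frame(mapping = nm, region = sprintf("1:%d x 1:%d", p$k, p$k),
                 observed = re$observed, expected = re$expected,
                 odds_ratio = re$odds_ratio, p_value = re$p_value,
                 stringsAsFactors = FALSE)
    })))
  utils::write.table(enr, file.path(out_dir, "region_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- stage: concordance ---------------------------------------------
  conc <- run_stage("concordance", {
    sets <- stats::setNames(lapply(a_ids, function(id)
      top_region_genes(maps[[paste0(id, "_vs_", b_id)]], p$k)), a_ids)
    intersect_and_rank(sets, datasets, om = hc,
                       species = om$species_a,
                       tpm_threshold = p$tpm_threshold)
  })
  utils::write.table(conc$ranking, file.path(out_dir, "concordant_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(verbose, "concordance", "%d concordant genes (%g%% overlap)",
            length(conc$intersection), conc$overlap_percent)

  # -- stage: similarity ----------------------------------------------
  similarity <- if (length(conc$intersection) >= 3L) run_stage("similarity", {
    sig <- concordant_signal_matrix(conc$intersection, datasets, hc,
                                    om$species_a, p$tpm_threshold)
    groups <- vapply(strsplit(colnames(sig), "\\."), `[[`, character(1), 1L)
    norm <- row_normalize(sig)
    hcl <- upgma_cluster(norm)
    write_dendrogram_newick(hcl, file.path(out_dir, "dendrogram.nwk"))
    pc_all <- pca_scores(norm, n_components = NULL)
    pc2 <- pca_scores(norm, n_components = min(2L, pc_all$rank))
    utils::write.table(
      data.frame(sample = rownames(pc2$scores), pc2$scores, group = groups),
      file.path(out_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    d <- stats::dist(pc_all$scores)
    tests <- list(
      anosim_all = anosim_test(d, groups, p$n_permutations, p$seed),
      adonis_all = adonis_test(d, groups, p$n_permutations, p$seed))
    for (pr in utils::combn(unique(groups), 2L, simplify = FALSE)) {
      sel <- groups %in% pr
      dsub <- stats::dist(pc_all$scores[sel, , drop = FALSE])
      key <- paste(pr, collapse = "_")
      tests[[paste0("anosim_", key)]] <-
        anosim_test(dsub, groups[sel], p$n_permutations, p$seed)
      tests[[paste0("adonis_", key)]] <-
        adonis_test(dsub, groups[sel], p$n_permutations, p$seed)
    }
    tdf <- do.call(rbind, lapply(names(tests), function(nm)
      data.frame(comparison = nm, statistic = tests[[nm]]$statistic_name,
                 value = tests[[nm]]$statistic, p_value = tests[[nm]]$p_value,
                 mode = tests[[nm]]$mode,
                 n_permutations = tests[[nm]]$n_permutations)))
    utils::write.table(tdf, file.path(out_dir, "similarity_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(matrix = sig, dendrogram = hcl, pca = pc2, tests = tests,
         table = tdf)
  }) else NULL

  # -- stage: over-representation -------------------------------------
  overrep <- NULL
  if (!is.null(config$gene_sets)) {
    overrep <- run_stage("overrepresentation", {
      collection <- read_gmt(config$gene_sets)
      enrich(conc$intersection, collection,
             threshold = p$enrichment_threshold)
    })
    utils::write.table(overrep, file.path(out_dir, "overrepresentation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- stage: reference projection ------------------------------------
  projection <- NULL
  if (!is.null(config$reference_list)) {
    projection <- run_stage("projection", {
      ref <- read_gene_list(config$reference_list)
      lapply(maps[seq_along(a_ids)], project_reference_list, ref = ref)
    })
    for (nm in names(projection))
      write_quantile_map(projection[[nm]],
                         file.path(out_dir, paste0("projection_", nm)))
  }

  # -- summary + manifest ---------------------------------------------
  expressed_sets <- lapply(calls, `[[`, "expressed")
  summary_tbl <- list(
    expressed_counts = lengths(expressed_sets),
    highly_expressed_counts = lengths(lapply(calls, `[[`, "highly_expressed")),
    expressed_overlaps = summarize_overlaps(expressed_sets),
    region_enrichment = enr,
    n_concordant = length(conc$intersection),
    concordant_overlap_percent = conc$overlap_percent)
  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "MANIFEST.yaml"]
  manifest <- list(
    package = "orthoquant",
    version = as.character(utils::packageVersion("orthoquant")),
    started = format(t_start, "%Y-%m-%d %H:%M:%S %Z"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed = p$seed,
    parameters = p,
    config = config[setdiff(names(config), "parameters")],
    checksums = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "MANIFEST.yaml"))
  stage_log(verbose, "done", "outputs in %s", out_dir)
  invisible(list(datasets = datasets, calls = calls, orthology = om,
                 maps = maps, enrichment = enr, concordance = conc,
                 similarity = similarity, overrepresentation = overrep,
                 projection = projection, summary = summary_tbl,
                 manifest = manifest))
}

# Signal matrix (genes x all samples) for a set of species-A genes:
# the gene's own TPMs in species-A datasets, the replicate-wise mean
# TPM of its expressed high-confidence orthologs in species-B datasets.
concordant_signal_matrix <- function(genes, datasets, hc_map, species_a,
                                     tpm_threshold = 1.0) {
  hc <- hc_map$pairs[hc_map$pairs$confidence == 1L, , drop = FALSE]
  cols <- list()
  for (ds in datasets) {
    block <- matrix(NA_real_, length(genes), ncol(ds$tpm),
                    dimnames = list(genes, paste(ds$dataset_id,
                                                 ds$replicates, sep = ".")))
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      if (identical(ds$species, species_a)) {
        if (g %in% ds$genes) block[i, ] <- ds$tpm[g, ]
      } else {
        orth <- unique(hc$gene_b[hc$gene_a == g])
        orth <- orth[orth %in% ds$genes]
        orth <- orth[rowSums(ds$tpm[orth, , drop = FALSE] > tpm_threshold) ==
                       ncol(ds$tpm)]
        if (length(orth)) block[i, ] <- colMeans(ds$tpm[orth, , drop = FALSE])
      }
    }
    cols[[ds$dataset_id]] <- block
  }
  m <- do.call(cbind, cols)
  keep <- rowSums(is.na(m)) == 0L
  log2(m[keep, , drop = FALSE])
}
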