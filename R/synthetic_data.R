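# Synthetic paired-species study generator. Produces TPM matrices for
# two human-like datasets and one zebrafish-like dataset plus a
# many-to-many orthology table, with tunable zero-TPM fractions,
# below-1-TPM fractions, cross-species rank concordance (a Gaussian
# copula on latent log expression) and extra concordance among the
# top-expressed stratum. Ground truth (latent means, planted highly
# expressed genes, zero sets) is recorded so pipeline results can be
# checked against what was planted.

#' Simulation configuration
#'
#' Defaults emulate the shape of a three-dataset oocyte study: two
#' human datasets and one zebrafish dataset of three single-cell
#' replicates each, with roughly 75/65/45% zero-TPM genes and
#' 87/80/61% below-1-TPM genes respectively, about 60% of human genes
#' carrying at least one orthology edge, roughly half of the ortholog
#' pairs flagged high-confidence, and extra many-to-many edges at a
#' rate chosen so pairs outnumber genes by about a third.
#'
#' @param seed Integer seed; a fixed seed makes [simulate_study()]
#'   byte-identical across runs.
#' @param n_genes_a,n_genes_b Genes in species A (human-like) and B
#'   (zebrafish-like).
#' @param n_replicates Replicates per dataset.
#' @param dataset_ids Labels: two species-A datasets then the species-B
#'   dataset.
#' @param zero_fraction,sub1_fraction Named per-dataset fractions of
#'   zero-TPM genes and of genes below 1 TPM (the latter includes the
#'   former, so `sub1_fraction >= zero_fraction`).
#' @param orthology_fraction Fraction of species-A genes with at least
#'   one ortholog; protein-coding genes are weighted 3:1 when drawing
#'   them.
#' @param high_conf_fraction Probability that a pair is flagged
#'   high-confidence.
#' @param many_to_many_rate Expected extra ortholog edges per base
#'   (one-to-one) edge; extras create the many-to-many structure.
#' @param concordance_rho Gaussian-copula correlation between the
#'   latent log expression of orthologous genes, in [0, 1].
#' @param concordance_bias_top Additive boost to the copula correlation
#'   for genes in the top expression stratum (capped at 0.99).
#' @param top_stratum Fraction of species-A genes counted as the top
#'   stratum for the boost.
#' @param within_species_rho Latent correlation between the two
#'   species-A datasets.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise.
#' @param biotype_mix Named proportions of gene biotypes.
#' @param n_planted_high,planted_shift_sd Number of genes per dataset
#'   whose latent mean is shifted up by `planted_shift_sd` standard
#'   deviations of log TPM (over above-1-TPM genes) to plant a known
#'   highly expressed set; 0 plants nothing.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_a = 24000L,
                       n_genes_b = 26000L,
                       n_replicates = 3L,
                       dataset_ids = c("H1", "H2", "ZF"),
                       zero_fraction = c(H1 = 0.75, H2 = 0.65, ZF = 0.45),
                       sub1_fraction = c(H1 = 0.87, H2 = 0.80, ZF = 0.61),
                       orthology_fraction = 0.6,
                       high_conf_fraction = 0.53,
                       many_to_many_rate = 0.3,
                       concordance_rho = 0.7,
                       concordance_bias_top = 0.2,
                       top_stratum = 0.3,
                       within_species_rho = 0.9,
                       replicate_cv = 0.4,
                       biotype_mix = c(protein_coding = 0.5, lincRNA = 0.12,
                                       pseudogene = 0.25, other = 0.13),
                       n_planted_high = 0L,
                       planted_shift_sd = 4) {
  cfg <- list(seed = as.integer(seed), n_genes_a = as.integer(n_genes_a),
              n_genes_b = as.integer(n_genes_b),
              n_replicates = as.integer(n_replicates),
              dataset_ids = as.character(dataset_ids),
              zero_fraction = zero_fraction, sub1_fraction = sub1_fraction,
              orthology_fraction = orthology_fraction,
              high_conf_fraction = high_conf_fraction,
              many_to_many_rate = many_to_many_rate,
              concordance_rho = concordance_rho,
              concordance_bias_top = concordance_bias_top,
              top_stratum = top_stratum,
              within_species_rho = within_species_rho,
              replicate_cv = replicate_cv, biotype_mix = biotype_mix,
              n_planted_high = as.integer(n_planted_high),
              planted_shift_sd = planted_shift_sd)
  if (length(cfg$dataset_ids) != 3L)
    oq_validation_error("expected three dataset IDs (two species-A, one species-B)")
  for (fld in c("zero_fraction", "sub1_fraction")) {
    v <- cfg[[fld]]
    if (length(v) != 3L)
      oq_validation_error(sprintf("'%s' needs one value per dataset", fld))
    if (is.null(names(v))) names(cfg[[fld]]) <- cfg$dataset_ids
  }
  if (any(cfg$zero_fraction < 0 | cfg$zero_fraction >= 1))
    oq_validation_error("'zero_fraction' must lie in [0, 1)")
  if (any(cfg$sub1_fraction < cfg$zero_fraction[names(cfg$sub1_fraction)]))
    oq_validation_error("'sub1_fraction' must be >= 'zero_fraction'")
  for (fld in c("orthology_fraction", "high_conf_fraction",
                "concordance_rho", "top_stratum", "within_species_rho")) {
    if (cfg[[fld]] < 0 || cfg[[fld]] > 1)
      oq_validation_error(sprintf("'%s' must lie in [0, 1]", fld))
  }
  if (cfg$many_to_many_rate < 0 || cfg$concordance_bias_top < 0 ||
      cfg$replicate_cv < 0)
    oq_validation_error("rates, bias and CV must be non-negative")
  if (abs(sum(cfg$biotype_mix) - 1) > 1e-8)
    oq_validation_error("'biotype_mix' proportions must sum to 1")
  structure(cfg, class = "sim_config")
}

# Given descending-propensity ranks of nonzero genes, pick the
# log-normal shape so that after renormalizing each sample to 1e6 the
# below-1-TPM fraction over ALL genes matches the target.
calibrate_lognormal <- function(n_total, n_zero, sub1_target) {
  n_nz <- n_total - n_zero
  t_nz <- (sub1_target * n_total - n_zero) / n_nz
  p <- seq_len(n_nz) / (n_nz + 1)
  f <- function(sdlog) {
    v <- exp(sdlog * stats::qnorm(p))
    mean(1e6 * v / sum(v) < 1) - t_nz
  }
  lo <- 0.2; hi <- 10
  if (f(lo) > 0 || f(hi) < 0)
    oq_validation_error(sprintf(
      "infeasible zero/sub-1 fraction combination (target %.3f among nonzero genes)",
      t_nz))
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

# Turn a latent propensity vector into per-gene mean TPM summing to 1e6.
latent_to_mean_tpm <- function(z, zero_fraction, sub1_target) {
  n <- length(z)
  n_zero <- round(zero_fraction * n)
  ord <- order(z)                     # ascending propensity
  mu <- numeric(n)
  nz_idx <- ord[seq.int(n_zero + 1L, n)]
  sdlog <- calibrate_lognormal(n, n_zero, sub1_target)
  p <- seq_len(length(nz_idx)) / (length(nz_idx) + 1)
  v <- exp(sdlog * stats::qnorm(p))
  mu[nz_idx] <- 1e6 * v / sum(v)
  mu
}

#' Simulate a paired-species expression study
#'
#' Draws latent gene propensities (standard normal), couples the two
#' species-A datasets at `within_species_rho` and each orthologous
#' species-B gene to its primary species-A partner at
#' `concordance_rho` (boosted by `concordance_bias_top` in the top
#' stratum), maps propensity ranks onto a log-normal TPM body
#' calibrated to the requested zero and below-1 fractions, plants
#' highly expressed genes if requested, and adds multiplicative
#' log-normal replicate noise before renormalizing every replicate to
#' one million.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `simulated_study`: `datasets` (named list of
#'   [expression_dataset()]), `orthology` (an [orthology_map()] with
#'   species labels `"speciesA"`/`"speciesB"`), and `truth` (latent
#'   mean TPMs, zero sets, planted highly expressed genes, the config).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids_a <- sprintf("GA%05d", seq_len(cfg$n_genes_a))
  ids_b <- sprintf("GB%05d", seq_len(cfg$n_genes_b))
  biotypes_a <- stats::setNames(
    sample(names(cfg$biotype_mix), cfg$n_genes_a, replace = TRUE,
           prob = cfg$biotype_mix), ids_a)
  biotypes_b <- stats::setNames(
    sample(names(cfg$biotype_mix), cfg$n_genes_b, replace = TRUE,
           prob = cfg$biotype_mix), ids_b)

  # latent propensity core for species A, shared by the two A datasets
  u_a <- stats::rnorm(cfg$n_genes_a)
  wr <- cfg$within_species_rho
  z_a1 <- wr * u_a + sqrt(1 - wr^2) * stats::rnorm(cfg$n_genes_a)
  z_a2 <- wr * u_a + sqrt(1 - wr^2) * stats::rnorm(cfg$n_genes_a)

  # orthology: base one-to-one edges plus many-to-many extras
  n_orth <- round(cfg$orthology_fraction * cfg$n_genes_a)
  if (n_orth > cfg$n_genes_b)
    oq_validation_error("n_genes_b too small for the requested orthology_fraction")
  w <- ifelse(biotypes_a == "protein_coding", 3, 1)
  orth_a <- sample(ids_a, n_orth, prob = w)
  orth_b <- sample(ids_b, n_orth)
  primary_partner <- stats::setNames(orth_a, orth_b)
  n_extra <- round(cfg$many_to_many_rate * n_orth)
  extra_a <- sample(orth_a, n_extra, replace = TRUE)
  extra_b <- sample(orth_b, n_extra, replace = TRUE)
  ga <- c(orth_a, extra_a); gb <- c(orth_b, extra_b)
  keep <- !duplicated(paste(ga, gb, sep = "\r"))
  ga <- ga[keep]; gb <- gb[keep]
  conf <- stats::rbinom(length(ga), 1L, cfg$high_conf_fraction)
  orthology <- orthology_map(ga, gb, conf, "speciesA", "speciesB")

  # species-B latent: coupled to the primary partner's core propensity
  top_cut <- stats::quantile(u_a, 1 - cfg$top_stratum)
  z_b <- stats::rnorm(cfg$n_genes_b)
  pb <- match(ids_b, names(primary_partner))
  coupled <- !is.na(pb)
  partner_u <- u_a[match(primary_partner[pb[coupled]], ids_a)]
  rho_g <- pmin(1, cfg$concordance_rho +
                  cfg$concordance_bias_top * (partner_u >= top_cut))
  z_b[coupled] <- rho_g * partner_u +
    sqrt(1 - rho_g^2) * stats::rnorm(sum(coupled))

  latents <- list(z_a1, z_a2, z_b)
  universes <- list(ids_a, ids_a, ids_b)
  biotypes <- list(biotypes_a, biotypes_a, biotypes_b)
  sigma <- sqrt(log(1 + cfg$replicate_cv^2))
  datasets <- list(); truth_mu <- list(); planted <- list()
  planted_pool <- NULL
  for (i in seq_along(cfg$dataset_ids)) {
    id <- cfg$dataset_ids[[i]]
    mu <- latent_to_mean_tpm(latents[[i]], cfg$zero_fraction[[id]],
                             cfg$sub1_fraction[[id]])
    names(mu) <- universes[[i]]
    if (cfg$n_planted_high > 0L) {
      # same planted set for the two species-A datasets; genes are
      # placed at mean + shift * SD of the above-threshold log body (a
      # compact cluster, not a relative shift, so the planted effect
      # stays at the stated number of SDs after renormalization)
      pool <- names(mu)[mu > 1]
      sel <- if (i == 2L && !is.null(planted_pool))
        planted_pool[mu[planted_pool] > 0] else sample(pool, cfg$n_planted_high)
      if (i == 1L) planted_pool <- sel
      l <- log2(mu[pool])
      target <- mean(l) + cfg$planted_shift_sd * stats::sd(l)
      mu[sel] <- 2^(target + stats::runif(length(sel), 0, 0.25))
      mu <- 1e6 * mu / sum(mu)
      planted[[id]] <- sel
    }
    noise <- matrix(stats::rnorm(length(mu) * cfg$n_replicates,
                                 -sigma^2 / 2, sigma),
                    nrow = length(mu))
    tpm <- mu * exp(noise)
    tpm[mu == 0, ] <- 0
    tpm <- sweep(tpm, 2L, colSums(tpm), function(x, s) 1e6 * x / s)
    rownames(tpm) <- universes[[i]]
    colnames(tpm) <- paste0(id, letters[seq_len(cfg$n_replicates)])
    species <- if (i <= 2L) "speciesA" else "speciesB"
    datasets[[id]] <- expression_dataset(tpm, id, species, biotypes[[i]])
    truth_mu[[id]] <- mu
  }
  structure(list(datasets = datasets,
                 orthology = orthology,
                 truth = list(latent_mean_tpm = truth_mu,
                              planted_high = planted,
                              config = cfg)),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d dataset(s): %s; %d ortholog pair(s)\n",
              length(x$datasets), paste(names(x$datasets), collapse = ", "),
              nrow(x$orthology$pairs)))
  invisible(x)
}

#' Parameter-recovery report for a simulated study
#'
#' Runs the expression-call and quantile-mapping stages on a simulated
#' study and compares what the pipeline detects with what the generator
#' planted: observed zero/below-1 TPM fractions vs the configured ones,
#' Jaccard overlap of planted vs detected highly expressed genes, and
#' the odds ratio of the top-left quantile cell (a readout of the
#' concordance parameter).
#'
#' @param study A [simulate_study()] result.
#' @param k Region size for the top-corner enrichment (default 1: the
#'   single (1,1) cell).
#' @param n_quantiles Quantiles per dataset (default 10).
#' @return List with `per_dataset` (data frame of fractions and
#'   Jaccard) and `top_corner` (data frame per species-A dataset:
#'   observed, expected, odds ratio, p-value).
#' @export
recover_parameters <- function(study, k = 1L, n_quantiles = 10L) {
  stopifnot(inherits(study, "simulated_study"))
  cfg <- study$truth$config
  calls <- lapply(study$datasets, expression_calls)
  per_ds <- do.call(rbind, lapply(names(study$datasets), function(id) {
    ds <- study$datasets[[id]]
    planted <- study$truth$planted_high[[id]]
    detected <- calls[[id]]$highly_expressed
    jac <- if (length(planted))
      length(intersect(planted, detected)) /
        length(union(planted, detected)) else NA_real_
    data.frame(dataset = id,
               zero_fraction_observed = mean(ds$tpm == 0),
               zero_fraction_target = unname(cfg$zero_fraction[[id]]),
               sub1_fraction_observed = mean(ds$tpm < 1),
               sub1_fraction_target = unname(cfg$sub1_fraction[[id]]),
               n_expressed = length(calls[[id]]$expressed),
               jaccard_planted_high = jac,
               stringsAsFactors = FALSE)
  }))
  b_id <- cfg$dataset_ids[[3L]]
  qa_b <- assign_quantiles(calls[[b_id]], n_quantiles)
  top_corner <- do.call(rbind, lapply(cfg$dataset_ids[1:2], function(id) {
    qa_a <- assign_quantiles(calls[[id]], n_quantiles)
    qm <- build_quantile_mapping(qa_a, qa_b, study$orthology)
    re <- region_enrichment(qm, seq_len(k), seq_len(k),
                            alternative = "greater")
    data.frame(dataset = id, observed = re$observed, expected = re$expected,
               odds_ratio = re$odds_ratio, p_value = re$p_value,
               stringsAsFactors = FALSE)
  }))
  list(per_dataset = per_ds, top_corner = top_corner)
}
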