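#' Simulation configuration for synthetic osteosarcoma cohorts
#'
#' Parameters of the synthetic data generator. Defaults describe a cohort
#' of 150 patients carrying a 5-miRNA prognostic profile with per-feature
#' log-hazard 0.5 on recurrence-free survival, an exponential
#' proportional-hazards event model (baseline 0.008 events/month) with
#' independent uniform censoring over a 240-month follow-up window,
#' metastasis prevalence 0.23, a pathologic-necrosis class linked to the
#' latent risk, mRNA targets negatively correlated with their regulator
#' miRNAs, CpG methylation M-values correlated with miRNA expression at
#' 0.35, and a 30-drug pharmacogenomic table with 3 planted active drugs
#' assayed across 15 cell lines.
#'
#' @param n_samples number of patients.
#' @param n_profile_features number of prognostic (profile) miRNAs.
#' @param n_noise_features number of non-prognostic miRNAs (and noise
#'   methylation probes).
#' @param log_hazard_effects numeric vector of per-profile-feature log
#'   hazard ratios per SD of expression; recycled to
#'   `n_profile_features`.
#' @param baseline_hazard baseline event rate, events per month (> 0).
#' @param censor_window months; censoring times are uniform on
#'   `[0, censor_window]` (> 0).
#' @param metastasis_prob probability of metastasis at diagnosis.
#' @param necrosis_link log-odds of suboptimal pathologic necrosis per SD
#'   of latent risk.
#' @param target_regulation expected negative correlation between a
#'   profile miRNA and each of its mRNA targets (magnitude, in `[0, 1]`).
#' @param methyl_rho expected (Pearson) correlation between a planted
#'   CpG's M-values and its regulator miRNA, `|methyl_rho| <= 1`.
#' @param n_drugs,n_active_drugs,n_cell_lines pharmacogenomic table sizes;
#'   `n_active_drugs` drugs are planted to pass every filter stage.
#' @param seed integer master seed; all tables derive deterministic
#'   sub-seeds from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 150,
                       n_profile_features = 5,
                       n_noise_features = 45,
                       log_hazard_effects = 0.5,
                       baseline_hazard = 0.008,
                       censor_window = 240,
                       metastasis_prob = 0.23,
                       necrosis_link = 1.0,
                       target_regulation = 0.5,
                       methyl_rho = 0.35,
                       n_drugs = 30,
                       n_active_drugs = 3,
                       n_cell_lines = 15,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_profile_features = as.integer(n_profile_features),
              n_noise_features = as.integer(n_noise_features),
              log_hazard_effects = rep_len(as.numeric(log_hazard_effects),
                                           as.integer(n_profile_features)),
              baseline_hazard = baseline_hazard,
              censor_window = censor_window,
              metastasis_prob = metastasis_prob,
              necrosis_link = necrosis_link,
              target_regulation = target_regulation,
              methyl_rho = methyl_rho,
              n_drugs = as.integer(n_drugs),
              n_active_drugs = as.integer(n_active_drugs),
              n_cell_lines = as.integer(n_cell_lines),
              seed = as.integer(seed))
  for (f in c("n_samples", "n_profile_features", "n_noise_features",
              "n_drugs", "n_cell_lines"))
    if (cfg[[f]] <= 0L) stop("`", f, "` must be a positive count")
  if (cfg$n_active_drugs < 0L || cfg$n_active_drugs > cfg$n_drugs)
    stop("`n_active_drugs` must lie in [0, n_drugs]")
  if (!is.numeric(cfg$baseline_hazard) || cfg$baseline_hazard <= 0)
    stop("`baseline_hazard` must be > 0 (events per month)")
  if (!is.numeric(cfg$censor_window) || cfg$censor_window <= 0)
    stop("`censor_window` must be > 0 (months)")
  if (cfg$metastasis_prob < 0 || cfg$metastasis_prob > 1)
    stop("`metastasis_prob` must lie in [0, 1]")
  if (abs(cfg$methyl_rho) > 1) stop("`methyl_rho` must satisfy |rho| <= 1")
  if (cfg$target_regulation < 0 || cfg$target_regulation > 1)
    stop("`target_regulation` must lie in [0, 1]")
  if (is.na(cfg$seed)) stop("`seed` must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param path YAML file whose keys mirror the `sim_config()` arguments.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

# number of expansive / restrictive targets planted per profile miRNA,
# and extra unregulated genes padding the mRNA universe
TARGETS_EXPANSIVE <- 8L
TARGETS_RESTRICTIVE <- 3L
CPGS_PER_MIRNA <- 8L

sub_seeds <- function(seed, n = 10L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a full synthetic cohort
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume: profile miRNA log-expression with proportional-hazards effects
#' on survival (per-sample hazard `baseline_hazard * exp(sum_g beta_g *
#' z_gs)` on standardized expression), independent uniform censoring,
#' a metastasis covariate, a necrosis class whose log-odds of suboptimal
#' response follow the latent risk, mRNA targets negatively correlated
#' with their regulator miRNA, CpG beta values whose M-values correlate
#' with the regulator miRNA at `methyl_rho`, and drug-association / IC50
#' tables in which the planted active drugs carry strong associations
#' (|coefficient| in [0.30, 0.60], p < 5e-4) with >= 3 profile-target
#' genes and median IC50 below the reference drug (cisplatin).
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `clinical`
#'   (data.frame: sample_id, time_months, event, metastasis, necrosis,
#'   endpoint), `mirna`, `mrna` (`log2norm` space), `methylation` (`beta`
#'   space), `cpg_annotation`, `target_map` (mirna_id, gene_id, tier),
#'   `drug_assoc`, `ic50`, and `truth` (latent risk, per-feature true
#'   sign, planted drug list, gene networks).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  seeds <- sub_seeds(config$seed, 8L)
  n <- config$n_samples
  p <- config$n_profile_features
  samples <- sprintf("sample_%03d", seq_len(n))
  profile_ids <- sprintf("mir_profile_%02d", seq_len(p))
  noise_ids <- sprintf("mir_noise_%02d", seq_len(config$n_noise_features))

  ## miRNA expression (log2-normalized space)
  set.seed(seeds[1L])
  mirna <- matrix(stats::rnorm(n * (p + config$n_noise_features), mean = 8, sd = 1),
                  nrow = p + config$n_noise_features,
                  dimnames = list(c(profile_ids, noise_ids), samples))
  z <- t(scale(t(mirna[profile_ids, , drop = FALSE])))

  ## survival: exponential PH with uniform censoring
  set.seed(seeds[2L])
  risk <- as.numeric(crossprod(z, config$log_hazard_effects))
  t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(risk))
  t_cens <- stats::runif(n, 0, config$censor_window)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  ## clinical covariates
  set.seed(seeds[3L])
  metastasis <- stats::rbinom(n, 1L, config$metastasis_prob)
  risk_z <- as.numeric(scale(risk))
  if (any(!is.finite(risk_z))) risk_z <- rep(0, n)  # all effects zero
  p_subopt <- stats::plogis(config$necrosis_link * risk_z)
  necrosis <- ifelse(stats::runif(n) < p_subopt, "suboptimal", "optimal")
  clinical <- data.frame(sample_id = samples, time_months = time, event = event,
                         metastasis = metastasis, necrosis = necrosis,
                         endpoint = "RFS", stringsAsFactors = FALSE)

  ## mRNA targets: negative coupling to the regulator miRNA
  set.seed(seeds[4L])
  tr <- config$target_regulation
  target_rows <- list()
  gene_mat <- list()
  for (j in seq_len(p)) {
    genes <- sprintf("gene_%s_t%02d", sub("mir_", "", profile_ids[j]), seq_len(TARGETS_EXPANSIVE))
    vals <- t(vapply(seq_along(genes), function(i)
      -tr * z[j, ] + sqrt(1 - tr^2) * stats::rnorm(n), numeric(n)))
    rownames(vals) <- genes
    gene_mat[[j]] <- vals
    target_rows[[j]] <- data.frame(
      mirna_id = profile_ids[j], gene_id = genes,
      tier = ifelse(seq_along(genes) <= TARGETS_RESTRICTIVE, "restrictive", "expansive"),
      stringsAsFactors = FALSE)
  }
  n_pad <- 2L * config$n_noise_features + 20L
  pad_ids <- sprintf("gene_noise_%03d", seq_len(n_pad))
  pad <- matrix(stats::rnorm(n_pad * n), nrow = n_pad, dimnames = list(pad_ids, samples))
  mrna <- rbind(do.call(rbind, gene_mat), pad)
  colnames(mrna) <- samples
  target_map <- do.call(rbind, target_rows)

  ## methylation: M-values correlated with the regulator miRNA
  set.seed(seeds[5L])
  rho <- config$methyl_rho
  cpg_rows <- list()
  meth_m <- list()
  for (j in seq_len(p)) {
    probes <- sprintf("cg_%s_%02d", sub("mir_", "", profile_ids[j]), seq_len(CPGS_PER_MIRNA))
    vals <- t(vapply(seq_along(probes), function(i)
      rho * z[j, ] + sqrt(1 - rho^2) * stats::rnorm(n), numeric(n)))
    rownames(vals) <- probes
    meth_m[[j]] <- vals
    cpg_rows[[j]] <- data.frame(probe_id = probes, feature_id = profile_ids[j],
                                locus = "14q32", stringsAsFactors = FALSE)
  }
  noise_probes <- sprintf("cg_noise_%03d", seq_len(config$n_noise_features))
  meth_noise <- matrix(stats::rnorm(config$n_noise_features * n),
                       nrow = config$n_noise_features,
                       dimnames = list(noise_probes, samples))
  m_values <- rbind(do.call(rbind, meth_m), meth_noise)
  colnames(m_values) <- samples
  # shift/scale M then invert the logit2 to obtain beta in (0, 1)
  m_scaled <- 1.5 * m_values - 1
  beta <- 2^m_scaled / (1 + 2^m_scaled)
  cpg_annotation <- rbind(do.call(rbind, cpg_rows),
                          data.frame(probe_id = noise_probes, feature_id = NA_character_,
                                     locus = "other", stringsAsFactors = FALSE))

  ## drug-gene associations and IC50 sensitivities
  set.seed(seeds[6L])
  network_22 <- target_map$gene_id
  network_5 <- target_map$gene_id[target_map$tier == "restrictive"]
  drug_ids <- sprintf("drug_%02d", seq_len(config$n_drugs))
  active <- drug_ids[seq_len(config$n_active_drugs)]
  assoc <- list()
  for (d in drug_ids) {
    if (d %in% active) {
      g5 <- sample(network_5, 2L)
      g22 <- sample(setdiff(network_22, network_5), 2L)
      genes <- c(g5, g22)
      coef <- stats::runif(length(genes), 0.30, 0.60) * sample(c(-1, 1), length(genes), TRUE)
      pv <- stats::runif(length(genes), 1e-6, 5e-4)
    } else {
      genes <- sample(network_22, sample(1:4, 1L))
      # strong-but-insignificant and significant-but-weak rows exercise
      # the conjunction in the stage-1 filter
      coef <- stats::runif(length(genes), 0.05, 0.20)
      pv <- stats::runif(length(genes), 0.01, 0.99)
      if (stats::runif(1) < 0.3) {
        coef[1L] <- stats::runif(1, 0.3, 0.5); pv[1L] <- stats::runif(1, 0.05, 0.5)
      }
    }
    assoc[[d]] <- data.frame(drug_id = d, gene_id = genes, coefficient = coef,
                             p = pv, stringsAsFactors = FALSE)
  }
  drug_assoc <- do.call(rbind, assoc)
  rownames(drug_assoc) <- NULL

  set.seed(seeds[7L])
  lines <- sprintf("oscell_%02d", seq_len(config$n_cell_lines))
  ref_median <- 8.4
  ic50 <- lapply(c(drug_ids, "cisplatin"), function(d) {
    target <- if (d == "cisplatin") ref_median
              else if (d %in% active) stats::runif(1, 0.05, 0.25) * ref_median
              else stats::runif(1, 0.5, 5) * ref_median
    vals <- stats::rlnorm(length(lines), sdlog = 0.4)
    vals <- vals * target / stats::median(vals)  # pin the median by construction
    data.frame(drug_id = d, cell_line_id = lines, ic50_um = vals, stringsAsFactors = FALSE)
  })
  ic50 <- do.call(rbind, ic50)
  rownames(ic50) <- NULL

  structure(list(
    clinical = clinical,
    mirna = expression_matrix(mirna, "log2norm"),
    mrna = expression_matrix(mrna, "log2norm"),
    methylation = expression_matrix(beta, "beta"),
    cpg_annotation = cpg_annotation,
    target_map = target_map,
    drug_assoc = drug_assoc,
    ic50 = ic50,
    truth = list(latent_risk = stats::setNames(risk, samples),
                 true_sign = stats::setNames(sign(config$log_hazard_effects), profile_ids),
                 profile_features = profile_ids,
                 planted_drugs = active,
                 reference_drug = "cisplatin",
                 network_22 = network_22,
                 network_5 = network_5),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d samples | %d miRNAs | %d genes | ",
                     "%d CpGs | %d drugs (%d planted active)\n"),
              nrow(x$clinical), nrow(x$mirna), nrow(x$mrna), nrow(x$methylation),
              x$config$n_drugs, x$config$n_active_drugs))
  invisible(x)
}

#' Write every cohort table to a directory as TSV
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(cohort$clinical, "clinical.tsv")
  write_matrix(cohort$mirna, file.path(dir, "mirna_log2.tsv"))
  write_matrix(cohort$mrna, file.path(dir, "mrna_log2.tsv"))
  write_matrix(cohort$methylation, file.path(dir, "methylation_beta.tsv"))
  tsv(cohort$cpg_annotation, "cpg_annotation.tsv")
  tsv(cohort$target_map, "target_map.tsv")
  tsv(cohort$drug_assoc, "drug_associations.tsv")
  tsv(cohort$ic50, "drug_ic50.tsv")
  invisible(dir)
}
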