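# Small, fast cohort configurations for replicate-heavy tests.
lean_config <- function(seed, n_samples = 60, log_hazard_effects = 0.5, ...) {
  sim_config(n_samples = n_samples, n_profile_features = 5,
             n_noise_features = 4, log_hazard_effects = log_hazard_effects,
             n_drugs = 5, n_active_drugs = 1, n_cell_lines = 4, seed = seed, ...)
}

# All-positive-sign profile over the planted features.
truth_profile <- function(cohort) {
  sg <- cohort$truth$true_sign
  sg[sg == 0] <- 1
  risk_profile(cohort$truth$profile_features, sg, "simulation truth")
}

# Simple toy expression matrix.
toy_matrix <- function(values, space = "log2norm",
                       features = sprintf("f%d", seq_len(nrow(values))),
                       samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  expression_matrix(values, space)
}
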