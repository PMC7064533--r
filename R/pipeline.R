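#' Configuration-driven pipeline run
#'
#' Orchestrates the analysis stages in dependency order over a synthetic
#' or user-supplied cohort: `simulate` -> `score` (signed average) ->
#' `cluster` (+ R-index) -> `survival` (KM / log-rank / Cox) ->
#' `composite` -> `gsa` (LS/KS target-set tests) -> `methyl` ->
#' `pharmaco`. Each stage writes its outputs as TSV/JSON under the run
#' directory; a run log records the seed, a hash of the configuration,
#' and any dropped features or samples. Deterministic stages are
#' bit-identical across reruns with the same configuration.
#'
#' @param config a named list, or path to a YAML file, with elements:
#'   `seed` (integer), `stages` (character vector; default all),
#'   `simulate` (list of [sim_config()] fields) *or* `inputs` (named
#'   paths: `clinical`, `mirna`, `mrna`, `methylation`,
#'   `cpg_annotation`, `target_map`, `drug_assoc`, `ic50`), optional
#'   `profile` (list with `feature_ids`, `signs`), and optional stage
#'   parameter lists `gsa` (`n_perm`), `r_index`
#'   (`n_perturbations`, `noise_sd_factor`), `pharmaco`
#'   ([drug_filter_config()] fields).
#' @param out_dir run directory (created; must not require overwriting
#'   another stage's outputs).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else config_path <- NULL
  stages_all <- c("simulate", "score", "cluster", "survival", "composite",
                  "gsa", "methyl", "pharmaco")
  stages <- config$stages %||% stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- stages_all[stages_all %in% stages]  # dependency order
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  ## --- load or simulate the cohort -----------------------------------
  if ("simulate" %in% stages || !is.null(config$simulate)) {
    sim_args <- config$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    write_cohort(cohort, file.path(out_dir, "cohort"))
    note("simulate: cohort of ", nrow(cohort$clinical), " samples, seed ", sim_args$seed)
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config needs either a `simulate` block or `inputs` paths")
    missing_paths <- unlist(inp)[!file.exists(unlist(inp))]
    if (length(missing_paths))
      stop("input path(s) do not exist: ", paste(missing_paths, collapse = ", "))
    cohort <- list(
      clinical = utils::read.delim(inp$clinical, stringsAsFactors = FALSE),
      mirna = if (!is.null(inp$mirna)) read_matrix(inp$mirna, "log2norm"),
      mrna = if (!is.null(inp$mrna)) read_matrix(inp$mrna, "log2norm"),
      methylation = if (!is.null(inp$methylation)) read_matrix(inp$methylation, "beta"),
      cpg_annotation = if (!is.null(inp$cpg_annotation))
        utils::read.delim(inp$cpg_annotation, stringsAsFactors = FALSE),
      target_map = if (!is.null(inp$target_map))
        utils::read.delim(inp$target_map, stringsAsFactors = FALSE),
      drug_assoc = if (!is.null(inp$drug_assoc))
        utils::read.delim(inp$drug_assoc, stringsAsFactors = FALSE),
      ic50 = if (!is.null(inp$ic50)) utils::read.delim(inp$ic50, stringsAsFactors = FALSE),
      truth = NULL)
  }

  ## --- upfront validation of stage prerequisites ---------------------
  need <- function(stage, what, ok)
    if (stage %in% stages && !ok)
      stop("stage '", stage, "' requested but ", what, " is missing")
  need("composite", "a `necrosis` column in the clinical table",
       "necrosis" %in% names(cohort$clinical))
  need("score", "the miRNA matrix", !is.null(cohort$mirna))
  need("gsa", "the mRNA matrix and target map",
       !is.null(cohort$mrna) && !is.null(cohort$target_map))
  need("methyl", "the methylation matrix and CpG annotation",
       !is.null(cohort$methylation) && !is.null(cohort$cpg_annotation))
  need("pharmaco", "the drug association and IC50 tables",
       !is.null(cohort$drug_assoc) && !is.null(cohort$ic50))

  profile <- if (!is.null(config$profile)) {
    risk_profile(config$profile$feature_ids, config$profile$signs, "config")
  } else if (!is.null(cohort$truth)) {
    sg <- cohort$truth$true_sign
    sg[sg == 0] <- 1
    risk_profile(cohort$truth$profile_features, sg, "simulation truth")
  } else NULL

  surv <- survival_from_clinical(cohort$clinical)
  results <- list(cohort = cohort, seed = seed)

  for (stage in stages) {
    if (stage == "simulate") next
    if (stage == "score") {
      if (is.null(profile)) stop("stage 'score' needs a risk profile")
      sc <- signed_average_score(cohort$mirna, profile)
      if (length(sc$dropped))
        note("score: dropped missing profile feature(s): ",
             paste(sc$dropped, collapse = ", "))
      tsv(data.frame(sample_id = names(sc$score), score = sc$score,
                     group = sc$group), "risk_scores.tsv")
      results$score <- sc
      note("score: median cutpoint ", format(sc$cutpoint, digits = 10))
    }
    if (stage == "cluster") {
      feats <- if (!is.null(profile)) intersect(profile$feature_ids, rownames(cohort$mirna))
               else rownames(cohort$mirna)
      rp <- config$r_index %||% list()
      ri <- r_index(cohort$mirna, feats, k = 2,
                    n_perturbations = rp$n_perturbations %||% 50,
                    noise_sd_factor = rp$noise_sd_factor %||% 0.5,
                    seed = seed)
      tsv(data.frame(sample_id = names(ri$original$cluster),
                     cluster = ri$original$cluster), "clusters.tsv")
      results$cluster <- ri
      note("cluster: R-index ", format(ri$r, digits = 10), " over ",
           ri$n_perturbations, " perturbations")
    }
    if (stage == "survival") {
      out <- list()
      if (!is.null(results$score)) {
        d <- survival_data(surv$time, surv$event, group = results$score$group)
        out$signed_average <- list(logrank = logrank(d),
                                   km = lapply(split(seq_len(nrow(d)), d$group),
                                               function(i) km_curve(d[i, ])))
      }
      if (!is.null(results$cluster)) {
        d <- survival_data(surv$time, surv$event,
                           group = paste0("cluster", results$cluster$original$cluster))
        out$cluster <- list(logrank = logrank(d))
      }
      if (is.null(results$score) && is.null(results$cluster))
        stop("stage 'survival' needs outputs of 'score' or 'cluster'; ",
             "missing upstream stage")
      jsonlite::write_json(
        lapply(out, function(o) list(logrank = o$logrank)),
        file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = 10)
      results$survival <- out
    }
    if (stage == "composite") {
      if (is.null(results$score)) stop("stage 'composite' needs stage 'score'")
      comp <- composite_classify(results$score$group, cohort$clinical$necrosis)
      if (length(comp$excluded))
        note("composite: excluded ", length(comp$excluded),
             " sample(s) with missing inputs")
      tsv(data.frame(sample_id = cohort$clinical$sample_id,
                     composite = as.character(comp$label)), "composite_groups.tsv")
      keep <- !is.na(comp$label)
      d <- survival_data(surv$time[keep], surv$event[keep],
                         group = as.character(comp$label[keep]))
      results$composite <- list(label = comp$label, logrank = logrank(d))
      note("composite: log-rank p ", format(results$composite$logrank$p, digits = 6))
    }
    if (stage == "gsa") {
      tm <- if (inherits(cohort$target_map, "gene_target_map")) cohort$target_map
            else read_target_map(cohort$target_map)
      gp <- config$gsa %||% list()
      gsa <- gene_set_survival(cohort$mrna, surv, tm, tier = "expansive",
                               n_perm = gp$n_perm %||% 1000, seed = seed)
      tsv(gsa, "gene_set_survival.tsv")
      results$gsa <- gsa
    }
    if (stage == "methyl") {
      probes <- cohort$cpg_annotation$probe_id[!is.na(cohort$cpg_annotation$feature_id)]
      rp <- config$r_index %||% list()
      mcs <- methylation_cluster_survival(
        cohort$methylation, probes, cohort$clinical, k = 2,
        n_perturbations = rp$n_perturbations %||% 50,
        noise_sd_factor = rp$noise_sd_factor %||% 0.5, seed = seed)
      corr <- mirna_cpg_correlation(cohort$mirna, cohort$methylation,
                                    cohort$cpg_annotation)
      tsv(corr$summary, "mirna_cpg_correlation.tsv")
      results$methyl <- list(cluster_survival = mcs, correlation = corr)
      note("methyl: clustering R-index ", format(mcs$r_index$r, digits = 10))
    }
    if (stage == "pharmaco") {
      pc <- do.call(drug_filter_config, config$pharmaco %||% list())
      n22 <- cohort$truth$network_22 %||% unique(cohort$drug_assoc$gene_id)
      n5 <- cohort$truth$network_5 %||% n22
      screen <- drug_screen(cohort$drug_assoc, cohort$ic50, n22, n5, pc)
      tsv(screen$report, "drug_report.tsv")
      tsv(screen$final, "drug_final_list.tsv")
      results$pharmaco <- screen
      note("pharmaco: ", nrow(screen$final), " drug(s) in the final list")
    }
  }

  ## --- run log with config hash and seed -----------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  log <- list(seed = seed, stages = stages,
              config_hash = unname(tools::md5sum(cfg_file)),
              config_path = config_path, log = log_lines,
              timestamp_free = TRUE)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
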