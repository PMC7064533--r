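#' Drug-filter configuration
#'
#' Thresholds of the staged pharmacogenomic screen. Defaults follow the
#' stringent screen: association effect size `|coefficient| > 0.25` with
#' `p < 0.001` (both strict), at least 3 distinct gene hits within the
#' 22-miRNA target network and at least 1 within the 5-miRNA network, 20
#' top-ranked targets per miRNA, and cisplatin as the reference drug
#' whose median IC50 bounds the final list. `relaxed = TRUE` switches to
#' the relaxed criteria `|coefficient| > 0.15`, `p < 0.05`.
#'
#' @param coef_threshold minimum absolute regression coefficient
#'   (exclusive).
#' @param p_threshold maximum association p-value (exclusive).
#' @param min_hits_22,min_hits_5 minimum distinct-gene hit counts in the
#'   two networks.
#' @param top_n_targets targets per miRNA entering the screen.
#' @param reference_drug drug whose median IC50 is the selection bound.
#' @param relaxed use the relaxed coefficient/p thresholds.
#' @return A validated list of class `drug_filter_config`.
#' @export
drug_filter_config <- function(coef_threshold = 0.25, p_threshold = 0.001,
                               min_hits_22 = 3, min_hits_5 = 1,
                               top_n_targets = 20, reference_drug = "cisplatin",
                               relaxed = FALSE) {
  if (relaxed) { coef_threshold <- 0.15; p_threshold <- 0.05 }
  cfg <- list(coef_threshold = coef_threshold, p_threshold = p_threshold,
              min_hits_22 = as.integer(min_hits_22),
              min_hits_5 = as.integer(min_hits_5),
              top_n_targets = as.integer(top_n_targets),
              reference_drug = reference_drug, relaxed = relaxed)
  if (cfg$coef_threshold <= 0 || cfg$p_threshold <= 0)
    stop("thresholds must be > 0")
  if (cfg$min_hits_22 < 0 || cfg$min_hits_5 < 0)
    stop("minimum hit counts must be >= 0")
  class(cfg) <- "drug_filter_config"
  cfg
}

#' Rank each miRNA's gene targets by survival association
#'
#' Orders every miRNA's target genes by ascending univariate survival
#' p-value (ties broken by gene id, lexicographically smaller first) and
#' retains the top `top_n`; miRNAs with fewer available targets keep all
#' of them. Targets with no p-value are excluded and logged; a miRNA
#' left with no targets is skipped with a message.
#'
#' @param per_gene_p named numeric vector of per-gene survival p-values
#'   (e.g. from [per_gene_pvalues()]).
#' @param target_map a [read_target_map()] result.
#' @param top_n targets retained per miRNA (default 20).
#' @param tier which target tier to rank (default `"expansive"`).
#' @return Named list: per miRNA, the ranked character vector of retained
#'   gene ids.
#' @export
rank_top_targets <- function(per_gene_p, target_map, top_n = 20,
                             tier = c("expansive", "restrictive")) {
  tier <- match.arg(tier)
  out <- list()
  for (m in names(target_map)) {
    genes <- target_map[[m]][[tier]]
    absent <- setdiff(genes, names(per_gene_p))
    if (length(absent))
      message("rank_top_targets: ", m, ": excluding ", length(absent),
              " target(s) with no p-value")
    genes <- intersect(genes, names(per_gene_p))
    if (!length(genes)) {
      message("rank_top_targets: ", m, " has no usable targets; skipped")
      next
    }
    ord <- order(per_gene_p[genes], genes)
    out[[m]] <- genes[ord][seq_len(min(top_n, length(genes)))]
  }
  out
}

#' Stage 1: filter gene-drug associations on effect size and p-value
#'
#' Retains association rows with `|coefficient| > coef_threshold` and
#' `p < p_threshold`, both strict inequalities (a coefficient of exactly
#' 0.25 does not pass the default screen).
#'
#' @param assoc data.frame with columns `drug_id`, `gene_id`,
#'   `coefficient`, `p`.
#' @param config a [drug_filter_config()].
#' @return The passing rows ("hits").
#' @export
filter_associations <- function(assoc, config = drug_filter_config()) {
  need <- c("drug_id", "gene_id", "coefficient", "p")
  if (!all(need %in% names(assoc)))
    stop("associations need columns: ", paste(need, collapse = ", "))
  if (any(assoc$p <= 0 | assoc$p > 1)) stop("association p-values must lie in (0, 1]")
  assoc[abs(assoc$coefficient) > config$coef_threshold &
          assoc$p < config$p_threshold, , drop = FALSE]
}

#' Stage 2: network hit rule
#'
#' A drug survives iff its hits cover at least `min_hits_22` distinct
#' genes within the 22-miRNA target network and at least `min_hits_5`
#' distinct genes within the 5-miRNA network. Hits are counted per
#' distinct (drug, gene) pair, not per experiment row.
#'
#' @param hits passing associations from [filter_associations()].
#' @param network_22,network_5 character vectors of network gene ids.
#' @param config a [drug_filter_config()].
#' @return Character vector of surviving drug ids.
#' @export
select_drugs <- function(hits, network_22, network_5, config = drug_filter_config()) {
  if (!length(network_22) || !length(network_5)) stop("networks must be nonempty")
  if (!nrow(hits)) return(character())
  per_drug <- split(hits$gene_id, hits$drug_id)
  keep <- vapply(per_drug, function(genes) {
    g <- unique(genes)
    length(intersect(g, network_22)) >= config$min_hits_22 &&
      length(intersect(g, network_5)) >= config$min_hits_5
  }, logical(1))
  names(per_drug)[keep]
}

#' Stage 3: rank surviving drugs by median IC50 against a reference drug
#'
#' Computes each drug's median IC50 over the available osteosarcoma cell
#' lines (median = 50th percentile with midpoint interpolation for even
#' counts). Drugs with no sensitivity data are flagged
#' `no_sensitivity_data` and excluded from the final selection. The final
#' list contains the drugs whose median IC50 is less than or equal to
#' the reference drug's median (the reference sets the minimum potency
#' threshold, so a drug exactly at it passes), sorted ascending by
#' median IC50. Drugs measured in three or fewer cell lines are flagged
#' `limited_evidence`.
#'
#' @param drugs character vector of candidate drug ids (stage-2
#'   survivors).
#' @param sensitivity data.frame with columns `drug_id`, `cell_line_id`,
#'   `ic50_um` (positive, micromolar).
#' @param reference_drug drug id present in `sensitivity`.
#' @return data.frame: `drug_id`, `median_ic50`, `n_cell_lines`,
#'   `passes_ic50`, `limited_evidence`, `no_sensitivity_data`, sorted
#'   ascending by median IC50 (drugs without data last).
#' @export
rank_by_ic50 <- function(drugs, sensitivity, reference_drug = "cisplatin") {
  need <- c("drug_id", "cell_line_id", "ic50_um")
  if (!all(need %in% names(sensitivity)))
    stop("sensitivity table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(sensitivity$ic50_um) | sensitivity$ic50_um <= 0))
    stop("IC50 values must be positive and finite")
  ref <- sensitivity$ic50_um[sensitivity$drug_id == reference_drug]
  if (!length(ref)) stop("reference drug '", reference_drug, "' has no IC50 data")
  ref_median <- stats::median(ref)
  rows <- lapply(drugs, function(d) {
    v <- sensitivity$ic50_um[sensitivity$drug_id == d]
    if (!length(v))
      return(data.frame(drug_id = d, median_ic50 = NA_real_, n_cell_lines = 0L,
                        passes_ic50 = FALSE, limited_evidence = FALSE,
                        no_sensitivity_data = TRUE, stringsAsFactors = FALSE))
    med <- stats::median(v)
    data.frame(drug_id = d, median_ic50 = med, n_cell_lines = length(v),
               passes_ic50 = med <= ref_median, limited_evidence = length(v) <= 3L,
               no_sensitivity_data = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$no_sensitivity_data, out$median_ic50), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_median") <- ref_median
  out
}

#' Full staged pharmacogenomic screen
#'
#' Runs the three stages in order — association filter, network hit
#' rule, IC50 ranking against the reference drug — and assembles a
#' per-drug report with hit counts in both networks, the median passing
#' coefficient, median IC50, and per-stage pass flags
#' (`passes_stage3 => passes_stage2 => passes_stage1`).
#'
#' @param assoc gene-drug association table (`drug_id`, `gene_id`,
#'   `coefficient`, `p`).
#' @param sensitivity IC50 table (`drug_id`, `cell_line_id`, `ic50_um`).
#' @param network_22,network_5 network gene id vectors.
#' @param config a [drug_filter_config()].
#' @return List of class `drug_report`: `report` (one row per drug with
#'   any association), `final` (the stage-3 survivors sorted by median
#'   IC50), `reference_median`.
#' @export
drug_screen <- function(assoc, sensitivity, network_22, network_5,
                        config = drug_filter_config()) {
  hits <- filter_associations(assoc, config)
  stage2 <- select_drugs(hits, network_22, network_5, config)
  ranked <- rank_by_ic50(stage2, sensitivity, config$reference_drug)
  all_drugs <- unique(assoc$drug_id)
  report <- do.call(rbind, lapply(all_drugs, function(d) {
    dh <- hits[hits$drug_id == d, , drop = FALSE]
    g <- unique(dh$gene_id)
    row <- ranked[ranked$drug_id == d, , drop = FALSE]
    data.frame(drug_id = d,
               hits_22 = length(intersect(g, network_22)),
               hits_5 = length(intersect(g, network_5)),
               median_coefficient = if (nrow(dh)) stats::median(abs(dh$coefficient)) else NA_real_,
               median_ic50 = if (nrow(row)) row$median_ic50 else NA_real_,
               n_cell_lines = if (nrow(row)) row$n_cell_lines else NA_integer_,
               passes_stage1 = nrow(dh) > 0L,
               passes_stage2 = d %in% stage2,
               passes_stage3 = nrow(row) > 0L && isTRUE(row$passes_ic50),
               limited_evidence = nrow(row) > 0L && isTRUE(row$limited_evidence),
               stringsAsFactors = FALSE)
  }))
  final <- ranked[ranked$passes_ic50 %in% TRUE, , drop = FALSE]
  structure(list(report = report, final = final,
                 reference_median = attr(ranked, "reference_median"),
                 config = config),
            class = "drug_report")
}

#' Candidate drug table from the published osteosarcoma screen
#'
#' The printed candidate table of the osteosarcoma pharmacogenomic
#' screen: per drug, class, median IC50 (micromolar) across available
#' osteosarcoma cell lines, the median regression coefficient over
#' passing associations, and the chemical-replicate count.
#' Methotrexate, etoposide and cisplatin are comparator rows (they did
#' not pass the stringent association screen; `comparator = TRUE`), and
#' cisplatin is the IC50 reference. Drugs with IC50 data from three or
#' fewer cell lines are flagged `limited_evidence`.
#'
#' @return data.frame with one row per drug.
#' @export
osteosarcoma_drug_table <- function() {
  path <- system.file("extdata", "osteosarcoma_drug_candidates.tsv",
                      package = "osteomir", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$comparator <- as.logical(df$comparator)
  df$limited_evidence <- as.logical(df$limited_evidence)
  df
}
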