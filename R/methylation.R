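#' Differential methylation between two sample groups
#'
#' Per-probe Welch two-sample t-test on M-values between two groups, with
#' Benjamini-Hochberg q-values reported alongside the unadjusted p. Beta
#' matrices are converted to M-values first: all methylation testing is
#' done in M space, where values are closer to homoscedastic normality.
#'
#' @param m_matrix an [expression_matrix()] in `M` (or `beta`, converted)
#'   space.
#' @param groups per-sample two-level factor or character vector.
#' @return List of class `differential_result`: `table` (probe_id,
#'   mean_diff = group1 - group2 in M units, t, p, bh_q), `n_significant`
#'   (probes with p < 0.05), `fraction_hyper_group1` (fraction of probes
#'   with higher mean M in group 1), `groups` (the two level names).
#' @export
differential_methylation <- function(m_matrix, groups) {
  if (matrix_space(m_matrix) == "beta") m_matrix <- beta_to_m(m_matrix)
  assert_space(m_matrix, "M")
  groups <- as.character(groups)
  if (length(groups) != ncol(m_matrix))
    stop("`groups` must label every sample")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  a <- unclass(m_matrix)[, groups == lev[1L], drop = FALSE]
  b <- unclass(m_matrix)[, groups == lev[2L], drop = FALSE]
  res <- t(vapply(seq_len(nrow(m_matrix)), function(i) {
    va <- stats::var(a[i, ]); vb <- stats::var(b[i, ])
    if (va == 0 && vb == 0)
      return(c(diff = mean(a[i, ]) - mean(b[i, ]), t = 0, p = 1))
    tt <- stats::t.test(a[i, ], b[i, ])
    c(diff = unname(tt$estimate[1L] - tt$estimate[2L]),
      t = unname(tt$statistic), p = tt$p.value)
  }, numeric(3)))
  tab <- data.frame(probe_id = rownames(m_matrix),
                    mean_diff = res[, "diff"], t = res[, "t"], p = res[, "p"],
                    bh_q = bh_fdr(res[, "p"]), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 n_significant = sum(tab$p < 0.05),
                 fraction_hyper_group1 = mean(tab$mean_diff > 0),
                 groups = lev),
            class = "differential_result")
}

#' Spearman correlation between miRNA expression and CpG methylation
#'
#' Rank correlation of each annotated (miRNA, probe) pair across shared
#' samples, with a per-miRNA summary: how many probes reach Spearman
#' p < 0.05, and the median and range of the estimated coefficients over
#' those significant probes. Constant vectors leave rho undefined and are
#' flagged.
#'
#' @param mirna_expr miRNA [expression_matrix()].
#' @param m_matrix methylation matrix (`M` or `beta`, converted).
#' @param annotation data.frame with `probe_id` and `feature_id` columns
#'   (probe -> regulator miRNA); probes with NA feature are ignored.
#' @return List: `pairs` (mirna_id, probe_id, rho, p, flagged),
#'   `summary` (per miRNA: n_probes, n_significant, median_rho, rho_min,
#'   rho_max over significant probes).
#' @export
mirna_cpg_correlation <- function(mirna_expr, m_matrix, annotation) {
  if (matrix_space(m_matrix) == "beta") m_matrix <- beta_to_m(m_matrix)
  shared <- intersect(colnames(mirna_expr), colnames(m_matrix))
  if (length(shared) < 5L) stop("need >= 5 shared samples")
  ann <- annotation[!is.na(annotation$feature_id) &
                      annotation$feature_id %in% rownames(mirna_expr) &
                      annotation$probe_id %in% rownames(m_matrix), , drop = FALSE]
  if (!nrow(ann)) stop("no annotated (miRNA, probe) pairs present in the matrices")
  pairs <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    x <- unclass(mirna_expr)[ann$feature_id[i], shared]
    y <- unclass(m_matrix)[ann$probe_id[i], shared]
    if (stats::var(x) == 0 || stats::var(y) == 0)
      return(data.frame(mirna_id = ann$feature_id[i], probe_id = ann$probe_id[i],
                        rho = NA_real_, p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(mirna_id = ann$feature_id[i], probe_id = ann$probe_id[i],
               rho = unname(ct$estimate), p = ct$p.value, flagged = FALSE,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(pairs, pairs$mirna_id), function(sub) {
    sig <- sub[!sub$flagged & sub$p < 0.05, ]
    data.frame(mirna_id = sub$mirna_id[1L], n_probes = nrow(sub),
               n_significant = nrow(sig),
               median_rho = if (nrow(sig)) stats::median(sig$rho) else NA_real_,
               rho_min = if (nrow(sig)) min(sig$rho) else NA_real_,
               rho_max = if (nrow(sig)) max(sig$rho) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ)
}

#' Methylation-based clustering with survival testing and robustness check
#'
#' Hierarchically clusters samples over a methylation probe subset
#' (centered correlation, average linkage), tests the resulting partition
#' for survival differences with the log-rank test, assesses cluster
#' reproducibility with the R-index, and repeats the clustering and
#' survival test after removing the 50% least variant probes as a
#' robustness check.
#'
#' @param m_matrix methylation matrix (`M` or `beta`, converted).
#' @param probe_subset probe identifiers to cluster over.
#' @param clinical clinical table (columns `time_months`, `event`),
#'   column-matched to the samples.
#' @param k number of clusters (default 2).
#' @param n_perturbations,noise_sd_factor,seed R-index controls.
#' @return List: `cluster`, `logrank`, `r_index`, and `robustness`
#'   (`cluster`, `logrank`, `agreement` = fraction of samples keeping
#'   their partition side, after the 50% variance filter).
#' @export
methylation_cluster_survival <- function(m_matrix, probe_subset, clinical, k = 2,
                                         n_perturbations = 50, noise_sd_factor = 0.5,
                                         seed = 1L) {
  if (matrix_space(m_matrix) == "beta") m_matrix <- beta_to_m(m_matrix)
  assert_space(m_matrix, "M")
  sub <- expression_matrix(unclass(m_matrix)[probe_subset, , drop = FALSE], "M")
  cl <- hier_cluster(sub, k = k)
  sd <- survival_data(clinical$time_months, clinical$event,
                      group = paste0("cluster", cl$cluster))
  lr <- logrank(sd)
  ri <- r_index(sub, k = k, n_perturbations = n_perturbations,
                noise_sd_factor = noise_sd_factor, seed = seed)
  filt <- variance_filter(sub, 0.50)
  cl2 <- hier_cluster(filt, k = k)
  sd2 <- survival_data(clinical$time_months, clinical$event,
                       group = paste0("cluster", cl2$cluster))
  lr2 <- logrank(sd2)
  agree <- max(mean(cl$cluster == cl2$cluster),
               mean(cl$cluster != cl2$cluster))  # label-swap invariant (k = 2)
  if (k > 2) agree <- pair_agreement(cl$cluster, cl2$cluster)
  list(cluster = cl, logrank = lr, r_index = ri,
       robustness = list(cluster = cl2, logrank = lr2, agreement = agree))
}
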