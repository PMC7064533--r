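#' Risk profile: signed feature weights
#'
#' An ordered set of feature identifiers with +1/-1 weights, the sign
#' taken from the direction of each feature's hazard ratio in the
#' discovery analysis (+1 = higher expression, poorer outcome).
#'
#' @param feature_ids character vector of feature identifiers.
#' @param signs numeric vector of +1/-1 weights, one per feature.
#' @param source free-text provenance (e.g. `"pilot discovery"`).
#' @return A list of class `risk_profile`.
#' @export
risk_profile <- function(feature_ids, signs, source = "") {
  if (length(feature_ids) != length(signs))
    stop("`signs` must have one entry per feature")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  if (anyDuplicated(feature_ids)) stop("duplicated feature identifiers in profile")
  structure(list(feature_ids = as.character(feature_ids),
                 signs = as.numeric(signs), source = source),
            class = "risk_profile")
}

#' @rdname risk_profile
#' @param path TSV with columns `feature_id` and `sign`.
#' @export
read_risk_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  risk_profile(df$feature_id, df$sign, source = path)
}

#' Signed-average risk score with median dichotomization
#'
#' The per-sample score is the mean of the profile features' expression,
#' each weighted by its +1/-1 sign: `S_s = (1/|G|) sum_g w_g x_gs`. With
#' `standardize = TRUE` (default) each feature is z-scored across samples
#' first, so no single high-variance feature dominates the average.
#' Samples are dichotomized at the within-cohort median of the score;
#' samples exactly at the median go to the low-score group. Higher score
#' means predicted poorer outcome under the sign convention.
#'
#' Profile features absent from the matrix are dropped with a warning and
#' recorded in the result's `dropped` field; an empty profile after
#' dropping is an error.
#'
#' @param matrix an [expression_matrix()] in `log2norm` or `M` space.
#' @param profile a [risk_profile()].
#' @param standardize z-score features before averaging (default TRUE).
#' @return List of class `risk_score`: `score` (named per sample),
#'   `group` (`"high"`/`"low"`), `cutpoint` (the median), `dropped`.
#' @export
signed_average_score <- function(matrix, profile, standardize = TRUE) {
  if (!matrix_space(matrix) %in% c("log2norm", "M"))
    stop("signed averaging expects a log2norm or M matrix")
  present <- profile$feature_ids %in% rownames(matrix)
  dropped <- profile$feature_ids[!present]
  if (length(dropped))
    warning("profile feature(s) absent from matrix, dropped: ",
            paste(dropped, collapse = ", "))
  ids <- profile$feature_ids[present]
  w <- profile$signs[present]
  if (!length(ids)) stop("no profile features left after dropping missing ones")
  x <- unclass(matrix)[ids, , drop = FALSE]
  if (standardize) x <- t(scale(t(x)))
  score <- as.numeric(crossprod(x, w)) / length(ids)
  names(score) <- colnames(matrix)
  cut <- stats::median(score)
  group <- ifelse(score > cut, "high", "low")
  structure(list(score = score, group = group, cutpoint = cut, dropped = dropped),
            class = "risk_score")
}

#' Hierarchical clustering of samples (centered correlation, average linkage)
#'
#' Agglomerative clustering of samples over a feature subset with
#' distance `d(a, b) = 1 - Pearson(a, b)` and average linkage, cut to
#' `k` clusters. Zero-variance features are dropped with a warning
#' (Pearson correlation is undefined over them). Deterministic given the
#' input order.
#'
#' @param matrix an [expression_matrix()].
#' @param feature_subset feature identifiers to cluster over (default:
#'   all).
#' @param k number of clusters (default 2).
#' @return List of class `cluster_assignment`: `cluster` (named integer
#'   labels 1..k), `k`, `linkage`, `distance`, `hclust` (the tree).
#' @export
hier_cluster <- function(matrix, feature_subset = rownames(matrix), k = 2) {
  if (k > ncol(matrix)) stop("k exceeds the number of samples")
  if (k < 2) stop("k must be >= 2")
  missing <- setdiff(feature_subset, rownames(matrix))
  if (length(missing))
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "))
  x <- unclass(matrix)[feature_subset, , drop = FALSE]
  v <- apply(x, 1L, stats::var)
  if (all(v == 0)) stop("all selected features have zero variance")
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(feature_subset[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, k = as.integer(k), linkage = "average",
                 distance = "centered correlation", hclust = hc),
            class = "cluster_assignment")
}

# fraction of originally co-clustered sample pairs still co-clustered
pair_agreement <- function(orig, new) {
  co_orig <- outer(orig, orig, "==")
  co_new <- outer(new, new, "==")
  ut <- upper.tri(co_orig)
  denom <- sum(co_orig[ut])
  if (denom == 0) return(NA_real_)
  sum(co_orig[ut] & co_new[ut]) / denom
}

#' Cluster reproducibility R-index
#'
#' Perturbs the data `n_perturbations` times with i.i.d. Gaussian noise
#' (common SD = `noise_sd_factor` times the pooled within-feature SD,
#' i.e. the square root of the mean per-feature variance), reclusters at
#' the same `k`, and records the fraction of sample pairs co-clustered in
#' the original partition that remain co-clustered. The R-index is the
#' mean of those per-perturbation agreements; 1 means perfectly
#' reproducible clusters, values near the chance level indicate unstable
#' structure.
#'
#' @inheritParams hier_cluster
#' @param n_perturbations number of noise perturbations (>= 1).
#' @param noise_sd_factor multiple of the pooled within-feature SD used
#'   as the noise SD (default 0.5).
#' @param seed integer seed for the noise draws.
#' @return List of class `r_index_result`: `r`, `n_perturbations`,
#'   `noise_sd`, `agreements`, `original` (the unperturbed partition).
#' @export
r_index <- function(matrix, feature_subset = rownames(matrix), k = 2,
                    n_perturbations = 50, noise_sd_factor = 0.5, seed = 1L) {
  if (n_perturbations < 1) stop("`n_perturbations` must be >= 1")
  base <- hier_cluster(matrix, feature_subset, k)
  x <- unclass(matrix)[feature_subset, , drop = FALSE]
  pooled_sd <- sqrt(mean(apply(x, 1L, stats::var)))
  noise_sd <- noise_sd_factor * pooled_sd
  set.seed(seed)
  agreements <- vapply(seq_len(n_perturbations), function(i) {
    pert <- x + stats::rnorm(length(x), sd = noise_sd)
    pm <- structure(pert, space = matrix_space(matrix),
                    class = c("expr_matrix", "matrix", "array"))
    new <- hier_cluster(pm, rownames(pm), k)
    pair_agreement(base$cluster, new$cluster)
  }, numeric(1))
  structure(list(r = mean(agreements), n_perturbations = as.integer(n_perturbations),
                 noise_sd = noise_sd, agreements = agreements, original = base),
            class = "r_index_result")
}

#' Composite prognostic classification
#'
#' Combines the molecular risk group with the pathologic necrosis class
#' into three prognostic groups: low risk + optimal necrosis is
#' `very_favorable`, high risk + suboptimal necrosis is
#' `very_unfavorable`, and the two mixed cells are `intermediate`.
#' Samples with a missing input are excluded and reported.
#'
#' @param risk_group character vector, `"high"` / `"low"` per sample.
#' @param necrosis character vector, `"optimal"` / `"suboptimal"`.
#' @return List: `label` (factor with the three composite levels, NA for
#'   excluded samples), `excluded` (indices with missing input).
#' @export
composite_classify <- function(risk_group, necrosis) {
  if (length(risk_group) != length(necrosis))
    stop("inputs must have equal length")
  ok_r <- risk_group %in% c("high", "low")
  ok_n <- necrosis %in% c("optimal", "suboptimal")
  excluded <- which(!(ok_r & ok_n))
  lab <- rep(NA_character_, length(risk_group))
  use <- setdiff(seq_along(lab), excluded)
  lab[use] <- ifelse(risk_group[use] == "low" & necrosis[use] == "optimal",
                     "very_favorable",
              ifelse(risk_group[use] == "high" & necrosis[use] == "suboptimal",
                     "very_unfavorable", "intermediate"))
  list(label = factor(lab, levels = c("very_favorable", "intermediate", "very_unfavorable")),
       excluded = excluded)
}

#' Classification concordance: chi-square, Fisher, Cramér's V
#'
#' Builds the contingency table of two labelings of the same samples and
#' quantifies their association: the chi-square statistic (no continuity
#' correction, as conventional for Cramér's V), Fisher's exact two-sided
#' p for 2x2 tables, and `V = sqrt(chi2 / (n * (min(r, c) - 1)))`.
#' Degenerate single-category labelings leave V undefined (NA) with a
#' note.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return List of class `concordance_result`: `contingency`, `chi2`,
#'   `chi2_p`, `fisher_p` (NA unless 2x2), `cramers_v`, `note`.
#' @export
concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must cover the same samples")
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(structure(list(contingency = tab, chi2 = NA_real_, chi2_p = NA_real_,
                          fisher_p = NA_real_, cramers_v = NA_real_,
                          note = "degenerate single-category labeling; V undefined"),
                     class = "concordance_result"))
  }
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(unname(chi$statistic) / (n * (min(dim(tab)) - 1)))
  fisher_p <- if (all(dim(tab) == 2L)) stats::fisher.test(tab)$p.value else NA_real_
  structure(list(contingency = tab, chi2 = unname(chi$statistic),
                 chi2_p = chi$p.value, fisher_p = fisher_p,
                 cramers_v = v, note = NULL),
            class = "concordance_result")
}
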