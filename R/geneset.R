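#' Per-gene univariate Cox survival p-values
#'
#' Two-sided score-test p from a univariate Cox proportional-hazards fit
#' (Efron ties) of each gene's expression against the survival endpoint.
#' Constant genes are assigned p = 1 and flagged rather than fitted.
#'
#' @param matrix an [expression_matrix()], genes in rows, samples
#'   column-matched to `survival`.
#' @param survival a [survival_data()] with one row per sample.
#' @return data.frame: `gene_id`, `p`, `flagged` (TRUE for constant
#'   genes).
#' @export
per_gene_pvalues <- function(matrix, survival) {
  if (ncol(matrix) != nrow(survival))
    stop("genes must be column-matched to the survival data")
  res <- t(apply(unclass(matrix), 1L, function(x)
    cox_score_p(survival$time, survival$event, x)))
  data.frame(gene_id = rownames(matrix), p = unname(res[, "p"]),
             flagged = res[, "flagged"] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

clamp_pvals <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("p-value(s) of 0 clamped to the machine minimum")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  pvals
}

#' LS and KS gene-set statistics
#'
#' Functional-class-scoring summaries of a set of per-gene p-values:
#' `ls_stat` is the mean of `-ln(p)` over the set; `ks_stat` is the
#' maximal exceedance of the ascending-sorted p-values below the uniform
#' line, `max_i (i/k - p_(i))`, floored at 0 (one-sided toward small p).
#' Both are invariant to the ordering of the input.
#'
#' @param pvals numeric vector of per-gene p-values in (0, 1]; zeros are
#'   clamped to the machine minimum with a warning.
#' @return A single numeric statistic.
#' @export
ls_stat <- function(pvals) {
  if (!length(pvals)) stop("need >= 1 p-value")
  mean(-log(clamp_pvals(pvals)))
}

#' @rdname ls_stat
#' @export
ks_stat <- function(pvals) {
  if (!length(pvals)) stop("need >= 1 p-value")
  p <- sort(clamp_pvals(pvals))
  k <- length(p)
  max(0, max(seq_len(k) / k - p))
}

#' Permutation p-values for a gene set's LS/KS statistics
#'
#' The null distribution is formed by drawing `n_perm` random gene sets
#' of the same size, without replacement, from all measured genes, and
#' recomputing both statistics. `p = (1 + #{null >= observed}) /
#' (1 + n_perm)`, which can never be exactly 0.
#'
#' @param geneset character vector of gene identifiers (subset of the
#'   measured genes).
#' @param all_gene_pvals named numeric vector: per-gene p-values for the
#'   whole measured universe (names are gene ids).
#' @param n_perm number of random sets (>= 100).
#' @param seed integer seed for the permutation draws.
#' @return List of class `gene_set_result`: `set_size`, `ls`, `ks`,
#'   `p_ls`, `p_ks`, `n_perm`, `seed`, `too_small` (TRUE when < 5 usable
#'   genes, reported rather than tested silently).
#' @export
permutation_pvalue <- function(geneset, all_gene_pvals, n_perm = 1000, seed = 1L) {
  if (is.null(names(all_gene_pvals))) stop("`all_gene_pvals` must be named by gene id")
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  missing <- setdiff(geneset, names(all_gene_pvals))
  if (length(missing))
    stop("gene(s) not in the measured universe: ", paste(missing, collapse = ", "))
  k <- length(geneset)
  if (k > length(all_gene_pvals)) stop("set larger than the gene universe")
  obs_p <- all_gene_pvals[geneset]
  obs_ls <- ls_stat(obs_p)
  obs_ks <- ks_stat(obs_p)
  universe <- clamp_pvals(unname(all_gene_pvals))
  neglog <- -log(universe)
  set.seed(seed)
  null_ls <- numeric(n_perm)
  null_ks <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(universe), k)
    null_ls[i] <- mean(neglog[idx])
    p <- sort(universe[idx])
    null_ks[i] <- max(0, max(seq_len(k) / k - p))
  }
  structure(list(set_size = k, ls = obs_ls, ks = obs_ks,
                 p_ls = (1 + sum(null_ls >= obs_ls)) / (1 + n_perm),
                 p_ks = (1 + sum(null_ks >= obs_ks)) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 too_small = k < 5L),
            class = "gene_set_result")
}

#' Random-gene-set control for a candidate set
#'
#' Scores `n_sets` random gene sets of a fixed size with the full LS/KS
#' permutation machinery, as a control distribution against which a
#' candidate set's p-value can be ranked (guarding against significance
#' arising purely from the multitude of genes).
#'
#' @param all_gene_pvals named per-gene p-values (the universe).
#' @param n_sets number of control sets (default 10).
#' @param set_size genes per control set (default 44, the size of the
#'   union of the 5-miRNA target lists).
#' @param n_perm permutations per set.
#' @param seed integer seed.
#' @return List: `controls` (list of `gene_set_result`), `control_p_ls`,
#'   `control_p_ks` (numeric vectors).
#' @export
random_set_control <- function(all_gene_pvals, n_sets = 10, set_size = 44,
                               n_perm = 1000, seed = 1L) {
  if (length(all_gene_pvals) < set_size)
    stop("gene universe smaller than `set_size`")
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(names(all_gene_pvals), set_size))
  controls <- lapply(seq_along(sets), function(i)
    permutation_pvalue(sets[[i]], all_gene_pvals, n_perm = n_perm,
                       seed = seed + i))
  list(controls = controls,
       control_p_ls = vapply(controls, `[[`, numeric(1), "p_ls"),
       control_p_ks = vapply(controls, `[[`, numeric(1), "p_ks"),
       sets = sets)
}

#' EASE-score pathway enrichment with BH correction
#'
#' One-sided hypergeometric enrichment of a gene list against each
#' pathway in a collection, with the EASE penalization: the overlap count
#' is decremented by one before computing the upper tail, so an overlap
#' of 0 or 1 gives p = 1. Benjamini-Hochberg q-values are computed across
#' pathways.
#'
#' @param gene_list character vector (must be a subset of `background`).
#' @param background character vector: the gene universe.
#' @param pathway_collection named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame: `pathway`, `overlap`, `pathway_size` (within the
#'   background), `ease_p`, `bh_q`.
#' @export
ease_enrichment <- function(gene_list, background, pathway_collection) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("gene list member(s) outside the background: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  gene_list <- unique(gene_list)
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(pathway_collection), function(pw) {
    members <- intersect(unique(pathway_collection[[pw]]), background)
    K <- length(members)
    m <- length(intersect(gene_list, members))
    p <- if (m <= 1L) 1 else
      stats::phyper(m - 2L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = m, pathway_size = K, ease_p = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- bh_fdr(out$ease_p)
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals numeric p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Read a GMT-format gene-set collection
#'
#' Standard GMT: one set per line, tab-delimited, `name <tab> description
#' <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Read a miRNA-to-gene target map
#'
#' TSV with columns `mirna_id`, `gene_id`, `tier` (`"restrictive"` or
#' `"expansive"`). The restrictive tier is the higher-confidence subset:
#' per miRNA, restrictive targets are also members of the expansive set.
#'
#' @param path TSV path (or a data.frame with those columns).
#' @return List of class `gene_target_map`: per miRNA, `expansive` and
#'   `restrictive` character vectors.
#' @export
read_target_map <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "tier")
  if (!all(need %in% names(df)))
    stop("target map needs columns: ", paste(need, collapse = ", "))
  if (!all(df$tier %in% c("restrictive", "expansive")))
    stop("tier must be 'restrictive' or 'expansive'")
  mirnas <- unique(df$mirna_id)
  out <- lapply(mirnas, function(m) {
    sub <- df[df$mirna_id == m, ]
    restrictive <- unique(sub$gene_id[sub$tier == "restrictive"])
    list(expansive = unique(sub$gene_id), restrictive = restrictive)
  })
  structure(stats::setNames(out, mirnas), class = "gene_target_map")
}

#' Gene-set survival analysis over a target map
#'
#' Runs the LS/KS permutation test for each miRNA's target set against a
#' survival endpoint. For the expansive tier the expression matrix is
#' variance-filtered first (dropping the lowest 20% variance genes, to
#' reduce statistical noise); the restrictive tier is tested unfiltered.
#' Sets with fewer than 5 usable genes are reported as too small.
#'
#' @param matrix gene expression, `log2norm` space.
#' @param survival a [survival_data()].
#' @param target_map a [read_target_map()] result.
#' @param tier `"expansive"` or `"restrictive"`.
#' @param n_perm,seed permutation controls.
#' @return data.frame: `mirna_id`, `set_size`, `ls`, `ks`, `p_ls`,
#'   `p_ks`, `too_small`.
#' @export
gene_set_survival <- function(matrix, survival, target_map,
                              tier = c("expansive", "restrictive"),
                              n_perm = 1000, seed = 1L) {
  tier <- match.arg(tier)
  if (tier == "expansive") matrix <- variance_filter(matrix, 0.20)
  pg <- per_gene_pvalues(matrix, survival)
  universe <- stats::setNames(pg$p, pg$gene_id)
  rows <- lapply(names(target_map), function(m) {
    genes <- intersect(target_map[[m]][[tier]], names(universe))
    if (length(genes) < 5L)
      return(data.frame(mirna_id = m, set_size = length(genes),
                        ls = NA_real_, ks = NA_real_, p_ls = NA_real_,
                        p_ks = NA_real_, too_small = TRUE,
                        stringsAsFactors = FALSE))
    res <- permutation_pvalue(genes, universe, n_perm = n_perm, seed = seed)
    data.frame(mirna_id = m, set_size = res$set_size, ls = res$ls, ks = res$ks,
               p_ls = res$p_ls, p_ks = res$p_ks, too_small = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
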