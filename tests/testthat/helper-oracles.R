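# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# O(n^3) agglomerative average-linkage clustering over d = 1 - Pearson,
# stopping when k clusters remain. Returns integer labels.
naive_average_linkage <- function(x, k) {
  n <- ncol(x)
  d <- 1 - stats::cor(x)
  clusters <- as.list(seq_len(n))
  # cluster-to-cluster average distances, recomputed from scratch each merge
  cluster_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > k) {
    best <- c(Inf, 0L, 0L)
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in seq((i + 1L), length(clusters))) {
        dij <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dij < best[1L]) best <- c(dij, i, j)
      }
    i <- best[2L]; j <- best[3L]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  labels <- integer(n)
  for (c_idx in seq_along(clusters)) labels[clusters[[c_idx]]] <- c_idx
  labels
}

# Label-invariant partition comparison via pair co-membership.
same_partition <- function(a, b) {
  ca <- outer(a, a, "==")
  cb <- outer(b, b, "==")
  all(ca == cb)
}

# Brute-force scan: do two sequences share an exact common substring of
# length >= k? O(n * m * k).
brute_common_kmer <- function(a, b, k) {
  a <- chartr("Uu", "Tt", toupper(a)); b <- chartr("Uu", "Tt", toupper(b))
  na <- nchar(a)
  if (na < k) return(FALSE)
  for (start in seq_len(na - k + 1L)) {
    kmer <- substr(a, start, start + k - 1L)
    if (grepl(kmer, b, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# Manual two-group log-rank arithmetic: walk the event times, accumulate
# observed minus expected and the hypergeometric variance.
manual_logrank <- function(time, event, group) {
  g1 <- unique(group)[1L]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
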