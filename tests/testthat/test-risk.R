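test_that("signed average reduces to the obvious closed forms", {
  m <- toy_matrix(matrix(c(2, 4, 6, 1, 1, 1), ncol = 2),
                  features = c("fA", "fB", "fC"))
  # single feature, +1, unstandardized: the score is the expression itself
  p1 <- risk_profile("fA", 1)
  s1 <- signed_average_score(m, p1, standardize = FALSE)
  expect_equal(unname(s1$score), unname(unclass(m)["fA", ]))
  # equal features with opposite signs cancel
  m2 <- toy_matrix(matrix(c(3, 3, 5, 5), ncol = 2), features = c("fA", "fB"))
  s2 <- signed_average_score(m2, risk_profile(c("fA", "fB"), c(1, -1)),
                             standardize = FALSE)
  expect_equal(unname(s2$score), c(0, 0))
  # hand mean: (2 + 4 - 6) / 3 = 0 in sample 1
  s3 <- signed_average_score(m, risk_profile(c("fA", "fB", "fC"), c(1, 1, -1)),
                             standardize = FALSE)
  expect_equal(unname(s3$score[1]), 0)
})

test_that("signed average is linear per feature and invariant to feature order", {
  set.seed(2)
  m <- toy_matrix(matrix(rnorm(5 * 8), 5))
  prof <- risk_profile(rownames(m), c(1, -1, 1, 1, -1))
  base <- signed_average_score(m, prof, standardize = FALSE)
  # feature order
  perm <- sample(5)
  prof_p <- risk_profile(rownames(m)[perm], prof$signs[perm])
  expect_equal(signed_average_score(m, prof_p, standardize = FALSE)$score,
               base$score)
  # linearity in one feature: adding delta to fA moves every score by w/|G|*delta
  m2 <- unclass(m); m2["f1", ] <- m2["f1", ] + 2
  s2 <- signed_average_score(toy_matrix(m2), prof, standardize = FALSE)
  expect_equal(unname(s2$score - base$score), rep(2 * 1 / 5, 8))
})

test_that("median ties go to the low-score group and missing features warn", {
  m <- toy_matrix(matrix(c(1, 2, 2, 3), nrow = 1), features = "fA")
  sc <- signed_average_score(m, risk_profile("fA", 1), standardize = FALSE)
  expect_equal(sc$cutpoint, 2)
  expect_identical(unname(sc$group), c("low", "low", "low", "high"))
  expect_warning(
    sc2 <- signed_average_score(m, risk_profile(c("fA", "ghost"), c(1, 1)),
                                standardize = FALSE),
    "ghost")
  expect_identical(sc2$dropped, "ghost")
  expect_error(
    suppressWarnings(signed_average_score(m, risk_profile("ghost", 1))),
    "no profile features")
})

test_that("clustering recovers exact duplicate groups and ignores sample order", {
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  x <- cbind(a, a + rnorm(10, sd = 1e-8), a + rnorm(10, sd = 1e-8),
             b, b + rnorm(10, sd = 1e-8), b + rnorm(10, sd = 1e-8))
  m <- toy_matrix(x)
  cl <- hier_cluster(m, k = 2)
  expect_true(same_partition(cl$cluster, rep(1:2, each = 3)))
  perm <- c(4, 1, 5, 2, 6, 3)
  cl2 <- hier_cluster(toy_matrix(x[, perm]), k = 2)
  expect_true(same_partition(cl2$cluster, rep(1:2, each = 3)[perm]))
})

test_that("clustering matches the naive cubic agglomerator on random data", {
  set.seed(19)
  for (i in 1:20) {
    x <- matrix(rnorm(8 * 12), 8)
    m <- toy_matrix(x)
    for (k in 2:3) {
      fast <- hier_cluster(m, k = k)$cluster
      slow <- naive_average_linkage(x, k)
      expect_true(same_partition(fast, slow),
                  info = sprintf("instance %d, k = %d", i, k))
    }
  }
})

test_that("clustering guards its preconditions", {
  m <- toy_matrix(matrix(rnorm(12), 3))
  expect_error(hier_cluster(m, k = 10), "samples")
  flat <- toy_matrix(matrix(1, 3, 4))
  expect_error(hier_cluster(flat, k = 2), "zero variance")
  half <- toy_matrix(rbind(rnorm(4), rep(1, 4), rnorm(4)))
  expect_warning(hier_cluster(half, k = 2), "zero-variance")
})

test_that("R-index is exactly 1 without noise and degrades on structureless data", {
  set.seed(8)
  # separation must live in the feature *pattern*: centered correlation is
  # blind to a uniform shift, so the two groups carry opposite profiles
  pattern <- rep(c(5, -5), each = 5)
  blob <- cbind(matrix(rnorm(10 * 8), 10) + pattern,
                matrix(rnorm(10 * 8), 10) - pattern)
  m <- toy_matrix(blob)
  r0 <- r_index(m, k = 2, n_perturbations = 5, noise_sd_factor = 0, seed = 1)
  expect_identical(r0$r, 1)
  expect_equal(r0$r, mean(r0$agreements))
  r_blob <- r_index(m, k = 2, n_perturbations = 20, noise_sd_factor = 0.5, seed = 1)
  noise <- toy_matrix(matrix(rnorm(10 * 16), 10))
  r_noise <- r_index(noise, k = 2, n_perturbations = 20, noise_sd_factor = 0.5, seed = 1)
  expect_gte(r_blob$r, 0.95)
  expect_lt(r_noise$r, r_blob$r)
})

test_that("composite classification is the stated total function", {
  # exhaustive: 4 input cells -> 3 groups
  cells <- expand.grid(risk = c("low", "high"),
                       necrosis = c("optimal", "suboptimal"),
                       stringsAsFactors = FALSE)
  lab <- composite_classify(cells$risk, cells$necrosis)$label
  expect_identical(as.character(lab),
                   c("very_favorable", "intermediate",
                     "intermediate", "very_unfavorable"))
  expect_identical(levels(lab),
                   c("very_favorable", "intermediate", "very_unfavorable"))
  # missing inputs are excluded, not guessed
  res <- composite_classify(c("low", NA), c("optimal", "optimal"))
  expect_identical(res$excluded, 2L)
  expect_true(is.na(res$label[2]))
})

test_that("concordance: perfect association, a hand-checked table, degeneracy", {
  a <- rep(c("x", "y"), each = 10)
  expect_equal(concordance(a, a)$cramers_v, 1)
  # [[8, 2], [2, 8]]: chi-square without continuity correction is 7.2
  a2 <- rep(c("g1", "g2"), each = 10)
  b2 <- c(rep("h1", 8), rep("h2", 2), rep("h1", 2), rep("h2", 8))
  cc <- concordance(a2, b2)
  expect_equal(cc$chi2, 7.2, tolerance = 1e-12)
  expect_equal(cc$cramers_v, sqrt(7.2 / 20), tolerance = 1e-12)
  expect_equal(cc$fisher_p, fisher.test(table(a2, b2))$p.value)
  dg <- concordance(rep("only", 6), rep(c("u", "v"), 3))
  expect_true(is.na(dg$cramers_v))
  expect_match(dg$note, "degenerate")
})

test_that("independent labels give near-zero V at large n", {
  set.seed(25)
  a <- sample(c("x", "y"), 4000, replace = TRUE)
  b <- sample(c("u", "v"), 4000, replace = TRUE)
  expect_lt(concordance(a, b)$cramers_v, 0.06)
})
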