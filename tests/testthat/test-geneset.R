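test_that("per-gene Cox p-values are uniform under the null and powered under a planted effect", {
  set.seed(41)
  n <- 100
  t <- rexp(n, 0.05); cens <- runif(n, 0, 40)
  d <- survival_data(pmin(t, cens), as.integer(t <= cens))
  genes <- matrix(rnorm(500 * n), 500)
  pg <- per_gene_pvalues(toy_matrix(genes), d)
  expect_gt(ks.test(pg$p, "punif")$p.value, 0.01)

  hits <- vapply(1:30, function(i) {
    set.seed(500 + i)
    x <- rnorm(300)
    tt <- rexp(300, 0.05 * exp(1 * x)); cc <- runif(300, 0, 40)
    dd <- survival_data(pmin(tt, cc), as.integer(tt <= cc))
    per_gene_pvalues(toy_matrix(matrix(x, 1)), dd)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  const <- per_gene_pvalues(toy_matrix(matrix(1, 1, n)), d)
  expect_equal(const$p, 1)
  expect_true(const$flagged)
})

test_that("LS and KS statistics match their closed forms and ignore ordering", {
  expect_equal(ls_stat(c(1, 1, 1)), 0)
  expect_equal(ks_stat(c(1, 1, 1)), 0)
  expect_equal(ls_stat(c(0.1, 0.01)), (-log(0.1) - log(0.01)) / 2)
  expect_equal(ks_stat(c(0.1, 0.2)), 0.8)   # max(1/2 - 0.1, 1 - 0.2)
  set.seed(6)
  p <- runif(20)
  expect_equal(ls_stat(p), ls_stat(rev(p)))
  expect_equal(ks_stat(p), ks_stat(sample(p)))
  expect_warning(out <- ls_stat(c(0, 0.5)), "clamped")
  expect_true(is.finite(out))
})

test_that("permutation p-values obey the add-one rule and its degeneracies", {
  universe <- setNames(rep(0.3, 50), sprintf("g%d", 1:50))
  res <- permutation_pvalue(sprintf("g%d", 1:10), universe, n_perm = 100, seed = 1)
  expect_equal(res$p_ls, 1)  # every null set has the same LS as the observed one
  expect_gt(res$p_ls, 0); expect_gt(res$p_ks, 0)
  expect_error(permutation_pvalue(sprintf("g%d", 1:60), universe, n_perm = 100),
               "universe")
  expect_error(permutation_pvalue("g1", universe, n_perm = 50), "n_perm")
  expect_true(permutation_pvalue(sprintf("g%d", 1:3), setNames(runif(30),
               sprintf("g%d", 1:30)), n_perm = 100, seed = 2)$too_small)
})

test_that("random-set controls are deterministic under a fixed seed", {
  universe <- setNames(runif(100), sprintf("g%d", 1:100))
  a <- random_set_control(universe, n_sets = 3, set_size = 10, n_perm = 100, seed = 4)
  b <- random_set_control(universe, n_sets = 3, set_size = 10, n_perm = 100, seed = 4)
  expect_identical(a$control_p_ls, b$control_p_ls)
  expect_identical(a$sets, b$sets)
  expect_error(random_set_control(universe[1:5], set_size = 10), "universe")
})

test_that("a planted coherent set beats its random controls", {
  set.seed(47)
  n <- 300
  x <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.8 * x)); cens <- runif(n, 0, 40)
  d <- survival_data(pmin(t, cens), as.integer(t <= cens))
  # 20 genes tracking the latent effect, 180 noise genes
  planted <- t(vapply(1:20, function(i) 0.7 * x + rnorm(n, sd = 0.7), numeric(n)))
  noise <- matrix(rnorm(180 * n), 180)
  mat <- toy_matrix(rbind(planted, noise))
  pg <- per_gene_pvalues(mat, d)
  universe <- setNames(pg$p, pg$gene_id)
  cand <- permutation_pvalue(sprintf("f%d", 1:20), universe, n_perm = 500, seed = 5)
  ctrl <- random_set_control(universe, n_sets = 10, set_size = 20,
                             n_perm = 500, seed = 6)
  expect_lte(cand$p_ls, 0.01)
  expect_true(all(cand$p_ls <= ctrl$control_p_ls))
})

test_that("EASE enrichment applies the decrement rule and matches direct summation", {
  bg <- sprintf("g%d", 1:100)
  pw <- list(path20 = bg[1:20])
  # overlap 1 -> p = 1
  r1 <- ease_enrichment(c(bg[1], bg[50:58]), bg, pw)
  expect_equal(r1$ease_p, 1)
  # list = pathway = background -> no enrichment possible
  r2 <- ease_enrichment(bg[1:20], bg[1:20], list(pw = bg[1:20]))
  expect_equal(r2$ease_p, 1)
  # list 10, background 100, pathway 20, overlap 8: tail with overlap 7
  glist <- c(bg[1:8], bg[90:91])
  r3 <- ease_enrichment(glist, bg, pw)
  expect_equal(r3$overlap, 8)
  expect_equal(r3$ease_p, sum(dhyper(7:10, 20, 80, 10)), tolerance = 1e-12)
  expect_error(ease_enrichment("g1", character(), pw), "background")
  expect_error(ease_enrichment("zz", bg, pw), "outside")
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("GMT collections and target maps parse their formats", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), gmt)
  coll <- read_gmt(gmt)
  expect_identical(coll$setA, c("g1", "g2", "g3"))
  writeLines("broken_line_without_genes", gmt)
  expect_error(read_gmt(gmt), "malformed")

  tm <- read_target_map(data.frame(
    mirna_id = c("m1", "m1", "m2"), gene_id = c("gA", "gB", "gC"),
    tier = c("restrictive", "expansive", "expansive")))
  expect_identical(tm$m1$restrictive, "gA")
  expect_setequal(tm$m1$expansive, c("gA", "gB"))
})

test_that("tiered gene-set survival applies the 20% variance filter to the expansive tier only", {
  co <- simulate_cohort(lean_config(seed = 91, n_samples = 80))
  surv <- survival_from_clinical(co$clinical)
  tm <- read_target_map(co$target_map)
  res_exp <- gene_set_survival(co$mrna, surv, tm, tier = "expansive",
                               n_perm = 200, seed = 1)
  expect_true(all(res_exp$set_size <= 8))
  # restrictive tier: 3 planted targets per miRNA -> all reported too small
  res_res <- gene_set_survival(co$mrna, surv, tm, tier = "restrictive",
                               n_perm = 200, seed = 1)
  expect_true(all(res_res$too_small))
  expect_true(all(is.na(res_res$p_ls)))
})
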