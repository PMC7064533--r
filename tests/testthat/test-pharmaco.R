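test_that("target ranking keeps the smallest p-values with the stated tie rule", {
  set.seed(71)
  p30 <- setNames(runif(30), sprintf("g%02d", 1:30))
  tm <- read_target_map(data.frame(mirna_id = "m1", gene_id = names(p30),
                                   tier = "expansive"))
  top <- rank_top_targets(p30, tm, top_n = 20)$m1
  expect_length(top, 20)
  expect_setequal(top, names(sort(p30))[1:20])
  expect_identical(top, top[order(p30[top], top)])

  # fewer available targets than top_n: all retained
  tm15 <- read_target_map(data.frame(mirna_id = "m1", gene_id = names(p30)[1:15],
                                     tier = "expansive"))
  expect_length(rank_top_targets(p30, tm15, top_n = 20)$m1, 15)

  # tie at the cut: lexicographically smaller gene id wins
  ptie <- setNames(c(rep(0.01, 2), rep(0.5, 3)), c("gB", "gA", "gE", "gC", "gD"))
  tmt <- read_target_map(data.frame(mirna_id = "m1", gene_id = names(ptie),
                                    tier = "expansive"))
  top3 <- rank_top_targets(ptie, tmt, top_n = 3)$m1
  expect_identical(top3, c("gA", "gB", "gC"))

  # unavailable p-values are excluded with a log message
  expect_message(rank_top_targets(p30[1:10], tm, top_n = 20), "no p-value")
})

test_that("stage-1 association filter uses strict inequalities on both thresholds", {
  assoc <- data.frame(drug_id = c("d1", "d2", "d3", "d4"),
                      gene_id = c("g1", "g1", "g1", "g1"),
                      coefficient = c(0.25, 0.30, 0.30, -0.40),
                      p = c(0.0005, 0.0005, 0.001, 0.0001))
  out <- filter_associations(assoc)
  expect_setequal(out$drug_id, c("d2", "d4"))  # 0.25 exactly and p = 0.001 fail
  # relaxed mode admits (0.20, 0.01) which the defaults exclude
  row <- data.frame(drug_id = "d5", gene_id = "g1", coefficient = 0.20, p = 0.01)
  expect_equal(nrow(filter_associations(row)), 0)
  expect_equal(nrow(filter_associations(row, drug_filter_config(relaxed = TRUE))), 1)
})

test_that("stage-2 network rule is a conjunction counted over distinct genes", {
  cfg <- drug_filter_config()
  n22 <- sprintf("n%d", 1:10); n5 <- sprintf("n%d", 1:2)
  hit <- function(drug, genes) data.frame(drug_id = drug, gene_id = genes,
                                          coefficient = 0.5, p = 1e-5)
  # 3 hits in the 22-network but none in the 5-network: excluded
  h1 <- hit("dA", c("n3", "n4", "n5"))
  expect_length(select_drugs(h1, n22, n5, cfg), 0)
  # 4 hits of which 1 in the 5-network: retained
  h2 <- hit("dB", c("n1", "n3", "n4", "n5"))
  expect_identical(select_drugs(h2, n22, n5, cfg), "dB")
  # repeated experiment rows for one gene count once
  h3 <- hit("dC", c("n1", "n1", "n1", "n2"))
  expect_length(select_drugs(h3, n22, n5, cfg), 0)
})

test_that("a toy table with two planted passing drugs returns exactly those two", {
  set.seed(73)
  n22 <- sprintf("n%d", 1:12); n5 <- sprintf("n%d", 1:3)
  rows <- list()
  for (d in sprintf("d%02d", 1:10)) {
    if (d %in% c("d03", "d07")) {
      rows[[d]] <- data.frame(drug_id = d, gene_id = c("n1", "n4", "n5"),
                              coefficient = 0.4, p = 1e-4)
    } else {
      rows[[d]] <- data.frame(drug_id = d, gene_id = sample(n22, 3),
                              coefficient = 0.1, p = 0.5)
    }
  }
  assoc <- do.call(rbind, rows)
  hits <- filter_associations(assoc)
  got <- select_drugs(hits, n22, n5)
  # exhaustive enumeration oracle over all drugs
  expected <- character()
  for (d in unique(assoc$drug_id)) {
    sub <- assoc[assoc$drug_id == d & abs(assoc$coefficient) > 0.25 & assoc$p < 0.001, ]
    g <- unique(sub$gene_id)
    if (sum(g %in% n22) >= 3 && sum(g %in% n5) >= 1) expected <- c(expected, d)
  }
  expect_setequal(got, expected)
  expect_setequal(got, c("d03", "d07"))
})

test_that("stage-3 IC50 ranking flags, excludes and sorts as stated", {
  sens <- data.frame(
    drug_id = c(rep("ref", 4), rep("cheap", 5), rep("pricey", 4), "single"),
    cell_line_id = sprintf("c%d", 1:14),
    ic50_um = c(8, 9, 8.4, 8.6, 1, 1.2, 0.9, 1.1, 1.3, 20, 22, 25, 21, 3.3))
  out <- rank_by_ic50(c("cheap", "pricey", "single", "nodata"), sens, "ref")
  expect_identical(out$drug_id[1:3], c("cheap", "single", "pricey"))
  expect_true(out$passes_ic50[out$drug_id == "cheap"])
  expect_false(out$passes_ic50[out$drug_id == "pricey"])
  expect_true(out$limited_evidence[out$drug_id == "single"])
  expect_equal(out$median_ic50[out$drug_id == "single"], 3.3)  # median of one
  expect_true(out$no_sensitivity_data[out$drug_id == "nodata"])
  # even count: midpoint interpolation
  expect_equal(attr(out, "reference_median"), (8.4 + 8.6) / 2)
  expect_error(rank_by_ic50("cheap", sens, "ghost"), "ghost")
})

test_that("a drug exactly at the reference median passes (<= rule)", {
  sens <- data.frame(drug_id = c("ref", "edge"), cell_line_id = c("c1", "c2"),
                     ic50_um = c(5, 5))
  out <- rank_by_ic50("edge", sens, "ref")
  expect_true(out$passes_ic50)
})

test_that("the staged screen is monotone in its thresholds on random tables", {
  set.seed(79)
  for (i in 1:15) {
    assoc <- data.frame(drug_id = sample(sprintf("d%d", 1:12), 60, replace = TRUE),
                        gene_id = sample(sprintf("g%d", 1:15), 60, replace = TRUE),
                        coefficient = runif(60, -0.6, 0.6),
                        p = runif(60)^2)
    n22 <- sprintf("g%d", 1:15); n5 <- sprintf("g%d", 1:4)
    strict <- drug_filter_config()
    loose <- drug_filter_config(coef_threshold = 0.1, p_threshold = 0.05,
                                min_hits_22 = 1, min_hits_5 = 0)
    s_strict <- select_drugs(filter_associations(assoc, strict), n22, n5, strict)
    s_loose <- select_drugs(filter_associations(assoc, loose), n22, n5, loose)
    expect_true(all(s_strict %in% s_loose),
                info = sprintf("instance %d", i))
  }
})

test_that("planted drugs survive the full screen and inert drugs do not", {
  co <- simulate_cohort(sim_config(n_samples = 40, n_noise_features = 4,
                                   n_drugs = 12, n_active_drugs = 3,
                                   n_cell_lines = 6, seed = 83))
  screen <- drug_screen(co$drug_assoc, co$ic50, co$truth$network_22,
                        co$truth$network_5)
  expect_true(all(co$truth$planted_drugs %in% screen$final$drug_id))
  inert <- setdiff(unique(co$drug_assoc$drug_id), co$truth$planted_drugs)
  expect_length(intersect(inert, screen$final$drug_id), 0)
  # stage flags are nested
  rep <- screen$report
  expect_true(all(!rep$passes_stage2 | rep$passes_stage1))
  expect_true(all(!rep$passes_stage3 | rep$passes_stage2))
})

test_that("the published candidate table reproduces the final list of 19 drugs", {
  tab <- osteosarcoma_drug_table()
  expect_equal(nrow(tab), 22)
  candidates <- tab$name[!tab$comparator]
  sens <- data.frame(drug_id = tab$name, cell_line_id = "median_proxy",
                     ic50_um = tab$median_ic50_um)
  ranked <- rank_by_ic50(candidates, sens, "cisplatin")
  expect_equal(sum(ranked$passes_ic50), 19)
  expect_equal(attr(ranked, "reference_median"), 8.414)
})
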