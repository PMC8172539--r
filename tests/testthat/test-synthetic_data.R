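test_that("generator is a pure function of config and seed", {
  cfg <- expression_sim_config(clusters = null_roster(50, 50), n_genes = 200,
                               n_gpcr = 40, seed = 31)
  a <- make_expression_dataset(cfg)
  b <- make_expression_dataset(cfg)
  expect_identical(as.matrix(a$dataset$matrix), as.matrix(b$dataset$matrix))
  expect_identical(a$cells, b$cells)
  expect_identical(a$genes, b$genes)
  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_expression(a$dataset, file.path(d1, "m.mtx"), file.path(d1, "g.txt"),
                   file.path(d1, "c.txt"))
  write_expression(b$dataset, file.path(d2, "m.mtx"), file.path(d2, "g.txt"),
                   file.path(d2, "c.txt"))
  expect_identical(readLines(file.path(d1, "m.mtx")),
                   readLines(file.path(d2, "m.mtx")))
})

test_that("default roster reproduces the reference composition", {
  roster <- default_cluster_roster()
  expect_equal(sum(roster$n_cells), 5190L)
  expect_equal(roster$n_cells[roster$cluster == "L4/5 IT"], 1238L)
  expect_equal(sum(roster$n_reporter), 676L)
  expect_equal(roster$n_reporter[roster$cluster == "L4/5 IT"], 502L)
})

test_that("planted markers hit their fold and detection targets", {
  # the contrast set detects the marker in only ~5% of cells, so a single
  # draw of the mean ratio is noisy; average the sampling check over seeds
  ratios <- sapply(17:19, function(s) {
    cfg <- expression_sim_config(clusters = null_roster(500, 500),
                                 n_genes = 300, n_gpcr = 50, seed = s)
    sim <- make_expression_dataset(cfg)
    planted <- sim$truth$gene[1]
    target <- sim$cells$cell_id[sim$cells$cluster == "L4/5 IT"]
    contrast <- sim$cells$cell_id[sim$cells$cluster == "Pvalb"]
    ge_t <- set_mean_expression(sim$dataset, target)
    ge_c <- set_mean_expression(sim$dataset, contrast)
    ge_t$ge[ge_t$gene == planted] / ge_c$ge[ge_c$gene == planted]
  })
  expect_lt(abs(mean(ratios) - 10) / 10, 0.2)

  cfg <- expression_sim_config(clusters = null_roster(500, 500), n_genes = 300,
                               n_gpcr = 50, seed = 17)
  sim <- make_expression_dataset(cfg)
  planted <- sim$truth$gene[1]
  target <- sim$cells$cell_id[sim$cells$cluster == "L4/5 IT"]
  contrast <- sim$cells$cell_id[sim$cells$cluster == "Pvalb"]
  pct_t <- detection_fraction(sim$dataset, target)[planted]
  pct_c <- detection_fraction(sim$dataset, contrast)[planted]
  expect_lt(abs(pct_t - 0.9), 0.05)
  expect_lt(abs(pct_c - 0.05), 0.03)
})

test_that("infeasible planted configurations are rejected", {
  expect_error(
    expression_sim_config(planted = tibble::tibble(
      coupling = "Gi", fold = 10, pct_t = 1.4, pct_c = 0.05, base_cpm = 3
    )),
    class = "impulscreen_configuration_error"
  )
  expect_error(
    expression_sim_config(planted = tibble::tibble(
      coupling = "Gi", fold = -1, pct_t = 0.9, pct_c = 0.05, base_cpm = 3
    )),
    class = "impulscreen_configuration_error"
  )
})

test_that("generated bundles round-trip through the readers unchanged", {
  cfg <- expression_sim_config(clusters = null_roster(30, 30), n_genes = 80,
                               n_gpcr = 20, seed = 5)
  sim <- make_expression_dataset(cfg)
  dir <- withr::local_tempdir()
  write_expression(sim$dataset, file.path(dir, "m.mtx"),
                   file.path(dir, "g.txt"), file.path(dir, "c.txt"))
  write_annotation(sim$cells, file.path(dir, "cells.csv"))
  write_annotation(sim$genes, file.path(dir, "genes.csv"))
  back <- read_expression(file.path(dir, "m.mtx"), file.path(dir, "g.txt"),
                          file.path(dir, "c.txt"))
  expect_equal(as.matrix(back$matrix), as.matrix(sim$dataset$matrix),
               ignore_attr = TRUE)
  ann <- read_annotations(file.path(dir, "cells.csv"),
                          file.path(dir, "genes.csv"))
  expect_equal(ann$cells$class, sim$cells$class)
  expect_equal(ann$genes$coupling, sim$genes$coupling)
  expect_silent(validate_annotation_coverage(back, ann$cells))
})

test_that("simulated cohorts carry planted drug effects in both directions", {
  gi <- agent_params(drug_multipliers = list(cno = list(premature_hazard = 0.3)))
  gq <- agent_params(drug_multipliers = list(cno = list(premature_hazard = 3)))
  cfg <- cohort_sim_config(
    groups = list(gi = list(n = 8, agent = gi), gq = list(n = 8, agent = gq)),
    spec = "fiti9", seed = 21
  )
  cohort <- make_cohort(cfg)
  expect_equal(nrow(cohort$sessions), 32L)  # 16 subjects x 2 conditions
  metrics <- cohort_metrics(cohort)
  res <- challenge_table(metrics)
  prem <- dplyr::filter(res$tests, parameter == "pct_premature")
  expect_lt(prem$mean_log_ratio[prem$group == "gi"], 0)
  expect_gt(prem$mean_log_ratio[prem$group == "gq"], 0)
})

test_that("null cohorts centre the paired premature difference on zero", {
  null_agent <- agent_params(drug_multipliers = list(cno = list(premature_hazard = 1)))
  cfg <- cohort_sim_config(groups = list(ctrl = list(n = 12, agent = null_agent)),
                           spec = "fiti9", seed = 33)
  metrics <- cohort_metrics(make_cohort(cfg))
  wide <- tidyr::pivot_wider(
    dplyr::select(metrics, subject, condition, pct_premature),
    names_from = condition, values_from = pct_premature
  )
  d <- wide$cno - wide$vehicle
  expect_lt(abs(mean(d)) / sd(d), 1.5)  # within ~1.5 SEM-scaled units of 0
})
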