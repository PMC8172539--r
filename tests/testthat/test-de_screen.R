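test_that("build_comparison assembles target and contrast sets by level", {
  cells <- tiny_cells()
  cmp1 <- build_comparison(cells, "reporter", 1)
  expect_equal(length(cmp1$set_t), 4L)
  expect_equal(length(cmp1$set_c), 3L)

  cells2 <- dplyr::bind_rows(cells, tibble::tibble(
    cell_id = c("l6a", "l6b2", "l23a"),
    class = "glutamatergic",
    cluster = c("L6 IT", "L6 CT", "L2/3 IT"),
    reporter_positive = FALSE, region = "ACA"
  ))
  expect_equal(length(build_comparison(cells2, "reporter", 2)$set_c), 7L)
  expect_equal(length(build_comparison(cells2, "reporter", 3)$set_c), 8L)

  # overlap resolution: a reporter-positive L2/3 cell stays in Set-T
  cells3 <- cells2
  cells3$reporter_positive[cells3$cell_id == "l23a"] <- TRUE
  cmp3 <- build_comparison(cells3, "reporter", 3)
  expect_true("l23a" %in% cmp3$set_t)
  expect_false("l23a" %in% cmp3$set_c)
  expect_length(intersect(cmp3$set_t, cmp3$set_c), 0)

  no_l45 <- dplyr::mutate(cells, cluster = sub("L4/5 IT", "L6 IT", cluster))
  expect_error(build_comparison(no_l45, "cluster", 1),
               class = "impulscreen_configuration_error")
})

test_that("set means use the zero-preserving pseudocounted log2 transform", {
  m <- rbind(c(0, 0), c(3, 5), c(7, 7))
  ds <- expression_dataset(m, c("zero", "ab", "cc"), c("c1", "c2"))
  res <- set_mean_expression(ds, c("c1", "c2"))
  expect_equal(res$ge, c(0, 4, 7))
  expect_equal(res$expr, c(0, log2(5), 3))
  single <- set_mean_expression(ds, "c2")
  expect_equal(single$ge, c(0, 5, 7))
  expect_error(set_mean_expression(ds, character(0)),
               class = "impulscreen_argument_error")
})

test_that("diff_mean matches the fold-change thresholds", {
  expect_equal(diff_mean(2.5, 2.5), 0)
  expect_equal(diff_mean(log2(1 + 3), log2(1 + 0)), 2)
  # for well-expressed genes the pseudocount vanishes: ratio 3 ~ 1.58
  expect_equal(diff_mean(log2(1 + 3e6), log2(1 + 1e6)), log2(3),
               tolerance = 1e-5)
  expect_equal(round(log2(3), 2), 1.58)
})

test_that("detection fractions count cells at the CPM threshold", {
  m <- rbind(c(0, 1, 2, 0.5), c(0, 0, 0, 0))
  ds <- expression_dataset(m, c("a", "b"), paste0("c", 1:4))
  expect_equal(unname(detection_fraction(ds, paste0("c", 1:4))), c(0.5, 0))
  expect_equal(unname(detection_fraction(ds, paste0("c", 1:4), threshold = 0)),
               c(1, 1))
})

test_that("beta is the signed detection-fraction separation", {
  expect_equal(beta_statistic(0.8, 0.1, 1.2), 0.7)
  expect_equal(beta_statistic(0.1, 0.8, -0.4), -0.7)
  expect_equal(beta_statistic(0.9, 0.1, 0), 0)
})

test_that("bonferroni caps at 1 and rejects empty families", {
  expect_equal(bonferroni(0.001, 10), 0.01)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(c(0.2, 0.7), 1), c(0.2, 0.7))
  expect_error(bonferroni(0.1, 0), class = "impulscreen_argument_error")
})

test_that("rank-sum p equals exhaustive enumeration on small exact cases", {
  expect_equal(wilcox_p_vec(c(10, 11, 12), c(0, 1, 2)), 0.1)
  # constant gene: no separation
  expect_equal(wilcox_p_vec(c(5, 5, 5), c(5, 5, 5)), 1)
  withr::with_seed(42, {
    for (rep in 1:10) {
      n_t <- sample(2:6, 1); n_c <- sample(2:6, 1)
      v <- sample(seq_len(50), n_t + n_c)  # distinct values
      x <- v[seq_len(n_t)]; y <- v[-seq_len(n_t)]
      expect_equal(wilcox_p_vec(x, y), ranksum_enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact oracle on 5-vs-5 genes", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      x <- runif(5, 0, 10); y <- runif(5, 0, 10)
      approx_p <- wilcox_p_vec(x, y, exact_max = 0)
      expect_lt(abs(approx_p - ranksum_enum_p(x, y)), 0.02)
    }
  })
})

test_that("rank-sum p agrees with stats::wilcox.test on tied data", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      x <- sample(0:5, 30, replace = TRUE)   # heavy ties
      y <- sample(0:5, 25, replace = TRUE) + rbinom(25, 1, 0.3)
      ref <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      expect_equal(wilcox_p_vec(x, y), ref, tolerance = 1e-9)
    }
  })
})

test_that("screen_comparison flags planted genes and rejects near-misses", {
  withr::with_seed(123, {
    n <- 100
    planted <- c(rlnorm(n, log(50 / 0.9), 0.3) * rbinom(n, 1, 0.9),
                 rlnorm(n, log(1 / 0.05), 0.3) * rbinom(n, 1, 0.05))
    housekeeping <- rlnorm(2 * n, log(20), 0.4)
    # ~2.5-fold gene: significant but below the threefold criterion
    mild <- c(rlnorm(n, log(2.4), 0.2), rlnorm(n, log(1), 0.2))
    m <- rbind(planted, housekeeping, mild)
    ds <- expression_dataset(m, c("marker", "hk", "mild"),
                             sprintf("c%03d", 1:(2 * n)))
    cells <- tibble::tibble(
      cell_id = ds$cell_ids,
      class = rep(c("glutamatergic", "GABAergic"), each = n),
      cluster = rep(c("L4/5 IT", "Pvalb"), each = n),
      reporter_positive = rep(c(TRUE, FALSE), each = n), region = "ACA"
    )
    cmp <- build_comparison(cells, "reporter", 1)
    rec <- screen_comparison(ds, cmp)
    expect_true(rec$passes_primary[rec$gene == "marker"])
    expect_true(rec$tenfold_flag[rec$gene == "marker"])
    expect_false(rec$passes_primary[rec$gene == "hk"])
    mild_row <- rec[rec$gene == "mild", ]
    expect_lt(mild_row$p_bonf, 0.05)        # significant...
    expect_false(mild_row$passes_primary)   # ...but fails the fold criterion
    # record invariants
    expect_true(all(rec$p_bonf >= rec$p_raw))
    expect_true(all(rec$p_bonf <= 1))
    expect_true(all(rec$beta >= -1 & rec$beta <= 1))
    expect_true(all(sign(rec$beta) == sign(rec$diff_mean) |
                      rec$beta == 0 | rec$diff_mean == 0))
  })
})

test_that("identical target/contrast expression yields zero diff and beta", {
  m <- rbind(c(3, 7, 3, 7), c(0, 2, 0, 2))
  ds <- expression_dataset(m, c("a", "b"), paste0("c", 1:4))
  cells <- tibble::tibble(
    cell_id = ds$cell_ids, class = c("glutamatergic", "glutamatergic",
                                     "GABAergic", "GABAergic"),
    cluster = c("L4/5 IT", "L4/5 IT", "Pvalb", "Pvalb"),
    reporter_positive = c(TRUE, TRUE, FALSE, FALSE), region = "ACA"
  )
  rec <- screen_comparison(ds, build_comparison(cells, "reporter", 1))
  expect_equal(rec$diff_mean, c(0, 0))
  expect_equal(rec$beta, c(0, 0))
  expect_equal(rec$p_raw, c(1, 1))
})

test_that("scaling all CPM values leaves the rank-sum p unchanged", {
  withr::with_seed(5, {
    x <- rlnorm(20, 1, 1); y <- rlnorm(20, 0.5, 1)
    p1 <- wilcox_p_vec(x, y)
    p2 <- wilcox_p_vec(10 * x, 10 * y)
    expect_identical(p1, p2)
    # detection fractions scale with the threshold
    m <- matrix(c(x, y), nrow = 1)
    ds1 <- expression_dataset(m, "g", paste0("c", 1:40))
    ds2 <- expression_dataset(10 * m, "g", paste0("c", 1:40))
    expect_equal(detection_fraction(ds1, ds1$cell_ids, 1),
                 detection_fraction(ds2, ds2$cell_ids, 10))
  })
})

test_that("rank_candidates filters on coupling and pass pattern", {
  recs <- tibble::tibble(
    gene = rep(c("gi_hit", "gq_hit", "partial"), each = 2),
    comparison = rep(c("reporter_L1", "cluster_L1"), 3),
    diff_mean = c(3, 2.5, 4, 3.5, 3, 0.1),
    beta = c(0.8, 0.7, 0.9, 0.8, 0.6, 0.0),
    expr_c = c(0.5, 0.6, 0.2, 0.3, 1, 1),
    tenfold_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    passes_primary = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  genes <- tibble::tibble(
    gene_id = c("gi_hit", "gq_hit", "partial"),
    is_gpcr = TRUE, coupling = c("Gi", "Gq", "Gi"), is_sensory = FALSE
  )
  gi <- rank_candidates(recs, genes, coupling_filter = "Gi")
  expect_equal(gi$gene, "gi_hit")
  expect_equal(gi$rank, 1L)
  expect_true(gi$tenfold_all)

  any_c <- rank_candidates(recs, genes, coupling_filter = "any")
  expect_equal(any_c$gene, c("gq_hit", "gi_hit"))  # higher min diff_mean first

  none <- rank_candidates(recs[recs$gene == "partial", ], genes)
  expect_equal(nrow(none), 0L)

  expect_error(rank_candidates(recs, genes, require_all = "nonexistent"),
               class = "impulscreen_argument_error")
})
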