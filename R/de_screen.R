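#' Build a target/contrast comparison from cell annotations
#'
#' Defines the two cell sets of one differential-expression comparison. The
#' target set (Set-T) is either the reporter-positive glutamatergic cells
#' (`target_mode = "reporter"`, the fluorescence pull) or all cells in the
#' layer-4/5 intratelencephalic clusters (`target_mode = "cluster"`). The
#' contrast set (Set-C) grows with `contrast_level`:
#' level 1 = GABAergic cells only (least conservative);
#' level 2 = adds non-neuronal cells and layer-6 glutamatergic clusters;
#' level 3 = adds layer-2/3 glutamatergic clusters (most conservative).
#' A cell eligible for both pools is assigned to Set-T and removed from Set-C,
#' preserving disjointness.
#'
#' @param cells Cell annotation tibble (`cell_id`, `class`, `cluster`,
#'   `reporter_positive`).
#' @param target_mode `"reporter"` or `"cluster"`.
#' @param contrast_level 1, 2 or 3.
#' @param target_clusters,l6_clusters,l23_clusters Regular expressions matched
#'   against cluster labels of glutamatergic cells. Override for annotation
#'   vocabularies that name layer-5 clusters differently (e.g. human data).
#' @param name Comparison name; default `"<mode>_L<level>"`.
#' @return A list of class `comparison_definition` with elements `name`,
#'   `target_mode`, `contrast_level`, `set_t`, `set_c`.
#' @export
build_comparison <- function(cells,
                             target_mode = c("reporter", "cluster"),
                             contrast_level = 1,
                             target_clusters = "^L4/5",
                             l6_clusters = "^L6",
                             l23_clusters = "^L2/3",
                             name = NULL) {
  target_mode <- match.arg(target_mode)
  stopifnot(contrast_level %in% 1:3)
  if (is.null(name)) name <- sprintf("%s_L%d", target_mode, contrast_level)

  glut <- cells$class == "glutamatergic"
  in_target_cluster <- glut & grepl(target_clusters, cells$cluster)
  set_t <- if (target_mode == "reporter") {
    cells$cell_id[glut & cells$reporter_positive]
  } else {
    if (!any(in_target_cluster)) {
      abort(sprintf("no glutamatergic cluster matches '%s'", target_clusters),
            class = "impulscreen_configuration_error")
    }
    cells$cell_id[in_target_cluster]
  }

  in_c <- cells$class == "GABAergic"
  if (contrast_level >= 2) {
    in_c <- in_c | cells$class == "non-neuronal" |
      (glut & grepl(l6_clusters, cells$cluster))
  }
  if (contrast_level >= 3) {
    in_c <- in_c | (glut & grepl(l23_clusters, cells$cluster))
  }
  set_c <- setdiff(cells$cell_id[in_c], set_t)

  if (!length(set_t)) {
    abort(sprintf("comparison '%s': target set is empty", name),
          class = "impulscreen_configuration_error")
  }
  if (!length(set_c)) {
    abort(sprintf("comparison '%s': contrast set at level %d is empty",
                  name, contrast_level),
          class = "impulscreen_configuration_error")
  }
  structure(
    list(name = name, target_mode = target_mode,
         contrast_level = as.integer(contrast_level),
         set_t = set_t, set_c = set_c),
    class = "comparison_definition"
  )
}

#' @export
print.comparison_definition <- function(x, ...) {
  cat(sprintf("<comparison_definition> %s: |Set-T| = %d, |Set-C| = %d (level %d)\n",
              x$name, length(x$set_t), length(x$set_c), x$contrast_level))
  invisible(x)
}

#' Per-gene mean expression over a cell set
#'
#' `ge` is the arithmetic mean CPM of each gene across the set's cells; `expr`
#' is `log2(1 + ge)`, so a gene with zero CPM everywhere has expression 0.
#'
#' @param ds An [expression_dataset()].
#' @param cell_ids Non-empty subset of the dataset's cells.
#' @return A tibble with columns `gene`, `ge`, `expr`.
#' @export
set_mean_expression <- function(ds, cell_ids) {
  if (!length(cell_ids)) {
    abort("cell set is empty", class = "impulscreen_argument_error")
  }
  unknown <- setdiff(cell_ids, ds$cell_ids)
  if (length(unknown)) {
    abort(paste0("cell ids absent from dataset: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "impulscreen_argument_error")
  }
  ge <- Matrix::rowMeans(ds$matrix[, match(cell_ids, ds$cell_ids), drop = FALSE])
  tibble(gene = ds$gene_ids, ge = unname(ge), expr = log2(1 + unname(ge)))
}

#' Log2 fold-change between pseudocounted set means
#'
#' `diff_mean = expr_t - expr_c` with `expr = log2(1 + GE)`; for well-expressed
#' genes this converges to the plain log2 ratio of set means, and it stays
#' finite when the contrast mean is 0. The threefold selection criterion
#' corresponds to `diff_mean > log2(3) ~ 1.58` in that regime.
#'
#' @param expr_t,expr_c Pseudocounted log2 mean expression values.
#' @return `expr_t - expr_c`.
#' @export
diff_mean <- function(expr_t, expr_c) expr_t - expr_c

#' Per-gene detection fraction in a cell set
#'
#' Fraction of the set's cells in which the gene is detected at
#' `CPM >= threshold` (default 1, the conventional detection threshold).
#'
#' @param ds An [expression_dataset()].
#' @param cell_ids Non-empty subset of the dataset's cells.
#' @param threshold Detection threshold on the CPM scale, >= 0.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
detection_fraction <- function(ds, cell_ids, threshold = 1) {
  if (!length(cell_ids)) {
    abort("cell set is empty", class = "impulscreen_argument_error")
  }
  stopifnot(threshold >= 0)
  m <- ds$matrix[, match(cell_ids, ds$cell_ids), drop = FALSE]
  if (threshold == 0) {
    out <- rep(1, nrow(m))           # every value >= 0 counts as detected
  } else {
    out <- Matrix::rowSums(m >= threshold) / ncol(m)
  }
  setNames(as.numeric(out), ds$gene_ids)
}

#' Signed detection-fraction separation (Beta)
#'
#' `beta = s * |pct_t - pct_c|`, where `s` is the sign of the differential
#' expression (`diff_mean`); `sign(0)` is defined as 0, so a gene with equal
#' set means has `beta = 0` regardless of the detection fractions.
#'
#' @param pct_t,pct_c Detection fractions in `[0, 1]`.
#' @param diff_mean Log2 fold-change whose sign orients beta.
#' @return Beta in `[-1, 1]`.
#' @export
beta_statistic <- function(pct_t, pct_c, diff_mean) {
  sign(diff_mean) * abs(pct_t - pct_c)
}

#' Bonferroni correction
#'
#' @param p_raw Numeric vector of raw p-values.
#' @param m Number of comparisons in the family, >= 1.
#' @return `min(1, m * p_raw)`, elementwise.
#' @export
bonferroni <- function(p_raw, m) {
  if (m < 1) abort("m must be >= 1", class = "impulscreen_argument_error")
  pmin(1, m * p_raw)
}

#' Run one differential-expression comparison over all genes
#'
#' Computes, per gene: set mean expression (`ge_t`, `ge_c`, and their
#' pseudocounted log2 transforms `expr_t`, `expr_c`), the log2 fold-change
#' `diff_mean`, detection fractions `pct_t`, `pct_c`, the signed separation
#' `beta`, the Wilcoxon rank-sum p-value (`p_raw`) and its Bonferroni
#' correction (`p_bonf`). A gene `passes_primary` when `p_bonf < alpha`,
#' `diff_mean > 0`, and the pseudocounted mean ratio
#' `(1 + ge_t) / (1 + ge_c) >= fold_min`; `tenfold_flag` applies the same
#' ratio criterion with `tenfold`.
#'
#' @param ds An [expression_dataset()].
#' @param comparison A [build_comparison()] definition.
#' @param alpha Significance level on the corrected p (default 0.05).
#' @param fold_min Primary fold criterion on the pseudocounted mean ratio
#'   (default 3).
#' @param tenfold Secondary fold criterion (default 10).
#' @param bonferroni_m Family size for the correction; default = number of
#'   genes in the matrix. Use 402 to reproduce a GPCR-only family.
#' @param detection_threshold CPM detection threshold (default 1).
#' @param exact_max Passed to [wilcoxon_de()].
#' @return A tibble with one row per gene and columns `gene`, `comparison`,
#'   `ge_t`, `ge_c`, `expr_t`, `expr_c`, `diff_mean`, `pct_t`, `pct_c`,
#'   `beta`, `p_raw`, `p_bonf`, `passes_primary`, `tenfold_flag`.
#' @export
screen_comparison <- function(ds, comparison, alpha = 0.05, fold_min = 3,
                              tenfold = 10, bonferroni_m = NULL,
                              detection_threshold = 1, exact_max = 8) {
  stopifnot(inherits(comparison, "comparison_definition"))
  if (is.null(bonferroni_m)) bonferroni_m <- nrow(ds$matrix)
  t_stats <- set_mean_expression(ds, comparison$set_t)
  c_stats <- set_mean_expression(ds, comparison$set_c)
  pct_t <- detection_fraction(ds, comparison$set_t, detection_threshold)
  pct_c <- detection_fraction(ds, comparison$set_c, detection_threshold)
  p_raw <- wilcoxon_de(ds, comparison$set_t, comparison$set_c,
                       exact_max = exact_max)
  dm <- diff_mean(t_stats$expr, c_stats$expr)
  ratio <- (1 + t_stats$ge) / (1 + c_stats$ge)
  p_bonf <- bonferroni(p_raw, bonferroni_m)
  tibble(
    gene = ds$gene_ids,
    comparison = comparison$name,
    ge_t = t_stats$ge, ge_c = c_stats$ge,
    expr_t = t_stats$expr, expr_c = c_stats$expr,
    diff_mean = dm,
    pct_t = unname(pct_t), pct_c = unname(pct_c),
    beta = beta_statistic(unname(pct_t), unname(pct_c), dm),
    p_raw = unname(p_raw), p_bonf = unname(p_bonf),
    passes_primary = p_bonf < alpha & dm > 0 & ratio >= fold_min,
    tenfold_flag = p_bonf < alpha & dm > 0 & ratio >= tenfold
  )
}

#' Run a grid of comparisons
#'
#' Convenience wrapper running [screen_comparison()] for every combination of
#' target mode and contrast level (the full grid is 2 x 3 = 6 comparisons).
#'
#' @param ds An [expression_dataset()].
#' @param cells Cell annotation tibble.
#' @param target_modes,contrast_levels Grid axes.
#' @param ... Passed to [screen_comparison()] and [build_comparison()].
#' @inheritParams build_comparison
#' @inheritParams screen_comparison
#' @return An object of class `screen_grid`: list with `records` (stacked
#'   per-gene tibble) and `comparisons` (the definitions).
#' @export
screen_grid <- function(ds, cells,
                        target_modes = c("reporter", "cluster"),
                        contrast_levels = 1:3,
                        target_clusters = "^L4/5",
                        l6_clusters = "^L6", l23_clusters = "^L2/3",
                        ...) {
  validate_annotation_coverage(ds, cells)
  grid <- expand.grid(mode = target_modes, level = contrast_levels,
                      stringsAsFactors = FALSE)
  comparisons <- purrr::pmap(grid, function(mode, level) {
    build_comparison(cells, target_mode = mode, contrast_level = level,
                     target_clusters = target_clusters,
                     l6_clusters = l6_clusters, l23_clusters = l23_clusters)
  })
  records <- purrr::map(comparisons, function(cmp) {
    screen_comparison(ds, cmp, ...)
  }) %>% bind_rows()
  structure(list(records = records, comparisons = comparisons),
            class = "screen_grid")
}

#' @export
print.screen_grid <- function(x, ...) {
  cat(sprintf("<screen_grid> %d comparisons x %d genes; %d passing records\n",
              length(x$comparisons),
              length(unique(x$records$gene)),
              sum(x$records$passes_primary)))
  invisible(x)
}

#' Rank GPCR candidates across comparisons
#'
#' Keeps genes annotated as GPCRs (optionally excluding sensory receptors)
#' that pass the primary criteria in every required comparison and whose
#' coupling class matches `coupling_filter`. Candidates are ordered by
#' descending minimum `diff_mean` across the required comparisons, then
#' descending minimum `beta`, then ascending maximum contrast expression
#' `expr_c` (low off-target expression wins), with alphabetical tie-break.
#'
#' @param records Screen records across comparisons (from [screen_grid()] or
#'   stacked [screen_comparison()] outputs).
#' @param genes Gene annotation tibble (`gene_id`, `is_gpcr`, `coupling`,
#'   `is_sensory`).
#' @param coupling_filter `"Gi"`, `"Gq"`, `"Gs"` or `"any"`.
#' @param require_all Character vector of comparison names that a candidate
#'   must pass; default all comparisons present in `records`.
#' @param exclude_sensory Drop genes flagged `is_sensory` (the non-sensory
#'   GPCR restriction used for human data).
#' @return A tibble of class `candidate_table` with columns `gene`,
#'   `coupling`, `n_passed`, `min_diff_mean`, `min_beta`, `max_expr_c`,
#'   `tenfold_all`, `rank`.
#' @export
rank_candidates <- function(records, genes, coupling_filter = "Gi",
                            require_all = NULL, exclude_sensory = FALSE) {
  if (inherits(records, "screen_grid")) records <- records$records
  have <- unique(records$comparison)
  if (is.null(require_all)) require_all <- have
  unknown <- setdiff(require_all, have)
  if (length(unknown)) {
    abort(paste0("unknown comparison name(s): ", paste(unknown, collapse = ", ")),
          class = "impulscreen_argument_error")
  }
  gpcr <- genes %>% filter(.data$is_gpcr)
  if (exclude_sensory) gpcr <- gpcr %>% filter(!.data$is_sensory)
  if (coupling_filter != "any") {
    gpcr <- gpcr %>% filter(.data$coupling == coupling_filter)
  }
  cand <- records %>%
    filter(.data$comparison %in% require_all,
           .data$gene %in% gpcr$gene_id) %>%
    group_by(.data$gene) %>%
    summarise(
      n_passed = sum(.data$passes_primary),
      min_diff_mean = min(.data$diff_mean),
      min_beta = min(.data$beta),
      max_expr_c = max(.data$expr_c),
      tenfold_all = all(.data$tenfold_flag),
      .groups = "drop"
    ) %>%
    filter(.data$n_passed == length(require_all)) %>%
    left_join(gpcr %>% select("gene_id", "coupling"),
              by = c(gene = "gene_id")) %>%
    arrange(desc(.data$min_diff_mean), desc(.data$min_beta),
            .data$max_expr_c, .data$gene) %>%
    mutate(rank = row_number()) %>%
    select("gene", "coupling", "n_passed", "min_diff_mean", "min_beta",
           "max_expr_c", "tenfold_all", "rank")
  class(cand) <- c("candidate_table", class(cand))
  cand
}
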