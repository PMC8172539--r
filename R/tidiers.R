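#' Tidy a screen grid
#'
#' @param x A [screen_grid()] result.
#' @param ... Unused.
#' @return The per-gene, per-comparison record tibble.
#' @export
tidy.screen_grid <- function(x, ...) x$records

#' Summarise a screen grid
#'
#' @param x A [screen_grid()] result.
#' @param ... Unused.
#' @return One-row tibble: number of genes, comparisons, primary passers and
#'   tenfold passers.
#' @export
glance.screen_grid <- function(x, ...) {
  tibble(
    n_genes = length(unique(x$records$gene)),
    n_comparisons = length(x$comparisons),
    n_passing_records = sum(x$records$passes_primary),
    n_tenfold_records = sum(x$records$tenfold_flag)
  )
}

#' Tidy a challenge result
#'
#' @param x A [challenge_table()] result.
#' @param ... Unused.
#' @return The group-level test tibble (one row per group x parameter).
#' @export
tidy.challenge_result <- function(x, ...) x$tests

#' Summarise a challenge result
#'
#' @param x A [challenge_table()] result.
#' @param ... Unused.
#' @return One-row tibble with cohort dimensions and the smallest group-level
#'   p-value.
#' @export
glance.challenge_result <- function(x, ...) {
  tibble(
    n_subjects = length(unique(x$ratios$subject)),
    n_groups = length(unique(x$ratios$group)),
    n_parameters = length(unique(x$ratios$parameter)),
    min_p = suppressWarnings(min(x$tests$p, na.rm = TRUE))
  )
}
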