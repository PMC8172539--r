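#' Integer flooring of sparse percentage parameters
#'
#' Percentages that can legitimately be 0 (premature and perseverative
#' response rates) are raised to the next full integer before log
#' transformation: values in `[0, 1)` become 1, values in `[1, 2)` become 2,
#' and so on — i.e. `floor(x) + 1`. This keeps the subsequent log10 ratio
#' finite and damps biologically insignificant sub-1% values.
#'
#' @param x Non-negative percentage value(s).
#' @return Integer percentage(s), `floor(x) + 1`.
#' @export
floor_rule <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("floor_rule is defined for non-negative percentages only",
          class = "impulscreen_argument_error")
  }
  floor(x) + 1
}

#' Within-subject log10 drug/vehicle ratio
#'
#' Normalises a drug-condition value to the same subject's vehicle value and
#' log10-transforms the ratio. With `apply_floor = TRUE` both values pass
#' through [floor_rule()] first (used for the percentage parameters that can
#' be 0).
#'
#' @param drug,vehicle Parameter values under the drug and vehicle conditions.
#' @param apply_floor Apply [floor_rule()] to both values first.
#' @return `log10(drug' / vehicle')`.
#' @export
log_ratio <- function(drug, vehicle, apply_floor = FALSE) {
  if (apply_floor) {
    drug <- floor_rule(drug)
    vehicle <- floor_rule(vehicle)
  }
  if (any(vehicle <= 0, na.rm = TRUE)) {
    abort("vehicle value must be positive (after any flooring)",
          class = "impulscreen_argument_error")
  }
  log10(drug / vehicle)
}

#' One-sample t-test
#'
#' Classical two-sided one-sample t-test against `mu`, with a t-based
#' confidence interval. Degenerate samples (zero variance) are an error
#' rather than a meaningless statistic.
#'
#' @param values Numeric sample, length >= 2.
#' @param mu Null value (default 0).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `estimate`, `t`, `df`, `p`, `ci_lo`, `ci_hi`.
#' @export
one_sample_t <- function(values, mu = 0, conf_level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("need at least 2 non-missing values", class = "impulscreen_argument_error")
  }
  if (sd(values) == 0) {
    abort("degenerate sample: zero variance", class = "impulscreen_degenerate_error")
  }
  fit <- t.test(values, mu = mu, conf.level = conf_level)
  tibble(estimate = unname(fit$estimate), t = unname(fit$statistic),
         df = unname(fit$parameter), p = fit$p.value,
         ci_lo = fit$conf.int[1], ci_hi = fit$conf.int[2])
}

#' Paired t-test
#'
#' Equivalent to [one_sample_t()] on the pairwise differences `a - b`.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble as for [one_sample_t()].
#' @export
paired_t <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) {
    abort("paired samples must have equal length",
          class = "impulscreen_argument_error")
  }
  one_sample_t(a - b, mu = 0, conf_level = conf_level)
}

#' Sidak adjustment for multiple comparisons
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of comparisons in the family, >= 1.
#' @return `1 - (1 - p)^m`, capped at 1.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, 1 - (1 - p)^m)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length >= 3, each with positive
#'   variance.
#' @return One-row tibble: `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("need at least 3 complete pairs", class = "impulscreen_argument_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("degenerate variance in correlation input",
          class = "impulscreen_degenerate_error")
  }
  fit <- cor.test(x, y, method = "pearson")
  tibble(r = unname(fit$estimate), df = unname(fit$parameter),
         p = fit$p.value)
}

#' Within-subject challenge statistics for a cohort
#'
#' Takes per-subject, per-condition session metrics (long on subject and
#' condition, wide on parameters) and assembles the within-subject challenge
#' analysis: for each parameter, the drug value is normalised to the same
#' subject's vehicle value, the ratio is log10-transformed (with
#' [floor_rule()] applied symmetrically to both conditions for the parameters
#' in `floor_params`), and each group's log-ratios are tested against 0 with a
#' one-sample t-test. Pearson correlations between the log-ratio of
#' `pct_premature` and those of the other parameters screen for behavioural
#' confounds. Subjects missing either condition for a parameter are excluded
#' from that parameter's test with a warning.
#'
#' @param metrics Tibble with columns `subject`, `group`, `condition` and one
#'   column per parameter (e.g. the output of [session_metrics()] stacked over
#'   a cohort).
#' @param drug Name of the drug condition (default `"cno"`).
#' @param vehicle Name of the vehicle condition (default `"vehicle"`).
#' @param parameters Parameter columns to analyse; default: every numeric
#'   metric column present from the standard set.
#' @param floor_params Parameters receiving the integer flooring (default
#'   `pct_premature` and `pct_perseverative`).
#' @param conf_level Confidence level for group intervals (default 0.95).
#' @return An object of class `challenge_result`: list with tibbles `ratios`
#'   (per subject x parameter log-ratios), `tests` (per group x parameter
#'   one-sample tests) and `correlations` (per group confound screen against
#'   the premature-response log-ratio).
#' @export
challenge_table <- function(metrics, drug = "cno", vehicle = "vehicle",
                            parameters = NULL,
                            floor_params = c("pct_premature", "pct_perseverative"),
                            conf_level = 0.95) {
  default_params <- c("pct_premature", "accuracy", "pct_omission",
                      "pct_perseverative", "response_latency_mean",
                      "response_latency_median", "reward_latency_mean",
                      "reward_latency_median")
  if (is.null(parameters)) parameters <- intersect(default_params, names(metrics))
  .require_cols(metrics, c("subject", "group", "condition"), "metrics table")
  missing_cond <- setdiff(c(drug, vehicle), unique(metrics$condition))
  if (length(missing_cond)) {
    abort(paste0("condition(s) absent from metrics: ",
                 paste(missing_cond, collapse = ", ")),
          class = "impulscreen_argument_error")
  }

  long <- metrics %>%
    filter(.data$condition %in% c(drug, vehicle)) %>%
    select("subject", "group", "condition", dplyr::all_of(parameters)) %>%
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value") %>%
    mutate(condition = ifelse(.data$condition == drug, "drug", "vehicle")) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "value")

  incomplete <- long %>% filter(is.na(.data$drug) | is.na(.data$vehicle))
  if (nrow(incomplete)) {
    warn(paste0("excluding subject x parameter pairs with a missing condition: ",
                paste(unique(incomplete$subject), collapse = ", ")))
    long <- long %>% filter(!is.na(.data$drug), !is.na(.data$vehicle))
  }

  ratios <- long %>%
    mutate(
      floored = .data$parameter %in% floor_params,
      log_ratio = ifelse(.data$floored,
                         log10(floor_rule(.data$drug) / floor_rule(.data$vehicle)),
                         log10(.data$drug / .data$vehicle))
    )
  if (any(!is.finite(ratios$log_ratio))) {
    warn("dropping non-finite log-ratios (zero or missing values outside the floor set)")
    ratios <- ratios %>% filter(is.finite(.data$log_ratio))
  }

  safe_t <- function(v) {
    tryCatch(one_sample_t(v, 0, conf_level),
             error = function(e) tibble(estimate = mean(v), t = NA_real_,
                                        df = NA_real_, p = NA_real_,
                                        ci_lo = NA_real_, ci_hi = NA_real_))
  }
  tests <- ratios %>%
    group_by(.data$group, .data$parameter) %>%
    summarise(
      n = dplyr::n(),
      mean_log_ratio = mean(.data$log_ratio),
      test = list(safe_t(.data$log_ratio)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("test") %>%
    select("group", "parameter", "n", "mean_log_ratio", "t", "df", "p",
           "ci_lo", "ci_hi")

  prem <- ratios %>%
    filter(.data$parameter == "pct_premature") %>%
    select("subject", "group", prem_log_ratio = "log_ratio")
  safe_r <- function(x, y) {
    tryCatch(pearson_r(x, y),
             error = function(e) tibble(r = NA_real_, df = NA_real_,
                                        p = NA_real_))
  }
  correlations <- ratios %>%
    filter(.data$parameter != "pct_premature") %>%
    left_join(prem, by = c("subject", "group")) %>%
    group_by(.data$group, .data$parameter) %>%
    summarise(
      cor = list(safe_r(.data$log_ratio, .data$prem_log_ratio)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("cor")

  structure(
    list(ratios = ratios, tests = tests, correlations = correlations,
         drug = drug, vehicle = vehicle, conf_level = conf_level),
    class = "challenge_result"
  )
}

#' @export
print.challenge_result <- function(x, ...) {
  cat(sprintf("<challenge_result> %d subjects, %d groups, %d parameters (%s vs %s)\n",
              length(unique(x$ratios$subject)),
              length(unique(x$ratios$group)),
              length(unique(x$ratios$parameter)), x$drug, x$vehicle))
  print(x$tests, ...)
  invisible(x)
}
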