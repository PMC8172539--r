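#' Configure a simulated behavioural cohort
#'
#' Each group carries a base [agent_params()] (with drug multipliers for the
#' non-vehicle conditions) and a number of subjects. Subjects receive
#' log-normal random effects on the premature hazard and on both latency
#' locations, so individual differences compose multiplicatively with drug
#' effects.
#'
#' @param groups Named list; each element a list with `n` (subjects, >= 2)
#'   and `agent` (an [agent_params()] whose `drug_multipliers` name every
#'   non-vehicle condition).
#' @param spec A [challenge_spec()] or preset name (see [challenge_preset()]).
#' @param conditions Character vector of conditions; must include
#'   `"vehicle"`.
#' @param subject_sdlog Log-scale standard deviation of the subject random
#'   effects (default 0.3).
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(groups, spec = "fiti9",
                              conditions = c("vehicle", "cno"),
                              subject_sdlog = 0.3, seed = 1L) {
  if (is.character(spec)) spec <- challenge_preset(spec)
  stopifnot(inherits(spec, "challenge_spec"))
  if (!"vehicle" %in% conditions) {
    abort("conditions must include 'vehicle'", class = "impulscreen_configuration_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("groups must be a named list", class = "impulscreen_configuration_error")
  }
  for (g in groups) {
    stopifnot(g$n >= 2, inherits(g$agent, "agent_params"))
  }
  structure(
    list(groups = groups, spec = spec, conditions = conditions,
         subject_sdlog = subject_sdlog, seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Simulate a behavioural cohort
#'
#' Simulates every subject under every condition via [simulate_session()],
#' with per-subject random effects drawn once and reused across conditions
#' (the within-subject design). Session seeds derive deterministically from
#' the cohort seed.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list with `sessions` (tibble: `subject`, `group`, `condition`,
#'   `seed`, list-column `log`) and `truth` (tibble of each subject's
#'   realised agent parameters).
#' @export
make_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  subjects <- withr::with_seed(cfg$seed, {
    purrr::imap(cfg$groups, function(g, gname) {
      purrr::map(seq_len(g$n), function(s) {
        re_hazard <- rlnorm(1, 0, cfg$subject_sdlog)
        re_lat <- rnorm(1, 0, cfg$subject_sdlog)
        agent <- g$agent
        agent$premature_hazard <- agent$premature_hazard * re_hazard
        agent$response_latency_meanlog <- agent$response_latency_meanlog + re_lat
        agent$reward_latency_meanlog <- agent$reward_latency_meanlog + re_lat
        list(subject = sprintf("%s_s%02d", gname, s), group = gname,
             agent = agent, re_hazard = re_hazard, re_latency = exp(re_lat))
      })
    }) %>% purrr::flatten()
  })

  grid <- tidyr::expand_grid(
    idx = seq_along(subjects),
    condition = cfg$conditions
  )
  sessions <- grid %>%
    mutate(
      subject = purrr::map_chr(.data$idx, ~ subjects[[.x]]$subject),
      group = purrr::map_chr(.data$idx, ~ subjects[[.x]]$group),
      seed = derive_seed(cfg$seed, paste0(.data$subject, ":", .data$condition))
    )
  sessions$log <- purrr::pmap(
    list(sessions$idx, sessions$condition, sessions$seed),
    function(i, cond, sd) {
      simulate_session(cfg$spec, subjects[[i]]$agent, condition = cond, seed = sd)
    }
  )
  sessions <- sessions %>% select("subject", "group", "condition", "seed", "log")

  truth <- purrr::map(subjects, function(s) {
    tibble(subject = s$subject, group = s$group,
           premature_hazard = s$agent$premature_hazard,
           re_hazard = s$re_hazard, re_latency = s$re_latency)
  }) %>% bind_rows()

  list(sessions = sessions, truth = truth, spec = cfg$spec)
}

#' Score a simulated cohort into per-session metrics
#'
#' Classifies every session log and computes [session_metrics()], yielding the
#' table that [challenge_table()] consumes.
#'
#' @param cohort Output of [make_cohort()].
#' @return A tibble with `subject`, `group`, `condition` and metric columns.
#' @export
cohort_metrics <- function(cohort) {
  cohort$sessions %>%
    mutate(metrics = purrr::map(.data$log, function(l) {
      session_metrics(classify_trials(l, cohort$spec))
    })) %>%
    select("subject", "group", "condition", "metrics") %>%
    tidyr::unnest("metrics")
}

#' Derive a stage- or unit-specific seed from a global seed
#'
#' Hashes a label into a 31-bit offset so pipeline stages and simulated
#' subjects get distinct, reproducible random streams from one global seed.
#'
#' @param seed Integer global seed.
#' @param label Character label(s).
#' @return Integer seed(s) below 2^31.
#' @export
derive_seed <- function(seed, label) {
  vapply(label, function(lbl) {
    h <- 0
    for (ch in utf8ToInt(lbl)) h <- (h * 31 + ch) %% 1000003L
    as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
  }, integer(1), USE.NAMES = FALSE)
}
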