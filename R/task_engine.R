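#' Define a 5-CSRTT challenge protocol
#'
#' A challenge is parameterised by the inter-trial interval (ITI; a single
#' fixed duration or a finite set of durations with sampling weights for
#' variable-ITI protocols), the stimulus duration (SD), the limited-hold
#' extension beyond the SD (LH), the post-error timeout, and the session
#' length. All durations are in seconds.
#'
#' @param name Protocol name.
#' @param iti Numeric vector of ITI durations (length 1 for fixed ITI).
#' @param iti_weights Sampling weights for `iti`; default equal.
#' @param sd_s Stimulus duration in seconds.
#' @param lh_extra Limited-hold extension beyond the SD (default 2 s); the
#'   response window is `[stim_on, stim_on + sd_s + lh_extra)`.
#' @param timeout Timeout after premature/incorrect/omission trials (default
#'   5 s, house light off).
#' @param session_length Session duration in seconds (default 1800).
#' @param n_holes Number of stimulus holes (default 5).
#' @return A list of class `challenge_spec`.
#' @export
challenge_spec <- function(name = "custom", iti = 5, iti_weights = NULL,
                           sd_s = 2, lh_extra = 2, timeout = 5,
                           session_length = 1800, n_holes = 5L) {
  if (!length(iti) || any(iti <= 0)) {
    abort("iti must be a non-empty list of positive durations",
          class = "impulscreen_argument_error")
  }
  stopifnot(sd_s > 0, lh_extra > 0, timeout > 0, session_length > 0)
  if (is.null(iti_weights)) iti_weights <- rep(1, length(iti))
  stopifnot(length(iti_weights) == length(iti), all(iti_weights > 0))
  structure(
    list(name = name, iti = iti, iti_weights = iti_weights / sum(iti_weights),
         sd_s = sd_s, lh_extra = lh_extra, timeout = timeout,
         session_length = session_length, n_holes = as.integer(n_holes)),
    class = "challenge_spec"
  )
}

#' Named 5-CSRTT challenge presets
#'
#' `baseline` (ITI 5 s, SD 2 s), `fiti9` (fixed-ITI impulsivity challenge,
#' ITI 9 s), `sd1` (attention challenge, SD 1 s), `combined` (ITI 7 s, SD 1 s)
#' and `viti` (variable ITI drawn from \{2, 5, 7.5, 12.5\} s with equal
#' weights — a stand-in set of plausible values).
#'
#' @param name Preset name.
#' @return A [challenge_spec()].
#' @export
challenge_preset <- function(name = c("baseline", "fiti9", "sd1", "combined",
                                      "viti")) {
  name <- match.arg(name)
  switch(name,
    baseline = challenge_spec("baseline", iti = 5, sd_s = 2),
    fiti9    = challenge_spec("fiti9", iti = 9, sd_s = 2),
    sd1      = challenge_spec("sd1", iti = 5, sd_s = 1),
    combined = challenge_spec("combined", iti = 7, sd_s = 1),
    viti     = challenge_spec("viti", iti = c(2, 5, 7.5, 12.5), sd_s = 2)
  )
}

#' Parameterise a simulated 5-CSRTT agent
#'
#' A competing-risks generative model of a mouse in the task: during the ITI,
#' premature pokes arrive as a Poisson process with rate `premature_hazard`;
#' once the stimulus appears, the agent registers it with probability
#' `p_detect`, omits anyway with probability `p_omit_given_detect`, and
#' otherwise responds at a log-normal latency truncated at the response
#' window, choosing the lit hole with probability `accuracy_given_response`.
#' Correct responses are followed by reward collection at a log-normal reward
#' latency, with a perseverative repeat poke with probability `p_perseverate`.
#' Drug conditions act multiplicatively through `drug_multipliers`.
#'
#' @param premature_hazard Premature-poke rate during the ITI, events/s.
#' @param p_detect Probability of registering the stimulus.
#' @param p_omit_given_detect Probability of omitting despite detection.
#' @param accuracy_given_response Probability the response hits the lit hole.
#' @param response_latency_meanlog,response_latency_sdlog Log-normal location
#'   and scale of the response latency (s).
#' @param reward_latency_meanlog,reward_latency_sdlog Log-normal location and
#'   scale of the reward-collection latency (s).
#' @param p_perseverate Probability of a perseverative poke after a correct
#'   response.
#' @param hold_s Snout-in-hole dwell time (s).
#' @param consume_s Receptacle dwell time after reward delivery (s).
#' @param drug_multipliers Named list of conditions; each condition is a list
#'   with any of `premature_hazard`, `p_omit`, `response_latency`,
#'   `reward_latency` (multiplicative factors, all > 0). The condition
#'   `"vehicle"` is always available with all factors 1.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(premature_hazard = 0.05,
                         p_detect = 0.95,
                         p_omit_given_detect = 0.15,
                         accuracy_given_response = 0.8,
                         response_latency_meanlog = log(0.8),
                         response_latency_sdlog = 0.4,
                         reward_latency_meanlog = log(1.2),
                         reward_latency_sdlog = 0.4,
                         p_perseverate = 0.2,
                         hold_s = 0.3,
                         consume_s = 2,
                         drug_multipliers = list()) {
  probs <- c(p_detect, p_omit_given_detect, accuracy_given_response,
             p_perseverate)
  stopifnot(all(probs >= 0 & probs <= 1), premature_hazard >= 0,
            hold_s > 0, consume_s > 0)
  for (m in drug_multipliers) stopifnot(all(unlist(m) > 0))
  structure(
    list(premature_hazard = premature_hazard, p_detect = p_detect,
         p_omit_given_detect = p_omit_given_detect,
         accuracy_given_response = accuracy_given_response,
         response_latency_meanlog = response_latency_meanlog,
         response_latency_sdlog = response_latency_sdlog,
         reward_latency_meanlog = reward_latency_meanlog,
         reward_latency_sdlog = reward_latency_sdlog,
         p_perseverate = p_perseverate, hold_s = hold_s,
         consume_s = consume_s, drug_multipliers = drug_multipliers),
    class = "agent_params"
  )
}

.resolve_multipliers <- function(agent, condition) {
  base <- list(premature_hazard = 1, p_omit = 1,
               response_latency = 1, reward_latency = 1)
  if (identical(condition, "vehicle")) return(base)
  m <- agent$drug_multipliers[[condition]]
  if (is.null(m)) {
    abort(sprintf("condition '%s' not found in drug_multipliers", condition),
          class = "impulscreen_argument_error")
  }
  utils::modifyList(base, m)
}

#' Generate a trial schedule (ITI durations and lit holes)
#'
#' Holes are drawn uniformly and independently (pseudo-random presentation);
#' an optional no-immediate-repeat rule redraws any hole equal to its
#' predecessor. ITI durations are drawn from the spec's duration set with its
#' weights. Deterministic under `seed`.
#'
#' @param spec A [challenge_spec()].
#' @param n_trials Number of trials to schedule.
#' @param seed Integer seed.
#' @param no_immediate_repeat Forbid the same hole twice in a row (default
#'   off).
#' @return A tibble with columns `iti` and `hole`.
#' @export
generate_schedule <- function(spec, n_trials, seed,
                              no_immediate_repeat = FALSE) {
  withr::with_seed(seed, .draw_schedule(spec, n_trials, no_immediate_repeat))
}

.draw_schedule <- function(spec, n_trials, no_immediate_repeat = FALSE) {
  iti <- if (length(spec$iti) == 1) {
    rep(spec$iti, n_trials)
  } else {
    sample(spec$iti, n_trials, replace = TRUE, prob = spec$iti_weights)
  }
  hole <- sample.int(spec$n_holes, n_trials, replace = TRUE)
  if (no_immediate_repeat && n_trials > 1) {
    for (k in 2:n_trials) {
      while (hole[k] == hole[k - 1]) hole[k] <- sample.int(spec$n_holes, 1L)
    }
  }
  tibble(iti = iti, hole = hole)
}

#' Simulate one 5-CSRTT session
#'
#' Runs the agent through the trial cycle and emits a timestamped event log.
#' Trials follow the operant cycle: an ITI in which any hole poke is a
#' premature response, stimulus onset in one pseudo-randomly chosen hole, a
#' half-open response window `[stim_on, stim_on + SD + LH)` in which the first
#' poke is classified correct (lit hole) or incorrect, and an omission if no
#' poke arrives. Premature, incorrect and omitted trials trigger a timeout
#' (house light off, represented by `timeout_start`/`timeout_end` events);
#' correct trials deliver a reward whose collection ends with receptacle exit,
#' which initiates the next ITI. The session ends at `session_length`; a trial
#' counts only if its outcome is decided strictly before session end.
#'
#' The returned log carries the simulator's hidden per-trial ground truth in
#' `attr(log, "truth")`, for validating [classify_trials()].
#'
#' @param spec A [challenge_spec()].
#' @param agent An [agent_params()].
#' @param condition Condition name; `"vehicle"` or a key of the agent's
#'   `drug_multipliers`.
#' @param seed Integer seed.
#' @return A `session_log` tibble with attributes `truth`, `condition`,
#'   `spec_name` and `seed`.
#' @export
simulate_session <- function(spec, agent, condition = "vehicle", seed = 1) {
  stopifnot(inherits(spec, "challenge_spec"), inherits(agent, "agent_params"))
  mult <- .resolve_multipliers(agent, condition)
  withr::with_seed(seed, .simulate_session_impl(spec, agent, mult)) -> out
  attr(out$log, "truth") <- out$truth
  attr(out$log, "condition") <- condition
  attr(out$log, "spec_name") <- spec$name
  attr(out$log, "seed") <- seed
  out$log
}

.simulate_session_impl <- function(spec, agent, mult) {
  t_end <- spec$session_length
  window <- spec$sd_s + spec$lh_extra
  hazard <- agent$premature_hazard * mult$premature_hazard
  p_omit <- min(1, agent$p_omit_given_detect * mult$p_omit)
  rml <- agent$response_latency_meanlog + log(mult$response_latency)
  rsl <- agent$response_latency_sdlog
  wml <- agent$reward_latency_meanlog + log(mult$reward_latency)
  wsl <- agent$reward_latency_sdlog

  # generous trial cap: shortest possible cycle is ~the timeout
  n_cap <- ceiling(t_end / max(0.5, min(min(spec$iti), spec$timeout))) + 10L

  sched <- .draw_schedule(spec, n_cap)
  iti <- sched$iti
  hole <- sched$hole
  prem_t <- if (hazard > 0) rexp(n_cap, hazard) else rep(Inf, n_cap)
  premature <- prem_t < iti
  detect <- runif(n_cap) < agent$p_detect
  omit_d <- runif(n_cap) < p_omit
  respond <- detect & !omit_d
  # response latency truncated at the response window (inverse-CDF)
  lat <- stats::qlnorm(runif(n_cap) * stats::plnorm(window, rml, rsl), rml, rsl)
  hit <- runif(n_cap) < agent$accuracy_given_response
  offset <- sample.int(spec$n_holes - 1L, n_cap, replace = TRUE)
  wrong_hole <- ((hole - 1L + offset) %% spec$n_holes) + 1L
  rew_lat <- rlnorm(n_cap, wml, wsl)
  persev <- runif(n_cap) < agent$p_perseverate
  persev_frac <- runif(n_cap, 0.3, 0.7)

  outcome <- ifelse(premature, "premature",
                    ifelse(!respond, "omission",
                           ifelse(hit, "correct", "incorrect")))
  dur <- ifelse(outcome == "premature", prem_t + spec$timeout,
         ifelse(outcome == "correct",
                iti + lat + agent$hold_s + rew_lat + agent$consume_s,
         ifelse(outcome == "incorrect", iti + lat + spec$timeout,
                iti + window + spec$timeout)))
  start <- c(0, cumsum(dur))[seq_len(n_cap)]
  outcome_t <- ifelse(outcome == "premature", start + prem_t,
               ifelse(outcome == "omission", start + iti + window,
                      start + iti + lat))
  n_trials <- sum(outcome_t < t_end)

  ev_time <- numeric(0); ev_kind <- character(0); ev_arg <- integer(0)
  add <- function(time, kind, arg = NA_integer_) {
    keep <- time < t_end
    ev_time <<- c(ev_time, time[keep])
    ev_kind <<- c(ev_kind, rep(kind, sum(keep)))
    ev_arg <<- c(ev_arg, rep_len(as.integer(arg), length(time))[keep])
  }
  k <- seq_len(n_trials)
  if (n_trials > 0) {
    pr <- k[outcome[k] == "premature"]
    add(start[pr] + prem_t[pr], "poke_in", hole_vec <- sample.int(spec$n_holes, length(pr), replace = TRUE))
    add(start[pr] + prem_t[pr], "timeout_start")
    add(start[pr] + prem_t[pr] + agent$hold_s, "poke_out", hole_vec)
    add(start[pr] + prem_t[pr] + spec$timeout, "timeout_end")

    ns <- k[outcome[k] != "premature"]
    add(start[ns] + iti[ns], "stim_on", hole[ns])

    co <- k[outcome[k] == "correct"]
    poke_t <- start[co] + iti[co] + lat[co]
    add(start[co] + iti[co] + pmin(spec$sd_s, lat[co]), "stim_off", hole[co])
    add(poke_t, "poke_in", hole[co])
    p_out <- poke_t + agent$hold_s
    add(p_out, "poke_out", hole[co])
    pv <- persev[co]
    add(p_out[pv] + persev_frac[co][pv] * rew_lat[co][pv], "poke_in", hole[co][pv])
    add(p_out[pv] + (persev_frac[co][pv] + (1 - persev_frac[co][pv]) / 2) *
          rew_lat[co][pv], "poke_out", hole[co][pv])
    r_in <- p_out + rew_lat[co]
    add(r_in, "receptacle_in")
    add(r_in, "reward")
    add(r_in + agent$consume_s, "receptacle_out")

    ic <- k[outcome[k] == "incorrect"]
    poke_t <- start[ic] + iti[ic] + lat[ic]
    add(start[ic] + iti[ic] + pmin(spec$sd_s, lat[ic]), "stim_off", hole[ic])
    add(poke_t, "poke_in", wrong_hole[ic])
    add(poke_t, "timeout_start")
    add(poke_t + agent$hold_s, "poke_out", wrong_hole[ic])
    add(poke_t + spec$timeout, "timeout_end")

    om <- k[outcome[k] == "omission"]
    add(start[om] + iti[om] + spec$sd_s, "stim_off", hole[om])
    add(start[om] + iti[om] + window, "timeout_start")
    add(start[om] + iti[om] + window + spec$timeout, "timeout_end")
  }
  # partial next trial: stimulus may come on before session end
  nk <- n_trials + 1L
  if (nk <= n_cap && !premature[nk] && start[nk] + iti[nk] < t_end) {
    add(start[nk] + iti[nk], "stim_on", hole[nk])
    if (start[nk] + iti[nk] + spec$sd_s < t_end) {
      add(start[nk] + iti[nk] + spec$sd_s, "stim_off", hole[nk])
    }
  }
  ev_time <- c(ev_time, t_end)
  ev_kind <- c(ev_kind, "session_end")
  ev_arg <- c(ev_arg, NA_integer_)

  prio <- match(ev_kind, c("stim_on", "stim_off", "poke_in", "timeout_start",
                           "poke_out", "receptacle_in", "reward",
                           "receptacle_out", "timeout_end", "session_end"))
  o <- order(ev_time, prio, method = "radix")
  log <- session_log(ev_time[o], ev_kind[o], ev_arg[o], source = "simulated session")

  truth <- tibble(
    trial = k,
    iti_used = iti[k],
    hole = hole[k],
    outcome = outcome[k],
    perseverative = outcome[k] == "correct" & persev[k] &
      (start[k] + iti[k] + lat[k] + agent$hold_s +
         persev_frac[k] * rew_lat[k]) < t_end,
    response_latency = ifelse(outcome[k] %in% c("correct", "incorrect"),
                              lat[k], NA_real_),
    reward_latency = ifelse(outcome[k] == "correct" &
                              (start[k] + iti[k] + lat[k] + agent$hold_s +
                                 rew_lat[k]) < t_end,
                            rew_lat[k], NA_real_)
  )
  list(log = log, truth = truth)
}

#' Classify an event log into trial outcomes
#'
#' Replays the 5-CSRTT state machine over a session log: any hole poke during
#' the ITI is a premature response; after stimulus onset the first poke within
#' the half-open window `[stim_on, stim_on + SD + LH)` is correct (lit hole)
#' or incorrect (other hole); absence of a poke by window end is an omission.
#' A repeat poke into the correct hole after a correct response and before
#' receptacle entry marks the trial perseverative. Response latency is the
#' first-poke time minus stimulus onset; reward latency runs from the exit of
#' the correct hole to receptacle entry. Pokes during timeouts are tallied
#' separately (`attr(., "n_timeout_pokes")`) and belong to no trial; a trial
#' whose outcome is still undecided at session end is dropped.
#'
#' @param log A `session_log` (from [read_session_log()] or
#'   [simulate_session()]).
#' @param spec The [challenge_spec()] the session was run under (supplies SD,
#'   LH and timeout).
#' @return A tibble with one row per trial: `trial`, `iti_used`, `hole`,
#'   `outcome`, `perseverative`, `response_latency`, `reward_latency`.
#'   `iti_used` and `hole` are `NA` for premature trials (the scheduled
#'   stimulus never appeared).
#' @export
classify_trials <- function(log, spec) {
  stopifnot(inherits(spec, "challenge_spec"))
  window <- spec$sd_s + spec$lh_extra
  n <- nrow(log)
  tms <- log$time_s; evs <- log$event; args <- log$arg

  res <- vector("list", 64L)
  n_rec <- 0L
  push <- function(rec) {
    n_rec <<- n_rec + 1L
    if (n_rec > length(res)) length(res) <<- 2L * n_rec
    res[[n_rec]] <<- rec
  }

  state <- "iti"
  trial_start <- 0
  lit <- NA_integer_; stim_t <- NA_real_
  cur <- NULL           # pending correct-trial record
  resp_hole <- NA_integer_; resp_out <- NA_real_
  n_timeout_pokes <- 0L

  bad <- function(i, msg) {
    abort(sprintf("inconsistent log at event %d (%s, t=%.3f): %s",
                  i, evs[i], tms[i], msg),
          class = "impulscreen_classification_error")
  }
  expire_window <- function(t) {
    # omission once the response window has lapsed (half-open window:
    # an event exactly at the boundary is already outside it)
    if (state == "window" && t >= stim_t + window) {
      push(list(iti_used = stim_t - trial_start, hole = lit,
                outcome = "omission", perseverative = FALSE,
                response_latency = NA_real_, reward_latency = NA_real_))
      state <<- "timeout"
    }
  }

  for (i in seq_len(n)) {
    ev <- evs[i]; t <- tms[i]; a <- args[i]
    if (state == "window") expire_window(t)
    if (ev == "stim_on") {
      if (state != "iti") bad(i, "stimulus onset outside the ITI")
      lit <- a; stim_t <- t; state <- "window"
    } else if (ev == "poke_in") {
      if (state == "iti") {
        push(list(iti_used = NA_real_, hole = NA_integer_,
                  outcome = "premature", perseverative = FALSE,
                  response_latency = NA_real_, reward_latency = NA_real_))
        state <- "timeout"
      } else if (state == "window") {
        if (a == lit) {
          cur <- list(iti_used = stim_t - trial_start, hole = lit,
                      outcome = "correct", perseverative = FALSE,
                      response_latency = t - stim_t,
                      reward_latency = NA_real_)
          resp_hole <- a; resp_out <- NA_real_
          state <- "reward_pending"
        } else {
          push(list(iti_used = stim_t - trial_start, hole = lit,
                    outcome = "incorrect", perseverative = FALSE,
                    response_latency = t - stim_t,
                    reward_latency = NA_real_))
          state <- "timeout"
        }
      } else if (state == "reward_pending") {
        if (!is.na(resp_hole) && a == resp_hole) cur$perseverative <- TRUE
      } else if (state == "timeout") {
        n_timeout_pokes <- n_timeout_pokes + 1L
      }
      # pokes in "consume" belong to no trial; ignored
    } else if (ev == "poke_out") {
      if (state == "reward_pending" && !is.na(resp_hole) && a == resp_hole &&
          is.na(resp_out)) {
        resp_out <- t
      }
    } else if (ev == "receptacle_in") {
      if (state == "reward_pending") {
        if (!is.na(resp_out)) cur$reward_latency <- t - resp_out
        state <- "consume"
      }
      # receptacle pokes during the ITI are ignored
    } else if (ev == "receptacle_out") {
      if (state == "consume") {
        push(cur); cur <- NULL
        trial_start <- t; state <- "iti"
      }
    } else if (ev == "timeout_start") {
      if (state == "window") expire_window(stim_t + window)
      if (!state %in% c("timeout")) bad(i, "timeout without a terminating outcome")
    } else if (ev == "timeout_end") {
      if (state != "timeout") bad(i, "timeout_end without timeout")
      trial_start <- t; state <- "iti"
    } else if (ev == "session_end") {
      if (state == "window") expire_window(t)   # lapsed window still an omission
      if (state %in% c("reward_pending", "consume") && !is.null(cur)) {
        push(cur); cur <- NULL
      }
      break
    }
    # stim_off and reward carry no classification information
  }

  out <- bind_rows(lapply(res[seq_len(n_rec)], as_tibble))
  if (!nrow(out)) {
    out <- tibble(iti_used = numeric(), hole = integer(), outcome = character(),
                  perseverative = logical(), response_latency = numeric(),
                  reward_latency = numeric())
  }
  out <- mutate(out, trial = row_number(), .before = 1)
  attr(out, "n_timeout_pokes") <- n_timeout_pokes
  out
}

#' Session-level 5-CSRTT performance metrics
#'
#' Computes the standard read-outs from classified trials:
#' `pct_premature = 100 * n_premature / n_trials`,
#' `accuracy = 100 * n_correct / (n_correct + n_incorrect)`,
#' `pct_omission = 100 * n_omission / n_trials`,
#' `pct_perseverative = 100 * n_perseverative / n_correct`,
#' plus mean and median response and reward latencies. Ratios with zero
#' denominator are `NA`, never 0.
#'
#' @param trials Tibble from [classify_trials()] (may be empty).
#' @return A one-row tibble of counts and metrics.
#' @export
session_metrics <- function(trials) {
  n_trials <- nrow(trials)
  n_prem <- sum(trials$outcome == "premature")
  n_corr <- sum(trials$outcome == "correct")
  n_inc <- sum(trials$outcome == "incorrect")
  n_om <- sum(trials$outcome == "omission")
  n_pers <- sum(trials$perseverative)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rl <- trials$response_latency[!is.na(trials$response_latency)]
  wl <- trials$reward_latency[!is.na(trials$reward_latency)]
  tibble(
    n_trials = n_trials, n_premature = n_prem, n_correct = n_corr,
    n_incorrect = n_inc, n_omission = n_om, n_perseverative = n_pers,
    pct_premature = ratio(n_prem, n_trials),
    accuracy = ratio(n_corr, n_corr + n_inc),
    pct_omission = ratio(n_om, n_trials),
    pct_perseverative = ratio(n_pers, n_corr),
    response_latency_mean = if (length(rl)) mean(rl) else NA_real_,
    response_latency_median = if (length(rl)) median(rl) else NA_real_,
    reward_latency_mean = if (length(wl)) mean(wl) else NA_real_,
    reward_latency_median = if (length(wl)) median(wl) else NA_real_
  )
}
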