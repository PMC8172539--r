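test_that("schedules are deterministic, uniform over holes, honour fixed ITI", {
  spec <- challenge_preset("fiti9")
  s1 <- generate_schedule(spec, 100, seed = 1)
  s2 <- generate_schedule(spec, 100, seed = 1)
  expect_identical(s1, s2)
  expect_true(all(s1$iti == 9))

  big <- generate_schedule(challenge_preset("viti"), 10000, seed = 2)
  gof <- stats::chisq.test(table(big$hole), p = rep(0.2, 5))
  expect_gt(gof$p.value, 0.001)
  expect_true(all(big$iti %in% c(2, 5, 7.5, 12.5)))

  nr <- generate_schedule(spec, 500, seed = 3, no_immediate_repeat = TRUE)
  expect_true(all(diff(nr$hole) != 0))
})

test_that("degenerate agents produce the expected outcome profiles", {
  spec <- challenge_preset("baseline")
  quiet <- agent_params(premature_hazard = 0)
  tr <- classify_trials(simulate_session(spec, quiet, seed = 1), spec)
  expect_equal(sum(tr$outcome == "premature"), 0L)

  perfect <- agent_params(premature_hazard = 0, p_detect = 1,
                          p_omit_given_detect = 0,
                          accuracy_given_response = 1)
  tr <- classify_trials(simulate_session(spec, perfect, seed = 2), spec)
  expect_true(all(tr$outcome == "correct"))
})

test_that("premature fraction follows exponential survival of the ITI", {
  # P(premature) = 1 - exp(-hazard * iti) = 1 - exp(-1.8) for 0.2/s over 9 s
  spec <- challenge_spec("long", iti = 9, session_length = 36000)
  agent <- agent_params(premature_hazard = 0.2)
  outcomes <- character(0)
  s <- 0
  while (length(outcomes) < 2000) {
    s <- s + 1
    truth <- attr(simulate_session(spec, agent, seed = s), "truth")
    outcomes <- c(outcomes, truth$outcome)
  }
  outcomes <- outcomes[1:2000]
  expected <- 1 - exp(-1.8)
  sigma <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(mean(outcomes == "premature") - expected), 3 * sigma)
})

test_that("hand-written logs classify per the trial state machine", {
  spec <- challenge_spec("demo", iti = 5, sd_s = 2, lh_extra = 2, timeout = 5,
                        session_length = 60)
  log <- session_log(
    time_s = c(2.0, 2.3, 7.0, 12.0, 12.8, 13.1, 14.0, 14.1, 15.5, 21.5,
               25.5, 29.5, 30.5, 60),
    event = c("poke_in", "poke_out", "timeout_end",
              "stim_on", "poke_in", "poke_out", "receptacle_in", "reward",
              "receptacle_out",
              "stim_on", "stim_off", "timeout_start", "timeout_end",
              "session_end"),
    arg = c(3, 3, NA, 2, 2, 2, NA, NA, NA, 4, 4, NA, NA, NA)
  )
  tr <- classify_trials(log, spec)
  expect_equal(tr$outcome, c("premature", "correct", "omission"))
  expect_equal(tr$response_latency[2], 0.8)
  expect_equal(tr$reward_latency[2], 0.9)
  expect_false(any(tr$perseverative))
})

test_that("a poke exactly at the window boundary is an omission", {
  spec <- challenge_spec("b", iti = 5, sd_s = 2, lh_extra = 2,
                        session_length = 60)
  log <- session_log(
    time_s = c(5, 9, 9.2, 14, 60),
    event = c("stim_on", "poke_in", "poke_out", "timeout_end", "session_end"),
    arg = c(1, 1, 1, NA, NA)
  )
  tr <- classify_trials(log, spec)
  expect_equal(tr$outcome[1], "omission")
  expect_equal(attr(tr, "n_timeout_pokes"), 1L)
})

test_that("perseverative pokes are detected between response and reward", {
  spec <- challenge_spec("p", iti = 5, sd_s = 2, session_length = 60)
  log <- session_log(
    time_s = c(5, 5.8, 6.1, 6.6, 6.9, 7.8, 7.81, 9.8, 60),
    event = c("stim_on", "poke_in", "poke_out", "poke_in", "poke_out",
              "receptacle_in", "reward", "receptacle_out", "session_end"),
    arg = c(2, 2, 2, 2, 2, NA, NA, NA, NA)
  )
  tr <- classify_trials(log, spec)
  expect_equal(tr$outcome, "correct")
  expect_true(tr$perseverative)
  # reward latency runs from the response poke's exit, not the repeat poke
  expect_equal(tr$reward_latency, 7.8 - 6.1)
})

test_that("simulated logs round-trip through the classifier exactly", {
  specs <- c("baseline", "fiti9", "sd1", "combined", "viti")
  withr::with_seed(99, {
    for (rep in 1:40) {
      spec <- challenge_preset(sample(specs, 1))
      agent <- random_agent()
      seed <- sample.int(1e6, 1)
      log <- simulate_session(spec, agent, seed = seed)
      truth <- attr(log, "truth")
      tr <- classify_trials(log, spec)
      expect_equal(nrow(tr), nrow(truth))
      expect_identical(tr$outcome, truth$outcome)
      expect_equal(tr$response_latency, truth$response_latency,
                   tolerance = 1e-8)
      expect_identical(tr$perseverative, truth$perseverative)
      # conservation
      expect_equal(sum(tr$outcome %in% c("premature", "correct", "incorrect",
                                         "omission")), nrow(tr))
    }
  })
})

test_that("session metrics implement the standard 5-CSRTT formulas", {
  tr <- tibble::tibble(
    trial = 1:10,
    iti_used = 5, hole = 1L,
    outcome = c(rep("premature", 2), rep("correct", 5), "incorrect",
                rep("omission", 2)),
    perseverative = c(rep(FALSE, 2), TRUE, TRUE, rep(FALSE, 6)),
    response_latency = c(rep(NA, 2), rep(0.8, 6), rep(NA, 2)),
    reward_latency = c(rep(NA, 2), rep(1.2, 5), rep(NA, 3))
  )
  m <- session_metrics(tr)
  expect_equal(m$pct_premature, 20)
  expect_equal(m$accuracy, 100 * 5 / 6)
  expect_equal(m$pct_omission, 20)
  expect_equal(m$pct_perseverative, 40)
  expect_equal(m$n_trials, 10L)

  empty <- session_metrics(tr[tr$outcome == "premature", ])
  expect_true(is.na(empty$accuracy))
  expect_true(is.na(empty$pct_perseverative))
  none <- session_metrics(tr[0, ])
  expect_true(is.na(none$pct_premature))
})

test_that("expected premature rate is monotone in hazard and ITI", {
  hazards <- c(0.02, 0.08, 0.2)
  itis <- c(4, 7, 10)
  rate <- matrix(NA_real_, 3, 3)
  for (i in seq_along(hazards)) {
    for (j in seq_along(itis)) {
      spec <- challenge_spec("m", iti = itis[j], session_length = 20000)
      agent <- agent_params(premature_hazard = hazards[i])
      truth <- attr(simulate_session(spec, agent, seed = 1000 + 10 * i + j),
                    "truth")
      rate[i, j] <- mean(truth$outcome[seq_len(min(500, nrow(truth)))] ==
                           "premature")
    }
  }
  slack <- 0.05
  expect_true(all(diff(rate[, 1]) > -slack) && all(diff(rate[, 3]) > -slack))
  expect_true(all(diff(rate[1, ]) > -slack) && all(diff(rate[3, ]) > -slack))
  # and the extremes are well separated
  expect_gt(rate[3, 3], rate[1, 1])
})
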