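step_series <- function(duration = 30, at = 10, size = 0.5, base = 0.2) {
  g <- c(rep(base, at), rep(base + size, duration + 1 - at))
  value_series(matrix(g, 1, byrow = TRUE), duration)
}

test_that("the press hazard follows its formula", {
  d <- stimulus_design(1, "x", duration_s = 30, seed = 1)
  v <- step_series()
  # no gains: constant base rate
  p0 <- response_params(base_rate = 0.05, change_gain = 0,
                        congruence_gain = 0)
  expect_equal(press_hazard(v, d, p0), rep(0.05, 30))
  # constant series: change term vanishes
  flat <- value_series(matrix(0.4, 1, 31), 30)
  p1 <- response_params(base_rate = 0.07, change_gain = 2,
                        congruence_gain = 1)
  expect_equal(press_hazard(flat, d, p1), rep(0.07, 30))
  # a 0.5 step at second 10 with gain 1: 0.55 there, base elsewhere
  p2 <- response_params(base_rate = 0.05, change_gain = 1,
                        congruence_gain = 0)
  hz <- press_hazard(v, d, p2)
  expect_equal(hz[10], 0.55)
  expect_equal(hz[-10], rep(0.05, 29))
  expect_error(press_hazard(v, stimulus_design(1, "y", duration_s = 60),
                            p2), "durations differ")
})

test_that("hazards stay in [0,1] and are monotone in change gain", {
  d <- stimulus_design(2, "x", trend_level = 0.71, framing = "invasive",
                       salience = "saturation", seed = 2)
  v <- generate_exp2_series(d)
  gains <- c(0, 0.5, 1, 3, 10, 100)
  prev <- rep(-Inf, 30)
  for (g in gains) {
    hz <- press_hazard(v, d, response_params(change_gain = g))
    expect_true(all(hz >= 0 & hz <= 1))
    expect_true(all(hz >= prev - 1e-12))
    prev <- hz
  }
})

test_that("framing congruence and low salience modulate the hazard", {
  d_inv <- stimulus_design(2, "x", trend_level = 0.71, framing = "invasive",
                           salience = "saturation", seed = 3)
  d_end <- stimulus_design(2, "x", trend_level = 0.71,
                           framing = "endangered", salience = "saturation",
                           seed = 3)
  d_hue <- stimulus_design(2, "x", trend_level = 0.71, framing = "endangered",
                           salience = "hue", seed = 3)
  v <- generate_exp2_series(d_inv)
  p <- response_params(base_rate = 0.05, change_gain = 1,
                       congruence_gain = 1, low_salience_factor = 0.5)
  hz_inv <- press_hazard(v, d_inv, p)   # congruent: invasive x rising
  hz_end <- press_hazard(v, d_end, p)   # incongruent
  hz_hue <- press_hazard(v, d_hue, p)   # incongruent + low salience
  expect_true(all(hz_inv >= hz_end))
  expect_gt(mean(hz_inv), mean(hz_end))
  expect_true(all(hz_end >= hz_hue))
})

test_that("cohort simulation is deterministic and well-formed", {
  co1 <- make_test_cohort(n_participants = 6, n_stimuli = 3, seed = 5)
  co2 <- make_test_cohort(n_participants = 6, n_stimuli = 3, seed = 5)
  expect_identical(co1$logs, co2$logs)
  expect_identical(co1$trials, co2$trials)
  # press times ordered, within [0, duration], refractory respected
  by_trial <- split(co1$logs$press_time_s,
                    paste(co1$logs$participant_id, co1$logs$stimulus_id))
  for (t in by_trial) {
    expect_false(is.unsorted(t))
    expect_true(all(t >= 0 & t <= 30))
    if (length(t) > 1) expect_true(all(diff(t) >= 0.5))
  }
  expect_warning(
    simulate_cohort(list(stimulus_design(1, "s", duration_s = 30, seed = 1)),
                    list(s = generate_exp1_series(30, seed = 1)),
                    1, response_params(), seed = 1),
    "at least 2")
})

test_that("per-bin press proportions recover the change gain", {
  # isolate the hazard mechanism: no intercept spread, no refractory
  params <- response_params(base_rate = 0.05, change_gain = 2,
                            congruence_gain = 0, participant_sd = 0,
                            refractory_s = 0)
  n <- 200
  props <- NULL
  dgs <- NULL
  for (i in 1:3) {
    d <- stimulus_design(1, paste0("s", i), duration_s = 60, seed = i)
    v <- generate_exp1_series(60, seed = i)
    co <- simulate_cohort(list(d), stats::setNames(list(v), d$stimulus_id),
                          n, params, seed = 70 + i)
    M <- bin_cohort(filter_trials(co), window_s = 0)[[1]]
    # align rows to all n participants (empty trials have zero rows here)
    filled <- matrix(0, n, 60)
    filled[match(rownames(M), sprintf("p%03d", 1:n)), ] <- M
    props <- c(props, colMeans(filled))
    dgs <- c(dgs, abs(diff(v$global_series)))
  }
  slope <- stats::coef(stats::lm(props ~ dgs))[["dgs"]]
  expect_lt(abs(slope - params$change_gain) / params$change_gain, 0.1)
})

test_that("trial filtering classifies and counts every trial", {
  co <- make_test_cohort(n_participants = 10, n_stimuli = 3, seed = 8)
  audit <- attr(co, "filter_audit")
  expect_equal(unname(audit["total"]), 30)
  expect_equal(sum(audit[c("ok", "empty", "post_end")]),
               unname(audit["total"]))
  expect_true(all(co$trials$status[co$trials$n_presses == 0] == "empty"))
})
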