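test_that("piecewise-linear series rescale to [0,1] exactly", {
  for (s in 1:25) {
    v <- generate_exp1_series(seed = s)
    expect_identical(dim(v$values), c(10L, 61L))
    expect_equal(min(v$values), 0)
    expect_equal(max(v$values), 1)
    expect_true(length(v$slope_changes) >= 5 &&
                  length(v$slope_changes) <= 10)
    expect_true(!is.unsorted(v$slope_changes, strictly = TRUE))
  }
})

test_that("zero noise collapses every region onto the global series", {
  v <- generate_exp1_series(seed = 4, noise_sd = 0)
  expect_equal(max(abs(sweep(v$values, 2, v$global_series))), 0)
  expect_error(generate_exp1_series(seed = 1, noise_sd = -0.1),
               "non-negative")
})

test_that("series generators are seed-deterministic", {
  expect_identical(generate_exp1_series(seed = 9),
                   generate_exp1_series(seed = 9))
  d <- enumerate_design(2)[[5]]
  expect_identical(generate_exp2_series(d), generate_exp2_series(d))
})

test_that("series descriptors follow their definitions", {
  v <- generate_exp1_series(seed = 2)
  g <- colMeans(v$values)
  expect_equal(v$global_series, g)
  expect_equal(v$trend, g[61] - g[1])
  expect_equal(v$summed_values, sum(g))
  expect_equal(v$max_slope, max(abs(diff(g))))
  expect_true(abs(v$trend) <= 1 && v$max_slope >= 0)
  expect_equal(series_descriptors(v),
               data.frame(trend = v$trend, summed_values = v$summed_values,
                          max_slope = v$max_slope))
})

test_that("feasible start ranges keep both endpoints in [0,1]", {
  expect_equal(feasible_start_range(-1), c(1, 1))
  expect_equal(feasible_start_range(-0.43), c(0.43, 1))
  expect_equal(feasible_start_range(0), c(0, 1))
  expect_equal(feasible_start_range(0.43), c(0, 0.57))
  expect_equal(feasible_start_range(1), c(0, 0))
  expect_error(feasible_start_range(1.2), "feasible")
})

test_that("linear-trend stimuli truncate but never rescale", {
  # trend 1 forces start 0 and a noise-free rise 0 -> 1
  d <- stimulus_design(2, "x", trend_level = 1, framing = "invasive",
                       salience = "saturation", noise_sd = 0, seed = 3)
  v <- generate_exp2_series(d)
  expect_equal(v$global_series[1], 0)
  expect_equal(v$global_series[31], 1)
  # noise-free realized trend equals the nominal trend exactly
  for (tr in exp2_trend_grid()) {
    dd <- stimulus_design(2, "x", trend_level = tr, noise_sd = 0, seed = 5)
    expect_equal(generate_exp2_series(dd)$trend, tr)
  }
  # bounds hold under noise across many seeds
  for (s in 1:50) {
    dd <- stimulus_design(2, "x", trend_level = -0.71, seed = s)
    vv <- generate_exp2_series(dd)
    expect_true(min(vv$values) >= 0 && max(vv$values) <= 1)
  }
})

test_that("truncation bias in the realized trend is small (Monte-Carlo)", {
  trends <- vapply(1:10000, function(s) {
    d <- stimulus_design(2, "x", trend_level = 0.43, seed = s)
    v <- generate_exp2_series(d)
    v$trend
  }, 0)
  expect_lt(abs(mean(trends) - 0.43), 0.02)
})

test_that("spatial-pattern series confine the trend to the changing set", {
  m <- build_region_map(n_regions = 10, seed = 11)
  d <- stimulus_design(3, "x", trend_level = 1, framing = "endangered",
                       salience = "clustered",
                       changing_regions = c(0, 2, 5, 7), noise_sd = 0,
                       seed = 2)
  v <- generate_exp3_series(d, m)
  delta <- v$values[, 31] - v$values[, 1]
  expect_equal(unname(delta[c(1, 3, 6, 8)]), rep(1, 4))
  expect_equal(unname(delta[-c(1, 3, 6, 8)]), rep(0, 6))
  # whole-map trend is the mean of the region trends: 4/10 * 1
  expect_equal(v$trend, 0.4)
  bad <- stimulus_design(3, "x", trend_level = 1, salience = "clustered",
                         changing_regions = c(0, 1, 99), seed = 2)
  expect_error(generate_exp3_series(bad, m), "region ids")
})

test_that("factorial enumerations are complete and duplicate-free", {
  d2 <- enumerate_design(2)
  expect_length(d2, 32)
  t2 <- design_table(d2)
  expect_equal(sort(unique(t2$trend)),
               c(-1, -0.71, -0.43, -0.14, 0.14, 0.43, 0.71, 1))
  expect_equal(anyDuplicated(t2[c("trend", "framing", "salience")]), 0L)

  d3 <- enumerate_design(3)
  expect_length(d3, 32)
  t3 <- design_table(d3)
  expect_equal(sort(unique(t3$trend)), c(-1, -0.5, 0.5, 1))
  expect_true(all(t3$n_changing %in% c(3L, 4L)))
  expect_equal(anyDuplicated(
    t3[c("trend", "framing", "salience", "n_changing")]), 0L)
  expect_error(enumerate_design(4), "must be 2 or 3")
})
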