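test_that("debouncing keeps presses >= 0.5 s after the last retained one", {
  expect_equal(debounce(c(1.0, 1.3, 2.0)), c(1.0, 2.0))
  expect_equal(debounce(numeric(0)), numeric(0))
  # chaining is relative to the last *retained* press: 0.59 goes, 1.08 stays
  expect_equal(debounce(c(0.10, 0.59, 1.08)), c(0.10, 1.08))
  expect_equal(debounce(c(0, 0.4, 0.8, 1.2)), c(0, 0.8))
  expect_error(debounce(c(2, 1)), "ascending")
})

test_that("presses land in half-open one-second bins", {
  b <- bin_presses(3.2, 60)
  expect_equal(which(b$bins == 1), 4L)  # 0-based bin 3
  expect_equal(bin_presses(c(3.2, 3.9), 60)$k, 1L)
  expect_equal(bin_presses(numeric(0), 30),
               structure(list(bins = integer(30), k = 0L),
                         class = "binned_response"))
  # a press at exactly the duration clamps into the last bin
  expect_equal(which(bin_presses(30, 30)$bins == 1), 30L)
  expect_error(bin_presses(-0.1, 30), "negative")
  expect_error(bin_presses(30.4, 30), "after stimulus end")
})

test_that("the group norm is the leave-one-out proportion", {
  M <- rbind(c(1, 0, 1, 0),
             c(1, 0, 0, 0),
             c(1, 1, 0, 0))
  gn <- group_norm(M, 1)
  expect_equal(gn$proportions, c(1, 0.5, 0, 0))
  expect_equal(gn$n_others, 2)
  # the excluded row never affects the norm
  M2 <- M
  M2[1, ] <- c(0, 1, 0, 1)
  expect_equal(group_norm(M2, 1)$proportions, gn$proportions)
  expect_equal(group_norm(rbind(c(1, 0), c(0, 0)), 1)$proportions, c(0, 0))
  expect_error(group_norm(M[1, , drop = FALSE], 1), "at least 2")
})

test_that("correlation bounds match the brute-force placements", {
  p <- c(0.0, 0.1, 0.2, 0.9)
  b <- correlation_bounds(1, p)
  expect_equal(unname(b["r_max"]), stats::cor(c(0, 0, 0, 1), p))
  expect_equal(unname(b["r_min"]), stats::cor(c(1, 0, 0, 0), p))
  expect_error(correlation_bounds(0, p), "k = 0")
  expect_error(correlation_bounds(4, p), "k = 0")
  expect_error(correlation_bounds(1, rep(0.5, 6)), "zero variance")

  set.seed(42)
  for (n in c(5, 8, 12)) {
    p <- stats::runif(n)
    for (k in 1:(n - 1)) {
      expect_equal(correlation_bounds(k, p), bounds_oracle(k, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("scaled agreement hits its extremes and matches the oracle", {
  p <- c(0, 0.2, 0.8, 1, 0.4, 0)
  # top-k placement -> 1; bottom-k placement -> 0
  expect_equal(scaled_agreement(c(0, 0, 1, 1, 0, 0), p)$agreement, 1)
  expect_equal(scaled_agreement(c(1, 0, 0, 0, 0, 1), p)$agreement, 0)
  expect_equal(scaled_agreement(c(0, 1, 1, 0, 0, 0), p)$agreement,
               unname(agreement_oracle(c(0, 1, 1, 0, 0, 0), p)))
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    p <- stats::runif(n)
    k <- sample(n - 1, 1)
    bins <- numeric(n)
    bins[sample(n, k)] <- 1
    sa <- scaled_agreement(bins, p)
    expect_equal(sa$agreement, unname(agreement_oracle(bins, p)),
                 tolerance = 1e-12)
    expect_true(sa$agreement >= -1e-12 && sa$agreement <= 1 + 1e-12)
    expect_true(sa$r_min <= sa$r_obs + 1e-12 &&
                  sa$r_obs <= sa$r_max + 1e-12)
  }
})

test_that("unit durations partition the stimulus", {
  expect_equal(unit_durations(c(10, 20), 30), c(10, 10, 10))
  expect_equal(unit_durations(numeric(0), 30), 30)
  # 11 equally spaced presses in 60 s -> 12 units of 5 s
  expect_equal(unit_durations(seq(5, 55, by = 5), 60), rep(5, 12))
  set.seed(3)
  t <- sort(stats::runif(6, 0, 30))
  expect_equal(sum(unit_durations(t, 30)), 30)
  expect_length(unit_durations(t, 30), 7)
})

test_that("the vectorized cohort path agrees with the scalar path", {
  set.seed(11)
  M <- matrix(rbinom(15 * 20, 1, 0.25), 15, 20)
  M[1, ] <- c(rep(1, 5), rep(0, 15))  # include a structured row
  core <- segmap:::agreement_core(M)
  for (i in seq_len(nrow(M))) {
    k <- sum(M[i, ])
    p <- colMeans(M[-i, ])
    if (k == 0 || k == ncol(M) || stats::sd(p) == 0) {
      expect_true(is.na(core$agreement[i]))
    } else {
      sa <- scaled_agreement(M[i, ], p)
      expect_equal(core$r_obs[i], sa$r_obs, tolerance = 1e-12)
      expect_equal(core$r_min[i], sa$r_min, tolerance = 1e-12)
      expect_equal(core$r_max[i], sa$r_max, tolerance = 1e-12)
      expect_equal(core$agreement[i], sa$agreement, tolerance = 1e-12)
    }
  }
})

test_that("cohort agreement records stay in [0,1] and audit exclusions", {
  co <- make_test_cohort(n_participants = 12, n_stimuli = 4, seed = 21)
  recs <- cohort_agreement(bin_cohort(co))
  expect_true(all(recs$agreement >= -1e-12 & recs$agreement <= 1 + 1e-12))
  expect_true(all(recs$r_min <= recs$r_max))
  audit <- attr(co, "filter_audit")
  expect_equal(nrow(recs) + nrow(attr(recs, "exclusions")),
               unname(audit["ok"]))
})
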