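sim_ri_data <- function(n_part = 40, n_trials = 8, beta = c(0.5, 0.03),
                        sd_id = 0.08, sd_e = 0.15) {
  id <- rep(seq_len(n_part), each = n_trials)
  trend <- rep(seq(-1, 1, length.out = n_trials), n_part)
  b <- stats::rnorm(n_part, 0, sd_id)
  data.frame(
    participant_id = factor(id), trend = trend,
    agreement = beta[1] + beta[2] * trend + b[id] +
      stats::rnorm(n_part * n_trials, 0, sd_e))
}

test_that("an intercept-only model recovers the grand mean", {
  set.seed(2)
  d <- sim_ri_data()
  fit <- fit_lmm(agreement ~ 1 + (1 | participant_id), d)
  expect_equal(fit$coefficients$estimate[1], mean(d$agreement),
               tolerance = 1e-6)
  expect_true(all(c("se", "ci_lower", "ci_upper", "t", "df", "p", "d") %in%
                    names(fit$coefficients)))
  expect_true(fit$coefficients$ci_lower[1] < fit$coefficients$estimate[1])
  expect_true(fit$r2_conditional >= fit$r2_marginal)
})

test_that("rank-deficient fixed effects raise an aliasing error", {
  set.seed(3)
  d <- sim_ri_data()
  d$trend2 <- d$trend  # perfectly aliased copy
  expect_error(fit_lmm(agreement ~ trend + trend2 + (1 | participant_id), d),
               "rank-deficient")
})

test_that("Wald intervals reach nominal coverage under the fitted spec", {
  set.seed(17)
  true_beta <- 0.03
  hits <- vapply(seq_len(500), function(i) {
    d <- sim_ri_data(n_part = 30, n_trials = 6)
    fit <- fit_lmm(agreement ~ trend + (1 | participant_id), d)
    co <- fit$coefficients[fit$coefficients$term == "trend", ]
    co$ci_lower <= true_beta && true_beta <= co$ci_upper
  }, TRUE)
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("the descriptor model recovers a planted trend effect", {
  set.seed(23)
  n_stim <- 15
  desc <- data.frame(
    stimulus_id = paste0("s", seq_len(n_stim)),
    trend = stats::runif(n_stim, -1, 1),
    summed_values = stats::runif(n_stim, 20, 40),
    max_slope = stats::runif(n_stim, 0.05, 0.3))
  n_part <- 40
  tab <- desc[rep(seq_len(n_stim), n_part), ]
  tab$participant_id <- factor(rep(seq_len(n_part), each = n_stim))
  b <- stats::rnorm(n_part, 0, 0.05)
  tab$agreement <- 0.5 + 0.06 * tab$trend +
    b[as.integer(tab$participant_id)] + stats::rnorm(nrow(tab), 0, 0.1)
  fit <- exploratory_descriptor_model(tab)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "trend"], 0.06, tolerance = 0.03)
  expect_lt(co$p[co$term == "trend"], 0.001)
  expect_gt(co$p[co$term == "summed_values"], 0.01)
  expect_gt(co$p[co$term == "max_slope"], 0.01)

  # negative control: descriptors permuted across stimuli
  perm <- tab
  reord <- c(8, 3, 12, 1, 15, 6, 10, 2, 14, 5, 9, 13, 4, 11, 7)
  key <- match(perm$stimulus_id, desc$stimulus_id)
  perm$trend <- desc$trend[reord][key]
  perm$summed_values <- desc$summed_values[reord][key]
  perm$max_slope <- desc$max_slope[reord][key]
  fitp <- exploratory_descriptor_model(perm)
  expect_gt(fitp$coefficients$p[fitp$coefficients$term == "trend"], 0.01)
})

test_that("degenerate descriptor tables are handled explicitly", {
  tab <- data.frame(stimulus_id = rep(c("a", "b"), each = 4),
                    trend = rep(c(0.2, 0.2), each = 4),
                    summed_values = rep(c(10, 10), each = 4),
                    max_slope = rep(c(0.1, 0.1), each = 4),
                    participant_id = factor(rep(1:4, 2)),
                    agreement = stats::runif(8))
  expect_error(exploratory_descriptor_model(tab), "collinear|aliased")
  tab2 <- data.frame(stimulus_id = rep(c("a", "b", "c", "d"), each = 4),
                     trend = rep(c(-1, 0, .5, 1), each = 4),
                     summed_values = rep(c(10, 20, 15, 12), each = 4),
                     max_slope = rep(c(.1, .2, .15, .3), each = 4),
                     participant_id = factor(rep(1:4, 4)),
                     agreement = 0.5)
  fit <- exploratory_descriptor_model(tab2)
  expect_equal(fit$coefficients$estimate[-1], c(0, 0, 0))
})

test_that("permuting the outcome destroys the three-way interaction", {
  fx <- make_paper_fixture(2, seed = 31)
  ag <- cohort_agreement(bin_cohort(fx$cohort))
  tab <- agreement_model_table(ag, fx$designs)
  set.seed(61)
  tab$agreement <- sample(tab$agreement)
  fit <- fit_lmm(agreement ~ trend * framing * salience +
                   (1 | participant_id), tab)
  co <- fit$coefficients
  p3 <- co$p[grepl("^trend:.+:.+$", co$term)]
  expect_gt(p3, 0.01)
})
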