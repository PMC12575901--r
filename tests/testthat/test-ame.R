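# One factorial fit shared across the AME tests.
ame_fixture <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fx <- make_paper_fixture(2, seed = 13)
      ag <- cohort_agreement(bin_cohort(fx$cohort))
      tab <- agreement_model_table(ag, fx$designs)
      fit <<- fit_lmm(agreement ~ trend * framing * salience +
                        (1 | participant_id), tab)
    }
    fit
  }
})

test_that("the reference cell's AME is the trend coefficient itself", {
  fit <- ame_fixture()
  a <- ame_trend(fit, c(framing = "endangered", salience = "hue"))
  co <- fit$coefficients[fit$coefficients$term == "trend", ]
  expect_equal(a$ame, co$estimate)
  expect_equal(a$se, co$se, tolerance = 1e-10)
})

test_that("coefficient-summation AMEs equal numeric derivatives", {
  fit <- ame_fixture()
  cells <- expand.grid(framing = c("endangered", "invasive"),
                       salience = c("hue", "saturation"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    at <- c(framing = cells$framing[i], salience = cells$salience[i])
    expect_lt(abs(ame_trend(fit, at)$ame - ame_trend_numeric(fit, at)),
              1e-10)
  }
})

test_that("cell AMEs satisfy the coefficient-algebra identity", {
  fit <- ame_fixture()
  cells <- ame_trend_cells(fit)
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  lhs <- sum(cells$ame)
  rhs <- 4 * est["trend"] + 2 * est["trend:framinginvasive"] +
    2 * est["trend:saliencesaturation"] +
    est["trend:framinginvasive:saliencesaturation"]
  expect_equal(lhs, unname(rhs), tolerance = 1e-12)
})

test_that("published coefficient tables reproduce the printed AME", {
  co <- c("trend" = -0.002,
          "trend:framinginvasive" = 0.005,
          "trend:saliencesaturation" = -0.029,
          "trend:framinginvasive:saliencesaturation" = 0.046)
  ame <- ame_from_coefficients(
    co, c(framing = "invasive", salience = "saturation"))
  expect_equal(ame, 0.020)
  # reference cell: only the bare trend coefficient is active
  expect_equal(ame_from_coefficients(
    co, c(framing = "endangered", salience = "hue")), -0.002)
  expect_equal(ame_from_coefficients(
    co, c(framing = "endangered", salience = "saturation")), -0.031)
})

test_that("a model without trend terms is rejected", {
  set.seed(5)
  d <- data.frame(agreement = stats::runif(40),
                  framing = factor(rep(c("endangered", "invasive"), 20)),
                  participant_id = factor(rep(1:10, each = 4)))
  fit <- fit_lmm(agreement ~ framing + (1 | participant_id), d)
  expect_error(ame_trend(fit, c(framing = "invasive")), "no trend")
})
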