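#' Published variance components of the colour-factorial agreement model
#'
#' The documented default variance components for power simulation: the
#' per-participant random intercept and slope standard deviations, their
#' correlation matrix, and the residual standard deviation estimated by the
#' colour-factorial segmentation-agreement model. (The assumptions behind
#' the original a-priori power runs were not published; these fitted
#' components are the package's documented stand-in.)
#'
#' @return list with `sd` (named: intercept, trend, framing, salience),
#'   `cor` (4 x 4 correlation matrix), `residual_sd`.
#' @export
table6_components <- function() {
  sd <- c(intercept = 0.0911, trend = 0.0310, framing = 0.0028,
          salience = 0.0142)
  cor <- matrix(c(1, 0.61, -0.32, -0.20,
                  0.61, 1, -0.74, -0.69,
                  -0.32, -0.74, 1, 0.99,
                  -0.20, -0.69, 0.99, 1), 4, 4,
                dimnames = list(names(sd), names(sd)))
  list(sd = sd, cor = cor, residual_sd = 0.1777)
}

#' Monte-Carlo power for the trend x framing x salience interaction
#'
#' Simulates agreement data from the mixed-model data-generating process —
#' per-participant random intercepts and slopes with the supplied
#' covariance, all fixed effects zero except the three-way interaction set
#' to `effect`, Gaussian residuals — refits the full factorial model per
#' replicate, and counts rejections of the interaction at level `alpha`
#' (Satterthwaite test). Replicates whose fit fails count as
#' non-rejections and are reported separately.
#'
#' @param effect true three-way-interaction coefficient.
#' @param n_participants participants per replicate.
#' @param design per-participant trial structure: a [design_table()]
#'   data.frame (or design list) with `trend`, `framing`, `salience`
#'   columns; every participant sees every row once.
#' @param variance_components list as returned by [table6_components()].
#' @param reps Monte-Carlo replicates (default 200; below 50 a warning is
#'   raised — the binomial CI is wide).
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @return object of class `seg_power`: `power`, exact binomial `ci`,
#'   `rejections`, `reps`, `nonconverged`, `effect`, `n_participants`,
#'   `alpha`.
#' @export
power_simulation <- function(effect, n_participants, design,
                             variance_components = table6_components(),
                             reps = 200L, alpha = 0.05, seed = 1L) {
  if (reps < 50) warning("fewer than 50 replicates: power CI will be wide")
  if (!is.data.frame(design)) design <- design_table(design)
  vc <- variance_components
  Sigma <- diag(vc$sd) %*% vc$cor %*% diag(vc$sd)
  ch <- chol(Sigma)

  base <- prepare_model_table(
    design[c("trend", "framing", "salience")])
  f2 <- as.numeric(base$framing != levels(base$framing)[1])
  s2 <- as.numeric(base$salience != levels(base$salience)[1])
  Z1 <- cbind(1, base$trend, f2, s2)          # random-effect design
  n_trials <- nrow(base)
  dat <- base[rep(seq_len(n_trials), n_participants), ]
  dat$participant_id <- factor(rep(seq_len(n_participants),
                                   each = n_trials))
  Z <- Z1[rep(seq_len(n_trials), n_participants), ]
  fx <- effect * dat$trend * rep(f2, n_participants) *
    rep(s2, n_participants)
  form <- agreement ~ trend * framing * salience +
    (trend + framing + salience | participant_id)

  rej <- logical(reps)
  bad <- logical(reps)
  start <- NULL
  with_seed(substream_seed(seed, "power"), {
    for (r in seq_len(reps)) {
      b <- matrix(stats::rnorm(n_participants * 4), n_participants) %*% ch
      dat$agreement <- fx +
        rowSums(Z * b[as.integer(dat$participant_id), ]) +
        stats::rnorm(nrow(dat), 0, vc$residual_sd)
      res <- tryCatch({
        fit <- fit_lmm(form, dat, start = start)
        co <- fit$coefficients
        row <- match_interaction(co$term)
        start <- lme4::getME(fit$model, "theta")
        co$p[row] < alpha
      }, error = function(e) NA)
      if (is.na(res)) bad[r] <- TRUE else rej[r] <- res
    }
  })
  k <- sum(rej)
  ci <- as.numeric(stats::binom.test(k, reps)$conf.int)
  structure(list(power = k / reps, ci = ci, rejections = k, reps = reps,
                 nonconverged = sum(bad), effect = effect,
                 n_participants = n_participants, alpha = alpha),
            class = "seg_power")
}

match_interaction <- function(terms) {
  hit <- grep("^trend:.+:.+$", terms)
  if (length(hit) != 1) stop("three-way trend interaction term not found")
  hit
}

#' @export
print.seg_power <- function(x, ...) {
  cat(sprintf(
    "<seg_power> effect %.3g, n %d: power %.3f (95%% CI %.3f-%.3f, %d/%d; %d fit failures)\n",
    x$effect, x$n_participants, x$power, x$ci[1], x$ci[2], x$rejections,
    x$reps, x$nonconverged))
  invisible(x)
}
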