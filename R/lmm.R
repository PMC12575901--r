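#' Fit a linear mixed model under the reporting contract
#'
#' REML fit via [lmerTest::lmer()] with Satterthwaite degrees of freedom
#' and Wald 95% confidence intervals for the fixed effects. Factors should
#' use treatment coding; [prepare_model_table()] sets the reference levels
#' used throughout (endangered, hue, distributed, cross-stimulus).
#' Boundary (zero-variance) random effects are reported, not hidden;
#' rank-deficient fixed effects raise an error naming the aliased terms;
#' optimizer non-convergence raises an error carrying the diagnostics.
#'
#' @param formula an `lmer` model formula.
#' @param data model data.frame (one row per analyzable trial).
#' @param reml fit by REML (default TRUE).
#' @param start optional start values for the covariance parameters.
#' @return object of class `seg_lmm`: list with `coefficients` (estimate,
#'   se, ci_lower, ci_upper, t, df, p, d per term), `random_effects`,
#'   `residual_sd`, `r2_marginal`, `r2_conditional`, `singular`, `model`.
#' @export
fit_lmm <- function(formula, data, reml = TRUE, start = NULL) {
  fit <- withCallingHandlers(
    lmerTest::lmer(formula, data = data, REML = reml, start = start,
                   control = lme4::lmerControl(
                     optimizer = "bobyqa", calc.derivs = FALSE,
                     check.conv.singular = "ignore")),
    warning = function(w) invokeRestart("muffleWarning"))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("mixed-model optimizer did not converge (code ", conv, "): ",
         paste(unlist(fit@optinfo$message), collapse = "; "))
  }
  X <- lme4::getME(fit, "X")
  dropped <- attr(X, "col.dropped")
  if (!is.null(dropped) || qr(X)$rank < ncol(X)) {
    stop("rank-deficient fixed effects; aliased: ",
         paste(if (is.null(dropped)) "unknown term" else names(dropped),
               collapse = ", "))
  }
  summarize_lmm(fit)
}

summarize_lmm <- function(fit) {
  co <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  re_var <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  total_sd <- sqrt(re_var + resid_sd^2)
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lower = co[, "Estimate"] - z * co[, "Std. Error"],
    ci_upper = co[, "Estimate"] + z * co[, "Std. Error"],
    t = co[, "t value"],
    df = co[, "df"],
    p = co[, "Pr(>|t|)"],
    d = co[, "Estimate"] / total_sd,
    row.names = NULL, stringsAsFactors = FALSE)
  r2 <- r2_mixed(fit)
  structure(
    list(coefficients = coefs, random_effects = vc, residual_sd = resid_sd,
         r2_marginal = r2[1], r2_conditional = r2[2],
         singular = lme4::isSingular(fit), model = fit),
    class = "seg_lmm")
}

#' @export
print.seg_lmm <- function(x, digits = 3, ...) {
  cat("<seg_lmm>", if (x$singular) "(boundary fit)" else "", "\n")
  print(cbind(term = x$coefficients$term,
              round(x$coefficients[-1], digits)), row.names = FALSE)
  cat(sprintf("R2 marginal %.3f / conditional %.3f, residual sd %.3f\n",
              x$r2_marginal, x$r2_conditional, x$residual_sd))
  invisible(x)
}

# Marginal / conditional R2 for a Gaussian mixed model: fixed-effect
# variance over total, and fixed-plus-random over total, with each random
# term's contribution averaged over the observed design.
r2_mixed <- function(fit) {
  var_f <- stats::var(stats::predict(fit, re.form = NA))
  vc <- lme4::VarCorr(fit)
  fr <- stats::model.frame(fit)
  var_r <- 0
  re_terms <- lme4::findbars(stats::formula(fit))
  for (term in re_terms) {
    g <- deparse(term[[3]])
    Sigma <- as.matrix(vc[[g]])
    Zt <- stats::model.matrix(stats::reformulate(deparse(term[[2]])), fr)
    Zt <- Zt[, rownames(Sigma), drop = FALSE]
    var_r <- var_r + mean(rowSums((Zt %*% Sigma) * Zt))
  }
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Set the treatment-coded reference levels of a model table
#'
#' Reference levels follow the published sign conventions: framing
#' `endangered`, salience `hue` (colour factorial) or `distributed`
#' (spatial factorial), comparison contrast `cross_stimulus`. Trend stays
#' numeric on its natural `[-1, 1]` scale.
#'
#' @param df data.frame with any of the columns `framing`, `salience`,
#'   `comparison`.
#' @return the data.frame with releveled factors.
#' @export
prepare_model_table <- function(df) {
  ref_of <- function(x, prefs) {
    lev <- unique(as.character(x))
    ref <- prefs[prefs %in% lev]
    if (length(ref) == 0) return(factor(x))
    stats::relevel(factor(x), ref = ref[1])
  }
  if (!is.null(df$framing)) df$framing <- ref_of(df$framing, "endangered")
  if (!is.null(df$salience)) {
    df$salience <- ref_of(df$salience, c("hue", "distributed"))
  }
  if (!is.null(df$comparison)) {
    df$comparison <- ref_of(df$comparison, c("cross_stimulus", "other_group"))
  }
  df
}

#' Merge agreement records with design factors
#'
#' @param records agreement records ([cohort_agreement()] output).
#' @param designs design list or [design_table()] data.frame.
#' @return model table with agreement, trend, framing, salience columns,
#'   releveled by [prepare_model_table()].
#' @export
agreement_model_table <- function(records, designs) {
  dt <- if (is.data.frame(designs)) designs else design_table(designs)
  out <- merge(records, dt, by = "stimulus_id", sort = FALSE)
  prepare_model_table(out)
}

#' Exploratory descriptor model
#'
#' Agreement regressed on the stimulus-level descriptors — trend, summed
#' values, maximal slope — with random intercepts for participant and
#' stimulus. Raises an aliasing error when the descriptors are collinear
#' across stimuli. A constant outcome returns zero slopes directly (the
#' mixed model is degenerate there).
#'
#' @param table data.frame with columns `agreement`, `trend`,
#'   `summed_values`, `max_slope`, `participant_id`, `stimulus_id`.
#' @return a `seg_lmm` (or a minimal zero-slope stand-in for constant
#'   outcomes).
#' @export
exploratory_descriptor_model <- function(table) {
  X <- cbind(1, table$trend, table$summed_values, table$max_slope)
  if (qr(X)$rank < 4) {
    stop("aliased descriptors: trend, summed_values and max_slope are ",
         "collinear across stimuli")
  }
  if (stats::var(table$agreement) == 0) {
    coefs <- data.frame(
      term = c("(Intercept)", "trend", "summed_values", "max_slope"),
      estimate = c(table$agreement[1], 0, 0, 0), se = 0,
      ci_lower = NA_real_, ci_upper = NA_real_, t = NA_real_,
      df = NA_real_, p = NA_real_, d = NA_real_)
    return(structure(list(coefficients = coefs, random_effects = NULL,
                          residual_sd = 0, r2_marginal = NA_real_,
                          r2_conditional = NA_real_, singular = TRUE,
                          model = NULL),
                     class = "seg_lmm"))
  }
  fit_lmm(agreement ~ trend + summed_values + max_slope +
            (1 | participant_id) + (1 | stimulus_id), table)
}
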