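#' Average marginal effect of trend in a factorial cell
#'
#' For the treatment-coded factorial model the marginal effect of trend in
#' a framing x salience cell is the sum of the trend coefficient and every
#' trend interaction active in that cell (e.g. invasive x saturation
#' activates trend, trend:framing, trend:salience and the three-way term).
#' The standard error follows from the delta method on the coefficient
#' covariance; for this linear model the coefficient sum matches the
#' averaged per-observation derivative exactly.
#'
#' @param fit a [fit_lmm()] result from the full factorial specification.
#' @param at named character vector of cell levels, e.g.
#'   `c(framing = "invasive", salience = "saturation")`.
#' @param trend_var name of the numeric trend column (default "trend").
#' @return one-row data.frame: `ame`, `se`, `ci_lower`, `ci_upper`, `z`,
#'   `p`, plus the cell levels.
#' @export
ame_trend <- function(fit, at, trend_var = "trend") {
  terms <- fit$coefficients$term
  a <- ame_weights(terms, at, trend_var)
  if (sum(a) == 0) stop("model has no ", trend_var, " terms")
  V <- as.matrix(stats::vcov(fit$model))
  est <- sum(a * fit$coefficients$estimate)
  se <- sqrt(drop(t(a) %*% V %*% a))
  z <- est / se
  zq <- stats::qnorm(0.975)
  out <- data.frame(ame = est, se = se, ci_lower = est - zq * se,
                    ci_upper = est + zq * se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  cbind(as.data.frame(as.list(at), stringsAsFactors = FALSE), out)
}

#' Marginal effect of trend from published coefficients
#'
#' The coefficient-summation rule applied to a named coefficient vector
#' (for instance a table transcribed from a report), without needing the
#' fitted model object.
#'
#' @param coefs named numeric vector of fixed-effect estimates, with
#'   treatment-coded interaction names like `trend:framinginvasive`.
#' @param at named character vector of cell levels.
#' @param trend_var trend variable name.
#' @return the marginal effect (numeric scalar).
#' @examples
#' co <- c("trend" = -0.002, "trend:framinginvasive" = 0.005,
#'         "trend:saliencesaturation" = -0.029,
#'         "trend:framinginvasive:saliencesaturation" = 0.046)
#' ame_from_coefficients(co, c(framing = "invasive", salience = "saturation"))
#' @export
ame_from_coefficients <- function(coefs, at, trend_var = "trend") {
  a <- ame_weights(names(coefs), at, trend_var)
  sum(a * coefs)
}

# 0/1 weight per term: 1 when the term contains the trend variable and all
# its other components are active at the given cell levels.
ame_weights <- function(terms, at, trend_var) {
  active <- paste0(names(at), as.character(at))
  vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!trend_var %in% parts) return(0)
    rest <- setdiff(parts, trend_var)
    as.numeric(all(rest %in% active))
  }, 0, USE.NAMES = FALSE)
}

#' Marginal effect of trend by numeric differentiation
#'
#' Central finite difference of the model's population-level predictions
#' with respect to trend, averaged over the observations of the given
#' cell's factor levels. Agrees with [ame_trend()] to machine precision
#' for the linear model; exposed as a consistency check.
#'
#' @inheritParams ame_trend
#' @param h half-width of the finite difference (default 1e-4).
#' @return numeric scalar.
#' @export
ame_trend_numeric <- function(fit, at, trend_var = "trend", h = 1e-4) {
  fr <- stats::model.frame(fit$model)
  for (v in names(at)) {
    fr[[v]] <- factor(as.character(at[[v]]), levels = levels(fr[[v]]))
  }
  up <- fr; up[[trend_var]] <- up[[trend_var]] + h
  dn <- fr; dn[[trend_var]] <- dn[[trend_var]] - h
  mean((stats::predict(fit$model, newdata = up, re.form = NA) -
          stats::predict(fit$model, newdata = dn, re.form = NA)) / (2 * h))
}

#' Marginal effects of trend for every factorial cell
#'
#' @param fit full-factorial [fit_lmm()] result.
#' @param framing_levels,salience_levels factor levels (defaults read from
#'   the model frame).
#' @param trend_var trend variable name.
#' @return data.frame with one row per framing x salience cell.
#' @export
ame_trend_cells <- function(fit, framing_levels = NULL,
                            salience_levels = NULL, trend_var = "trend") {
  fr <- stats::model.frame(fit$model)
  if (is.null(framing_levels)) framing_levels <- levels(fr$framing)
  if (is.null(salience_levels)) salience_levels <- levels(fr$salience)
  cells <- expand.grid(framing = framing_levels, salience = salience_levels,
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ame_trend(fit, c(framing = cells$framing[i],
                     salience = cells$salience[i]), trend_var)
  })
  do.call(rbind, out)
}
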