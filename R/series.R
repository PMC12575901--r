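#' Construct a value series
#'
#' A value series holds the per-region keyframe values of one stimulus
#' (regions x keyframes, values in `[0, 1]`; a `duration_s`-second stimulus
#' has `duration_s + 1` integer-second keyframes) together with the derived
#' global (mean) series and its descriptors: trend (last minus first global
#' value), summed values, and maximal one-second slope.
#'
#' @param values regions x (duration + 1) numeric matrix in `[0, 1]`.
#' @param duration_s duration in seconds.
#' @return object of class `value_series`.
#' @export
value_series <- function(values, duration_s) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == duration_s + 1L)
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stop("values must lie in [0, 1]")
  }
  g <- colMeans(values)
  structure(
    list(values = values, duration_s = as.integer(duration_s),
         global_series = g,
         trend = g[length(g)] - g[1],
         summed_values = sum(g),
         max_slope = if (length(g) > 1) max(abs(diff(g))) else 0),
    class = "value_series")
}

#' @export
print.value_series <- function(x, ...) {
  cat(sprintf(
    "<value_series> %d regions x %d s | trend %+0.3f, max slope %0.3f\n",
    nrow(x$values), x$duration_s, x$trend, x$max_slope))
  invisible(x)
}

#' Descriptors of a value series
#'
#' @param series a `value_series`.
#' @return one-row data.frame with `trend`, `summed_values`, `max_slope`.
#' @export
series_descriptors <- function(series) {
  data.frame(trend = series$trend, summed_values = series$summed_values,
             max_slope = series$max_slope)
}

#' Generate a random piecewise-linear stimulus (experiment-1 style)
#'
#' The global series starts at 0 and each second advances by the current
#' slope, drawn uniformly from `[-1, 1]`; the slope changes at 5 to 10
#' seed-chosen distinct interior seconds. The global series is min-max
#' rescaled to `[0, 1]`, independent Gaussian noise (sd `noise_sd`) is added
#' per region per second, and the full matrix is min-max rescaled to
#' `[0, 1]` again, so the matrix minimum is exactly 0 and its maximum
#' exactly 1.
#'
#' @param duration_s duration in seconds (default 60).
#' @param n_regions number of regions (default 10).
#' @param noise_sd per-region noise sd (default 0.1).
#' @param seed integer seed.
#' @param smooth_noise integer width of an optional moving-average kernel
#'   applied to each region's noise over time (default 0 = off; the raw
#'   generator uses i.i.d. per-second noise).
#' @return a [value_series()].
#' @export
generate_exp1_series <- function(duration_s = 60L, n_regions = 10L,
                                 noise_sd = 0.1, seed = 1L,
                                 smooth_noise = 0L) {
  stopifnot(duration_s >= 2)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(substream_seed(seed, "exp1"), {
    n_changes <- sample(5:10, 1L)
    change_at <- sort(sample(seq_len(duration_s - 1L), n_changes))
    slopes <- stats::runif(n_changes + 1L, -1, 1)
    slope_per_sec <- slopes[1L + findInterval(seq_len(duration_s) - 1L,
                                              change_at)]
    g <- cumsum(c(0, slope_per_sec))
    g <- rescale01(g)
    noise <- matrix(stats::rnorm(n_regions * (duration_s + 1L), 0, noise_sd),
                    n_regions)
    if (smooth_noise > 1) {
      k <- rep(1 / smooth_noise, smooth_noise)
      noise <- t(apply(noise, 1, function(r) {
        stats::filter(r, k, sides = 2) |> fill_ends(r)
      }))
    }
    vals <- rep(1, n_regions) %o% g + noise
    vals <- rescale01(vals)
    attr_changes <- change_at
    out <- value_series(vals, duration_s)
    out$slope_changes <- attr_changes
    out
  })
}

rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < 1e-300) return(x - rng[1])
  (x - rng[1]) / (rng[2] - rng[1])
}

fill_ends <- function(sm, raw) {
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- raw[is.na(sm)]
  sm
}

#' Feasible start values for a nominal trend
#'
#' A stimulus whose mean value changes by `trend_level` over its run must
#' start somewhere that keeps both endpoints inside `[0, 1]`:
#' `[max(0, -trend), min(1, 1 - trend)]`. A trend of -1 forces a start of 1;
#' a trend of -0.43 allows any start in `[0.43, 1]`.
#'
#' @param trend_level real in `[-1, 1]`.
#' @return numeric `c(lo, hi)`.
#' @export
feasible_start_range <- function(trend_level) {
  if (abs(trend_level) > 1) {
    stop("no feasible start value: |trend| > 1")
  }
  c(max(0, -trend_level), min(1, 1 - trend_level))
}

#' Generate a colour-factorial stimulus (experiment-2 style)
#'
#' The noise-free global series runs linearly from a feasible start value
#' (drawn uniformly from [feasible_start_range()]) to start + trend.
#' Per-region series add independent Gaussian noise (sd `design$noise_sd`)
#' per second and are *truncated* — clipped, never rescaled — to `[0, 1]`,
#' preserving the nominal trend manipulation.
#'
#' @param design a [stimulus_design()] with `experiment == 2`.
#' @param n_regions number of regions (default 10).
#' @return a [value_series()].
#' @export
generate_exp2_series <- function(design, n_regions = 10L) {
  stopifnot(inherits(design, "stimulus_design"), design$experiment == 2L)
  dur <- design$duration_s
  rng <- feasible_start_range(design$trend_level)
  start <- with_seed(substream_seed(design$seed, "start"),
                     stats::runif(1, rng[1], rng[2]))
  g <- seq(start, start + design$trend_level, length.out = dur + 1L)
  vals <- add_truncated_noise(rep(1, n_regions) %o% g, design)
  value_series(vals, dur)
}

add_truncated_noise <- function(base, design) {
  if (design$noise_sd == 0) return(pmin(pmax(base, 0), 1))
  noise <- with_seed(substream_seed(design$seed, "noise"),
                     matrix(stats::rnorm(length(base), 0, design$noise_sd),
                            nrow(base)))
  pmin(pmax(base + noise, 0), 1)
}

#' Generate a spatial-pattern stimulus (experiment-3 style)
#'
#' The changing regions follow a shared linear trajectory with total change
#' `design$trend_level` from a feasible start; each stable region holds a
#' constant level drawn uniformly from `[0.2, 0.8]`. All regions then
#' receive independent per-second Gaussian noise (sd `design$noise_sd`) and
#' are truncated to `[0, 1]`.
#'
#' @param design a [stimulus_design()] with `experiment == 3` and a
#'   non-empty `changing_regions` set.
#' @param map the `region_map` the design was resolved against.
#' @return a [value_series()].
#' @export
generate_exp3_series <- function(design, map) {
  stopifnot(inherits(design, "stimulus_design"), design$experiment == 3L)
  n_regions <- length(map$regions)
  ids <- design$changing_regions
  if (length(ids) == 0) stop("design has no changing regions")
  if (any(ids < 0 | ids >= n_regions)) {
    stop("changing_regions outside the map's region ids")
  }
  dur <- design$duration_s
  rng <- feasible_start_range(design$trend_level)
  draws <- with_seed(substream_seed(design$seed, "levels"),
                     list(start = stats::runif(1, rng[1], rng[2]),
                          stable = stats::runif(n_regions, 0.2, 0.8)))
  g <- seq(draws$start, draws$start + design$trend_level,
           length.out = dur + 1L)
  base <- draws$stable %o% rep(1, dur + 1L)
  base[ids + 1L, ] <- rep(1, length(ids)) %o% g
  vals <- add_truncated_noise(base, design)
  value_series(vals, dur)
}

#' Generate the series for a list of designs
#'
#' @param designs list of [stimulus_design()] objects (experiment 2 or 3;
#'   experiment-3 designs must carry resolved changing regions).
#' @param map `region_map`, required for experiment-3 designs.
#' @param n_regions regions for experiment-2 designs.
#' @return named list of [value_series()], keyed by `stimulus_id`.
#' @export
generate_series <- function(designs, map = NULL, n_regions = 10L) {
  out <- lapply(designs, function(d) {
    switch(as.character(d$experiment),
           "2" = generate_exp2_series(d, n_regions = n_regions),
           "3" = generate_exp3_series(d, map),
           stop("generate_series handles experiment 2 and 3 designs"))
  })
  names(out) <- vapply(designs, `[[`, "", "stimulus_id")
  out
}
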