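#' Response-model parameters
#'
#' Parameters of the synthetic key-press model. Per second, a participant
#' presses with hazard
#' `clip(base_rate + change_gain * |dg| + congruence_gain * c, 0, 1)`,
#' where `dg` is the one-second change of the stimulus' global value series
#' and `c = |dg|` when the stimulus' trend direction is congruent with its
#' framing (invasive -> increasing, endangered -> decreasing), else 0.
#' Low-salience stimuli (hue colour scales, distributed change) halve the
#' effective change gain. These are artifact conventions for generating
#' data with the assumed statistical structure — not estimates of human
#' behaviour.
#'
#' @param base_rate baseline per-second press hazard in (0, 1).
#' @param change_gain non-negative weight on `|dg|`.
#' @param congruence_gain weight on the framing-congruence term.
#' @param participant_sd sd of the per-participant log-hazard intercept.
#' @param refractory_s minimum gap between retained presses (seconds).
#' @param low_salience_factor multiplier on `change_gain` for low-salience
#'   stimuli (default 0.5).
#' @return a `response_params` list.
#' @export
response_params <- function(base_rate = 0.05, change_gain = 1.5,
                            congruence_gain = 0.75, participant_sd = 0.4,
                            refractory_s = 0.5, low_salience_factor = 0.5) {
  stopifnot(base_rate > 0, base_rate < 1, change_gain >= 0,
            participant_sd >= 0, refractory_s >= 0)
  structure(list(base_rate = base_rate, change_gain = change_gain,
                 congruence_gain = congruence_gain,
                 participant_sd = participant_sd,
                 refractory_s = refractory_s,
                 low_salience_factor = low_salience_factor),
            class = "response_params")
}

#' Per-second press hazard for one stimulus
#'
#' @param series the stimulus' [value_series()].
#' @param design its [stimulus_design()].
#' @param params a [response_params()].
#' @return numeric hazard vector of length `duration_s`, entries in
#'   `[0, 1]`; element t covers the second `[t-1, t)`.
#' @export
press_hazard <- function(series, design, params) {
  if (series$duration_s != design$duration_s) {
    stop("series and design durations differ")
  }
  dg <- abs(diff(series$global_series))
  gain <- params$change_gain
  if (!is.na(design$salience) &&
      design$salience %in% c("hue", "distributed")) {
    gain <- gain * params$low_salience_factor
  }
  trend_sign <- sign(if (is.na(design$trend_level)) series$trend
                     else design$trend_level)
  congruent <- (design$framing == "invasive" && trend_sign > 0) ||
    (design$framing == "endangered" && trend_sign < 0)
  cterm <- if (congruent) dg else 0
  pmin(pmax(params$base_rate + gain * dg +
              params$congruence_gain * cterm, 0), 1)
}

#' Simulate a cohort of segmenting participants
#'
#' Each participant gets a log-hazard intercept `b ~ N(0, participant_sd)`;
#' their hazard for every stimulus is `clip(hazard * exp(b), 0, 1)`. Presses
#' are per-second Bernoulli draws placed uniformly within their second and
#' thinned so retained presses are at least `refractory_s` apart. Fully
#' deterministic given the seed.
#'
#' @param designs list of [stimulus_design()] objects.
#' @param series named list of [value_series()] (names = stimulus ids).
#' @param n_participants cohort size (a warning is raised below 2, since
#'   agreement needs at least two participants).
#' @param params a [response_params()].
#' @param seed integer seed.
#' @param group optional per-participant group labels (length 1 or
#'   `n_participants`).
#' @return object of class `seg_cohort`: list with `logs` (one row per
#'   press: participant_id, stimulus_id, group, press_time_s), `trials`
#'   (one row per participant x stimulus: n_presses, status), `duration_s`,
#'   `designs`.
#' @export
simulate_cohort <- function(designs, series, n_participants, params, seed,
                            group = "all") {
  if (n_participants < 2) {
    warning("agreement needs at least 2 participants")
  }
  ids <- vapply(designs, `[[`, "", "stimulus_id")
  if (!all(ids %in% names(series))) stop("every design needs a series")
  dur <- unique(vapply(designs, `[[`, 0L, "duration_s"))
  if (length(dur) != 1) stop("stimuli must share one duration")
  group <- rep_len(group, n_participants)
  pid <- sprintf("p%03d", seq_len(n_participants))

  b <- with_seed(substream_seed(seed, "intercepts"),
                 stats::rnorm(n_participants, 0, params$participant_sd))
  mult <- exp(b)

  logs <- vector("list", length(ids))
  trials <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    hz <- press_hazard(series[[ids[s]]], designs[[s]], params)
    hmat <- pmin(mult %o% hz, 1)  # participants x seconds
    draws <- with_seed(substream_seed(seed, "press", s), {
      u <- matrix(stats::runif(length(hmat)), nrow(hmat))
      offs <- matrix(stats::runif(length(hmat)), nrow(hmat))
      list(hit = u < hmat, offs = offs)
    })
    sec <- col(hmat) - 1L
    plist <- lapply(seq_len(n_participants), function(i) {
      t_i <- sec[i, draws$hit[i, ]] + draws$offs[i, draws$hit[i, ]]
      thin_refractory(sort(t_i), params$refractory_s)
    })
    np <- lengths(plist)
    logs[[s]] <- data.frame(
      participant_id = rep(pid, np),
      stimulus_id = ids[s],
      group = rep(group, np),
      press_time_s = unlist(plist),
      stringsAsFactors = FALSE)
    trials[[s]] <- data.frame(
      participant_id = pid, stimulus_id = ids[s], group = group,
      n_presses = np, stringsAsFactors = FALSE)
  }
  new_cohort(do.call(rbind, logs), do.call(rbind, trials), dur, designs)
}

new_cohort <- function(logs, trials, duration_s, designs) {
  rownames(logs) <- NULL
  rownames(trials) <- NULL
  structure(list(logs = logs, trials = trials,
                 duration_s = as.integer(duration_s), designs = designs),
            class = "seg_cohort")
}

#' @export
print.seg_cohort <- function(x, ...) {
  cat(sprintf(
    "<seg_cohort> %d participants x %d stimuli (%d s), %d presses\n",
    length(unique(x$trials$participant_id)),
    length(unique(x$trials$stimulus_id)), x$duration_s, nrow(x$logs)))
  invisible(x)
}

thin_refractory <- function(times, gap) {
  if (length(times) < 2 || gap <= 0) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= gap) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Classify and filter trials
#'
#' Labels every participant x stimulus trial `ok`, `empty` (no presses) or
#' `post_end` (any press beyond the stimulus duration; such logs are
#' treated as logging errors and excluded whole). The returned cohort
#' carries the audit counts in `attr(, "filter_audit")` — exclusions are
#' counted, never silently dropped.
#'
#' @param cohort a `seg_cohort`.
#' @return the cohort with `trials$status` filled in and the audit
#'   attribute set.
#' @export
filter_trials <- function(cohort) {
  lg <- cohort$logs
  post <- unique(lg[lg$press_time_s > cohort$duration_s,
                    c("participant_id", "stimulus_id")])
  key <- function(d) paste(d$participant_id, d$stimulus_id)
  st <- ifelse(cohort$trials$n_presses == 0L, "empty", "ok")
  st[key(cohort$trials) %in% key(post)] <- "post_end"
  cohort$trials$status <- st
  audit <- c(total = nrow(cohort$trials), table(factor(
    st, levels = c("ok", "empty", "post_end"))))
  attr(cohort, "filter_audit") <- audit
  cohort
}

#' Simulated cohorts with the published trial accounting
#'
#' Builds a synthetic stand-in for the two factorial datasets with the
#' exact defective-trial bookkeeping reported for them: the colour-scale
#' experiment has 117 participants x 31 stimuli (one stimulus was lost to a
#' presentation error) with exactly 267 empty logs and 11 logs whose only
#' presses fall after the video end; the spatial-pattern experiment has
#' 176 x 32 with 395 empty and 13 post-end logs. Defective logs are placed
#' seed-randomly; simulated trials not designated defective are guaranteed
#' at least one press so the counts are exact by construction.
#'
#' @param experiment 2 or 3.
#' @param seed integer seed.
#' @param params a [response_params()].
#' @return list with `cohort` (already [filter_trials()]ed), `designs`,
#'   `series`, and (experiment 3) `map`.
#' @export
make_paper_fixture <- function(experiment, seed = 1L,
                               params = response_params()) {
  stopifnot(experiment %in% c(2, 3))
  if (experiment == 2) {
    designs <- enumerate_design(2, seed = seed)
    # the stimulus lost to the presentation error: trend 1, hue, invasive
    drop <- vapply(designs, function(d) {
      d$trend_level == 1 && d$salience == "hue" && d$framing == "invasive"
    }, TRUE)
    designs <- designs[!drop]
    series <- generate_series(designs)
    map <- NULL
    n_part <- 117L; n_empty <- 267L; n_post <- 11L
  } else {
    map <- build_region_map(n_regions = 10L,
                            seed = substream_seed(seed, "map"))
    designs <- resolve_changing_regions(enumerate_design(3, seed = seed), map)
    series <- generate_series(designs, map = map)
    n_part <- 176L; n_empty <- 395L; n_post <- 13L
  }
  cohort <- simulate_cohort(designs, series, n_part, params,
                            seed = substream_seed(seed, "cohort"))
  cohort <- force_defective_trials(cohort, n_empty, n_post,
                                   seed = substream_seed(seed, "defects"))
  cohort <- filter_trials(cohort)
  list(cohort = cohort, designs = designs, series = series, map = map)
}

# Designate exactly n_empty trials as empty and n_post as post-end-only;
# inject one uniform press into any other trial that simulated empty.
force_defective_trials <- function(cohort, n_empty, n_post, seed) {
  tr <- cohort$trials
  n <- nrow(tr)
  dur <- cohort$duration_s
  pick <- with_seed(substream_seed(seed, "placement"),
                    sample.int(n, n_empty + n_post))
  empty_idx <- pick[seq_len(n_empty)]
  post_idx <- pick[n_empty + seq_len(n_post)]
  key <- paste(tr$participant_id, tr$stimulus_id)
  lkey <- paste(cohort$logs$participant_id, cohort$logs$stimulus_id)

  drop <- lkey %in% key[c(empty_idx, post_idx)]
  logs <- cohort$logs[!drop, , drop = FALSE]

  post_rows <- cohort$trials[post_idx, c("participant_id", "stimulus_id",
                                         "group")]
  post_rows$press_time_s <- with_seed(substream_seed(seed, "post"),
                                      dur + stats::runif(n_post, 0.05, 2))
  rescue_idx <- setdiff(which(tr$n_presses == 0L), c(empty_idx, post_idx))
  rescue_rows <- tr[rescue_idx, c("participant_id", "stimulus_id", "group")]
  if (nrow(rescue_rows) > 0) {
    rescue_rows$press_time_s <- with_seed(
      substream_seed(seed, "rescue"),
      stats::runif(nrow(rescue_rows), 0, dur))
  }
  logs <- rbind(logs, post_rows,
                if (nrow(rescue_rows) > 0) rescue_rows)
  logs <- logs[order(logs$stimulus_id, logs$participant_id,
                     logs$press_time_s), ]

  npress <- table(factor(paste(logs$participant_id, logs$stimulus_id),
                         levels = key))
  tr$n_presses <- as.integer(npress)
  new_cohort(logs, tr, dur, cohort$designs)
}
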