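#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. All analysis defaults follow
#' the published constants: 1-second bins, 0.5-second debounce, 10000
#' permutation iterations, alpha 0.05. Stage seeds derive deterministically
#' from the root seed.
#'
#' @param experiment 1, 2 or 3.
#' @param seed root seed.
#' @param n_participants cohort size (defaults: 80 for experiment 1 split
#'   into two timeline-unit groups, 117 for the colour factorial, 176 for
#'   the spatial factorial).
#' @param n_stimuli experiment-1 stimulus count (default 15).
#' @param params a [response_params()].
#' @param noise_sd generator noise sd (default 0.1).
#' @param null_iterations permutation iterations (default 10000).
#' @param debounce_s debounce window (default 0.5).
#' @param alpha test level (default 0.05).
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(experiment, seed = 1L,
                            n_participants = c(80L, 117L, 176L)[experiment],
                            n_stimuli = 15L,
                            params = response_params(),
                            noise_sd = 0.1,
                            null_iterations = 10000L,
                            debounce_s = 0.5,
                            alpha = 0.05,
                            out_dir = tempfile("segmap_run_")) {
  stopifnot(experiment %in% 1:3)
  structure(list(experiment = as.integer(experiment),
                 seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_stimuli = as.integer(n_stimuli), params = params,
                 noise_sd = noise_sd,
                 null_iterations = as.integer(null_iterations),
                 debounce_s = debounce_s, alpha = alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Restrict a binned cohort to one experimental group
#'
#' @param binned [bin_cohort()] output carrying a `groups` attribute.
#' @param g group label.
#' @return the binned list with only that group's rows (stimuli left with
#'   fewer than 2 rows are dropped).
#' @export
group_subset <- function(binned, g) {
  groups <- attr(binned, "groups")
  sub <- lapply(binned, function(M) {
    M[groups[rownames(M)] == g, , drop = FALSE]
  })
  sub <- sub[vapply(sub, nrow, 0L) >= 2]
  attr(sub, "groups") <- groups
  sub
}

#' Run the full pipeline
#'
#' generate -> simulate -> filter -> agreement -> permutation null ->
#' specificity -> mixed models, writing every intermediate artifact and a
#' machine-readable audit (stage counts, seeds) under `config$out_dir`.
#' Reruns with the same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  audit <- list(experiment = config$experiment, seed = config$seed,
                params = unclass(config$params))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- generate ---------------------------------------------------------
  built <- stage("generate", {
    if (config$experiment == 1) {
      designs <- lapply(seq_len(config$n_stimuli), function(i) {
        stimulus_design(1, sprintf("e1_s%02d", i), noise_sd = config$noise_sd,
                        seed = substream_seed(config$seed, "stim", i))
      })
      series <- lapply(designs, function(d) {
        generate_exp1_series(duration_s = d$duration_s,
                             noise_sd = d$noise_sd, seed = d$seed)
      })
      names(series) <- vapply(designs, `[[`, "", "stimulus_id")
      list(designs = designs, series = series, map = NULL)
    } else if (config$experiment == 2) {
      designs <- enumerate_design(2, seed = config$seed)
      list(designs = designs, series = generate_series(designs), map = NULL)
    } else {
      map <- build_region_map(n_regions = 10L,
                              seed = substream_seed(config$seed, "map"))
      designs <- resolve_changing_regions(enumerate_design(3, config$seed),
                                          map)
      list(designs = designs, series = generate_series(designs, map = map),
           map = map)
    }
  })
  write_design_manifest(built$designs, out("designs.json"))
  write_series_csv(built$series, out("series.csv"))
  if (!is.null(built$map)) {
    write_region_map_geojson(built$map, out("map.geojson"))
  }

  # -- simulate ---------------------------------------------------------
  cohort <- stage("simulate", {
    group <- if (config$experiment == 1) {
      rep(c("days", "years"), length.out = config$n_participants)
    } else "all"
    simulate_cohort(built$designs, built$series, config$n_participants,
                    config$params, seed = substream_seed(config$seed, "cohort"),
                    group = group)
  })
  write_response_logs(cohort, out("logs.csv"), out("trials.csv"))

  # -- filter -----------------------------------------------------------
  cohort <- stage("filter", filter_trials(cohort))
  audit$trials <- as.list(attr(cohort, "filter_audit"))
  utils::write.csv(cohort$trials, out("trial_status.csv"), row.names = FALSE)

  # -- agreement --------------------------------------------------------
  agr <- stage("agreement", {
    binned <- bin_cohort(cohort, window_s = config$debounce_s)
    groups <- attr(binned, "groups")
    recs <- if (config$experiment == 1) {
      # within-group agreement
      per_group <- lapply(unique(groups), function(g) {
        cohort_agreement(group_subset(binned, g))
      })
      do.call(rbind, per_group)
    } else {
      cohort_agreement(binned)
    }
    list(binned = binned, records = recs)
  })
  utils::write.csv(agr$records, out("agreement.csv"), row.names = FALSE)
  audit$agreement <- list(records = nrow(agr$records),
                          excluded = nrow(attr(agr$records, "exclusions")),
                          mean = mean(agr$records$agreement))

  # -- permutation null -------------------------------------------------
  nul <- stage("null", {
    permutation_null(agr$binned, iterations = config$null_iterations,
                     seed = substream_seed(config$seed, "null"))
  })
  obs <- mean(agr$records$agreement)
  null_summary <- list(iterations = nul$iterations, mean = nul$mean,
                       sd = nul$sd, q2.5 = nul$q2.5, q97.5 = nul$q97.5,
                       observed_mean = obs,
                       p = two_tailed_p(nul, obs))
  jsonlite::write_json(null_summary, out("null_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  audit$null <- null_summary

  # -- models -----------------------------------------------------------
  fit <- stage("models", {
    if (config$experiment == 1) {
      groups <- attr(agr$binned, "groups")
      spec <- do.call(rbind, lapply(unique(groups), function(g) {
        specificity_table(group_subset(agr$binned, g), "cross_stimulus")
      }))
      tab <- prepare_model_table(spec)
      tab$contrast <- factor(
        ifelse(tab$comparison == "same_stimulus", "same", "cross"),
        levels = c("cross", "same"))
      fit_lmm(agreement ~ contrast + (1 | participant_id) +
                (1 | stimulus_id), tab)
    } else {
      tab <- agreement_model_table(agr$records, built$designs)
      fit_lmm(agreement ~ trend * framing * salience +
                (trend + framing + salience | participant_id), tab)
    }
  })
  utils::write.csv(fit$coefficients, out("model_coefficients.csv"),
                   row.names = FALSE)
  if (config$experiment != 1) {
    utils::write.csv(ame_trend_cells(fit), out("marginal_effects.csv"),
                     row.names = FALSE)
  }
  audit$model <- list(singular = fit$singular,
                      r2_marginal = fit$r2_marginal,
                      r2_conditional = fit$r2_conditional)

  jsonlite::write_json(audit, out("audit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
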