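# Long/tidy CSV layouts throughout: one row per press in the log file, one
# row per participant x stimulus in the trial manifest. Times are seconds
# as decimal numbers.

#' Write a cohort's response logs and trial manifest
#'
#' @param cohort a `seg_cohort`.
#' @param logs_path CSV path for presses (participant_id, stimulus_id,
#'   group, press_time_s).
#' @param trials_path CSV path for the trial manifest.
#' @return invisibly, the two paths.
#' @export
write_response_logs <- function(cohort, logs_path, trials_path) {
  utils::write.csv(cohort$logs, logs_path, row.names = FALSE)
  utils::write.csv(cohort$trials[setdiff(names(cohort$trials), "status")],
                   trials_path, row.names = FALSE)
  invisible(c(logs = logs_path, trials = trials_path))
}

#' Read response logs and a trial manifest
#'
#' Validates the layout (required columns, numeric times, no duplicated
#' participant/stimulus/time triples, reporting offending line numbers),
#' groups presses by trial, and materializes trials that appear in the
#' manifest but have no presses as empty logs.
#'
#' @param logs_path presses CSV.
#' @param trials_path trial-manifest CSV (participant_id, stimulus_id and
#'   optionally group).
#' @param duration_s stimulus duration in seconds.
#' @param designs optional design list to attach.
#' @return a `seg_cohort`.
#' @export
read_response_logs <- function(logs_path, trials_path, duration_s,
                               designs = NULL) {
  lg <- utils::read.csv(logs_path, stringsAsFactors = FALSE)
  tr <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  need <- c("participant_id", "stimulus_id", "press_time_s")
  miss <- setdiff(need, names(lg))
  if (nrow(lg) == 0) {
    warning("no presses in log file: ", logs_path)
    lg <- data.frame(participant_id = character(), stimulus_id = character(),
                     group = character(), press_time_s = numeric())
  } else if (length(miss) > 0) {
    stop("log file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(c("participant_id", "stimulus_id") %in% names(tr))) {
    stop("trial manifest missing participant_id/stimulus_id")
  }
  if (nrow(lg) > 0) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(lg$press_time_s))))
    if (length(bad) > 0) {
      stop("non-numeric press_time_s at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    }
    lg$press_time_s <- as.numeric(lg$press_time_s)
    dup <- duplicated(lg[c("participant_id", "stimulus_id", "press_time_s")])
    if (any(dup)) {
      stop("duplicated (participant, stimulus, time) triple at line(s) ",
           paste(utils::head(which(dup) + 1L, 5), collapse = ", "))
    }
  }
  if (is.null(lg$group)) lg$group <- "all"
  if (is.null(tr$group)) tr$group <- "all"
  counts <- table(factor(paste(lg$participant_id, lg$stimulus_id),
                         levels = paste(tr$participant_id, tr$stimulus_id)))
  orphan <- !(paste(lg$participant_id, lg$stimulus_id) %in%
                paste(tr$participant_id, tr$stimulus_id))
  if (any(orphan)) {
    stop("presses for trials absent from the manifest at line(s) ",
         paste(utils::head(which(orphan) + 1L, 5), collapse = ", "))
  }
  tr$n_presses <- as.integer(counts)
  new_cohort(lg, tr, duration_s, designs)
}

#' Write a design manifest as JSON
#'
#' @param designs list of [stimulus_design()] objects.
#' @param path output path.
#' @export
write_design_manifest <- function(designs, path) {
  payload <- lapply(designs, function(d) unclass(d))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a design manifest
#'
#' @param path JSON written by [write_design_manifest()].
#' @return list of [stimulus_design()] objects.
#' @export
read_design_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(d) {
    stimulus_design(
      experiment = d$experiment, stimulus_id = d$stimulus_id,
      trend_level = if (is.null(d$trend_level)) NA_real_ else d$trend_level,
      framing = d$framing,
      salience = null_na_chr(d$salience), duration_s = d$duration_s,
      changing_regions = unlist(d$changing_regions),
      noise_sd = d$noise_sd, timeline_unit = null_na_chr(d$timeline_unit),
      seed = d$seed)
  })
}

null_na_chr <- function(x) {
  if (is.null(x) || length(x) == 0) NA_character_ else as.character(x)
}

#' Write a region map as GeoJSON
#'
#' One Feature per region (Polygon geometry, closed ring) with the region
#' id and its adjacency list as properties.
#'
#' @param map a `region_map`.
#' @param path output path.
#' @export
write_region_map_geojson <- function(map, path) {
  features <- lapply(seq_along(map$regions), function(i) {
    poly <- map$regions[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(
           region_id = i - 1L,
           adjacent = as.integer(which(map$adjacency[i, ]) - 1L)),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(r) ring[r, ]))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize value series as long CSV
#'
#' Long format: stimulus_id, region_id, second, value.
#'
#' @param series named list of [value_series()].
#' @param path output CSV path.
#' @export
write_series_csv <- function(series, path) {
  rows <- lapply(names(series), function(sid) {
    v <- series[[sid]]$values
    data.frame(stimulus_id = sid,
               region_id = rep(seq_len(nrow(v)) - 1L, ncol(v)),
               second = rep(seq_len(ncol(v)) - 1L, each = nrow(v)),
               value = as.vector(v))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
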