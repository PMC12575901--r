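#' Construct a stimulus design
#'
#' A design carries everything needed to regenerate one stimulus: the
#' experiment it belongs to, its nominal trend (last-minus-first mean
#' value), the conceptual framing, the salience factor (colour-scale class
#' in the factorial colour experiment, spatial pattern in the spatial
#' experiment), the changing-region set (spatial experiment only), the
#' per-region noise level, and a seed.
#'
#' @param experiment 1, 2 or 3.
#' @param stimulus_id character id.
#' @param trend_level nominal trend in `[-1, 1]` (NA for experiment 1,
#'   where the trend is emergent).
#' @param framing one of `"endangered"`, `"invasive"`, `"none"`.
#' @param salience `"saturation"`/`"hue"` (experiment 2),
#'   `"clustered"`/`"distributed"` (experiment 3), or NA.
#' @param duration_s stimulus duration in seconds (60 for experiment 1,
#'   30 otherwise).
#' @param changing_regions integer vector of 0-based region ids that carry
#'   the trend (experiment 3 only; must have 3 or 4 elements there).
#' @param noise_sd per-region, per-second Gaussian noise sd (default 0.1).
#' @param timeline_unit metadata label (`"days"`, `"years"`, `"calendar"`).
#' @param seed integer seed for this stimulus.
#' @return a `stimulus_design` list.
#' @export
stimulus_design <- function(experiment, stimulus_id, trend_level = NA_real_,
                            framing = "none", salience = NA_character_,
                            duration_s = if (experiment == 1) 60L else 30L,
                            changing_regions = integer(),
                            noise_sd = 0.1,
                            timeline_unit = NA_character_,
                            seed = 1L) {
  stopifnot(experiment %in% 1:3)
  trend_level <- as.numeric(trend_level)
  framing <- match.arg(framing, c("none", "endangered", "invasive"))
  if (!is.na(trend_level) && abs(trend_level) > 1) {
    stop("trend_level must lie in [-1, 1]")
  }
  if (experiment == 2 &&
      !isTRUE(any(abs(trend_level - exp2_trend_grid()) < 1e-9))) {
    stop("experiment 2 trend_level must lie on the 8-point grid")
  }
  if (experiment == 3) {
    if (!trend_level %in% c(-1, -0.5, 0.5, 1)) {
      stop("experiment 3 trend_level must be one of -1, -0.5, 0.5, 1")
    }
    if (!length(changing_regions) %in% c(3L, 4L)) {
      stop("experiment 3 requires 3 or 4 changing regions")
    }
  } else if (length(changing_regions) > 0) {
    stop("changing_regions is only meaningful for experiment 3")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(experiment = as.integer(experiment), stimulus_id = stimulus_id,
         trend_level = trend_level, framing = framing, salience = salience,
         duration_s = as.integer(duration_s),
         changing_regions = as.integer(changing_regions),
         noise_sd = noise_sd, timeline_unit = timeline_unit,
         seed = as.integer(seed)),
    class = "stimulus_design")
}

#' The trend grid of the colour-scale factorial
#'
#' Eight equally spaced trend values on `[-1, 1]`, rounded to two decimals.
#'
#' @return numeric vector of length 8.
#' @export
exp2_trend_grid <- function() {
  round(seq(-1, 1, length.out = 8), 2)
}

#' Enumerate the factorial stimulus designs
#'
#' Experiment 2 crosses 8 trend levels with two framings and two
#' colour-scale classes (32 stimuli). Experiment 3 crosses 4 trend levels
#' with two framings, two spatial patterns, and 3-or-4 changing regions
#' (32 stimuli; the region-count factor masks the pattern manipulation).
#'
#' @param experiment 2 or 3.
#' @param seed root seed; each design gets a deterministic per-stimulus
#'   sub-seed.
#' @return list of [stimulus_design()] objects of length 32.
#' @examples
#' length(enumerate_design(2))  # 32
#' @export
enumerate_design <- function(experiment, seed = 1L) {
  if (!experiment %in% c(2, 3)) stop("experiment must be 2 or 3")
  if (experiment == 2) {
    grid <- expand.grid(trend = exp2_trend_grid(),
                        framing = c("endangered", "invasive"),
                        salience = c("hue", "saturation"),
                        stringsAsFactors = FALSE)
    designs <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      id <- sprintf("e2_t%+.2f_%s_%s", g$trend, substr(g$framing, 1, 3),
                    substr(g$salience, 1, 3))
      stimulus_design(2, id, trend_level = g$trend, framing = g$framing,
                      salience = g$salience,
                      seed = substream_seed(seed, "design", i))
    })
  } else {
    grid <- expand.grid(trend = c(-1, -0.5, 0.5, 1),
                        framing = c("endangered", "invasive"),
                        salience = c("distributed", "clustered"),
                        n_changing = c(3L, 4L),
                        stringsAsFactors = FALSE)
    designs <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      id <- sprintf("e3_t%+.1f_%s_%s_r%d", g$trend, substr(g$framing, 1, 3),
                    substr(g$salience, 1, 3), g$n_changing)
      # placeholder changing set; resolved against a map by
      # resolve_changing_regions()
      stimulus_design(3, id, trend_level = g$trend, framing = g$framing,
                      salience = g$salience,
                      changing_regions = seq_len(g$n_changing) - 1L,
                      seed = substream_seed(seed, "design", i))
    })
  }
  designs
}

#' Turn a design list into a data frame
#'
#' One row per stimulus with the factor columns used by the mixed models.
#'
#' @param designs list of [stimulus_design()] objects.
#' @return data.frame with columns `stimulus_id`, `experiment`, `trend`,
#'   `framing`, `salience`, `n_changing`, `duration_s`.
#' @export
design_table <- function(designs) {
  data.frame(
    stimulus_id = vapply(designs, `[[`, "", "stimulus_id"),
    experiment = vapply(designs, `[[`, 0L, "experiment"),
    trend = vapply(designs, `[[`, 0, "trend_level"),
    framing = vapply(designs, `[[`, "", "framing"),
    salience = vapply(designs, `[[`, "", "salience"),
    n_changing = vapply(designs, function(d) length(d$changing_regions), 0L),
    duration_s = vapply(designs, `[[`, 0L, "duration_s"),
    stringsAsFactors = FALSE)
}

#' Select the changing regions for a spatial-pattern stimulus
#'
#' Starts from one uniformly random region. Under the clustered pattern,
#' each subsequent region is drawn from the regions bordering the current
#' selection (the selection stays connected). Under the distributed
#' pattern, each subsequent region is drawn from the regions bordering
#' none of the current selection; when no such region exists the draw
#' falls back to a uniformly random unselected region.
#'
#' @param map a [build_region_map()] result.
#' @param pattern `"clustered"` or `"distributed"`.
#' @param count 3 or 4.
#' @param seed integer seed.
#' @return integer vector of 0-based region ids.
#' @export
select_changing_regions <- function(map, pattern, count, seed = 1L) {
  pattern <- match.arg(pattern, c("clustered", "distributed"))
  n <- length(map$regions)
  if (count > n) stop("count exceeds the number of regions")
  adj <- map$adjacency
  with_seed(substream_seed(seed, "selection"), {
    sel <- sample.int(n, 1L)
    while (length(sel) < count) {
      free <- setdiff(seq_len(n), sel)
      if (pattern == "clustered") {
        cand <- free[vapply(free, function(r) any(adj[r, sel]), TRUE)]
        if (length(cand) == 0) {
          stop("clustered selection stranded at step ", length(sel) + 1L,
               ": no unselected region borders the current selection")
        }
      } else {
        cand <- free[vapply(free, function(r) !any(adj[r, sel]), TRUE)]
        if (length(cand) == 0) cand <- free  # stated random fallback
      }
      sel <- c(sel, cand[sample.int(length(cand), 1L)])
    }
    sort(sel - 1L)
  })
}

#' Resolve placeholder changing-region sets against a map
#'
#' [enumerate_design()] fixes only the *number* of changing regions; this
#' helper replaces each placeholder set with a pattern-respecting selection
#' on the given map, seeded per stimulus.
#'
#' @param designs experiment-3 design list.
#' @param map a `region_map`.
#' @return the design list with concrete `changing_regions`.
#' @export
resolve_changing_regions <- function(designs, map) {
  lapply(designs, function(d) {
    if (d$experiment != 3) return(d)
    d$changing_regions <- select_changing_regions(
      map, d$salience, length(d$changing_regions), seed = d$seed)
    d
  })
}
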