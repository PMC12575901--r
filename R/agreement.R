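#' Debounce a press sequence
#'
#' Greedy left-to-right retention: the first press is kept, and each later
#' press is kept only if it falls at least `window_s` after the last
#' *retained* press.
#'
#' @param press_times ascending numeric press times (seconds).
#' @param window_s minimum gap (default 0.5 s).
#' @return the retained press times.
#' @examples
#' debounce(c(1.0, 1.3, 2.0))        # 0.3 s gap dropped
#' debounce(c(0.10, 0.59, 1.08))     # 0.59 dropped relative to 0.10
#' @export
debounce <- function(press_times, window_s = 0.5) {
  if (is.unsorted(press_times)) stop("press times must be ascending")
  thin_refractory(press_times, window_s)
}

#' Bin presses into one-second bins
#'
#' Half-open bins `[b, b+1)`, 0-based: a press at time t lands in bin
#' `floor(t)`; a press at exactly `duration_s` clamps into the last bin.
#' Multiple presses in a bin yield a single 1.
#'
#' @param press_times numeric press times in `[0, duration_s]`.
#' @param duration_s stimulus duration in seconds.
#' @return object of class `binned_response`: list with `bins` (binary
#'   vector of length `duration_s`) and `k` (number of 1-bins).
#' @export
bin_presses <- function(press_times, duration_s) {
  if (any(press_times < 0)) stop("negative press time")
  if (any(press_times > duration_s)) {
    stop("press after stimulus end; exclude the trial upstream")
  }
  idx <- pmin(floor(press_times), duration_s - 1L) + 1L
  bins <- integer(duration_s)
  bins[idx] <- 1L
  structure(list(bins = bins, k = sum(bins)), class = "binned_response")
}

#' Leave-one-out group norm
#'
#' Per-bin proportion of the *other* participants who pressed in each bin.
#'
#' @param binned_matrix participants x bins binary matrix.
#' @param exclude_idx row index of the target participant.
#' @return object of class `group_norm`: list with `proportions` and
#'   `n_others`.
#' @export
group_norm <- function(binned_matrix, exclude_idx) {
  if (nrow(binned_matrix) < 2) {
    stop("group norm needs at least 2 participants")
  }
  others <- binned_matrix[-exclude_idx, , drop = FALSE]
  structure(list(proportions = colMeans(others), n_others = nrow(others)),
            class = "group_norm")
}

norm_proportions <- function(norm) {
  if (inherits(norm, "group_norm")) norm$proportions else as.numeric(norm)
}

#' Extremal correlations attainable at a press count
#'
#' Given `k` filled bins and a group norm, the maximum (minimum) Pearson
#' correlation over all placements of the k ones is attained by placing
#' them on the k largest (smallest) norm values; ties are broken by the
#' earliest bin index (the correlation is unaffected by the tie-break).
#'
#' @param k number of 1-bins, `0 < k < n_bins`.
#' @param norm a [group_norm()] or plain proportion vector with nonzero
#'   variance.
#' @return named numeric `c(r_min, r_max)`.
#' @export
correlation_bounds <- function(k, norm) {
  p <- norm_proportions(norm)
  n <- length(p)
  if (k <= 0 || k >= n) {
    stop("correlation bounds undefined for k = 0 or k = n_bins; ",
         "the trial must be excluded upstream")
  }
  if (stats::sd(p) == 0) stop("group norm has zero variance")
  ord_desc <- order(p, seq_along(p), decreasing = c(TRUE, FALSE),
                    method = "radix")
  ord_asc <- order(p, seq_along(p), method = "radix")
  top <- placement_vector(ord_desc[seq_len(k)], n)
  bot <- placement_vector(ord_asc[seq_len(k)], n)
  c(r_min = stats::cor(bot, p), r_max = stats::cor(top, p))
}

placement_vector <- function(idx, n) {
  v <- numeric(n)
  v[idx] <- 1
  v
}

#' Scaled segmentation agreement for one trial
#'
#' The observed correlation between a participant's binned boundary series
#' and the leave-one-out group norm, rescaled by the extremal correlations
#' attainable at that participant's press count:
#' `agreement = (r_obs - r_min) / (r_max - r_min)`, which ranges from 0
#' to 1 and removes the confound of press frequency.
#'
#' @param binned a [bin_presses()] result (or binary vector).
#' @param norm a [group_norm()] (or proportion vector).
#' @return list with `r_obs`, `r_min`, `r_max`, `agreement`.
#' @export
scaled_agreement <- function(binned, norm) {
  bins <- if (inherits(binned, "binned_response")) binned$bins else
    as.numeric(binned)
  p <- norm_proportions(norm)
  k <- sum(bins)
  b <- correlation_bounds(k, p)
  if (b["r_max"] - b["r_min"] <= 0) {
    stop("degenerate trial: r_max equals r_min")
  }
  r_obs <- stats::cor(bins, p)
  list(r_obs = r_obs, r_min = unname(b["r_min"]),
       r_max = unname(b["r_max"]),
       agreement = unname((r_obs - b["r_min"]) / (b["r_max"] - b["r_min"])))
}

#' Event-unit durations from a press sequence
#'
#' Presses split the stimulus into event units bounded by the stimulus
#' start and end: m presses yield m + 1 units whose durations sum to the
#' stimulus duration.
#'
#' @param press_times ascending press times within `[0, duration_s]`.
#' @param duration_s stimulus duration.
#' @return numeric vector of unit durations.
#' @examples
#' unit_durations(c(10, 20), 30)  # 10 10 10
#' @export
unit_durations <- function(press_times, duration_s) {
  diff(c(0, press_times, duration_s))
}

# ---- vectorized cohort machinery --------------------------------------

# Per-trial agreement for one stimulus' binary matrix (participants x bins)
# against leave-one-out norms. Returns a data.frame with one row per row of
# M; degenerate rows (k == 0, k == n_bins, constant norm) get NA agreement.
# Uses the identity that, at fixed k, the correlation with the norm is a
# fixed affine function of sum(norm[bins == 1]), so observed/min/max
# correlations share one scaling and the agreement ratio reduces to sums.
agreement_core <- function(M, values_only = FALSE) {
  P <- nrow(M); B <- ncol(M)
  if (P < 2) stop("agreement needs at least 2 participants per stimulus")
  k <- rowSums(M)
  s <- colSums(M)
  N <- (rep(1, P) %o% s - M) / (P - 1)
  obs <- rowSums(M * N)

  # row-sorted cumulative sums via one grouped order() call
  Nt <- t(N)                               # bins x participants
  o <- order(rep(seq_len(P), each = B), as.vector(Nt))
  sorted <- matrix(as.vector(Nt)[o], B, P)  # ascending within column
  cs <- matrix(cumsum(as.vector(sorted)), B, P)
  cs <- cs - rep(c(0, cs[B, -P]), each = B) # per-column cumulative sums
  total <- cs[B, ]
  kc <- pmin(pmax(k, 1L), B - 1L)          # guarded index for degenerates
  bot <- cs[cbind(kc, seq_len(P))]
  top <- total - cs[cbind(B - kc, seq_len(P))]

  pbar <- total / B
  ss <- rowSums(N^2) - B * pbar^2
  valid <- k > 0 & k < B & ss > 1e-24 & (top - bot) > 0
  agreement <- ifelse(valid, (obs - bot) / (top - bot), NA_real_)
  if (values_only) return(agreement)
  sx <- sqrt((k - k^2 / B) / (B - 1))
  sp <- sqrt(ss / (B - 1))
  denom <- (B - 1) * sx * sp
  r <- function(num) ifelse(valid, (num - k * pbar) / denom, NA_real_)
  data.frame(
    k = k,
    r_obs = r(obs), r_min = r(bot), r_max = r(top),
    agreement = agreement)
}

#' Bin a cohort's trials per stimulus
#'
#' Debounces and bins every `ok` trial (run [filter_trials()] first; if the
#' cohort is unfiltered all non-empty, in-range trials are used).
#'
#' @param cohort a `seg_cohort`.
#' @param window_s debounce window (default 0.5 s).
#' @return named list (by stimulus id) of participants x bins binary
#'   matrices; rownames are participant ids, and
#'   `attr(, "groups")` maps participants to group labels.
#' @export
bin_cohort <- function(cohort, window_s = 0.5) {
  tr <- cohort$trials
  if (is.null(tr$status)) tr$status <- ifelse(tr$n_presses > 0, "ok", "empty")
  ok <- tr[tr$status == "ok", ]
  lg <- cohort$logs
  press_by_trial <- split(lg$press_time_s,
                          paste(lg$participant_id, lg$stimulus_id))
  B <- cohort$duration_s
  out <- lapply(split(ok, ok$stimulus_id), function(st) {
    m <- matrix(0L, nrow(st), B, dimnames = list(st$participant_id, NULL))
    at <- match(paste(st$participant_id, st$stimulus_id),
                names(press_by_trial))
    for (i in seq_len(nrow(st))) {
      t_i <- press_by_trial[[at[i]]]
      m[i, ] <- bin_presses(debounce(sort(t_i), window_s), B)$bins
    }
    m
  })
  groups <- tr$group[!duplicated(tr$participant_id)]
  names(groups) <- tr$participant_id[!duplicated(tr$participant_id)]
  attr(out, "groups") <- groups
  out
}

#' Same-stimulus agreement records for a cohort
#'
#' One record per analyzable trial: the participant's binned response
#' correlated with the leave-one-out group norm of all other participants
#' on the same stimulus, scaled by the attainable extremes. Trials whose
#' bounds are degenerate are excluded and counted in
#' `attr(, "exclusions")`.
#'
#' @param binned result of [bin_cohort()] (or a `seg_cohort`, which is
#'   binned on the fly).
#' @return data.frame with participant_id, stimulus_id, comparison,
#'   comparison_target, k, r_obs, r_min, r_max, agreement.
#' @export
cohort_agreement <- function(binned) {
  if (inherits(binned, "seg_cohort")) binned <- bin_cohort(binned)
  recs <- lapply(names(binned), function(sid) {
    M <- binned[[sid]]
    st <- agreement_core(M)
    data.frame(participant_id = rownames(M), stimulus_id = sid,
               comparison = "same_stimulus", comparison_target = sid,
               st, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  excl <- out[is.na(out$agreement), c("participant_id", "stimulus_id")]
  res <- out[!is.na(out$agreement), ]
  attr(res, "exclusions") <- excl
  res
}
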