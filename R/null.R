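#' Permutation null distribution of mean sample agreement
#'
#' Per iteration, every participant x stimulus binary vector is permuted
#' independently (press counts preserved, temporal placement randomized),
#' all agreements are recomputed with leave-one-out norms from the permuted
#' data, and the iteration statistic is the mean agreement across trials.
#'
#' @param binned named list of participants x bins binary matrices (from
#'   [bin_cohort()]).
#' @param iterations number of iterations (default 10000).
#' @param seed integer seed.
#' @return object of class `null_distribution`: list with `samples`,
#'   `mean`, `sd`, `q2.5`, `q97.5`, `iterations`.
#' @export
permutation_null <- function(binned, iterations = 10000L, seed = 1L) {
  binned <- binned[vapply(binned, nrow, 0L) >= 2]
  if (length(binned) == 0) stop("no stimuli with at least 2 valid trials")
  dims <- lapply(binned, dim)
  samples <- with_seed(substream_seed(seed, "null"), {
    vapply(seq_len(iterations), function(it) {
      acc <- 0; nacc <- 0L
      for (M in binned) {
        Mp <- permute_rows(M)
        a <- agreement_core(Mp, values_only = TRUE)
        a <- a[!is.na(a)]
        acc <- acc + sum(a)
        nacc <- nacc + length(a)
      }
      acc / nacc
    }, 0)
  })
  structure(list(samples = samples, mean = mean(samples),
                 sd = stats::sd(samples),
                 q2.5 = unname(stats::quantile(samples, 0.025)),
                 q97.5 = unname(stats::quantile(samples, 0.975)),
                 iterations = as.integer(iterations)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d iterations: mean %.3f (sd %.4f), 95%% [%.3f, %.3f]\n",
    x$iterations, x$mean, x$sd, x$q2.5, x$q97.5))
  invisible(x)
}

# Permute each row of a matrix independently with one grouped order() call.
permute_rows <- function(M) {
  P <- nrow(M); B <- ncol(M)
  Mt <- t(M)
  o <- order(rep(seq_len(P), each = B), stats::runif(P * B))
  Mp <- t(matrix(as.vector(Mt)[o], B, P))
  rownames(Mp) <- rownames(M)
  Mp
}

#' Two-tailed permutation p-value
#'
#' Symmetric tail mass around the null mean: with `d = |observed - mean|`,
#' `p = P(X <= mean - d) + P(X >= mean + d)`, each tail estimated
#' empirically with add-one smoothing, capped at 1. The smallest attainable
#' p with both tails empty is `2 / (iterations + 1)`.
#'
#' @param null a [permutation_null()] result.
#' @param observed_mean observed mean sample agreement.
#' @return p-value.
#' @export
two_tailed_p <- function(null, observed_mean) {
  x <- null$samples
  n <- length(x)
  d <- abs(observed_mean - null$mean)
  lo <- (sum(x <= null$mean - d) + 1) / (n + 1)
  hi <- (sum(x >= null$mean + d) + 1) / (n + 1)
  min(1, lo + hi)
}

#' Cross-stimulus and cross-group specificity contrasts
#'
#' `cross_stimulus`: every participant x stimulus response is additionally
#' correlated with the group norm of each *other* stimulus (leave-one-out
#' with respect to the participant wherever they contributed to that
#' stimulus), so with S stimuli each trial yields one same-stimulus record
#' and S - 1 cross-stimulus records. `cross_group`: every trial is scored
#' against its own group's leave-one-out norm and against the full norm of
#' the other group.
#'
#' @param binned result of [bin_cohort()]; for `cross_group` the attribute
#'   `groups` (participant -> group) must contain exactly two groups.
#' @param mode `"cross_stimulus"` or `"cross_group"`.
#' @return data.frame of agreement records with a `comparison` column
#'   (`same_stimulus`/`cross_stimulus` or `own_group`/`other_group`).
#' @export
specificity_table <- function(binned, mode = c("cross_stimulus",
                                               "cross_group")) {
  mode <- match.arg(mode)
  if (mode == "cross_stimulus") {
    if (length(binned) < 2) stop("cross-stimulus contrast needs >= 2 stimuli")
    if (length(unique(vapply(binned, ncol, 0L))) != 1) {
      stop("stimuli must share one duration")
    }
    same <- cohort_agreement(binned)
    cross <- list()
    sums <- lapply(binned, colSums)
    for (sid in names(binned)) {
      M <- binned[[sid]]
      for (tid in setdiff(names(binned), sid)) {
        Mo <- binned[[tid]]
        rec <- cross_records(M, Mo, sums[[tid]])
        if (is.null(rec)) next
        rec$participant_id <- rownames(M)
        rec$stimulus_id <- sid
        rec$comparison <- "cross_stimulus"
        rec$comparison_target <- tid
        cross[[length(cross) + 1L]] <- rec
      }
    }
    cross <- do.call(rbind, cross)
    cols <- c("participant_id", "stimulus_id", "comparison",
              "comparison_target", "k", "r_obs", "r_min", "r_max",
              "agreement")
    out <- rbind(same[cols], cross[cols])
  } else {
    groups <- attr(binned, "groups")
    glev <- unique(groups)
    if (length(glev) != 2) stop("cross-group contrast needs exactly 2 groups")
    recs <- list()
    for (sid in names(binned)) {
      M <- binned[[sid]]
      gv <- groups[rownames(M)]
      for (g in glev) {
        Mg <- M[gv == g, , drop = FALSE]
        Mo <- M[gv != g, , drop = FALSE]
        if (nrow(Mg) < 2 || nrow(Mo) < 1) next
        own <- agreement_core(Mg)
        own$participant_id <- rownames(Mg)
        own$stimulus_id <- sid
        own$comparison <- "own_group"
        own$comparison_target <- g
        other_norm <- colMeans(Mo)
        oth <- fixed_norm_records(Mg, other_norm)
        oth$participant_id <- rownames(Mg)
        oth$stimulus_id <- sid
        oth$comparison <- "other_group"
        oth$comparison_target <- setdiff(glev, g)
        recs[[length(recs) + 1L]] <- own
        recs[[length(recs) + 1L]] <- oth
      }
    }
    out <- do.call(rbind, recs)
    cols <- c("participant_id", "stimulus_id", "comparison",
              "comparison_target", "k", "r_obs", "r_min", "r_max",
              "agreement")
    out <- out[cols]
  }
  rownames(out) <- NULL
  excl <- out[is.na(out$agreement), ]
  res <- out[!is.na(out$agreement), ]
  attr(res, "exclusions") <- excl
  res
}

# Records for rows of M scored against the other-stimulus norm built from
# Mo's column sums, leave-one-out w.r.t. the focal participant when present.
cross_records <- function(M, Mo, so) {
  Po <- nrow(Mo)
  at <- match(rownames(M), rownames(Mo))
  recs <- lapply(seq_len(nrow(M)), function(i) {
    if (!is.na(at[i])) {
      if (Po < 2) return(single_record(M[i, ], rep(0, ncol(M))))  # degenerate
      p <- (so - Mo[at[i], ]) / (Po - 1)
    } else {
      p <- so / Po
    }
    single_record(M[i, ], p)
  })
  do.call(rbind, recs)
}

fixed_norm_records <- function(M, p) {
  do.call(rbind, lapply(seq_len(nrow(M)), function(i) single_record(M[i, ], p)))
}

single_record <- function(bins, p) {
  k <- sum(bins)
  B <- length(bins)
  if (k == 0 || k == B || stats::sd(p) == 0) {
    return(data.frame(k = k, r_obs = NA_real_, r_min = NA_real_,
                      r_max = NA_real_, agreement = NA_real_))
  }
  b <- correlation_bounds(k, p)
  if (b["r_max"] - b["r_min"] <= 0) {
    return(data.frame(k = k, r_obs = NA_real_, r_min = NA_real_,
                      r_max = NA_real_, agreement = NA_real_))
  }
  r_obs <- stats::cor(bins, p)
  data.frame(k = k, r_obs = r_obs, r_min = unname(b["r_min"]),
             r_max = unname(b["r_max"]),
             agreement = unname((r_obs - b["r_min"]) /
                                  (b["r_max"] - b["r_min"])))
}
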