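# Shared in-code fixtures: small simulated cohorts and brute-force oracles.

# A small cohort of piecewise-linear stimuli (exp-1 style dynamics, 30 s).
make_test_cohort <- function(n_participants = 20, n_stimuli = 5,
                             duration = 30, params = response_params(),
                             seed = 1) {
  designs <- lapply(seq_len(n_stimuli), function(i) {
    stimulus_design(1, sprintf("s%02d", i), duration_s = duration,
                    seed = substream_seed(seed, "stim", i))
  })
  series <- lapply(designs, function(d) {
    generate_exp1_series(duration_s = duration, seed = d$seed)
  })
  names(series) <- vapply(designs, `[[`, "", "stimulus_id")
  cohort <- simulate_cohort(designs, series, n_participants, params,
                            seed = substream_seed(seed, "cohort"))
  filter_trials(cohort)
}

# Exhaustive extremal correlations over all C(n, k) placements of k ones.
bounds_oracle <- function(k, p) {
  n <- length(p)
  placements <- utils::combn(n, k)
  rs <- apply(placements, 2, function(idx) {
    v <- numeric(n)
    v[idx] <- 1
    stats::cor(v, p)
  })
  c(r_min = min(rs), r_max = max(rs))
}

# Exhaustive scaled agreement for a concrete binary vector.
agreement_oracle <- function(bins, p) {
  b <- bounds_oracle(sum(bins), p)
  (stats::cor(bins, p) - b["r_min"]) / (b["r_max"] - b["r_min"])
}

# Is the induced subgraph on `ids` (0-based) connected under `adj`?
is_connected_subset <- function(ids, adj) {
  idx <- ids + 1L
  seen <- idx[1]
  repeat {
    nxt <- idx[!idx %in% seen &
                 vapply(idx, function(r) any(adj[r, seen]), TRUE)]
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
  }
  length(seen) == length(idx)
}

# A fake region map with a given adjacency matrix (geometry irrelevant).
fake_map <- function(adj) {
  structure(list(regions = vector("list", nrow(adj)), adjacency = adj,
                 outline = NULL, points = NULL, seed = 0L),
            class = "region_map")
}

cycle_adjacency <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    adj[i, j] <- adj[j, i] <- TRUE
  }
  adj
}
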