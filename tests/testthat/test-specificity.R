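test_that("cross-stimulus contrasts yield one record per other stimulus", {
  co <- make_test_cohort(n_participants = 8, n_stimuli = 2, seed = 41)
  sp <- specificity_table(bin_cohort(co), "cross_stimulus")
  per_pair <- table(sp$comparison) / sum(sp$comparison == "same_stimulus")
  expect_equal(unname(per_pair["cross_stimulus"]), 1)

  co5 <- make_test_cohort(n_participants = 8, n_stimuli = 5, seed = 41)
  sp5 <- specificity_table(bin_cohort(co5), "cross_stimulus")
  n_same <- sum(sp5$comparison == "same_stimulus")
  n_cross <- sum(sp5$comparison == "cross_stimulus")
  # up to exclusions, 4 cross records per participant-stimulus pair
  expect_equal(n_cross, 4 * n_same)
})

test_that("cross-stimulus norms are leave-one-out for the focal participant", {
  # 3 participants x 2 stimuli, constructed by hand
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    rownames(m) <- paste0("p", seq_along(rows))
    m
  }
  A <- mk(list(c(1, 0, 0, 0, 1, 0), c(0, 1, 0, 0, 1, 0),
               c(0, 0, 1, 0, 1, 0)))
  B <- mk(list(c(0, 1, 0, 1, 0, 0), c(1, 0, 0, 1, 0, 0),
               c(0, 0, 0, 1, 0, 1)))
  bn <- list(A = A, B = B)
  attr(bn, "groups") <- stats::setNames(rep("all", 3), rownames(A))
  sp <- specificity_table(bn, "cross_stimulus")
  rec <- sp[sp$participant_id == "p1" & sp$stimulus_id == "A" &
              sp$comparison == "cross_stimulus", ]
  # expected: p1's A-bins against the norm of B excluding p1's B-row
  p <- colMeans(B[-1, ])
  expect_equal(rec$r_obs, stats::cor(A[1, ], p))
  expect_equal(rec$agreement,
               unname(agreement_oracle(A[1, ], p)))
})

test_that("cross-group contrasts score own and other group norms", {
  co <- make_test_cohort(n_participants = 12, n_stimuli = 3, seed = 51)
  # assign two groups post hoc
  pids <- unique(co$trials$participant_id)
  gmap <- stats::setNames(rep(c("days", "years"), length.out = length(pids)),
                          pids)
  co$trials$group <- gmap[co$trials$participant_id]
  co$logs$group <- gmap[co$logs$participant_id]
  bn <- bin_cohort(co)
  sp <- specificity_table(bn, "cross_group")
  expect_setequal(unique(sp$comparison), c("own_group", "other_group"))
  # own-group and other-group records pair up per trial (up to exclusions)
  own <- sp[sp$comparison == "own_group", ]
  oth <- sp[sp$comparison == "other_group", ]
  expect_gt(nrow(own), 0)
  expect_gt(nrow(oth), 0)
  expect_true(all(own$comparison_target %in% c("days", "years")))
  expect_true(all(sp$agreement >= -1e-12 & sp$agreement <= 1 + 1e-12))
})

test_that("duration mismatches across stimuli are rejected", {
  bn <- list(A = matrix(rbinom(40, 1, .3), 4, 10),
             B = matrix(rbinom(48, 1, .3), 4, 12))
  attr(bn, "groups") <- c(a = "all")
  expect_error(specificity_table(bn, "cross_stimulus"), "one duration")
})
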