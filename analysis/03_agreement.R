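#!/usr/bin/env Rscript
# Segmentation agreement, permutation nulls, and specificity contrasts.
#
# For the two-group cohort: within-group scaled agreement, the 10000-
# iteration permutation null per group with the two-tailed p, the
# same-vs-cross-stimulus contrast, and the own-vs-other-group contrast.
# For the factorial fixtures: per-trial agreement tables for modelling.
# Outputs under results/agreement/.

suppressMessages(library(segmap))

seed <- 20260927L
out <- "results/agreement"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
null_iterations <- 10000L

d1 <- read_design_manifest("results/stimuli/designs_exp1.json")
co1 <- read_response_logs("results/responses/logs_exp1.csv",
                          "results/responses/trials_exp1.csv",
                          duration_s = 60, designs = d1)
co1 <- filter_trials(co1)
bn1 <- bin_cohort(co1)

null_summaries <- list()
spec_all <- list()
for (g in c("days", "years")) {
  bg <- group_subset(bn1, g)
  ag <- cohort_agreement(bg)
  obs <- mean(ag$agreement)
  nul <- permutation_null(bg, iterations = null_iterations,
                          seed = substream_seed(seed, "null", g))
  p <- two_tailed_p(nul, obs)
  message(sprintf(
    "group %s: mean agreement %.3f vs null %.3f (sd %.4f, 95%% [%.3f, %.3f]), p = %.4g",
    g, obs, nul$mean, nul$sd, nul$q2.5, nul$q97.5, p))
  null_summaries[[g]] <- list(observed = obs, null_mean = nul$mean,
                              null_sd = nul$sd, q2.5 = nul$q2.5,
                              q97.5 = nul$q97.5, p = p,
                              iterations = nul$iterations)
  sp <- specificity_table(bg, "cross_stimulus")
  sp$group <- g
  spec_all[[g]] <- sp
  same <- mean(sp$agreement[sp$comparison == "same_stimulus"])
  cross <- mean(sp$agreement[sp$comparison == "cross_stimulus"])
  message(sprintf("  same-stimulus %.3f vs cross-stimulus %.3f", same, cross))
}
jsonlite::write_json(null_summaries, file.path(out, "null_exp1.json"),
                     auto_unbox = TRUE, digits = NA)
spec <- do.call(rbind, spec_all)
write.csv(spec, file.path(out, "specificity_exp1.csv"), row.names = FALSE)

xg <- specificity_table(bn1, "cross_group")
write.csv(xg, file.path(out, "crossgroup_exp1.csv"), row.names = FALSE)
message(sprintf("own-group %.3f vs other-group %.3f",
                mean(xg$agreement[xg$comparison == "own_group"]),
                mean(xg$agreement[xg$comparison == "other_group"])))

# unit durations and press counts (grain descriptives)
presses <- split(co1$logs$press_time_s,
                 paste(co1$logs$participant_id, co1$logs$stimulus_id))
durs <- unlist(lapply(presses, function(t) {
  unit_durations(debounce(sort(t[t <= 60])), 60)
}))
message(sprintf("mean unit duration %.2f s (sd %.2f); %.2f presses/trial",
                mean(durs), sd(durs), mean(co1$trials$n_presses)))

for (exp in 2:3) {
  dd <- read_design_manifest(
    sprintf("results/stimuli/designs_exp%d.json", exp))
  co <- read_response_logs(
    sprintf("results/responses/logs_exp%d.csv", exp),
    sprintf("results/responses/trials_exp%d.csv", exp),
    duration_s = 30, designs = dd)
  co <- filter_trials(co)
  ag <- cohort_agreement(bin_cohort(co))
  tab <- agreement_model_table(ag, dd)
  write.csv(tab, file.path(out, sprintf("agreement_exp%d.csv", exp)),
            row.names = FALSE)
  message(sprintf("factorial %d: %d records, mean agreement %.3f (sd %.3f)",
                  exp, nrow(tab), mean(tab$agreement), sd(tab$agreement)))
}
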