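#!/usr/bin/env Rscript
# Synthetic participant cohorts.
#
# Simulates key-press logs from the change-driven hazard model for all
# three designs: an 80-participant two-group cohort for the piecewise
# stimuli, and the two factorial fixtures with the exact defective-trial
# accounting (117 x 31 with 267 empty / 11 post-end logs; 176 x 32 with
# 395 / 13). Writes logs, trial manifests and filter audits under
# results/responses/.

suppressMessages(library(segmap))

seed <- 20260927L
out <- "results/responses"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d1 <- read_design_manifest("results/stimuli/designs_exp1.json")
s1 <- lapply(d1, function(d) generate_exp1_series(60, seed = d$seed))
names(s1) <- vapply(d1, `[[`, "", "stimulus_id")
co1 <- simulate_cohort(d1, s1, 80,
                       response_params(base_rate = 0.12),
                       seed = substream_seed(seed, "cohort1"),
                       group = rep(c("days", "years"), each = 40))
co1 <- filter_trials(co1)
write_response_logs(co1, file.path(out, "logs_exp1.csv"),
                    file.path(out, "trials_exp1.csv"))
a1 <- attr(co1, "filter_audit")
message(sprintf("two-group cohort: %d trials (%d ok, %d empty, %d post-end), %.1f presses/trial",
                a1["total"], a1["ok"], a1["empty"], a1["post_end"],
                mean(co1$trials$n_presses)))

for (exp in 2:3) {
  fx <- make_paper_fixture(exp, seed = substream_seed(seed, "fixture", exp))
  write_response_logs(fx$cohort,
                      file.path(out, sprintf("logs_exp%d.csv", exp)),
                      file.path(out, sprintf("trials_exp%d.csv", exp)))
  a <- attr(fx$cohort, "filter_audit")
  jsonlite::write_json(as.list(a),
                       file.path(out, sprintf("audit_exp%d.json", exp)),
                       auto_unbox = TRUE)
  message(sprintf(
    "factorial fixture %d: %d trials -> %d analyzable (%d empty, %d post-end)",
    exp, a["total"], a["ok"], a["empty"], a["post_end"]))
}
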