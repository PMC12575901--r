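#!/usr/bin/env Rscript
# Mixed-model stage: specificity contrast models, the exploratory
# descriptor model, the full factorial models with random slopes, and the
# marginal effects of trend per framing x salience cell. Coefficient and
# AME tables go under results/models/.

suppressMessages(library(segmap))

out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# -- same- vs cross-stimulus contrast per group -------------------------
spec <- read.csv("results/agreement/specificity_exp1.csv")
spec <- prepare_model_table(spec)
spec$contrast <- factor(ifelse(spec$comparison == "same_stimulus",
                               "same", "cross"), levels = c("cross", "same"))
for (g in unique(spec$group)) {
  fit <- fit_lmm(agreement ~ contrast + (1 | participant_id) +
                   (1 | stimulus_id), spec[spec$group == g, ])
  write.csv(fit$coefficients,
            file.path(out, sprintf("contrast_%s.csv", g)), row.names = FALSE)
  co <- fit$coefficients[fit$coefficients$term == "contrastsame", ]
  message(sprintf(
    "group %s: same-vs-cross beta %.3f, 95%% CI [%.3f, %.3f], t(%.0f) = %.2f, p = %.3g, d = %.2f",
    g, co$estimate, co$ci_lower, co$ci_upper, co$df, co$t, co$p, co$d))
}

# -- exploratory descriptor model ---------------------------------------
desc <- read.csv("results/stimuli/descriptors_exp1.csv")
same <- spec[spec$comparison == "same_stimulus", ]
tab <- merge(same, desc, by = "stimulus_id")
fit_d <- exploratory_descriptor_model(tab)
write.csv(fit_d$coefficients, file.path(out, "descriptors_exp1.csv"),
          row.names = FALSE)
tr <- fit_d$coefficients[fit_d$coefficients$term == "trend", ]
message(sprintf("descriptor model: trend beta %.3f (p = %.3g)",
                tr$estimate, tr$p))

# -- factorial models with random slopes + marginal effects -------------
for (exp in 2:3) {
  tab <- prepare_model_table(
    read.csv(sprintf("results/agreement/agreement_exp%d.csv", exp)))
  fit <- fit_lmm(agreement ~ trend * framing * salience +
                   (trend + framing + salience | participant_id), tab)
  write.csv(fit$coefficients,
            file.path(out, sprintf("factorial_exp%d.csv", exp)),
            row.names = FALSE)
  i3 <- grepl("^trend:.+:.+$", fit$coefficients$term)
  message(sprintf(
    "factorial %d: three-way interaction beta %.3f (p = %.3g)%s",
    exp, fit$coefficients$estimate[i3], fit$coefficients$p[i3],
    if (fit$singular) " [boundary random effects]" else ""))
  ame <- ame_trend_cells(fit)
  write.csv(ame, file.path(out, sprintf("ame_exp%d.csv", exp)),
            row.names = FALSE)
  for (r in seq_len(nrow(ame))) {
    message(sprintf("  AME(trend | %s, %s) = %+.3f [%.3f, %.3f], p = %.3g",
                    ame$framing[r], ame$salience[r], ame$ame[r],
                    ame$ci_lower[r], ame$ci_upper[r], ame$p[r]))
  }

  # response-frequency (grain) model: debounced response count per
  # analyzable trial, same fixed and random structure
  fit_n <- fit_lmm(k ~ trend * framing * salience +
                     (trend + framing + salience | participant_id), tab)
  write.csv(fit_n$coefficients,
            file.path(out, sprintf("frequency_exp%d.csv", exp)),
            row.names = FALSE)
}
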