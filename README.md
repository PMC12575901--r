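# segmap

Event segmentation agreement for dynamic choropleth maps.

## What this is for

Viewers watching an animated thematic map — a fixed outline whose regions
change colour as a data value evolves — spontaneously segment the stream
into discrete events, and can be asked to mark event boundaries with a key
press. `segmap` is a simulation-and-analysis pipeline for that paradigm,
aimed at researchers in visualization cognition and event perception. It
covers:

* **Stimulus generation** — Voronoi region maps with adjacency; random
  piecewise-linear value dynamics (60 s); an 8-trend × framing ×
  colour-scale factorial; a 4-trend × framing × spatial-pattern factorial
  where only 3–4 clustered or distributed regions carry the trend.
* **Response simulation** — seeded synthetic cohorts whose per-second
  press hazard is `clip(base + gain·|Δg_t| + congruence·c_t, 0, 1)`, with
  participant heterogeneity, a 500-ms refractory period, empty trials,
  and post-video contaminant presses.
* **Agreement measurement** — debouncing, 1-second binning, leave-one-out
  group norms, and the scaled agreement

  `agreement = (r_obs − r_min) / (r_max − r_min)`,

  where `r_min`/`r_max` are the extreme correlations attainable at the
  trial's press count; plus permutation nulls (press counts preserved,
  timing randomized), two-tailed p values, and cross-stimulus /
  cross-group specificity contrasts.
* **Inference** — REML mixed models with Satterthwaite df and Wald CIs,
  average marginal effects of trend per framing × salience cell
  (coefficient summation = delta method = numeric derivative), an
  exploratory stimulus-descriptor model, and Monte-Carlo power simulation
  from published variance components.

## A worked example

```r
library(segmap)

# 1. A 10-region map and five 30-second stimuli with random piecewise trends
map <- build_region_map(n_regions = 10, seed = 7)
designs <- lapply(1:5, function(i)
  stimulus_design(1, sprintf("s%02d", i), duration_s = 30, seed = i))
series <- lapply(designs, function(d) generate_exp1_series(30, seed = d$seed))
names(series) <- sapply(designs, `[[`, "stimulus_id")

# 2. Twenty synthetic viewers whose presses track value change
cohort <- simulate_cohort(designs, series, n_participants = 20,
                          response_params(change_gain = 4), seed = 11)
cohort <- filter_trials(cohort)
attr(cohort, "filter_audit")
#>    total       ok    empty post_end
#>      100      100        0        0

# 3. Scaled agreement and its permutation null
binned <- bin_cohort(cohort)
records <- cohort_agreement(binned)
obs <- mean(records$agreement)
nul <- permutation_null(binned, iterations = 1000, seed = 2)
nul
#> <null_distribution> 1000 iterations: mean 0.488 (sd 0.0204), 95% [0.446, 0.527]
sprintf("observed mean agreement %.3f, p = %.4f", obs, two_tailed_p(nul, obs))
#> "observed mean agreement 0.653, p = 0.0020"

# 4. Stimulus specificity
sp <- specificity_table(binned, "cross_stimulus")
tapply(sp$agreement, sp$comparison, mean)
#> cross_stimulus  same_stimulus
#>      0.4964453      0.6534435
```

The cohort agrees far above the permutation null (0.653 vs a null of
0.488 ± 0.020; the two-tailed p of 0.002 is the smallest value a
1000-iteration null can report), and agreement is stimulus-specific:
responses match their own stimulus's group norm (0.65) much better than
other stimuli's norms (0.50). That is the qualitative signature expected
of genuine, change-locked segmentation.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the full study pipeline and
write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_stimuli.R` | region map, all three stimulus sets, design manifests |
| `02_responses.R` | synthetic cohorts incl. the 117 × 31 and 176 × 32 fixtures with exact trial accounting (3349 / 5224 analyzable) |
| `03_agreement.R` | per-group agreement, 10000-iteration permutation nulls, specificity contrasts |
| `04_models.R` | contrast, descriptor, and factorial mixed models; AME tables |
| `05_power.R` | Monte-Carlo power at the two published design sizes plus a type-I check |

Each is a thin narrative over exported package functions;
`run_pipeline(pipeline_config(...))` performs the same chain end-to-end
into a single audited run directory.

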