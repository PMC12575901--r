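#!/usr/bin/env Rscript
# Stimulus generation for the three experimental designs.
#
# Builds the Voronoi region map, the 15 random piecewise-linear stimuli of
# the first experiment, and the two 32-stimulus factorials (trend x framing
# x colour scale; trend x framing x spatial pattern with 3-or-4 changing
# regions), and writes geometry, design manifests and long-format value
# tables under results/stimuli/.

suppressMessages(library(segmap))

seed <- 20260927L
out <- "results/stimuli"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

map <- build_region_map(n_regions = 10, seed = substream_seed(seed, "map"))
write_region_map_geojson(map, file.path(out, "map.geojson"))
message("region map: ", length(map$regions), " regions, ",
        sum(map$adjacency) / 2, " adjacent pairs")

# -- random piecewise-linear stimuli (60 s, timeline-unit factor is metadata)
d1 <- lapply(1:15, function(i) {
  stimulus_design(1, sprintf("e1_s%02d", i),
                  timeline_unit = "days",  # label differs between groups only
                  seed = substream_seed(seed, "e1", i))
})
s1 <- lapply(d1, function(d) {
  generate_exp1_series(duration_s = 60, seed = d$seed)
})
names(s1) <- vapply(d1, `[[`, "", "stimulus_id")
write_design_manifest(d1, file.path(out, "designs_exp1.json"))
write_series_csv(s1, file.path(out, "series_exp1.csv"))
desc <- do.call(rbind, lapply(s1, series_descriptors))
desc$stimulus_id <- names(s1)
write.csv(desc, file.path(out, "descriptors_exp1.csv"), row.names = FALSE)
message(sprintf("piecewise stimuli: trend range [%.2f, %.2f], max slope up to %.2f",
                min(desc$trend), max(desc$trend), max(desc$max_slope)))

# -- colour factorial: 8 trends x 2 framings x 2 colour-scale classes
d2 <- enumerate_design(2, seed = seed)
s2 <- generate_series(d2)
write_design_manifest(d2, file.path(out, "designs_exp2.json"))
write_series_csv(s2, file.path(out, "series_exp2.csv"))
message("colour factorial: ", length(d2), " stimuli on trend grid ",
        paste(exp2_trend_grid(), collapse = " "))

# -- spatial factorial: 4 trends x 2 framings x 2 patterns x {3,4} regions
d3 <- resolve_changing_regions(enumerate_design(3, seed = seed), map)
s3 <- generate_series(d3, map = map)
write_design_manifest(d3, file.path(out, "designs_exp3.json"))
write_series_csv(s3, file.path(out, "series_exp3.csv"))
t3 <- design_table(d3)
message("spatial factorial: ", nrow(t3), " stimuli, ",
        sum(t3$n_changing == 3), " with 3 and ",
        sum(t3$n_changing == 4), " with 4 changing regions")
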