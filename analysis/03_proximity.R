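#!/usr/bin/env Rscript
# Stage 3: pair each macrophage with its nearest tumor cell at t0, form the
# top-15 closest and top-15 farthest groups, and run the one-tailed Welch
# comparison of their average speeds.

suppressMessages(library(tmequant))

run <- "results/run"
tracks <- read_tracks(file.path(run, "tracks.csv"))
population <- read.csv(file.path(run, "population.csv"))

pa <- proximity_analysis(tracks, population, k = 15)
write.csv(pa$records, "results/proximity_records.csv", row.names = FALSE)
jsonlite::write_json(pa$test, "results/proximity_test.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("close group mean speed: %.2f um/h\n", pa$test$mean_close))
cat(sprintf("far group mean speed:   %.2f um/h\n", pa$test$mean_far))
cat(sprintf("one-tailed Welch t = %.2f, p = %.3g\n", pa$test$t, pa$test$p))
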