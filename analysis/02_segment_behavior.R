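#!/usr/bin/env Rscript
# Behavioral segmentation of the simulated session: zone transitions with
# BIL/BID windows, per-zone rest fractions and speed histograms, maximum
# sustained speed, acceleration events, and the BIL effect on speed.

suppressPackageStartupMessages(library(patchpace))

track <- read_tracking_csv("results/session/tracking.csv",
                           arena = arena_config())
out_dir <- "results/behavior"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

transitions <- detect_transitions(track$zone, track$time)
cat(sprintf("%d transitions detected (%d dropped at session edges)\n",
            nrow(transitions$events), transitions$n_dropped_edge))
write.csv(transitions$events[, c("t0_index", "t0_time", "direction")],
          file.path(out_dir, "transitions.csv"), row.names = FALSE)

rf <- rest_fraction(track$speed, track$zone)
mss <- max_sustained_speed(track$speed)
cat(sprintf("rest fraction: dark %.2f, light %.2f; max sustained speed %.1f cm/s\n",
            rf[["dark"]], rf[["light"]], mss))

hist_df <- speed_histogram(track$speed, track$zone)
write.csv(hist_df, file.path(out_dir, "speed_histogram.csv"),
          row.names = FALSE)

ev <- extract_acceleration_events(track, transitions, mean_speed_thr = 5)
cat(sprintf("%d acceleration events by context:\n", nrow(ev)))
print(table(ev$context))
write.csv(ev[, c("center_index", "center_time", "mean_speed", "context")],
          file.path(out_dir, "acceleration_events.csv"), row.names = FALSE)

bil <- bil_effect(track$speed, transitions, phase = "both", seed = 1)
cat(sprintf("BIL effect on speed: %.2f cm/s (95%% CI %.2f to %.2f)\n",
            bil$estimate, bil$ci[1], bil$ci[2]))

write_summary_json(list(n_transitions = nrow(transitions$events),
                        rest_fraction = as.list(rf),
                        max_sustained_speed = mss,
                        n_accel_events = nrow(ev),
                        bil_speed = bil[c("estimate", "ci")]),
                   file.path(out_dir, "summary.json"))
cat("wrote", out_dir, "\n")
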