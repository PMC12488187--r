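#!/usr/bin/env Rscript
# Signal-behavior coupling: event-windowed cross-correlation of aggregate
# fluorescence with speed and acceleration, per-animal summaries, and
# transition-triggered averages (figure-ready CSVs).

suppressPackageStartupMessages(library(patchpace))

track <- read_tracking_csv("results/session/tracking.csv",
                           arena = arena_config())
loaded <- read_traces("results/session/traces.csv")
out_dir <- "results/coupling"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cond <- condition_dff(loaded$traces)
agg <- colMeans(cond$dff)

transitions <- detect_transitions(track$zone, track$time)
ev <- extract_acceleration_events(track, transitions, mean_speed_thr = 5)
cat(sprintf("%d acceleration events\n", nrow(ev)))

ec <- correlate_events(agg, track, ev)
write.csv(ec, file.path(out_dir, "event_correlations.csv"),
          row.names = FALSE)

sm <- summarize_coupling(ec, "sim1")
print(sm)
write.csv(sm, file.path(out_dir, "coupling_summary.csv"), row.names = FALSE)

tta <- transition_triggered_average(agg, track, transitions)
write.csv(tta, file.path(out_dir, "transition_triggered_average.csv"),
          row.names = FALSE)

bil <- bil_effect(agg, transitions, phase = "both", seed = 1)
cat(sprintf("BIL effect on aggregate dF/F: %.4f (95%% CI %.4f to %.4f)\n",
            bil$estimate, bil$ci[1], bil$ci[2]))

write_summary_json(list(n_events = nrow(ev),
                        bil_dff = bil[c("estimate", "ci")]),
                   file.path(out_dir, "summary.json"))
cat("wrote", out_dir, "\n")
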