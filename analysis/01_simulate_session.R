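#!/usr/bin/env Rscript
# Simulate one light/dark-box session (trajectory + calcium traces with
# ground-truth labels) and write it to results/session/ as plain-text files.
# Downstream scripts (02-05) consume these outputs.

suppressPackageStartupMessages(library(patchpace))

out_dir <- "results/session"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

arena <- arena_config()                      # 40 x 29 cm, 30 Hz
# slower, smoother speed dynamics than the config default so that
# accelerating/decelerating bouts are long enough for the deceleration-
# coupled neurons to be resolvable by their calcium kernel
beh_cfg <- behavior_gen_config(duration = 600, ou_tau = 2,
                               speed_smooth_s = 0.8, noise_sd = 2.5,
                               seed = 101)
track <- simulate_trajectory(arena, beh_cfg)
print(track)

pop <- neuron_population(15, classes = c("L+", "L-", "Q+", "Q-",
                                         "light", "dark", "DP", "null"))
sim <- simulate_traces(track, neuron_gen_config(pop, kernel_tau = 0.25,
                                                seed = 102))
print(sim$traces)
cat("ground-truth class mix:\n")
print(table(pop$class))

write_tracking_csv(track, file.path(out_dir, "tracking.csv"))
write_traces(sim$traces, file.path(out_dir, "traces.csv"),
             labels = cbind(sim$labels, class = pop$class))
write_summary_json(list(arena = unclass(arena),
                        behavior_cfg = unclass(beh_cfg),
                        n_neurons = nrow(pop)),
                   file.path(out_dir, "config.json"))
cat("wrote", out_dir, "\n")
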