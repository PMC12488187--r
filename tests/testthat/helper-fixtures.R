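# Shared fixtures, all built in code.

fs_default <- 30

# a small deterministic track: scripted zone sequence and speed
scripted_track <- function(zone_runs_s, speeds, fs = fs_default) {
  zone <- rep(rep(names(zone_runs_s), times = 1), times = zone_runs_s * fs)
  n <- length(zone)
  time <- (seq_len(n) - 1) / fs
  speed <- rep_len(speeds, n)
  # positions consistent with zone only (x on either side of a divider at 20)
  x <- ifelse(zone == "light", 30, 10)
  tracking_series(time, x, rep(14.5, n), zone = zone, speed = speed)
}

# brute-force ADI oracle: all-pairs count, wins + half-ties
adi_oracle <- function(acc, dec) {
  wins <- 0; ties <- 0
  for (a in acc) for (d in dec) {
    if (a > d) wins <- wins + 1
    else if (a == d) ties <- ties + 1
  }
  ((wins + 0.5 * ties) / (length(acc) * length(dec)) - 0.5) * 2
}

# brute-force max sustained speed: max over windows of window minima
sustained_oracle <- function(speed, w) {
  if (length(speed) < w) stop("too short")
  max(vapply(seq_len(length(speed) - w + 1L),
             function(i) min(speed[i:(i + w - 1L)]), numeric(1)))
}

default_arena <- function() arena_config()

quick_session <- function(seed = 42, duration = 300, ...) {
  simulate_trajectory(default_arena(),
                      behavior_gen_config(duration = duration, seed = seed,
                                          ...))
}
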