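test_that("compute_speed matches closed forms and a brute-force oracle", {
  fs <- 30
  n <- 90
  time <- (seq_len(n) - 1) / fs
  # stationary point -> all zeros
  expect_equal(compute_speed(rep(5, n), rep(5, n), time), rep(0, n))
  # x advancing 0.1 cm per frame -> 3 cm/s each frame
  x <- seq(0, by = 0.1, length.out = n)
  expect_equal(compute_speed(x, rep(0, n), time), rep(3, n))
  # random walk with smoothing equals finite differences + boxcar
  set.seed(7)
  xr <- cumsum(rnorm(n)); yr <- cumsum(rnorm(n))
  v_raw <- c(NA, sqrt(diff(xr)^2 + diff(yr)^2) * fs)
  v_raw[1] <- v_raw[2]
  oracle <- as.numeric(zoo::rollmean(zoo::zoo(v_raw), k = 5,
                                     fill = "extend", align = "center"))
  expect_equal(compute_speed(xr, yr, time, smoothing_window = 5), oracle)
  # non-monotonic timestamps rejected
  expect_error(compute_speed(x, rep(0, n), rev(time)), "increasing")
})

test_that("binarize_acceleration thresholds at +/-0.4 with a frame-wise oracle", {
  fs <- 30
  n <- 120
  time <- (seq_len(n) - 1) / fs
  # constant speed -> all neither
  st <- binarize_acceleration(rep(5, n), time)
  expect_true(all(st == "neither"))
  # ramp +1 cm/s per s -> all accelerating at default threshold
  st <- binarize_acceleration(time * 1, time, smoothing_window = 1)
  expect_true(all(st == "accelerating"))
  # triangular profile: states flip at the apex (frame-wise oracle, raw accel)
  apex <- 60
  sp <- c(seq(0, 5.9, length.out = apex), seq(6, 0.1, length.out = n - apex))
  acc <- c(NA, diff(sp) * fs); acc[1] <- acc[2]
  oracle <- ifelse(acc > 0.4, "accelerating",
                   ifelse(acc < -0.4, "decelerating", "neither"))
  st <- binarize_acceleration(sp, time, smoothing_window = 1)
  expect_equal(as.character(st), oracle)
  expect_error(binarize_acceleration(sp, time, thr = 0), ">")
})

test_that("detect_transitions matches a direct label-change scan", {
  # constant zone -> no events
  tr <- scripted_track(c(dark = 30), 5)
  expect_equal(nrow(detect_transitions(tr$zone, tr$time)$events), 0L)
  # single dark->light change: approach all BID, retreat all BIL
  tr <- scripted_track(c(dark = 10, light = 10), 5)
  d <- detect_transitions(tr$zone, tr$time)
  expect_equal(nrow(d$events), 1L)
  expect_equal(d$events$direction, "into_light")
  expect_equal(d$events$t0_index, 301L)
  expect_setequal(d$events$bid_idx[[1]], d$events$approach_idx[[1]])
  expect_setequal(d$events$bil_idx[[1]], d$events$retreat_idx[[1]])
  # 5 alternating crossings spaced 10 s: t0 indices match the scan exactly
  runs <- c(dark = 10, light = 10, dark = 10, light = 10, dark = 10,
            light = 10)
  tr <- scripted_track(runs, 5)
  d <- detect_transitions(tr$zone, tr$time)
  z <- as.character(tr$zone)
  scan <- which(z[-1] != z[-length(z)]) + 1L
  expect_equal(d$events$t0_index, scan)
  expect_equal(nrow(d$events) + d$n_dropped_edge, length(scan))
})

test_that("transition windows partition into complementary BIL/BID masks", {
  tr <- quick_session(seed = 5)
  d <- detect_transitions(tr$zone, tr$time)
  for (i in seq_len(nrow(d$events))) {
    win <- c(d$events$approach_idx[[i]], d$events$retreat_idx[[i]])
    bil <- d$events$bil_idx[[i]]; bid <- d$events$bid_idx[[i]]
    expect_length(intersect(bil, bid), 0)
    expect_setequal(c(bil, bid), win)
    expect_false(d$events$t0_index[i] %in% win)
  }
})

test_that("debouncing folds sub-dwell zone flickers into the previous residency", {
  fs <- 30
  zone <- c(rep("dark", 10 * fs), rep("light", 5), rep("dark", 10 * fs))
  time <- (seq_along(zone) - 1) / fs
  d <- detect_transitions(zone, time, min_dwell = 0.5)
  expect_equal(nrow(d$events), 0L)
  d2 <- detect_transitions(zone, time, min_dwell = 0)
  expect_equal(nrow(d2$events), 2L)
})

test_that("rest_fraction matches closed forms on piecewise-constant speeds", {
  n <- 600
  zone <- rep("dark", n)
  expect_equal(rest_fraction(rep(1, n), zone),
               c(light = NA_real_, dark = 1))
  sp <- rep(c(1, 5), each = n / 2)
  expect_equal(rest_fraction(sp, zone)[["dark"]], 0.5)
  # invariant to frame duplication (dwell-preserving reparameterization)
  idx <- rep(seq_len(n), each = 3)
  expect_equal(rest_fraction(sp[idx], zone[idx]), rest_fraction(sp, zone))
})

test_that("max_sustained_speed equals the max-of-window-minima oracle", {
  expect_equal(max_sustained_speed(rep(7, 60)), 7)
  sp <- rep(5, 60); sp[30] <- 50
  expect_equal(max_sustained_speed(sp), 5)
  set.seed(11)
  for (i in 1:20) {
    sp <- runif(80, 0, 20)
    expect_equal(max_sustained_speed(sp, 20), sustained_oracle(sp, 20))
  }
  # boundary properties
  sp <- runif(60, 0, 20)
  expect_equal(max_sustained_speed(sp, 1), max(sp))
  vals <- vapply(c(1, 5, 10, 20, 40), function(w)
    max_sustained_speed(sp, w), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(max_sustained_speed(sp[1:10], 20), "shorter")
})

test_that("speed_histogram is occupancy-normalized per zone", {
  n <- 300
  zone <- rep(c("light", "dark"), each = n / 2)
  sp <- c(rep(3.5, n / 2), rep(c(1.5, 7.5), each = n / 4))
  h <- speed_histogram(sp, zone, bin_width = 1)
  light <- h[h$zone == "light", ]
  expect_equal(sum(light$prob), 1)
  expect_equal(light$prob[light$bin_lo == 3], 1)
  dark <- h[h$zone == "dark", ]
  expect_equal(dark$prob[dark$bin_lo == 1], 0.5)
  expect_equal(dark$prob[dark$bin_lo == 7], 0.5)
})

test_that("acceleration events: scripted ramps are found with correct contexts", {
  fs <- 30
  # constant-speed session -> no events
  tr <- scripted_track(c(dark = 60), 8)
  ev <- extract_acceleration_events(tr, mean_speed_thr = 5)
  expect_equal(nrow(ev), 0L)
  # one ramp mid-session in dark -> one event, context within_dark
  n <- 60 * fs
  sp <- rep(8, n)
  sp[900:960] <- seq(8, 16, length.out = 61)
  sp[961:n] <- 16
  time <- (seq_len(n) - 1) / fs
  tr <- tracking_series(time, ifelse(rep(TRUE, n), 10, 10), rep(14.5, n),
                        zone = rep("dark", n), speed = sp)
  ev <- extract_acceleration_events(tr, mean_speed_thr = 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$context, "within_dark")
  expect_true(abs(ev$center_index - 900) <= 5)
  # equivariance to time shift of the whole session
  tr2 <- tracking_series(time + 100, tr$x, tr$y, zone = tr$zone, speed = sp)
  ev2 <- extract_acceleration_events(tr2, mean_speed_thr = 5)
  expect_equal(ev2$center_index, ev$center_index)
})

test_that("scripted ramps below the mean-speed filter are dropped", {
  fs <- 30
  n <- 240 * fs
  time <- (seq_len(n) - 1) / fs
  sp <- rep(0.5, n)
  onsets <- (1:12) * 18 * fs
  # 9 fast ramps (window mean > 6) and 3 slow ones (window mean < 6)
  for (j in seq_along(onsets)) {
    k <- onsets[j]
    peak <- if (j <= 9) 20 else 2
    sp[k:(k + 30)] <- seq(sp[k], peak, length.out = 31)
    sp[(k + 31):(k + 120)] <- peak
    sp[(k + 121):(k + 150)] <- seq(peak, 0.5, length.out = 30)
  }
  tr <- tracking_series(time, rep(10, n), rep(14.5, n),
                        zone = rep("dark", n), speed = sp)
  ev <- extract_acceleration_events(tr, mean_speed_thr = 6)
  expect_equal(nrow(ev), 9L)
  expect_true(all(vapply(ev$center_index, function(k)
    min(abs(k - onsets)) <= 5, logical(1))))
})

test_that("bil_effect is zero under symmetry, antisymmetric under label swap,
           and recovers a programmed increment", {
  tr <- quick_session(seed = 9, duration = 1200, bil_increment = 3)
  d <- detect_transitions(tr$zone, tr$time)
  be <- bil_effect(tr$speed, d, phase = "approach", n_boot = 400, seed = 2)
  expect_true(be$ci[1] <= 3 && 3 <= be$ci[2])
  # swapping zone labels negates the estimate
  zswap <- ifelse(as.character(tr$zone) == "light", "dark", "light")
  dswap <- detect_transitions(zswap, tr$time)
  be_swap <- bil_effect(tr$speed, dswap, phase = "approach", n_boot = 0)
  expect_equal(be_swap$estimate, -be$estimate, tolerance = 1e-10)
  # identical window profiles for both directions -> exactly zero
  fs <- 30
  runs <- c(dark = 20, light = 20, dark = 20, light = 20)
  trs <- scripted_track(runs, 6)
  ds <- detect_transitions(trs$zone, trs$time)
  be0 <- bil_effect(trs$speed, ds, phase = "approach", n_boot = 0)
  expect_equal(be0$estimate, 0)
  # one direction missing -> explicit error
  tr1 <- scripted_track(c(dark = 10, light = 10), 6)
  d1 <- detect_transitions(tr1$zone, tr1$time)
  expect_error(bil_effect(tr1$speed, d1), "direction")
})
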