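accel_state_vec <- function(acc_n, dec_n, nei_n = 0) {
  factor(rep(c("accelerating", "decelerating", "neither"),
             c(acc_n, dec_n, nei_n)),
         levels = c("accelerating", "decelerating", "neither"))
}

test_that("compute_adi matches hand-computed and frozen oracle values", {
  # identical distributions -> 0
  st <- accel_state_vec(4, 4)
  expect_equal(compute_adi(rep(1, 8), st), 0)
  # perfect separation, deceleration higher -> exactly -1
  expect_equal(compute_adi(c(1, 2, 3, 9, 10, 11, 12), accel_state_vec(3, 4)),
               -1)
  expect_equal(compute_adi(c(9, 10, 11, 1, 2, 3, 4), accel_state_vec(3, 4)),
               +1)
  # frozen value from the all-pairs oracle: acc {0.1, 0.4}, dec {0.2, 0.3, 0.5}
  expect_equal(compute_adi(c(0.1, 0.4, 0.2, 0.3, 0.5), accel_state_vec(2, 3)),
               -1 / 3, tolerance = 1e-12)
  # neither frames are excluded
  expect_equal(compute_adi(c(0.1, 0.4, 0.2, 0.3, 0.5, 99, 99),
                           accel_state_vec(2, 3, 2)),
               -1 / 3, tolerance = 1e-12)
  # empty class -> NA with flag
  out <- compute_adi(c(1, 2), accel_state_vec(2, 0))
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "empty_class")
})

test_that("compute_adi equals the pair-count oracle on 100 random tied instances", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    # draw from a small grid so ties are frequent
    acc <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE)
    dec <- sample(seq(0, 1, by = 0.1), n2, replace = TRUE)
    st <- accel_state_vec(n1, n2)
    expect_equal(compute_adi(c(acc, dec), st), adi_oracle(acc, dec),
                 tolerance = 1e-12)
  }
})

test_that("compute_adi is antisymmetric and rank-invariant", {
  set.seed(43)
  for (i in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    x <- c(sample(seq(0, 2, by = 0.25), n1, TRUE),
           sample(seq(0, 2, by = 0.25), n2, TRUE))
    st <- accel_state_vec(n1, n2)
    st_swap <- accel_state_vec(n2, n1)
    # label swap negates
    expect_equal(compute_adi(c(x[(n1 + 1):(n1 + n2)], x[1:n1]), st_swap),
                 -compute_adi(x, st), tolerance = 1e-12)
    # strictly monotone transform leaves the rank statistic unchanged
    expect_equal(compute_adi(exp(3 * x) - 1, st), compute_adi(x, st),
                 tolerance = 1e-12)
  }
})

test_that("classify_dp uses a strict threshold and is monotone in it", {
  expect_true(classify_dp(-0.95))
  expect_false(classify_dp(0.8))      # boundary: strict inequality
  expect_true(is.na(classify_dp(NA_real_)))
  set.seed(44)
  adis <- runif(200, -1, 1)
  counts <- vapply(seq(0, 1, by = 0.1), function(thr)
    sum(classify_dp(adis, thr)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("zone preference: trivial separations and insufficient data", {
  n <- 2000
  zone <- rep(c("light", "dark"), each = n / 2)
  # identical activity -> none
  out <- classify_zone_preference(rep(1, n), zone, n_neurons = 1)
  expect_equal(out$zone_pref, "none")
  # activity only in light -> light
  x <- c(runif(n / 2, 1, 2), rep(0, n / 2))
  expect_equal(classify_zone_preference(x, zone, 1)$zone_pref, "light")
  expect_equal(classify_zone_preference(rev(x), rev(zone), 1)$zone_pref,
               "light")
  # dark-preferring symmetric case
  expect_equal(classify_zone_preference(x, rev(zone), 1)$zone_pref, "dark")
  # a zone with <10 frames -> flagged
  out2 <- classify_zone_preference(x[1:20], c(rep("light", 15),
                                              rep("dark", 5)), 1)
  expect_equal(out2$zone_pref, "none")
  expect_equal(out2$flag, "insufficient_data")
})

test_that("speed tuning: noiseless linear and symmetric quadratic limits", {
  set.seed(45)
  v <- runif(3000, 0, 20)
  # dff proportional to speed -> L+ with rho 1
  out <- classify_speed_tuning(0.5 * v, v, n_neurons = 1)
  expect_equal(out$speed_class, "L+")
  expect_equal(out$rho, 1)
  expect_equal(classify_speed_tuning(-0.5 * v, v, 1)$speed_class, "L-")
  # symmetric quadratic on a symmetric speed distribution: the rank branch
  # must not claim it; quadratic fit is essentially perfect
  vq <- runif(3000, 0, 20)
  x <- (vq - 10)^2
  out2 <- classify_speed_tuning(x, vq, 1)
  expect_equal(out2$speed_class, "Q+")
  expect_gt(out2$fit_quality, 0.99)
  expect_lt(abs(out2$rho), 0.1)
  out3 <- classify_speed_tuning(-x, vq, 1)
  expect_equal(out3$speed_class, "Q-")
  # constant speed -> degenerate
  out4 <- classify_speed_tuning(x, rep(5, 3000), 1)
  expect_equal(out4$speed_class, "none")
  expect_equal(out4$flag, "degenerate")
})

test_that("Spearman branch takes precedence over the quadratic fallback", {
  set.seed(46)
  v <- runif(3000, 0, 20)
  # shifted-vertex parabola has a strong monotone component: must be L-,
  # never Q+, even though a quadratic fits it perfectly
  x <- (v - 25)^2
  out <- classify_speed_tuning(x, v, n_neurons = 1)
  expect_equal(out$speed_class, "L-")
})

test_that("transition activity and BIL/BID selectivity follow the masks", {
  tr <- quick_session(seed = 61, duration = 600)
  d <- detect_transitions(tr$zone, tr$time)
  ev <- d$events
  n <- length(tr$time)
  # all-zero neuron -> inactive
  out <- classify_transition_active(rep(0, n), d, tr$time)
  expect_false(out$transition_active)
  expect_equal(out$transition_selectivity, "inactive")
  # neuron firing only on pre-crossing frames of into_dark -> BIL-selective
  x <- rep(0, n)
  for (i in which(ev$direction == "into_dark"))
    x[ev$approach_idx[[i]]] <- 0.5
  out2 <- classify_transition_active(x, d, tr$time)
  expect_true(out2$transition_active)
  expect_equal(out2$transition_selectivity, "BIL_selective")
  # symmetric BID case: post-crossing frames of into_dark
  x3 <- rep(0, n)
  for (i in which(ev$direction == "into_dark"))
    x3[ev$retreat_idx[[i]]] <- 0.5
  out3 <- classify_transition_active(x3, d, tr$time)
  expect_equal(out3$transition_selectivity, "BID_selective")
  # activity in both masks -> nonselective
  out4 <- classify_transition_active(x + x3, d, tr$time)
  expect_equal(out4$transition_selectivity, "nonselective")
  # sub-threshold activity -> inactive (0.0238 threshold)
  out5 <- classify_transition_active(x * 0.04, d, tr$time)
  expect_false(out5$transition_active)
  # no transitions -> flagged missing
  tr0 <- scripted_track(c(dark = 30), 5)
  d0 <- detect_transitions(tr0$zone, tr0$time)
  out6 <- classify_transition_active(rep(1, length(tr0$time)), d0, tr0$time)
  expect_true(is.na(out6$transition_active))
  expect_equal(out6$flag, "no_transitions")
})

test_that("transition-selective generator neurons are recovered", {
  tr <- quick_session(seed = 62, duration = 900)
  nrn <- data.frame(bil_gain = c(25, 0), bid_gain = c(0, 25),
                    baseline_rate = 0)
  sim <- simulate_traces(tr, neuron_gen_config(nrn, kernel_tau = 0.15,
                                               noise_sd = 0.005, seed = 7))
  cond <- condition_dff(sim$traces)
  d <- detect_transitions(tr$zone, tr$time)
  out1 <- classify_transition_active(cond$dff[1, ], d, tr$time)
  out2 <- classify_transition_active(cond$dff[2, ], d, tr$time)
  expect_true(out1$transition_active)
  expect_equal(out1$transition_selectivity, "BIL_selective")
  expect_equal(out2$transition_selectivity, "BID_selective")
})

test_that("category_contingency reproduces closed-form chi-square values", {
  lab <- data.frame(a = rep(c("x", "y"), each = 10),
                    b = rep(c("p", "q"), each = 10))
  out <- category_contingency(lab, "a", "b")
  # [[10,0],[0,10]] -> chi-square 20 (n(ad-bc)^2 / (r1 r2 c1 c2))
  expect_equal(out$statistic, 20)
  expect_lt(out$p_value, 0.001)
  # equal rows -> statistic 0
  lab2 <- data.frame(a = rep(c("x", "y"), each = 10),
                     b = rep(c("p", "q"), 10))
  expect_equal(category_contingency(lab2, "a", "b")$statistic, 0)
  # small expected counts in a 2x2 -> Fisher substitution
  lab3 <- data.frame(a = rep(c("x", "y"), c(4, 4)),
                     b = c("p", "p", "p", "q", "q", "q", "q", "p"))
  expect_equal(category_contingency(lab3, "a", "b")$method, "fisher")
  # empty level -> informative error
  lab4 <- data.frame(a = rep("x", 10), b = rep(c("p", "q"), 5))
  expect_error(category_contingency(lab4, "a", "b"), "degenerate")
})

test_that("independent labels reject at ~alpha (chi-square calibration)", {
  set.seed(47)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    lab <- data.frame(a = sample(c("x", "y"), 120, TRUE),
                      b = sample(c("p", "q"), 120, TRUE))
    category_contingency(lab, "a", "b")$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(rate, 0.05 + 3 * se)
  expect_gt(rate, 0.05 - 3 * se)
})
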