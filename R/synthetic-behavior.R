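# Synthetic light/dark-box sessions: arena geometry, a zone-residency
# schedule, an Ornstein-Uhlenbeck-style speed process with rest bouts and
# transition excursions, and positions traced on a smooth loop inside each
# zone. The generator is the ground-truth oracle for the behavioral module.

#' Arena geometry for a light/dark box
#'
#' Default dimensions follow a standard two-zone box: 40 cm wide, 29 cm deep,
#' divided midway along the long axis into a light and a dark zone.
#'
#' @param width arena width along the divided axis (cm).
#' @param depth arena depth (cm).
#' @param divider_x boundary between zones along x (cm).
#' @param light_side `"high_x"` or `"low_x"`: which side of the divider is lit.
#' @param frame_rate tracking frame rate (Hz).
#' @return object of class `arena_config`.
#' @export
arena_config <- function(width = 40, depth = 29, divider_x = width / 2,
                         light_side = c("high_x", "low_x"), frame_rate = 30) {
  light_side <- match.arg(light_side)
  check_scalar(width, "width", lower = 0, strict_lower = TRUE)
  check_scalar(depth, "depth", lower = 0, strict_lower = TRUE)
  check_scalar(divider_x, "divider_x", lower = 0, strict_lower = TRUE)
  if (divider_x >= width) stop_input("divider_x must lie inside the arena")
  check_scalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  structure(list(width = width, depth = depth, divider_x = divider_x,
                 light_side = light_side, frame_rate = frame_rate),
            class = "arena_config")
}

#' Behavioral generator configuration
#'
#' Parameters of the synthetic trajectory: zone-dependent speed set-points,
#' rest-bout scheduling, transition scheduling, the transition speed
#' excursion, and the programmed body-in-light (BIL) speed increment. Within
#' a lead-in plus the +/-2 s transition window the speed set-point switches
#' to the mean of the two zone set-points, so `bil_increment` (added on
#' BIL-masked frames) is the only BIL/BID asymmetry and is the quantity the
#' BIL-effect estimator should recover.
#'
#' @param duration session length (s).
#' @param speed_mean_light,speed_mean_dark speed set-points (cm/s).
#' @param rest_bout_rate_light,rest_bout_rate_dark rest bouts per minute.
#' @param rest_speed_cap restful speed cap (cm/s); rest-bout target speed is
#'   0.4 x this cap.
#' @param rest_bout_duration mean rest-bout duration (s).
#' @param transition_rate zone transitions per minute (0 = never leave the
#'   starting zone).
#' @param transition_peak_amp peak amplitude of the symmetric speed excursion
#'   at crossings (cm/s).
#' @param bil_increment extra speed (cm/s) on BIL frames of transition
#'   windows.
#' @param noise_sd stationary SD of the speed fluctuation (cm/s), before
#'   smoothing.
#' @param ou_tau relaxation time of the speed process (s).
#' @param speed_smooth_s low-pass window (s) applied to the generated speed;
#'   0 disables.
#' @param dark_dwell_bias ratio of mean dark to mean light residency
#'   (>1 reproduces dark preference).
#' @param start_zone zone at t = 0 (animals are introduced into the light
#'   zone in the standard protocol).
#' @param seed integer seed (required; no global RNG state is used).
#' @return object of class `behavior_gen_config`.
#' @export
behavior_gen_config <- function(duration = 600,
                                speed_mean_light = 8, speed_mean_dark = 4,
                                rest_bout_rate_light = 1.5,
                                rest_bout_rate_dark = 6,
                                rest_speed_cap = 2, rest_bout_duration = 2,
                                transition_rate = 2,
                                transition_peak_amp = 4, bil_increment = 2,
                                noise_sd = 1.5, ou_tau = 2 / 3,
                                speed_smooth_s = 0.5, dark_dwell_bias = 2,
                                start_zone = c("light", "dark"), seed) {
  start_zone <- match.arg(start_zone)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  for (nm in c("speed_mean_light", "speed_mean_dark", "rest_bout_rate_light",
               "rest_bout_rate_dark", "rest_speed_cap", "rest_bout_duration",
               "transition_rate", "transition_peak_amp", "noise_sd"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(bil_increment, "bil_increment")
  check_scalar(ou_tau, "ou_tau", lower = 0, strict_lower = TRUE)
  check_scalar(dark_dwell_bias, "dark_dwell_bias", lower = 0,
               strict_lower = TRUE)
  if (missing(seed)) stop_input("`seed` is required")
  structure(mget(c("duration", "speed_mean_light", "speed_mean_dark",
                   "rest_bout_rate_light", "rest_bout_rate_dark",
                   "rest_speed_cap", "rest_bout_duration", "transition_rate",
                   "transition_peak_amp", "bil_increment", "noise_sd",
                   "ou_tau", "speed_smooth_s", "dark_dwell_bias",
                   "start_zone", "seed")),
            class = "behavior_gen_config")
}

# residency schedule: exponential dwell times per zone, floored at min_dwell,
# with dark residencies `dark_dwell_bias` times longer on average
schedule_residencies <- function(cfg, min_dwell = 5) {
  if (cfg$transition_rate <= 0)
    return(data.frame(zone = cfg$start_zone, duration = cfg$duration))
  gap <- 60 / cfg$transition_rate          # mean time between transitions
  b <- cfg$dark_dwell_bias
  mean_dark <- 2 * gap * b / (1 + b)
  mean_light <- 2 * gap / (1 + b)
  zones <- character(0); durs <- numeric(0)
  z <- cfg$start_zone; total <- 0
  while (total < cfg$duration) {
    m <- if (z == "dark") mean_dark else mean_light
    d <- max(min_dwell, stats::rexp(1, 1 / m))
    zones <- c(zones, z); durs <- c(durs, d)
    total <- total + d
    z <- if (z == "dark") "light" else "dark"
  }
  durs[length(durs)] <- durs[length(durs)] - (total - cfg$duration)
  data.frame(zone = zones, duration = durs)
}

# dense arclength parametrization of an ellipse inset in a zone rectangle;
# returns x(s), y(s) interpolators and the perimeter
zone_loop <- function(x0, x1, depth, gate_high_x) {
  cx <- (x0 + x1) / 2; cy <- depth / 2
  a <- 0.42 * (x1 - x0); b <- 0.42 * depth
  th0 <- if (gate_high_x) 0 else pi   # start at the point nearest the divider
  th <- th0 + seq(0, 2 * pi, length.out = 2049L)
  px <- cx + a * cos(th); py <- cy + b * sin(th)
  s <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  list(fx = stats::approxfun(s, px), fy = stats::approxfun(s, py),
       perimeter = s[length(s)])
}

#' Simulate a light/dark-box trajectory
#'
#' Generates one session: a zone-residency schedule (exponential dwells,
#' dark-biased), per-frame speed from a discretized Ornstein-Uhlenbeck process
#' relaxing toward zone-dependent set-points, scheduled rest bouts (reduced
#' set-point and noise), a symmetric Gaussian speed excursion at each
#' crossing, and the programmed BIL increment on BIL-masked window frames.
#' Positions advance along a smooth elliptical loop inset in the current
#' zone, so recomputing speed from positions reproduces the generated speed
#' (up to discretization); at a scheduled crossing the position jumps to the
#' other zone's gate, an abstraction documented in the methods vignette.
#'
#' @param arena an [arena_config()].
#' @param cfg a [behavior_gen_config()].
#' @return a [tracking_series()] whose `info` holds the generator ground
#'   truth (`transition_index`, `transition_direction`, `rest_mask`, `cfg`).
#' @export
simulate_trajectory <- function(arena, cfg) {
  stopifnot(inherits(arena, "arena_config"),
            inherits(cfg, "behavior_gen_config"))
  fs <- arena$frame_rate; dt <- 1 / fs
  n <- round(cfg$duration * fs)
  with_seed(cfg$seed, {
    res <- schedule_residencies(cfg)
    res_frames <- pmax(1L, round(res$duration * fs))
    # trim/extend trailing residencies so frames sum exactly to n
    while (sum(res_frames) > n) {
      excess <- sum(res_frames) - n
      last <- length(res_frames)
      if (res_frames[last] > excess) {
        res_frames[last] <- res_frames[last] - excess
      } else {
        res_frames <- res_frames[-last]
        res <- res[-last, , drop = FALSE]
      }
    }
    if (sum(res_frames) < n)
      res_frames[length(res_frames)] <- res_frames[length(res_frames)] +
        (n - sum(res_frames))
    zone <- rep(res$zone, res_frames)
    starts <- cumsum(c(1L, res_frames[-length(res_frames)]))
    trans_idx <- starts[-1L]
    trans_dir <- ifelse(res$zone[-1L] == "light", "into_light", "into_dark")

    # --- per-frame speed set-point ---
    target <- ifelse(zone == "light", cfg$speed_mean_light,
                     cfg$speed_mean_dark)
    sym <- (cfg$speed_mean_light + cfg$speed_mean_dark) / 2
    # the symmetric set-point starts well before the analysis window so the
    # speed process has fully relaxed by -2 s (>= 4 relaxation times for the
    # default ou_tau) and bil_increment is the only BIL/BID asymmetry
    lead <- round(5 * fs)
    for (k in trans_idx) {
      idx <- max(1L, k - lead):min(n, k + lead)
      target[idx] <- sym
    }
    # --- rest bouts (kept clear of transition windows) ---
    rest <- rep(FALSE, n)
    rate_of <- c(light = cfg$rest_bout_rate_light,
                 dark = cfg$rest_bout_rate_dark)
    guard <- round(4 * fs)
    near_trans <- rep(FALSE, n)
    for (k in trans_idx)
      near_trans[max(1L, k - guard):min(n, k + guard)] <- TRUE
    p_start <- rate_of[zone] / 60 * dt
    bout_starts <- which(stats::runif(n) < p_start & !near_trans)
    for (k in bout_starts) {
      len <- round(fs * min(2 * cfg$rest_bout_duration,
                            max(0.5, stats::rexp(1, 1 / cfg$rest_bout_duration))))
      idx <- k:min(n, k + len - 1L)
      idx <- idx[!near_trans[idx]]
      rest[idx] <- TRUE
    }
    target[rest] <- 0.4 * cfg$rest_speed_cap
    # --- OU recursion via a linear filter ---
    a <- dt / cfg$ou_tau
    step_sd <- cfg$noise_sd * sqrt(1 - (1 - a)^2)
    noise_scale <- ifelse(rest, 0.25, 1)
    eps <- stats::rnorm(n, 0, step_sd) * noise_scale
    v <- as.numeric(stats::filter(a * target + eps, 1 - a,
                                  method = "recursive", init = target[1L]))
    # low-pass to give speed the smoothness of real center-of-mass tracks,
    # so accelerating/decelerating bouts last a behaviorally plausible
    # fraction of a second rather than flipping frame to frame
    if (cfg$speed_smooth_s > 0) {
      w <- max(1L, round(cfg$speed_smooth_s * fs))
      v <- as.numeric(zoo::rollmean(zoo::zoo(v), k = w, fill = "extend",
                                    align = "center"))
    }
    # --- transition excursion + BIL increment ---
    w_in <- round(0.6 * fs); w_out <- round(2 * fs)
    tt <- seq_len(n) * dt
    for (j in seq_along(trans_idx)) {
      k <- trans_idx[j]
      idx <- max(1L, k - w_out):min(n, k + w_out)
      v[idx] <- v[idx] + cfg$transition_peak_amp *
        exp(-0.5 * ((tt[idx] - tt[k]) / 0.5)^2)
      bil <- if (trans_dir[j] == "into_dark")
        (k - w_out):(k - w_in) else (k + w_in):(k + w_out)
      bil <- bil[bil >= 1L & bil <= n]
      v[bil] <- v[bil] + cfg$bil_increment
    }
    v <- pmax(v, 0)

    # --- positions on per-zone loops ---
    light_high <- identical(arena$light_side, "high_x")
    xr <- list(light = if (light_high) c(arena$divider_x, arena$width)
               else c(0, arena$divider_x),
               dark = if (light_high) c(0, arena$divider_x)
               else c(arena$divider_x, arena$width))
    loops <- lapply(xr, function(r)
      zone_loop(r[1L], r[2L], arena$depth,
                gate_high_x = (r[1L] < arena$divider_x)))
    x <- numeric(n); y <- numeric(n)
    pos <- 1L
    for (i in seq_along(res_frames)) {
      idx <- pos:(pos + res_frames[i] - 1L)
      lp <- loops[[res$zone[i]]]
      # displacement into frame i is v[i]*dt, matching compute_speed()
      u <- cumsum(c(0, v[idx[-1L]] * dt)) %% lp$perimeter
      x[idx] <- lp$fx(u); y[idx] <- lp$fy(u)
      pos <- pos + res_frames[i]
    }
    time <- (seq_len(n) - 1L) * dt
    tracking_series(time, x, y, zone = zone, speed = v, arena = arena,
                    info = list(transition_index = trans_idx,
                                transition_direction = trans_dir,
                                rest_mask = rest, cfg = cfg))
  })
}
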