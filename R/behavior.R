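# Behavioral segmentation: speed, acceleration states, zone transitions with
# BIL/BID windows, rest fractions, sustained speed, acceleration events, and
# the BIL-effect estimator.

#' Speed from tracked positions
#'
#' Frame-wise speed as the Euclidean displacement of the tracked point divided
#' by the frame interval, optionally boxcar-smoothed. The first frame
#' duplicates the second so the series has the same length as the input.
#'
#' @param x,y position coordinates (cm).
#' @param time timestamps (s), strictly increasing.
#' @param smoothing_window boxcar width in frames; 1 = no smoothing.
#' @return numeric speed series (cm/s), same length as `time`.
#' @export
compute_speed <- function(x, y, time, smoothing_window = 1L) {
  check_time(time)
  if (length(x) != length(time) || length(y) != length(time))
    stop_input("positions and time must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("positions must be finite")
  check_scalar(smoothing_window, "smoothing_window", lower = 1)
  v <- sqrt(diff(x)^2 + diff(y)^2) / diff(time)
  v <- c(v[1L], v)
  if (smoothing_window > 1L)
    v <- as.numeric(zoo::rollmean(zoo::zoo(v), k = as.integer(smoothing_window),
                                  fill = "extend", align = "center"))
  v
}

#' Acceleration from a speed series
#'
#' First difference of the (optionally boxcar-smoothed) speed divided by the
#' frame interval; first frame duplicated. Smoothing before differentiation
#' (default 5 frames) suppresses single-frame tracking jitter.
#'
#' @param speed speed series (cm/s).
#' @param time timestamps (s).
#' @param smoothing_window boxcar width in frames applied to speed before
#'   differencing.
#' @return acceleration series (cm/s^2), same length as input.
#' @export
compute_acceleration <- function(speed, time, smoothing_window = 5L) {
  check_time(time)
  if (length(speed) != length(time))
    stop_input("speed and time must have equal length")
  s <- speed
  if (smoothing_window > 1L)
    s <- as.numeric(zoo::rollmean(zoo::zoo(s), k = as.integer(smoothing_window),
                                  fill = "extend", align = "center"))
  a <- diff(s) / diff(time)
  c(a[1L], a)
}

#' Binarize acceleration into accelerating / decelerating / neither
#'
#' Frames with acceleration above `+thr` are labeled `accelerating`, below
#' `-thr` `decelerating`, and `neither` otherwise. The default threshold is
#' 0.4 cm/s^2.
#'
#' @inheritParams compute_acceleration
#' @param thr threshold (cm/s^2), must be positive.
#' @param acceleration optional precomputed acceleration series; when `NULL`
#'   it is derived from `speed` via [compute_acceleration()].
#' @return factor with levels `accelerating`, `decelerating`, `neither`.
#' @export
binarize_acceleration <- function(speed, time, thr = 0.4, smoothing_window = 5L,
                                  acceleration = NULL) {
  check_scalar(thr, "thr", lower = 0, strict_lower = TRUE)
  a <- if (is.null(acceleration))
    compute_acceleration(speed, time, smoothing_window) else acceleration
  state <- rep("neither", length(a))
  state[a > thr] <- "accelerating"
  state[a < -thr] <- "decelerating"
  factor(state, levels = c("accelerating", "decelerating", "neither"))
}

#' Construct a tracking session container
#'
#' Bundles time, positions, zone labels, speed and derived acceleration state
#' for one light/dark-box session. When `speed` is omitted it is recomputed
#' from positions; when `zone` is omitted it is derived from x against the
#' arena divider.
#'
#' @param time timestamps (s).
#' @param x,y positions (cm).
#' @param zone per-frame zone factor (`light`/`dark`), or `NULL`.
#' @param speed per-frame speed (cm/s), or `NULL` to compute from positions.
#' @param arena an [arena_config()], required when `zone` is `NULL`.
#' @param accel_thr acceleration binarization threshold (cm/s^2).
#' @param accel_smooth boxcar width (frames) for speed smoothing before
#'   differentiation.
#' @param info free-form provenance list (generator ground truth, counts).
#' @return object of class `tracking_series`.
#' @export
tracking_series <- function(time, x, y, zone = NULL, speed = NULL,
                            arena = NULL, accel_thr = 0.4, accel_smooth = 5L,
                            info = list()) {
  check_time(time)
  n <- length(time)
  if (length(x) != n || length(y) != n)
    stop_input("positions must match time length")
  if (is.null(zone)) {
    if (is.null(arena)) stop_input("`arena` required to derive zone labels")
    zone <- zone_from_position(x, arena)
  }
  zone <- factor(as.character(zone), levels = c("light", "dark"))
  if (anyNA(zone)) stop_input("zone must be 'light' or 'dark' for every frame")
  if (is.null(speed)) speed <- compute_speed(x, y, time)
  if (length(speed) != n) stop_input("speed must match time length")
  if (any(speed < 0)) stop_input("speed must be non-negative")
  accel <- compute_acceleration(speed, time, accel_smooth)
  state <- binarize_acceleration(speed, time, thr = accel_thr,
                                 acceleration = accel)
  structure(list(time = time, x = x, y = y, zone = zone, speed = speed,
                 acceleration = accel, accel_state = state,
                 frame_rate = 1 / stats::median(diff(time)),
                 arena = arena, info = info),
            class = "tracking_series")
}

#' @export
as.data.frame.tracking_series <- function(x, ...) {
  data.frame(time_s = x$time, x_cm = x$x, y_cm = x$y,
             zone = as.character(x$zone), speed = x$speed,
             acceleration = x$acceleration,
             accel_state = as.character(x$accel_state))
}

#' @export
print.tracking_series <- function(x, ...) {
  cat(sprintf("<tracking_series> %d frames, %.1f s @ %.1f Hz\n",
              length(x$time), diff(range(x$time)), x$frame_rate))
  occ <- prop.table(table(x$zone))
  cat(sprintf("  occupancy: light %.1f%%, dark %.1f%%; mean speed %.2f cm/s\n",
              100 * occ[["light"]], 100 * occ[["dark"]], mean(x$speed)))
  invisible(x)
}

#' Zone label from x-position and arena geometry
#' @param x x positions (cm).
#' @param arena an [arena_config()].
#' @return factor (`light`/`dark`).
#' @export
zone_from_position <- function(x, arena) {
  light_high <- identical(arena$light_side, "high_x")
  lab <- ifelse((x > arena$divider_x) == light_high, "light", "dark")
  factor(lab, levels = c("light", "dark"))
}

# Transitions -------------------------------------------------------------

#' Detect zone transitions and build BIL/BID windows
#'
#' A transition is scored at the first frame of a new zone residency. Zone
#' changes separated by less than `min_dwell` seconds are treated as boundary
#' jitter and merged (short residencies are folded into the preceding one).
#' Each event carries an approach window (`-2 s` to `-0.6 s`), a retreat
#' window (`+0.6 s` to `+2 s`), and complementary body-in-light (BIL) /
#' body-in-dark (BID) masks: pre-crossing frames of into-dark events and
#' post-crossing frames of into-light events are BIL. Events whose full
#' `+/- window_s` windows fall outside the session are dropped and counted.
#'
#' @param zone per-frame zone factor/character.
#' @param time timestamps (s).
#' @param window_s outer window half-width (s), default 2.
#' @param gap_s inner gap half-width excluded around the crossing (s),
#'   default 0.6.
#' @param min_dwell minimum residency duration (s) for debouncing; 0 disables.
#' @return list with `events` (data frame: `t0_index`, `t0_time`, `direction`
#'   plus list-columns `approach_idx`, `retreat_idx`, `bil_idx`, `bid_idx`)
#'   and `n_dropped_edge`.
#' @export
detect_transitions <- function(zone, time, window_s = 2, gap_s = 0.6,
                               min_dwell = 0.5) {
  check_time(time)
  zone <- as.character(zone)
  if (length(zone) != length(time)) stop_input("zone must match time length")
  if (anyNA(zone)) stop_input("zone must be defined for every frame")
  fs <- 1 / stats::median(diff(time))
  z <- debounce_zone(zone, fs, min_dwell)
  chg <- which(z[-1L] != z[-length(z)]) + 1L
  w_in <- round(gap_s * fs)
  w_out <- round(window_s * fs)
  n <- length(z)
  keep <- chg - w_out >= 1L & chg + w_out <= n
  dropped <- sum(!keep)
  chg <- chg[keep]
  ev <- lapply(chg, function(k) {
    dir <- if (z[k] == "light") "into_light" else "into_dark"
    app <- seq.int(k - w_out, k - w_in)
    ret <- seq.int(k + w_in, k + w_out)
    if (dir == "into_dark") {
      bil <- app; bid <- ret
    } else {
      bil <- ret; bid <- app
    }
    list(t0_index = k, t0_time = time[k], direction = dir,
         approach_idx = app, retreat_idx = ret, bil_idx = bil, bid_idx = bid)
  })
  events <- data.frame(
    t0_index = vapply(ev, `[[`, integer(1), "t0_index"),
    t0_time = vapply(ev, `[[`, numeric(1), "t0_time"),
    direction = vapply(ev, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  events$approach_idx <- lapply(ev, `[[`, "approach_idx")
  events$retreat_idx <- lapply(ev, `[[`, "retreat_idx")
  events$bil_idx <- lapply(ev, `[[`, "bil_idx")
  events$bid_idx <- lapply(ev, `[[`, "bid_idx")
  list(events = events, n_dropped_edge = dropped, zone_debounced = z)
}

# fold residencies shorter than min_dwell into the preceding zone
debounce_zone <- function(zone, fs, min_dwell) {
  if (min_dwell <= 0) return(zone)
  r <- rle(zone)
  min_len <- ceiling(min_dwell * fs)
  repeat {
    short <- which(r$lengths < min_len)
    short <- short[short > 1L]
    if (!length(short)) break
    k <- short[1L]
    r$values[k] <- r$values[k - 1L]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

# Summaries ---------------------------------------------------------------

#' Fraction of time at restful speeds, per zone
#'
#' Fraction of frames in each zone with speed at or below `cap`
#' (default 2 cm/s). An unvisited zone yields `NA`.
#'
#' @param speed speed series (cm/s).
#' @param zone per-frame zone labels.
#' @param cap rest speed cap (cm/s).
#' @return named numeric vector with elements `light` and `dark`.
#' @export
rest_fraction <- function(speed, zone, cap = 2) {
  check_scalar(cap, "cap", lower = 0)
  zone <- as.character(zone)
  vapply(c(light = "light", dark = "dark"), function(zl) {
    in_z <- zone == zl
    if (!any(in_z)) return(NA_real_)
    mean(speed[in_z] <= cap)
  }, numeric(1))
}

#' Maximum sustained speed
#'
#' The greatest speed held for at least `min_frames` consecutive frames:
#' the maximum over all `min_frames`-length windows of the window minimum.
#'
#' @param speed speed series (cm/s).
#' @param min_frames run length (frames), default 20 (2/3 s at 30 Hz).
#' @return scalar speed (cm/s).
#' @export
max_sustained_speed <- function(speed, min_frames = 20L) {
  check_scalar(min_frames, "min_frames", lower = 1)
  min_frames <- as.integer(min_frames)
  if (length(speed) < min_frames)
    stop_input("session shorter than min_frames")
  if (min_frames == 1L) return(max(speed))
  mins <- zoo::rollapply(zoo::zoo(speed), width = min_frames, FUN = min,
                         align = "left")
  max(as.numeric(mins))
}

#' Per-zone occupancy-normalized speed distribution
#'
#' @param speed speed series (cm/s).
#' @param zone per-frame zone labels.
#' @param bin_width histogram bin width (cm/s).
#' @return data frame with `zone`, `bin_lo`, `bin_hi`, `prob` (sums to 1
#'   within each visited zone).
#' @export
speed_histogram <- function(speed, zone, bin_width = 1) {
  check_scalar(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  zone <- as.character(zone)
  breaks <- seq(0, max(speed) + bin_width, by = bin_width)
  out <- lapply(c("light", "dark"), function(zl) {
    v <- speed[zone == zl]
    if (!length(v)) return(NULL)
    h <- hist(v, breaks = breaks, plot = FALSE)
    data.frame(zone = zl, bin_lo = h$breaks[-length(h$breaks)],
               bin_hi = h$breaks[-1L], prob = h$counts / length(v))
  })
  do.call(rbind, out)
}

# Acceleration events -----------------------------------------------------

#' Extract acceleration events
#'
#' An acceleration onset is a frame where the binarized acceleration state
#' enters `accelerating` from a non-accelerating frame. Each onset seeds a
#' `window_s`-second window centered on it; windows clipped by the session
#' edges or whose mean speed does not exceed `mean_speed_thr` are dropped.
#' A surviving event is labeled `transition_into_light`/`transition_into_dark`
#' if its center lies within `transition_halo_s` of a transition (nearest
#' transition decides), else `within_light`/`within_dark` by the zone at its
#' center.
#'
#' @param track a [tracking_series()].
#' @param transitions result of [detect_transitions()] (or `NULL` to detect).
#' @param window_s event window length (s), default 4.
#' @param mean_speed_thr minimum window-average speed (cm/s); 6 is the
#'   photometry default, 5 the single-cell imaging default.
#' @param transition_halo_s half-width (s) around a transition within which an
#'   event is labeled a transition event.
#' @return data frame with `center_index`, `center_time`, `mean_speed`,
#'   `context`, and a list-column `window_idx`.
#' @export
extract_acceleration_events <- function(track, transitions = NULL,
                                        window_s = 4, mean_speed_thr = 6,
                                        transition_halo_s = 2) {
  stopifnot(inherits(track, "tracking_series"))
  check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  check_scalar(mean_speed_thr, "mean_speed_thr", lower = 0)
  if (is.null(transitions))
    transitions <- detect_transitions(track$zone, track$time)
  fs <- track$frame_rate
  half <- round(window_s / 2 * fs)
  n <- length(track$time)
  onsets <- rising_edges(as.character(track$accel_state), "accelerating")
  onsets <- onsets[onsets - half >= 1L & onsets + half <= n]
  if (!length(onsets))
    return(empty_accel_events())
  windows <- lapply(onsets, function(k) seq.int(k - half, k + half))
  mean_speed <- vapply(windows, function(w) mean(track$speed[w]), numeric(1))
  keep <- mean_speed > mean_speed_thr
  onsets <- onsets[keep]; windows <- windows[keep]
  mean_speed <- mean_speed[keep]
  if (!length(onsets))
    return(empty_accel_events())
  tr <- transitions$events
  context <- vapply(seq_along(onsets), function(i) {
    tc <- track$time[onsets[i]]
    if (nrow(tr)) {
      d <- abs(tr$t0_time - tc)
      j <- which.min(d)
      if (d[j] <= transition_halo_s)
        return(paste0("transition_", tr$direction[j]))
    }
    paste0("within_", as.character(track$zone[onsets[i]]))
  }, character(1))
  out <- data.frame(center_index = onsets, center_time = track$time[onsets],
                    mean_speed = mean_speed, context = context,
                    stringsAsFactors = FALSE)
  out$window_idx <- windows
  out
}

empty_accel_events <- function() {
  out <- data.frame(center_index = integer(0), center_time = numeric(0),
                    mean_speed = numeric(0), context = character(0),
                    stringsAsFactors = FALSE)
  out$window_idx <- list()
  out
}

# BIL effect --------------------------------------------------------------

#' BIL effect: body-in-light minus body-in-dark signal at transitions
#'
#' Difference between the mean of `series` over BIL-masked frames and over
#' BID-masked frames within the chosen phase window (approach: -2 to -0.6 s;
#' retreat: +0.6 to +2 s), pooled over transitions. In the approach phase the
#' BIL frames come from into-dark events and the BID frames from into-light
#' events (and vice versa on retreat), so at least one transition of each
#' direction is required. The percentile-bootstrap confidence interval
#' resamples transitions (stratified by direction) as the unit.
#'
#' @param series per-frame signal aligned to the tracking timebase (speed in
#'   cm/s or delta-F/F).
#' @param transitions result of [detect_transitions()].
#' @param phase `"approach"`, `"retreat"`, or `"both"` (pools both windows).
#' @param n_boot bootstrap replicates (0 disables the CI).
#' @param conf confidence level.
#' @param seed seed for the bootstrap resampling.
#' @return list with `estimate`, `ci` (length-2 or `NULL`), `n_bil`, `n_bid`
#'   (transition counts contributing to each side), `phase`.
#' @export
bil_effect <- function(series, transitions, phase = c("approach", "retreat",
                                                      "both"),
                       n_boot = 1000L, conf = 0.95, seed = 1L) {
  phase <- match.arg(phase)
  ev <- transitions$events
  if (!nrow(ev) || length(unique(ev$direction)) < 2L)
    stop_input("BIL effect undefined: need >=1 transition in each direction")
  phase_idx <- function(i) {
    idx <- switch(phase,
                  approach = ev$approach_idx[[i]],
                  retreat = ev$retreat_idx[[i]],
                  both = c(ev$approach_idx[[i]], ev$retreat_idx[[i]]))
    idx
  }
  # per-transition mean of the series over its BIL (or BID) frames in-phase
  per_ev <- lapply(seq_len(nrow(ev)), function(i) {
    idx <- phase_idx(i)
    bil <- intersect(idx, ev$bil_idx[[i]])
    bid <- intersect(idx, ev$bid_idx[[i]])
    c(bil = if (length(bil)) mean(series[bil]) else NA_real_,
      bid = if (length(bid)) mean(series[bid]) else NA_real_)
  })
  bil_m <- vapply(per_ev, `[[`, numeric(1), "bil")
  bid_m <- vapply(per_ev, `[[`, numeric(1), "bid")
  est_from <- function(take) {
    mean(bil_m[take], na.rm = TRUE) - mean(bid_m[take], na.rm = TRUE)
  }
  all_idx <- seq_len(nrow(ev))
  estimate <- est_from(all_idx)
  ci <- NULL
  if (n_boot > 0) {
    by_dir <- split(all_idx, ev$direction)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(by_dir, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      est_from(take)
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  n_by_dir <- table(ev$direction)
  list(estimate = estimate, ci = ci,
       n_bil = sum(!is.na(bil_m)), n_bid = sum(!is.na(bid_m)),
       n_into_light = as.integer(n_by_dir[["into_light"]]),
       n_into_dark = as.integer(n_by_dir[["into_dark"]]),
       phase = phase)
}
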