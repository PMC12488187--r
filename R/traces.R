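# Calcium-signal conditioning and event detection: noise-floor thresholding
# with max-normalization (miniscope path), double-exponential photometry
# detrending, peak-based fluorescence event detection, timebase alignment,
# and zone-wise inter-event intervals.

#' Construct a calcium-traces container
#'
#' @param time timestamps (s).
#' @param dff neurons x frames matrix of delta-F/F (a single channel may be
#'   passed as a vector or 1-row matrix).
#' @param noise_floor per-neuron baseline noise SD; estimated with
#'   [estimate_noise_floor()] when omitted.
#' @param modality `"miniscope"` or `"photometry"`.
#' @param neuron_ids optional identifiers (default `n1`, `n2`, ...).
#' @param info free-form provenance list.
#' @return object of class `calcium_traces`.
#' @export
calcium_traces <- function(time, dff, noise_floor = NULL,
                           modality = c("miniscope", "photometry"),
                           neuron_ids = NULL, info = list()) {
  modality <- match.arg(modality)
  check_time(time)
  if (is.vector(dff)) dff <- matrix(dff, nrow = 1L)
  if (!is.matrix(dff) || ncol(dff) != length(time))
    stop_input("`dff` must be a neurons x frames matrix matching `time`")
  if (any(!is.finite(dff))) stop_input("`dff` must be finite")
  if (is.null(noise_floor))
    noise_floor <- apply(dff, 1L, estimate_noise_floor)
  if (length(noise_floor) != nrow(dff) || any(noise_floor <= 0))
    stop_input("`noise_floor` must be positive, one value per neuron")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(dff)))
  rownames(dff) <- neuron_ids
  structure(list(time = time, dff = dff, noise_floor = noise_floor,
                 modality = modality, neuron_ids = neuron_ids, info = info),
            class = "calcium_traces")
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf("<calcium_traces> %d neurons x %d frames (%s), %.1f s\n",
              nrow(x$dff), ncol(x$dff), x$modality, diff(range(x$time))))
  invisible(x)
}

#' Robust baseline-noise estimate for a trace
#'
#' `1.4826 x median(|first difference - median|) / sqrt(2)`: the MAD of the
#' first-differenced trace rescaled to the SD of the underlying white noise.
#' Differencing removes slow transients so the estimate is robust to real
#' calcium events.
#'
#' @param x numeric trace.
#' @return scalar noise SD estimate.
#' @export
estimate_noise_floor <- function(x) {
  d <- diff(x)
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

#' Condition delta-F/F traces
#'
#' Values below `3 x noise_floor` are set to zero, then each neuron is
#' divided by its maximum (max-normalization). Neurons that are zero
#' everywhere after thresholding are left at zero and flagged.
#'
#' @param traces a [calcium_traces()] (or bare matrix/vector).
#' @param noise_floor per-neuron noise SD; defaults to the container's (or is
#'   estimated for bare input).
#' @param k_noise threshold multiple of the noise floor.
#' @return a [calcium_traces()] with conditioned `dff` in `[0, 1]` and
#'   `info$silent` flagging all-zero neurons.
#' @export
condition_dff <- function(traces, noise_floor = NULL, k_noise = 3) {
  if (!inherits(traces, "calcium_traces")) {
    nf <- if (is.matrix(traces)) ncol(traces) else length(traces)
    traces <- calcium_traces(seq_len(nf) - 1, traces,
                             noise_floor = noise_floor)
  }
  if (is.null(noise_floor)) noise_floor <- traces$noise_floor
  dff <- traces$dff
  dff[dff < k_noise * noise_floor] <- 0
  mx <- apply(dff, 1L, max)
  silent <- mx <= 0
  dff[!silent, ] <- dff[!silent, , drop = FALSE] / mx[!silent]
  out <- traces
  out$dff <- dff
  # noise floor follows the trace onto the normalized scale, so conditioning
  # is idempotent: re-applying zeroes nothing new and divides by max = 1
  out$noise_floor <- ifelse(silent, noise_floor, noise_floor / pmax(mx, 1e-12))
  out$info$silent <- silent
  out$info$conditioned <- TRUE
  out
}

#' Flatten a photometry signal by double-exponential baseline subtraction
#'
#' Fits `a*exp(-t/tau1) + b*exp(-t/tau2) + c` by least squares (one
#' reweighting pass excluding frames whose residual exceeds 3 robust SDs, so
#' transients do not drag the baseline) and subtracts the fit. On
#' non-convergence it falls back to a single exponential plus constant and
#' records a warning. The per-channel delta-F/F is the residual divided by
#' the fitted baseline.
#'
#' @param signal demodulated signal channel (e.g., 465 nm band).
#' @param time timestamps (s).
#' @param control optional simultaneous control channel (e.g., 405 nm),
#'   flattened independently for artifact inspection.
#' @return list with `flattened` (residual), `dff` (residual / fitted
#'   baseline), `fit` (fitted baseline), `coefficients`, `control` (same
#'   fields or `NULL`), and `warnings` (character).
#' @export
detrend_photometry <- function(signal, time, control = NULL) {
  check_time(time)
  if (length(signal) != length(time))
    stop_input("signal and time must have equal length")
  fit_one <- function(yv) {
    warn <- character(0)
    fit <- fit_double_exp(yv, time)
    if (is.null(fit)) {
      warn <- "double-exponential fit failed; single exponential used"
      fit <- fit_single_exp(yv, time)
    }
    # reweighting pass: refit without strong-transient frames
    resid <- yv - fit$baseline
    s <- 1.4826 * stats::median(abs(resid - stats::median(resid)))
    keep <- if (s > 0) abs(resid - stats::median(resid)) <= 3 * s
    else rep(TRUE, length(yv))
    if (any(!keep) && sum(keep) > 10L) {
      refit <- fit_double_exp(yv[keep], time[keep])
      if (!is.null(refit)) {
        fit <- list(baseline = predict_dexp(refit$coef, time),
                    coef = refit$coef)
      }
    }
    flattened <- yv - fit$baseline
    list(flattened = flattened, dff = flattened / fit$baseline,
         fit = fit$baseline, coefficients = fit$coef, warnings = warn)
  }
  out <- fit_one(signal)
  out$control <- if (!is.null(control)) fit_one(control) else NULL
  out
}

predict_dexp <- function(cf, time) {
  cf[["a"]] * exp(-time / cf[["tau1"]]) +
    cf[["b"]] * exp(-time / cf[["tau2"]]) + cf[["c"]]
}

fit_double_exp <- function(yv, time) {
  span <- diff(range(time))
  amp <- yv[1L] - yv[length(yv)]
  start <- list(a = amp * 0.6, tau1 = span / 10,
                b = amp * 0.4, tau2 = span / 2, c = yv[length(yv)])
  fit <- tryCatch(
    minpack.lm::nlsLM(yv ~ a * exp(-time / tau1) + b * exp(-time / tau2) + c,
                      data = data.frame(yv = yv, time = time), start = start,
                      lower = c(-Inf, span * 1e-4, -Inf, span * 1e-4, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(baseline = predict_dexp(cf, time), coef = cf)
}

fit_single_exp <- function(yv, time) {
  span <- diff(range(time))
  start <- list(a = yv[1L] - yv[length(yv)], tau1 = span / 5,
                c = yv[length(yv)])
  fit <- tryCatch(
    minpack.lm::nlsLM(yv ~ a * exp(-time / tau1) + c,
                      data = data.frame(yv = yv, time = time), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(a = 0, tau1 = 1, b = 0, tau2 = 1, c = mean(yv))
    return(list(baseline = rep(mean(yv), length(yv)), coef = cf))
  }
  cf0 <- stats::coef(fit)
  cf <- c(a = unname(cf0[["a"]]), tau1 = unname(cf0[["tau1"]]),
          b = 0, tau2 = 1, c = unname(cf0[["c"]]))
  list(baseline = predict_dexp(cf, time), coef = cf)
}

#' Detect fluorescence events as thresholded, refractory peaks
#'
#' Local maxima exceeding `mean + k_sd x SD` of the full trace, greedily
#' thinned so no two retained peaks are closer than `min_separation` (the
#' higher peak wins; on equal height the earlier peak wins).
#'
#' @param x conditioned (flattened, normalized) trace.
#' @param time timestamps (s).
#' @param min_separation refractory separation (s), default 1.
#' @param k_sd threshold in SDs above the mean, default 1.5.
#' @return list of class `event_series` with `times`, `indices`, `heights`,
#'   `intervals` (successive differences), and the detection parameters.
#' @export
detect_events <- function(x, time, min_separation = 1, k_sd = 1.5) {
  check_time(time)
  if (length(x) != length(time)) stop_input("x and time must match")
  check_scalar(min_separation, "min_separation", lower = 0)
  thr <- mean(x) + k_sd * stats::sd(x)
  n <- length(x)
  # local maxima: strictly above previous, at least as high as next
  # (plateaus keep their first frame)
  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1L], -Inf) & x > thr)
  if (length(cand)) {
    ord <- cand[order(-x[cand], cand)]   # height desc, then earlier
    kept <- integer(0)
    for (k in ord) {
      if (!length(kept) || all(abs(time[k] - time[kept]) >= min_separation))
        kept <- c(kept, k)
    }
    kept <- sort(kept)
  } else kept <- integer(0)
  structure(list(times = time[kept], indices = kept, heights = x[kept],
                 intervals = diff(time[kept]), threshold = thr,
                 min_separation = min_separation, k_sd = k_sd),
            class = "event_series")
}

#' Resample traces onto a behavior timebase
#'
#' Linear interpolation of each neuron's delta-F/F onto the tracking
#' timestamps; frames outside the overlap of the two timebases are dropped.
#'
#' @param traces a [calcium_traces()].
#' @param track a [tracking_series()] (or a numeric vector of target times).
#' @return list with `traces` (resampled [calcium_traces()]), `track_idx`
#'   (indices of the tracking frames retained), and an `alignment` report.
#' @export
align_traces <- function(traces, track) {
  t_to <- if (inherits(track, "tracking_series")) track$time else track
  t_from <- traces$time
  lo <- max(min(t_from), min(t_to)); hi <- min(max(t_from), max(t_to))
  if (lo >= hi) stop_input("trace and tracking timebases do not overlap")
  keep <- which(t_to >= lo & t_to <= hi)
  new_dff <- t(apply(traces$dff, 1L, function(yy)
    stats::approx(t_from, yy, xout = t_to[keep])$y))
  if (nrow(traces$dff) == 1L) new_dff <- matrix(new_dff, nrow = 1L)
  out <- traces
  out$time <- t_to[keep]
  out$dff <- new_dff
  list(traces = out, track_idx = keep,
       alignment = list(overlap_s = hi - lo,
                        n_dropped_track = length(t_to) - length(keep),
                        identical_timebase = isTRUE(all.equal(t_from, t_to))))
}

#' Mean inter-event interval per zone
#'
#' Each interval between successive events is assigned to the zone occupied
#' at the earlier event, provided both events fall in the same zone;
#' cross-zone pairs are dropped and counted. A zone needs at least one
#' within-zone pair to yield a value.
#'
#' @param events an `event_series` from [detect_events()].
#' @param zone per-frame zone labels on the tracking timebase.
#' @param time tracking timestamps (s).
#' @return list with `mean_interval` (named: light, dark), `n_pairs` (named),
#'   and `n_cross_zone_dropped`.
#' @export
interevent_interval_by_zone <- function(events, zone, time) {
  zone <- as.character(zone)
  if (length(events$times) < 2L)
    return(list(mean_interval = c(light = NA_real_, dark = NA_real_),
                n_pairs = c(light = 0L, dark = 0L), n_cross_zone_dropped = 0L))
  ez <- zone[vapply(events$times, function(tt) which.min(abs(time - tt)),
                    integer(1))]
  first <- ez[-length(ez)]; second <- ez[-1L]
  same <- first == second
  iv <- diff(events$times)
  res <- vapply(c(light = "light", dark = "dark"), function(zl) {
    sel <- same & first == zl
    if (!any(sel)) NA_real_ else mean(iv[sel])
  }, numeric(1))
  npair <- vapply(c(light = "light", dark = "dark"), function(zl)
    sum(same & first == zl), integer(1))
  list(mean_interval = res, n_pairs = npair,
       n_cross_zone_dropped = sum(!same))
}
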