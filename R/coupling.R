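# Signal-behavior coupling within acceleration events: lagged, normalized
# cross-correlation with a best-lag significance test, per-animal summaries
# over significant events, and transition-triggered averages.

#' Lagged cross-correlation within one acceleration event
#'
#' Both windows are centered and scaled, then the Pearson correlation of the
#' overlapping segments is computed at every integer-frame lag in
#' `[-max_lag, +max_lag]`. The reported `r_best` is the value of largest
#' magnitude (ties broken toward the smallest `|lag|`, then the negative
#' lag); a positive `lag_best` means the signal lags the behavior. The
#' p-value is the Pearson test at the best lag with effective dof = window
#' frames - 2; lag selection inflates this nominal level, so a circular-shift
#' permutation p-value is available via `p_method = "permutation"`.
#'
#' @param dff_window delta-F/F over one event window.
#' @param behavior_window speed or acceleration over the same frames.
#' @param dt frame interval (s).
#' @param max_lag maximum lag magnitude (s), default 1.
#' @param alpha significance level.
#' @param p_method `"pearson"` (analytic, at the best lag) or
#'   `"permutation"` (circular shifts of the signal window).
#' @param n_perm permutation count.
#' @param seed seed for the permutation draw.
#' @return list of class `event_correlation`: `r_best`, `lag_best` (s),
#'   `lag_frames`, `p_value`, `significant`, `r_by_lag` (named vector),
#'   `flag`.
#' @export
event_crosscorr <- function(dff_window, behavior_window, dt, max_lag = 1,
                            alpha = 0.05,
                            p_method = c("pearson", "permutation"),
                            n_perm = 1000L, seed = 1L) {
  p_method <- match.arg(p_method)
  n <- length(dff_window)
  if (length(behavior_window) != n)
    stop_input("event windows must have equal length")
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  max_k <- round(max_lag / dt)
  degenerate <- stats::sd(dff_window) == 0 || stats::sd(behavior_window) == 0
  if (degenerate)
    return(structure(list(r_best = NA_real_, lag_best = NA_real_,
                          lag_frames = NA_integer_, p_value = NA_real_,
                          significant = FALSE, r_by_lag = NULL,
                          flag = "degenerate"),
                     class = "event_correlation"))
  lags <- seq.int(-max_k, max_k)
  r_by_lag <- vapply(lags, function(k) lagged_cor(dff_window,
                                                  behavior_window, k),
                     numeric(1))
  names(r_by_lag) <- lags
  # best = largest |r|; ties -> smallest |lag|, then negative lag
  ord <- order(-abs(r_by_lag), abs(lags), lags)
  best <- ord[1L]
  r_best <- unname(r_by_lag[best])
  k_best <- lags[best]
  p <- if (p_method == "pearson") {
    df <- n - 2L
    tt <- r_best * sqrt(df / max(1e-12, 1 - r_best^2))
    2 * stats::pt(-abs(tt), df)
  } else {
    with_seed(seed, {
      null_r <- vapply(seq_len(n_perm), function(b) {
        s <- sample.int(n - 1L, 1L)
        shifted <- c(dff_window[(s + 1L):n], dff_window[seq_len(s)])
        rl <- vapply(lags, function(k) lagged_cor(shifted, behavior_window,
                                                  k), numeric(1))
        max(abs(rl))
      }, numeric(1))
      (1 + sum(null_r >= abs(r_best))) / (n_perm + 1)
    })
  }
  structure(list(r_best = r_best, lag_best = k_best * dt,
                 lag_frames = k_best, p_value = p,
                 significant = is.finite(p) && p < alpha,
                 r_by_lag = r_by_lag, flag = NA_character_),
            class = "event_correlation")
}

# correlation of overlapping segments with the signal delayed by k frames
lagged_cor <- function(sig, beh, k) {
  n <- length(sig)
  if (k >= 0) {
    a <- sig[(1L + k):n]; b <- beh[1L:(n - k)]
  } else {
    a <- sig[1L:(n + k)]; b <- beh[(1L - k):n]
  }
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(0)
  stats::cor(a, b)
}

#' Cross-correlate a signal with speed and acceleration over all events
#'
#' Convenience wrapper running [event_crosscorr()] for every extracted
#' acceleration event against both behavioral targets.
#'
#' @param signal per-frame signal on the tracking timebase.
#' @param track a [tracking_series()].
#' @param events acceleration events from [extract_acceleration_events()].
#' @param targets behavioral targets to correlate against.
#' @param ... passed to [event_crosscorr()].
#' @return data frame: `event_id`, `context`, `target`, `r_best`, `lag_best`,
#'   `p_value`, `significant`.
#' @export
correlate_events <- function(signal, track, events,
                             targets = c("speed", "acceleration"), ...) {
  dt <- 1 / track$frame_rate
  rows <- list()
  for (target in targets) {
    beh <- if (target == "speed") track$speed else track$acceleration
    for (i in seq_len(nrow(events))) {
      w <- events$window_idx[[i]]
      ec <- event_crosscorr(signal[w], beh[w], dt, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(event_id = i, context = events$context[i],
                   target = target, r_best = ec$r_best,
                   lag_best = ec$lag_best, p_value = ec$p_value,
                   significant = ec$significant, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(event_id = integer(0), context = character(0),
                      target = character(0), r_best = numeric(0),
                      lag_best = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  do.call(rbind, rows)
}

#' Per-animal coupling summary
#'
#' Arithmetic means of `r_best` and `lag_best` over significant events only,
#' per context x target, with the significant-event count. Means are `NA`
#' when no event in a cell is significant.
#'
#' @param event_correlations data frame from [correlate_events()].
#' @param animal_id identifier recorded in the output.
#' @return data frame: `animal_id`, `context`, `target`, `mean_r`,
#'   `mean_lag`, `n_significant`, `n_events`.
#' @export
summarize_coupling <- function(event_correlations, animal_id = "animal1") {
  contexts <- c("within_light", "within_dark", "transition_into_light",
                "transition_into_dark")
  targets <- unique(event_correlations$target)
  if (!length(targets)) targets <- c("speed", "acceleration")
  grid <- expand.grid(context = contexts, target = targets,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- event_correlations$context == grid$context[g] &
      event_correlations$target == grid$target[g]
    sig <- sel & event_correlations$significant %in% TRUE
    data.frame(animal_id = animal_id, context = grid$context[g],
               target = grid$target[g],
               mean_r = if (any(sig)) mean(event_correlations$r_best[sig])
               else NA_real_,
               mean_lag = if (any(sig)) mean(event_correlations$lag_best[sig])
               else NA_real_,
               n_significant = sum(sig), n_events = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level bootstrap CI over animals
#'
#' Percentile bootstrap of the across-animal mean of a per-animal summary
#' column (e.g., `mean_r`), resampling animals as the unit.
#'
#' @param values per-animal values (NA dropped).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed seed for the resampling.
#' @return list with `mean`, `ci`, `n_animals`.
#' @export
group_bootstrap_ci <- function(values, n_boot = 2000L, conf = 0.95,
                               seed = 1L) {
  values <- values[is.finite(values)]
  if (!length(values))
    return(list(mean = NA_real_, ci = c(NA_real_, NA_real_), n_animals = 0L))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(sample(values, length(values), replace = TRUE)), numeric(1)))
  a <- (1 - conf) / 2
  list(mean = mean(values),
       ci = unname(stats::quantile(boots, c(a, 1 - a))),
       n_animals = length(values))
}

#' Transition-triggered average of a signal with speed overlay
#'
#' The signal is z-scored over the session and averaged across transitions
#' separately for each direction over `[-window_s, +window_s]`; the paired
#' speed average is computed on the same base.
#'
#' @param signal per-frame signal on the tracking timebase.
#' @param track a [tracking_series()].
#' @param transitions result of [detect_transitions()].
#' @param window_s half-width of the triggered window (s).
#' @return data frame: `direction`, `lag_s`, `mean_z`, `sem_z`,
#'   `mean_speed`, `n`.
#' @export
transition_triggered_average <- function(signal, track, transitions,
                                         window_s = 2) {
  ev <- transitions$events
  if (!nrow(ev)) stop_input("no transitions to trigger on")
  fs <- track$frame_rate
  half <- round(window_s * fs)
  mu <- mean(signal); sdv <- stats::sd(signal)
  z <- if (sdv > 0) (signal - mu) / sdv else signal - mu
  n <- length(signal)
  offs <- seq.int(-half, half)
  out <- lapply(c("into_light", "into_dark"), function(dir) {
    ks <- ev$t0_index[ev$direction == dir]
    ks <- ks[ks - half >= 1L & ks + half <= n]
    if (!length(ks)) return(NULL)
    zm <- vapply(ks, function(k) z[k + offs], numeric(length(offs)))
    sm <- vapply(ks, function(k) track$speed[k + offs],
                 numeric(length(offs)))
    zm <- matrix(zm, nrow = length(offs)); sm <- matrix(sm,
                                                        nrow = length(offs))
    data.frame(direction = dir, lag_s = offs / fs,
               mean_z = rowMeans(zm),
               sem_z = apply(zm, 1L, stats::sd) / sqrt(ncol(zm)),
               mean_speed = rowMeans(sm), n = ncol(zm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
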