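# Per-neuron tuning classification: zone preference (rank test, Bonferroni
# over neurons), speed class (Spearman with quadratic fallback),
# acceleration/deceleration preference index (rank-based auROC), the
# deceleration-prediction flag, transition activity/selectivity, and
# contingency tests between label categories.

#' Zone preference of one neuron
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing frame-wise
#' delta-F/F in the light versus dark zone. The neuron is light-preferring if
#' the test is significant at `alpha / n_neurons` (Bonferroni over the
#' session's identified neurons) with greater light-zone activity; dark is
#' symmetric; otherwise `none`. Frame-wise samples are serially dependent, so
#' a block-decimation factor (`decimate`, keep every k-th frame) is offered
#' for conservative inference.
#'
#' @param dff one neuron's delta-F/F series.
#' @param zone per-frame zone labels.
#' @param n_neurons Bonferroni denominator (identified neurons in the
#'   animal).
#' @param alpha family-wise level before correction.
#' @param decimate keep every `decimate`-th frame (1 = all).
#' @param min_frames minimum frames required in each zone (after
#'   decimation).
#' @return list with `zone_pref` (`"light"`, `"dark"`, `"none"`), `p_value`,
#'   and `flag` (`NA` or `"insufficient_data"`).
#' @export
classify_zone_preference <- function(dff, zone, n_neurons, alpha = 0.05,
                                     decimate = 1L, min_frames = 10L) {
  check_scalar(n_neurons, "n_neurons", lower = 1)
  idx <- decimate_idx(length(dff), decimate)
  x <- dff[idx]; z <- as.character(zone)[idx]
  xl <- x[z == "light"]; xd <- x[z == "dark"]
  if (length(xl) < min_frames || length(xd) < min_frames)
    return(list(zone_pref = "none", p_value = NA_real_,
                flag = "insufficient_data"))
  wt <- suppressWarnings(stats::wilcox.test(xl, xd, exact = FALSE))
  pref <- "none"
  if (is.finite(wt$p.value) && wt$p.value < alpha / n_neurons) {
    r <- rank(c(xl, xd))
    light_higher <- mean(r[seq_along(xl)]) > mean(r[-seq_along(xl)])
    pref <- if (light_higher) "light" else "dark"
  }
  list(zone_pref = pref, p_value = wt$p.value, flag = NA_character_)
}

#' Speed tuning of one neuron
#'
#' Spearman rank correlation between delta-F/F and speed first: if
#' significant at `alpha / n_neurons`, the neuron is `L+` (rho > 0) or `L-`
#' (rho < 0). Otherwise the activity-speed relation is fitted with a
#' quadratic `a*x^2 + b*x + c`; if the goodness of fit (R-squared on the
#' frame-wise data) exceeds `fit_threshold` the neuron is `Q+` (a > 0) or
#' `Q-` (a < 0), else `none`. The Spearman branch always takes precedence.
#'
#' @inheritParams classify_zone_preference
#' @param speed per-frame speed (cm/s).
#' @param fit_threshold minimum quadratic R-squared (default 0.3).
#' @return list with `speed_class` (`"L+"`, `"L-"`, `"Q+"`, `"Q-"`,
#'   `"none"`), `rho`, `p_value`, `quad_coeffs` (a, b, c),
#'   `fit_quality`, and `flag`.
#' @export
classify_speed_tuning <- function(dff, speed, n_neurons, alpha = 0.05,
                                  decimate = 1L, fit_threshold = 0.3) {
  check_scalar(n_neurons, "n_neurons", lower = 1)
  idx <- decimate_idx(length(dff), decimate)
  x <- dff[idx]; v <- speed[idx]
  out <- list(speed_class = "none", rho = NA_real_, p_value = NA_real_,
              quad_coeffs = c(a = NA_real_, b = NA_real_, c = NA_real_),
              fit_quality = NA_real_, flag = NA_character_)
  if (stats::sd(v) == 0 || stats::sd(x) == 0) {
    out$flag <- "degenerate"
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(x, v, method = "spearman",
                                         exact = FALSE))
  out$rho <- unname(ct$estimate)
  out$p_value <- ct$p.value
  if (is.finite(ct$p.value) && ct$p.value < alpha / n_neurons) {
    out$speed_class <- if (out$rho > 0) "L+" else "L-"
    return(out)
  }
  fit <- stats::lm(x ~ v + I(v^2))
  cf <- stats::coef(fit)
  out$quad_coeffs <- c(a = unname(cf[["I(v^2)"]]), b = unname(cf[["v"]]),
                       c = unname(cf[["(Intercept)"]]))
  out$fit_quality <- summary(fit)$r.squared
  if (is.finite(out$fit_quality) && out$fit_quality > fit_threshold &&
      out$quad_coeffs[["a"]] != 0)
    out$speed_class <- if (out$quad_coeffs[["a"]] > 0) "Q+" else "Q-"
  out
}

#' Acceleration/deceleration preference index (ADI)
#'
#' Rank-based area under the ROC curve discriminating acceleration-frame
#' activity (positive class) from deceleration-frame activity, ties counted
#' half, rescaled to `adi = (auROC - 0.5) * 2`. `adi = +1` means activity
#' uniformly higher during acceleration, `-1` uniformly higher during
#' deceleration. Frames labeled `neither` are excluded.
#'
#' @param dff one neuron's delta-F/F series.
#' @param accel_state per-frame factor from [binarize_acceleration()].
#' @return scalar in `[-1, 1]`, or `NA` (with attribute `flag`) when either
#'   state is absent.
#' @export
compute_adi <- function(dff, accel_state) {
  st <- as.character(accel_state)
  acc <- dff[st == "accelerating"]
  dec <- dff[st == "decelerating"]
  if (!length(acc) || !length(dec))
    return(structure(NA_real_, flag = "empty_class"))
  n1 <- length(acc); n2 <- length(dec)
  r <- rank(c(acc, dec))
  auroc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  (auroc - 0.5) * 2
}

#' Deceleration-prediction flag
#'
#' A neuron is deceleration-predicting (DP) when `|adi|` strictly exceeds the
#' threshold (default 0.8).
#'
#' @param adi ADI value(s) from [compute_adi()].
#' @param dp_threshold strict threshold on `|adi|`.
#' @return logical (NA where `adi` is missing).
#' @export
classify_dp <- function(adi, dp_threshold = 0.8) {
  check_scalar(dp_threshold, "dp_threshold", lower = 0)
  ifelse(is.na(adi), NA, abs(adi) > dp_threshold)
}

#' Transition activity and BIL/BID selectivity of one neuron
#'
#' The neuron is transition-active if its delta-F/F exceeds
#' `activity_threshold` (default 0.0238, normalized units) at any frame
#' within `window_s` (default 2 s) of any zone crossing. Selectivity
#' considers super-threshold frames within the masked approach/retreat
#' windows only: `BIL_selective` if they occur exclusively on BIL frames,
#' `BID_selective` symmetric, `nonselective` if both, `inactive` if the
#' neuron is not transition-active.
#'
#' @param dff one neuron's conditioned delta-F/F series (tracking timebase).
#' @param transitions result of [detect_transitions()].
#' @param time tracking timestamps (s).
#' @param activity_threshold activity threshold (normalized delta-F/F).
#' @param window_s half-width of the activity window (s).
#' @return list with `transition_active`, `transition_selectivity`, `flag`.
#' @export
classify_transition_active <- function(dff, transitions, time,
                                       activity_threshold = 0.0238,
                                       window_s = 2) {
  ev <- transitions$events
  if (!nrow(ev))
    return(list(transition_active = NA, transition_selectivity = NA_character_,
                flag = "no_transitions"))
  fs <- 1 / stats::median(diff(time))
  half <- round(window_s * fs)
  n <- length(dff)
  win <- unique(unlist(lapply(ev$t0_index, function(k)
    max(1L, k - half):min(n, k + half))))
  active <- any(dff[win] > activity_threshold)
  if (!active)
    return(list(transition_active = FALSE,
                transition_selectivity = "inactive", flag = NA_character_))
  bil_idx <- unique(unlist(ev$bil_idx))
  bid_idx <- unique(unlist(ev$bid_idx))
  hit_bil <- any(dff[bil_idx] > activity_threshold)
  hit_bid <- any(dff[bid_idx] > activity_threshold)
  sel <- if (hit_bil && !hit_bid) "BIL_selective"
  else if (hit_bid && !hit_bil) "BID_selective"
  else if (hit_bil && hit_bid) "nonselective"
  else "nonselective"   # active only in the +/-0.6 s gap
  list(transition_active = TRUE, transition_selectivity = sel,
       flag = NA_character_)
}

#' Classify every neuron of a session
#'
#' Runs the full cascade — zone preference, speed class, ADI + DP flag,
#' transition activity/selectivity — on each row of a (conditioned)
#' [calcium_traces()] aligned to a [tracking_series()].
#'
#' @param traces a [calcium_traces()] on the tracking timebase (condition
#'   with [condition_dff()] first; done here when not already conditioned).
#' @param track a [tracking_series()].
#' @param transitions optional precomputed [detect_transitions()] result.
#' @param alpha per-test level before Bonferroni correction.
#' @param decimate block-decimation factor for the zone and speed tests.
#' @param dp_threshold DP threshold on `|ADI|`.
#' @param activity_threshold transition-activity threshold.
#' @param fit_threshold quadratic R-squared acceptance threshold.
#' @return data frame (one row per neuron): `neuron_id`, `zone_pref`,
#'   `speed_class`, `rho`, `a`, `b`, `c`, `fit_quality`, `adi`, `is_dp`,
#'   `transition_active`, `transition_selectivity`.
#' @export
classify_neurons <- function(traces, track, transitions = NULL, alpha = 0.05,
                             decimate = 30L, dp_threshold = 0.8,
                             activity_threshold = 0.0238,
                             fit_threshold = 0.3) {
  stopifnot(inherits(traces, "calcium_traces"),
            inherits(track, "tracking_series"))
  if (!isTRUE(traces$info$conditioned)) traces <- condition_dff(traces)
  if (!isTRUE(all.equal(traces$time, track$time)))
    stop_input("traces must be aligned to the tracking timebase; see align_traces()")
  if (is.null(transitions))
    transitions <- detect_transitions(track$zone, track$time)
  n_neurons <- nrow(traces$dff)
  rows <- lapply(seq_len(n_neurons), function(i) {
    x <- traces$dff[i, ]
    zp <- classify_zone_preference(x, track$zone, n_neurons, alpha, decimate)
    sp <- classify_speed_tuning(x, track$speed, n_neurons, alpha, decimate,
                                fit_threshold)
    adi <- compute_adi(x, track$accel_state)
    ta <- classify_transition_active(x, transitions, track$time,
                                     activity_threshold)
    data.frame(neuron_id = traces$neuron_ids[i], zone_pref = zp$zone_pref,
               speed_class = sp$speed_class, rho = sp$rho,
               a = sp$quad_coeffs[["a"]], b = sp$quad_coeffs[["b"]],
               c = sp$quad_coeffs[["c"]], fit_quality = sp$fit_quality,
               adi = as.numeric(adi),
               is_dp = classify_dp(as.numeric(adi), dp_threshold),
               transition_active = ta$transition_active,
               transition_selectivity = ta$transition_selectivity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Contingency test between two label categories
#'
#' Pearson chi-square without continuity correction on the contingency table
#' of two categorical label fields; Fisher's exact test is substituted when
#' any expected cell of a 2x2 table is below 5.
#'
#' @param labels data frame of neuron labels (from [classify_neurons()]).
#' @param factor_a,factor_b column names of the two categorical fields.
#' @return list with `table`, `statistic` (NA for Fisher), `dof`, `p_value`,
#'   `method`.
#' @export
category_contingency <- function(labels, factor_a, factor_b) {
  a <- as.character(labels[[factor_a]])
  b <- as.character(labels[[factor_b]])
  tab <- table(a, b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2L || ncol(tab) < 2L) {
    empt <- c(rownames(tab)[rowSums(tab) == 0],
              colnames(tab)[colSums(tab) == 0])
    stop_input("degenerate contingency table%s",
               if (length(empt)) paste0(": empty level ",
                                        paste(empt, collapse = ", "))
               else ": needs >=2 levels per factor")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == 2L) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(table = tab, statistic = NA_real_, dof = NA_integer_,
                p_value = ft$p.value, method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       dof = unname(ct$parameter), p_value = ct$p.value,
       method = "chisq")
}
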