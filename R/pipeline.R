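# End-to-end orchestration: validated configuration with recorded defaults,
# the behavior -> traces -> tuning -> coupling pipeline, and population
# category fractions.

pipeline_defaults <- list(
  rest_cap = 2,              # cm/s, restful speed cap
  accel_thr = 0.4,           # cm/s^2, acceleration binarization
  accel_smooth = 5L,         # frames of boxcar before differentiation
  mean_speed_thr_miniscope = 5,   # cm/s, acceleration-event filter (imaging)
  mean_speed_thr_photometry = 6,  # cm/s, acceleration-event filter
  dp_threshold = 0.8,        # |ADI| for the DP flag
  activity_threshold = 0.0238,    # normalized dF/F, transition activity
  k_sd = 1.5,                # event detection threshold (SDs)
  min_separation = 1,        # s, event refractory separation
  fit_threshold = 0.3,       # quadratic R^2 acceptance
  alpha = 0.05,              # per-test level before Bonferroni
  decimate = 30L,            # block decimation for frame-wise inference
  window_s = 2,              # s, transition window half-width
  gap_s = 0.6,               # s, excluded gap around crossings
  accel_window_s = 4,        # s, acceleration-event window
  max_lag = 1,               # s, cross-correlation lag bound
  min_dwell = 0.5,           # s, zone debounce
  min_sustained_frames = 20L # frames, max sustained speed
)

#' Pipeline configuration
#'
#' Validated threshold/window set for [run_pipeline()]. Every parameter has
#' its standard default recorded beside any override in the returned object.
#'
#' @param modality `"miniscope"` or `"photometry"` (selects the
#'   acceleration-event mean-speed default: 5 vs 6 cm/s).
#' @param seed seed for all randomized steps (bootstraps).
#' @param ... overrides of named defaults (see `patchpace:::pipeline_defaults`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(modality = c("miniscope", "photometry"),
                            seed = 1L, ...) {
  modality <- match.arg(modality)
  over <- list(...)
  bad <- setdiff(names(over), names(pipeline_defaults))
  if (length(bad))
    stop_input("unknown pipeline parameter(s): %s", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults, over)
  cfg$mean_speed_thr <- if (modality == "miniscope")
    cfg$mean_speed_thr_miniscope else cfg$mean_speed_thr_photometry
  for (nm in setdiff(names(cfg), c("modality")))
    check_scalar(cfg[[nm]], nm)
  cfg$modality <- modality
  cfg$seed <- seed
  cfg$defaults <- pipeline_defaults
  cfg$overrides <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on one session
#'
#' Behavior segmentation (transitions, rest fractions, sustained speed,
#' acceleration events), trace conditioning, per-neuron tuning
#' classification, aggregate-fluorescence coupling (event cross-correlations
#' and transition-triggered average), BIL effects on speed and fluorescence,
#' fluorescence event detection with zone-wise inter-event intervals, and
#' category tables. Deterministic given config and inputs.
#'
#' @param track a [tracking_series()].
#' @param traces a [calcium_traces()] (raw; conditioned internally), or
#'   `NULL` for behavior-only analysis.
#' @param config a [pipeline_config()].
#' @param animal_id identifier used in summaries.
#' @return list of class `pipeline_result` with elements `behavior`,
#'   `labels`, `category_fractions`, `coupling`, `bil`, `events`,
#'   `manifest`.
#' @export
run_pipeline <- function(track, traces = NULL, config = pipeline_config(),
                         animal_id = "animal1") {
  stopifnot(inherits(track, "tracking_series"),
            inherits(config, "pipeline_config"))
  transitions <- detect_transitions(track$zone, track$time,
                                    window_s = config$window_s,
                                    gap_s = config$gap_s,
                                    min_dwell = config$min_dwell)
  accel_events <- extract_acceleration_events(
    track, transitions, window_s = config$accel_window_s,
    mean_speed_thr = config$mean_speed_thr)
  behavior <- list(
    n_transitions = nrow(transitions$events),
    n_transitions_dropped_edge = transitions$n_dropped_edge,
    rest_fraction = rest_fraction(track$speed, track$zone, config$rest_cap),
    max_sustained_speed = max_sustained_speed(
      track$speed, config$min_sustained_frames),
    occupancy = prop.table(table(track$zone)),
    speed_histogram = speed_histogram(track$speed, track$zone),
    n_accel_events = nrow(accel_events))
  bil <- list(speed = tryCatch(
    bil_effect(track$speed, transitions, phase = "both",
               seed = config$seed),
    error = function(e) list(estimate = NA_real_, error = conditionMessage(e))))
  labels <- NULL; fractions <- NULL; coupling <- NULL; events_out <- NULL
  if (!is.null(traces)) {
    cond <- condition_dff(traces)
    if (!isTRUE(all.equal(cond$time, track$time)))
      cond <- align_traces(cond, track)$traces
    labels <- classify_neurons(cond, track, transitions,
                               alpha = config$alpha,
                               decimate = config$decimate,
                               dp_threshold = config$dp_threshold,
                               activity_threshold = config$activity_threshold,
                               fit_threshold = config$fit_threshold)
    fractions <- category_fractions(labels)
    # aggregate fluorescence for coupling and event-frequency analyses
    agg <- colMeans(cond$dff)
    ec <- correlate_events(agg, track, accel_events,
                           max_lag = config$max_lag)
    coupling <- list(
      events = ec,
      summary = summarize_coupling(ec, animal_id),
      triggered = if (nrow(transitions$events))
        transition_triggered_average(agg, track, transitions,
                                     config$window_s) else NULL)
    bil$dff <- tryCatch(
      bil_effect(agg, transitions, phase = "both", seed = config$seed),
      error = function(e) list(estimate = NA_real_,
                               error = conditionMessage(e)))
    ev <- detect_events(agg, track$time,
                        min_separation = config$min_separation,
                        k_sd = config$k_sd)
    events_out <- list(
      aggregate = ev,
      interval_by_zone = interevent_interval_by_zone(ev, track$zone,
                                                     track$time))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("patchpace")),
    config = unclass(config), animal_id = animal_id,
    n_frames = length(track$time), n_neurons = if (is.null(traces)) 0L
    else nrow(traces$dff))
  structure(list(behavior = behavior, transitions = transitions,
                 accel_events = accel_events, labels = labels,
                 category_fractions = fractions, coupling = coupling,
                 bil = bil, events = events_out, manifest = manifest),
            class = "pipeline_result")
}

#' Population category fractions
#'
#' Fractions of neurons that are speed-related (any of L+, L-, Q+, Q-),
#' zone-related, zone-and/or-speed-defined, DP, and fully categorized
#' (zone, speed, or DP). Categorized and uncategorized fractions sum to 1.
#'
#' @param labels data frame from [classify_neurons()].
#' @return named numeric vector of fractions plus `n_neurons`.
#' @export
category_fractions <- function(labels) {
  if (is.null(labels) || !nrow(labels))
    stop_input("`labels` must contain at least one neuron")
  speedy <- labels$speed_class %in% c("L+", "L-", "Q+", "Q-")
  zoned <- labels$zone_pref %in% c("light", "dark")
  dp <- labels$is_dp %in% TRUE
  categorized <- speedy | zoned | dp
  c(speed_related = mean(speedy),
    zone_related = mean(zoned),
    zone_or_speed = mean(speedy | zoned),
    dp = mean(dp),
    categorized = mean(categorized),
    uncategorized = mean(!categorized),
    n_neurons = nrow(labels))
}
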