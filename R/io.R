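# Plain-text interchange: tracking CSV, trace matrices with JSON sidecars,
# label tables, and JSON summaries.

#' Write / read a tracking session as CSV
#'
#' Columns `time_s`, `x_cm`, `y_cm`, `zone`. Reading accepts files without a
#' `zone` column when an arena is supplied (zone is then derived from x).
#'
#' @param track a [tracking_series()].
#' @param path CSV path.
#' @return `write_tracking_csv` returns `path` invisibly; `read_tracking_csv`
#'   returns a [tracking_series()].
#' @export
write_tracking_csv <- function(track, path) {
  df <- as.data.frame(track)[, c("time_s", "x_cm", "y_cm", "zone")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @param arena an [arena_config()], required when the file has no zone
#'   column.
#' @export
read_tracking_csv <- function(path, arena = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("time_s", "x_cm", "y_cm"))
    if (is.null(df[[nm]])) stop_input("tracking CSV lacks column `%s`", nm)
  tracking_series(df$time_s, df$x_cm, df$y_cm,
                  zone = df$zone, arena = arena)
}

#' Write / read calcium traces as a dense matrix with a JSON sidecar
#'
#' The matrix (neurons x frames) goes to `path` as headerless CSV; the
#' sidecar `<path>.json` holds timestamps, neuron ids, noise floors,
#' modality, and any ground-truth labels passed along.
#'
#' @param traces a [calcium_traces()].
#' @param path matrix CSV path (sidecar written at `<path>.json`).
#' @param labels optional ground-truth label data frame to embed.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   list with `traces` and `labels` (`NULL` when absent).
#' @export
write_traces <- function(traces, path, labels = NULL) {
  utils::write.table(traces$dff, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(time_s = traces$time, neuron_ids = traces$neuron_ids,
               noise_floor = traces$noise_floor, modality = traces$modality,
               labels = labels)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- if (!is.null(side$labels)) as.data.frame(side$labels) else NULL
  list(traces = calcium_traces(side$time_s, m,
                               noise_floor = side$noise_floor,
                               modality = side$modality,
                               neuron_ids = side$neuron_ids),
       labels = labels)
}

#' Write per-neuron labels as CSV
#' @param labels data frame from [classify_neurons()].
#' @param path CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a summary list as JSON
#' @param x list of summaries (numbers, vectors, tables coerced to lists).
#' @param path JSON path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Read generator configuration from a YAML or JSON file
#'
#' The file mirrors the generator configuration types: an `arena` block
#' ([arena_config()] fields), a `behavior` block ([behavior_gen_config()]
#' fields, including `seed`), and optionally a `neurons` block with
#' `kernel_tau`, `event_amplitude`, `noise_sd`, `seed`, and a `table` array
#' of per-neuron parameter records.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with `arena`, `behavior_cfg`, and `neuron_cfg` (`NULL` when
#'   the file has no `neurons` block).
#' @export
read_gen_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  arena <- do.call(arena_config, as.list(raw$arena))
  behavior_cfg <- do.call(behavior_gen_config, as.list(raw$behavior))
  neuron_cfg <- NULL
  if (!is.null(raw$neurons)) {
    nb <- raw$neurons
    tab <- as.data.frame(nb$table)
    args <- nb[setdiff(names(nb), "table")]
    neuron_cfg <- do.call(neuron_gen_config, c(list(neurons = tab), args))
  }
  list(arena = arena, behavior_cfg = behavior_cfg, neuron_cfg = neuron_cfg)
}
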