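# Readers and writers for the package's plain-text dialects: sweep sets as
# wide CSV + JSON sidecar, gait/score tables as CSV, stretch trials as channel
# CSV + spike-time list + JSON sidecar. All round-trip to numeric tolerance
# (values) and exactly (metadata).

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Write / read a sweep set
#'
#' The sweep-set dialect is a wide CSV (`time_s` plus one `sweep_<amplitude>`
#' column per step, voltages in mV) next to a JSON sidecar
#' (`<prefix>.json`) holding the metadata: neuron id, group, amplitudes,
#' sampling rate and step timing.
#'
#' @param sweeps A `sweep_set` ([simulate_neuron_sweeps()]).
#' @param prefix Path prefix; `<prefix>.csv` and `<prefix>.json` are written.
#' @return `write_sweep_set()` returns `prefix` invisibly; `read_sweep_set()`
#'   returns a `sweep_set` tibble.
#' @export
write_sweep_set <- function(sweeps, prefix) {
  stopifnot(inherits(sweeps, "sweep_set"))
  n <- length(sweeps$voltage[[1]])
  mat <- do.call(cbind, sweeps$voltage)
  colnames(mat) <- sprintf("sweep_%g", sweeps$amplitude_pa)
  df <- dplyr::bind_cols(
    tibble(time_s = (seq_len(n) - 1) / sweeps$sampling_rate_hz[1]),
    as_tibble(mat)
  )
  readr::write_csv(df, paste0(prefix, ".csv"))
  meta <- list(
    neuron_id = sweeps$neuron_id[1], group = sweeps$group[1],
    amplitudes_pa = sweeps$amplitude_pa,
    sampling_rate_hz = sweeps$sampling_rate_hz[1],
    onset_s = sweeps$onset_s[1], offset_s = sweeps$offset_s[1]
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(csv)) abort(sprintf("No such file: %s", csv))
  if (!file.exists(sidecar)) abort(sprintf("Missing JSON sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  cols <- sprintf("sweep_%g", meta$amplitudes_pa)
  require_columns(df, c("time_s", cols), basename(csv))
  out <- tibble(
    neuron_id = meta$neuron_id, group = meta$group,
    amplitude_pa = as.numeric(meta$amplitudes_pa),
    onset_s = meta$onset_s, offset_s = meta$offset_s,
    sampling_rate_hz = meta$sampling_rate_hz,
    voltage = purrr::map(cols, ~df[[.x]])
  )
  class(out) <- c("sweep_set", class(out))
  out
}

#' Write / read a gait table
#'
#' CSV with header row and columns `animal_id`, `group`, `trial`, then one
#' numeric column per gait variable (UTF-8, comma separator, `.` decimal).
#'
#' @param data A gait table ([simulate_gait_table()]).
#' @param path CSV path.
#' @return `write_gait_table()` returns `path` invisibly; `read_gait_table()`
#'   the parsed tibble.
#' @export
write_gait_table <- function(data, path) {
  require_columns(data, c("animal_id", "group", "trial"), "gait table")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_gait_table
#' @export
read_gait_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("animal_id", "group", "trial"), basename(path))
  var_cols <- setdiff(names(df), c("animal_id", "group", "trial"))
  bad <- var_cols[!purrr::map_lgl(df[var_cols], is.numeric)]
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric gait variable column(s): %s",
                  basename(path), paste(bad, collapse = ", ")))
  }
  if (anyNA(df[var_cols])) {
    abort(sprintf("%s: missing cells in gait variables.", basename(path)))
  }
  df
}

#' Write / read a stretch trial
#'
#' Channels go to `<stem>_channels.csv` (`time_s`, `length`, `tension`),
#' spike times to `<stem>_spikes.txt` (one time in seconds per line), and
#' the event metadata (ramp start/end, hold end, amplitude, ramp speed) to
#' `<stem>.json`.
#'
#' @param trial A `stretch_trial`.
#' @param dir Directory.
#' @param stem File stem.
#' @return `write_stretch_trial()` returns the stem path invisibly;
#'   `read_stretch_trial()` a `stretch_trial` (without the generator's
#'   ground-truth rate).
#' @export
write_stretch_trial <- function(trial, dir, stem = "trial") {
  stopifnot(inherits(trial, "stretch_trial"))
  base <- file.path(dir, stem)
  readr::write_csv(trial$channels, paste0(base, "_channels.csv"))
  writeLines(format(trial$spike_times_s, digits = 12, scientific = FALSE,
                    trim = TRUE),
             paste0(base, "_spikes.txt"))
  jsonlite::write_json(
    list(events = as.list(trial$events), amplitude = trial$amplitude,
         ramp_speed = trial$ramp_speed),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(base)
}

#' @rdname write_stretch_trial
#' @export
read_stretch_trial <- function(dir, stem = "trial") {
  base <- file.path(dir, stem)
  chan_path <- paste0(base, "_channels.csv")
  if (!file.exists(chan_path)) abort(sprintf("No such file: %s", chan_path))
  channels <- readr::read_csv(chan_path, show_col_types = FALSE,
                              progress = FALSE)
  require_columns(channels, c("time_s", "length", "tension"),
                  basename(chan_path))
  spikes <- as.numeric(readLines(paste0(base, "_spikes.txt")))
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  structure(
    list(channels = channels, spike_times_s = spikes,
         rate_true = NULL, events = unlist(meta$events),
         amplitude = meta$amplitude, ramp_speed = meta$ramp_speed,
         config = NULL),
    class = "stretch_trial"
  )
}

#' Write / read precision-task trial scores
#'
#' CSV with columns `animal_id`, `group`, `condition`, `trial`, `misses`,
#' `steps`.
#'
#' @param scores A trial-score table ([simulate_behavior_counts()]).
#' @param path CSV path.
#' @return `write_trial_scores()` returns `path` invisibly;
#'   `read_trial_scores()` the parsed tibble (validated: counts >= 0,
#'   `misses <= steps` where steps are recorded).
#' @export
write_trial_scores <- function(scores, path) {
  require_columns(scores, c("animal_id", "group", "condition", "trial",
                            "misses"), "trial scores")
  readr::write_csv(scores, path)
  invisible(path)
}

#' @rdname write_trial_scores
#' @export
read_trial_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("animal_id", "group", "condition", "trial", "misses"),
                  basename(path))
  if (any(df$misses < 0)) abort("`misses` must be >= 0.")
  if ("steps" %in% names(df) && any(df$misses > df$steps, na.rm = TRUE)) {
    abort("`misses` must not exceed `steps`.")
  }
  df
}
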