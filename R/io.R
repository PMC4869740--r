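#' @importFrom rlang abort
NULL

#' Write a recording bundle to disk
#'
#' Serialises a `plb_recording` as a flat binary trace plus plain-text
#' sidecars: `<prefix>.bin` (little-endian float samples), `<prefix>.json`
#' (sampling rate, duration, dtype, click schedule), `<prefix>_spikes.csv`
#' (ground-truth `unit_id`, `time_s`) and `<prefix>_units.json` (unit
#' parameters and templates).
#'
#' @param rec A `plb_recording` from [simulate_recording()].
#' @param prefix Output path prefix.
#' @param dtype `"float32"` (compact, ~7 significant digits) or `"float64"`
#'   (lossless round trip).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix, dtype = c("float32", "float64")) {
  stopifnot(inherits(rec, "plb_recording"))
  dtype <- match.arg(dtype)
  size <- if (dtype == "float32") 4L else 8L
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(rec$trace, con, size = size, endian = "little")

  meta <- list(
    sampling_rate = rec$sampling_rate,
    duration = rec$duration,
    noise_sd = rec$noise_sd,
    dtype = dtype,
    n_samples = length(rec$trace)
  )
  if (!is.null(rec$schedule)) {
    meta$schedule <- list(
      first_click = rec$schedule$first_click,
      inter_stimulus_interval = attr(rec$schedule, "inter_stimulus_interval"),
      inter_pair_interval = attr(rec$schedule, "inter_pair_interval"),
      stimulus_duration = attr(rec$schedule, "stimulus_duration")
    )
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(rec$spikes, paste0(prefix, "_spikes.csv"))
  units <- rec$units
  units$template <- lapply(units$template, as.numeric)
  jsonlite::write_json(units, paste0(prefix, "_units.json"), digits = NA)
  invisible(prefix)
}

#' Read a recording bundle written by [write_recording()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `plb_recording`.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  size <- if (meta$dtype == "float32") 4L else 8L
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  trace <- readBin(con, "double", n = meta$n_samples, size = size, endian = "little")
  schedule <- NULL
  if (!is.null(meta$schedule)) {
    first <- meta$schedule$first_click
    schedule <- tibble::tibble(
      pair = seq_along(first),
      first_click = first,
      second_click = first + meta$schedule$inter_stimulus_interval
    )
    attr(schedule, "inter_stimulus_interval") <- meta$schedule$inter_stimulus_interval
    attr(schedule, "inter_pair_interval") <- meta$schedule$inter_pair_interval
    attr(schedule, "stimulus_duration") <- meta$schedule$stimulus_duration
  }
  spikes <- readr::read_csv(paste0(prefix, "_spikes.csv"),
                            col_types = readr::cols(
                              unit_id = readr::col_integer(),
                              time_s = readr::col_double()
                            ))
  units <- jsonlite::read_json(paste0(prefix, "_units.json"), simplifyVector = TRUE)
  units <- tibble::as_tibble(units)
  units$template <- lapply(units$template, as.numeric)
  structure(
    list(
      trace = trace, sampling_rate = meta$sampling_rate,
      duration = meta$duration, noise_sd = meta$noise_sd,
      schedule = schedule, units = units, spikes = spikes
    ),
    class = "plb_recording"
  )
}

session_log_cols <- function() {
  readr::cols(
    trial_index = readr::col_integer(),
    outcome = readr::col_character(),
    premature = readr::col_logical(),
    perseverative_correct_responses = readr::col_integer(),
    correction_trial = readr::col_logical(),
    response_latency_s = readr::col_double(),
    reward_latency_s = readr::col_double(),
    stimulus_duration_s = readr::col_double(),
    delay_s = readr::col_double()
  )
}

#' Write a behavioural session log as CSV
#'
#' One row per trial in the session-log schema used throughout the
#' behavioural functions.
#'
#' @param log Trial data frame (see [simulate_5csrtt_session()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' Read a behavioural session log CSV
#'
#' @param path CSV path written by [write_session_log()].
#' @return A tibble in the session-log schema.
#' @export
read_session_log <- function(path) {
  readr::read_csv(path, col_types = session_log_cols())
}
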