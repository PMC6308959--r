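#' Read / write a sensor sample stream
#'
#' The on-disk stream format is CSV with one row per 0.5 s epoch and columns
#' `t_s, hr_bpm, skin_temp_c, gsr_us, amb_temp_c, rh_pct`. Readings the
#' sensor failed to detect are encoded as 0.
#'
#' @param path CSV file path.
#' @param stream A sample-stream data frame.
#' @return `read_sample_stream()` returns the stream data frame;
#'   `write_sample_stream()` returns `path` invisibly.
#' @export
read_sample_stream <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "hr_bpm", "skin_temp_c", "gsr_us", "amb_temp_c", "rh_pct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample stream is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' @rdname read_sample_stream
#' @export
write_sample_stream <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' Package one 60-epoch window of filtered readings
#'
#' Mirrors the device's transmission unit: after 60 filtered epochs the
#' window is packaged with its heart-rate and body-temperature means and
#' handed to the transport (here, JSON lines).
#'
#' @param epochs Data frame of exactly 60 filtered epochs with columns
#'   `t_s, hr_bpm, body_temp_c, gsr_us, amb_temp_c, rh_pct`.
#' @param seq Packet sequence number.
#' @return An object of class `whdd_packet`.
#' @export
pack_window <- function(epochs, seq = 1L) {
  if (!is.data.frame(epochs) || nrow(epochs) != 60) {
    stop("a packet holds exactly 60 epochs (got ",
         if (is.data.frame(epochs)) nrow(epochs) else "non-data-frame",
         ")", call. = FALSE)
  }
  structure(list(seq = as.integer(seq), samples = epochs,
                 window_hr_mean = mean(epochs$hr_bpm),
                 window_temp_mean = mean(epochs$body_temp_c)),
            class = "whdd_packet")
}

#' @export
print.whdd_packet <- function(x, ...) {
  cat(sprintf("<whdd_packet> #%d: 60 epochs, hr mean %.2f bpm, temp mean %.3f degC\n",
              x$seq, x$window_hr_mean, x$window_temp_mean))
  invisible(x)
}

#' Serialise / deserialise packets as JSON lines
#'
#' @param packets List of [pack_window()] packets.
#' @param path File path (one JSON object per line).
#' @return `read_packets()` returns a list of `whdd_packet`s;
#'   `write_packets()` returns `path` invisibly.
#' @export
write_packets <- function(packets, path) {
  lines <- vapply(packets, function(p) {
    jsonlite::toJSON(list(seq = p$seq, samples = p$samples,
                          window_hr_mean = p$window_hr_mean,
                          window_temp_mean = p$window_temp_mean),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_packets
#' @export
read_packets <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    pack_window(as.data.frame(x$samples), seq = x$seq)
  })
}

#' Compare device readings against a reference instrument
#'
#' Pairs each device reading with the reference measurement taken at the
#' same run and reports the signed errors (device minus reference), their
#' mean, and the mean absolute error. Display rounding follows the field's
#' reporting style: heart rates to integers, temperatures to 2 decimals.
#'
#' @param device Numeric vector of device readings.
#' @param reference Numeric vector of reference readings, same length.
#' @return An object of class `whdd_comparison` with fields `pairs` (data
#'   frame `device, reference, error`), `mean_error`, `mean_abs_error`.
#' @examples
#' compare_readings(c(74, 80), c(81, 78))
#' @export
compare_readings <- function(device, reference) {
  if (length(device) != length(reference) || length(device) < 1) {
    stop("`device` and `reference` must be equal-length with at least one pair",
         call. = FALSE)
  }
  err <- device - reference
  structure(list(
    pairs = data.frame(device = device, reference = reference, error = err),
    mean_error = mean(err),
    mean_abs_error = mean(abs(err))
  ), class = "whdd_comparison")
}

#' @export
print.whdd_comparison <- function(x, digits = 2, ...) {
  cat("<whdd_comparison>", nrow(x$pairs), "paired readings\n")
  cat(sprintf("  mean signed error  : %s\n", format(round(x$mean_error, digits))))
  cat(sprintf("  mean absolute error: %s\n", format(round(x$mean_abs_error, digits))))
  invisible(x)
}

#' Alert-onset timing versus user feedback
#'
#' Finds the first Dangerous-level assessment and the first user feedback
#' event and reports the signed lead `feedback_t - onset_t`: positive means
#' the system flagged danger before the runner felt it. A missing first
#' occurrence is reported as `NA`, not an error.
#'
#' @param assessments Assessment log data frame with `t_s` and `level`
#'   columns (time-ordered), e.g. from [run_pipeline()].
#' @param events Event log data frame with `t_s` and `event` columns;
#'   feedback button presses have `event == "feedback"`.
#' @return An object of class `whdd_alert_timing` with fields `onset_t`,
#'   `feedback_t`, `lead_s`.
#' @export
alert_timing <- function(assessments, events) {
  onset <- assessments$t_s[assessments$level == "Dangerous"][1]
  feedback <- events$t_s[events$event == "feedback"][1]
  if (is.null(onset) || length(onset) == 0) onset <- NA_real_
  if (is.null(feedback) || length(feedback) == 0) feedback <- NA_real_
  lead <- if (is.na(onset) || is.na(feedback)) NA_real_ else feedback - onset
  structure(list(onset_t = onset, feedback_t = feedback, lead_s = lead),
            class = "whdd_alert_timing")
}

#' @export
print.whdd_alert_timing <- function(x, ...) {
  cat("<whdd_alert_timing>\n")
  cat(sprintf("  first Dangerous assessment: %s\n",
              if (is.na(x$onset_t)) "absent" else paste0(x$onset_t, " s")))
  cat(sprintf("  first user feedback       : %s\n",
              if (is.na(x$feedback_t)) "absent" else paste0(x$feedback_t, " s")))
  if (!is.na(x$lead_s)) {
    cat(sprintf("  lead (feedback - onset)   : %+g s (system %s)\n", x$lead_s,
                if (x$lead_s >= 0) "earlier" else "later"))
  } else {
    cat("  lead: undefined\n")
  }
  invisible(x)
}

#' Run the full detection pipeline over a stream
#'
#' Composition of the whole in-run workflow: per-epoch heart-rate
#' threshold/error filtering and skin-to-core temperature
#' conversion/compensation, 60-epoch window means, per-window packaging,
#' and per-window fuzzy risk assessment against the resting baseline. A
#' final partial window is not assessed (its epoch count is reported).
#'
#' @param stream A sample-stream data frame, a CSV path, or a
#'   `whdd_session` (whose observed stream is used).
#' @param baseline A [baseline_profile()] with a valid heart-rate channel
#'   (and, for conductance deltas, a valid GSR channel).
#' @param config A [filter_config()].
#' @param fuzzy A fuzzy configuration; defaults to
#'   [default_fuzzy_config()] anchored at the baseline resting heart rate.
#' @param age Age in years used when deriving the default fuzzy config.
#' @return An object of class `whdd_pipeline_result`: list with `filtered`
#'   (per-epoch data frame), `packets` (list of [pack_window()] packets),
#'   `assessments` (per-window data frame `t_s, hr, body_temp, gsr_delta,
#'   danger_coeff, risk, level`), `leftover_epochs`.
#' @export
run_pipeline <- function(stream, baseline, config = filter_config(),
                         fuzzy = NULL, age = 26) {
  if (inherits(stream, "whdd_session")) {
    if (is.null(fuzzy)) age <- stream$runner$age
    stream <- stream$observed
  } else if (is.character(stream)) {
    stream <- read_sample_stream(stream)
  }
  if (!isTRUE(baseline$hr_valid)) {
    stop("pipeline requires a valid heart-rate baseline", call. = FALSE)
  }
  if (is.null(fuzzy)) {
    fuzzy <- default_fuzzy_config(relax_hr = baseline$relax_hr, age = age)
  }
  validate_fuzzy_config(fuzzy)

  n <- nrow(stream)
  hr_state <- hr_filter_state(baseline$relax_hr, config)
  temp_state <- temp_filter_state(config)
  hr_f <- temp_f <- numeric(n)
  packets <- list()
  rows <- list()
  wlen <- config$window_len
  for (i in seq_len(n)) {
    st <- hr_step(hr_state, stream$hr_bpm[i], config)
    hr_state <- st$state
    hr_f[i] <- st$value
    core <- skin_to_core(stream$skin_temp_c[i], stream$amb_temp_c[i], config$alpha)
    tt <- temp_threshold_step(temp_state, core, config)
    temp_state <- tt$state
    temp_f[i] <- tt$value
    if (hr_state$full) {
      wm_hr <- hr_window_mean(hr_state); hr_state <- wm_hr$state
      wm_temp <- temp_window_mean(temp_state); temp_state <- wm_temp$state
      idx <- (i - wlen + 1L):i
      epochs <- data.frame(t_s = stream$t_s[idx], hr_bpm = hr_f[idx],
                           body_temp_c = temp_f[idx],
                           gsr_us = stream$gsr_us[idx],
                           amb_temp_c = stream$amb_temp_c[idx],
                           rh_pct = stream$rh_pct[idx])
      pkt <- pack_window(epochs, seq = length(packets) + 1L)
      packets[[length(packets) + 1L]] <- pkt
      gsr_delta <- if (isTRUE(baseline$gsr_valid)) {
        mean(epochs$gsr_us) - baseline$relax_gsr
      } else {
        0
      }
      dc <- danger_coefficient(mean(epochs$amb_temp_c), mean(epochs$rh_pct))
      ra <- assess_risk(risk_inputs(wm_hr$mean, wm_temp$mean, gsr_delta, dc),
                        fuzzy, t_s = stream$t_s[i])
      rows[[length(rows) + 1L]] <- data.frame(
        t_s = ra$t_s, hr = wm_hr$mean, body_temp = wm_temp$mean,
        gsr_delta = gsr_delta, danger_coeff = dc,
        risk = ra$risk, level = ra$level)
    }
  }
  assessments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_s = numeric(0), hr = numeric(0), body_temp = numeric(0),
               gsr_delta = numeric(0), danger_coeff = numeric(0),
               risk = numeric(0), level = character(0))
  structure(list(
    filtered = data.frame(t_s = stream$t_s, hr_bpm = hr_f,
                          body_temp_c = temp_f, gsr_us = stream$gsr_us,
                          amb_temp_c = stream$amb_temp_c,
                          rh_pct = stream$rh_pct),
    packets = packets,
    assessments = assessments,
    leftover_epochs = n %% wlen
  ), class = "whdd_pipeline_result")
}

#' @export
print.whdd_pipeline_result <- function(x, ...) {
  cat("<whdd_pipeline_result>\n")
  cat(sprintf("  %d epochs filtered, %d packets, %d leftover epoch(s)\n",
              nrow(x$filtered), length(x$packets), x$leftover_epochs))
  if (nrow(x$assessments)) {
    peak <- x$assessments[which.max(x$assessments$risk), ]
    cat(sprintf("  peak risk %.2f (%s) at t = %g s\n",
                peak$risk, peak$level, peak$t_s))
    cat("  levels reached:",
        paste(unique(x$assessments$level), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write assessment and event logs
#'
#' Assessment logs are CSV `t_s, hr, body_temp, gsr_delta, danger_coeff,
#' risk, level`; event logs are CSV `t_s, event`.
#'
#' @param x Data frame to write.
#' @param path CSV file path.
#' @return Readers return the data frame; writers return `path` invisibly.
#' @export
write_assessment_log <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assessment_log
#' @export
read_assessment_log <- function(path) utils::read.csv(path)

#' @rdname write_assessment_log
#' @export
write_event_log <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assessment_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "character"))
  names(df) <- c("t_s", "event")
  df
}

#' Write / read a filter configuration as YAML
#'
#' @param config A [filter_config()].
#' @param path File path.
#' @return `read_filter_config()` returns a [filter_config()];
#'   `write_filter_config()` returns `path` invisibly.
#' @export
write_filter_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_filter_config
#' @export
read_filter_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$age <- NULL   # hr_upper is stored explicitly; do not re-derive
  do.call(filter_config, x)
}

#' Paired static-comparison tables bundled with the package
#'
#' Ten-run resting comparisons of the device against commercial reference
#' instruments: `"heart_rate"` gives the filtered heart rate versus a wrist
#' sphygmomanometer (bpm), `"body_temp"` the filtered body temperature
#' versus an infrared ear thermometer (degC).
#'
#' @param which `"heart_rate"` or `"body_temp"`.
#' @return Data frame with columns `run, device, reference`.
#' @export
static_comparison_table <- function(which = c("heart_rate", "body_temp")) {
  which <- match.arg(which)
  file <- switch(which,
                 heart_rate = "static_hr_comparison.csv",
                 body_temp = "static_temp_comparison.csv")
  utils::read.csv(system.file("extdata", file, package = "whdd",
                              mustWork = TRUE))
}
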