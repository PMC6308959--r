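#' Resting-baseline profile
#'
#' Per-user pre-run references: the resting heart rate that seeds the
#' heart-rate filter cascade and the resting skin conductance against which
#' in-run conductance change is measured, each with a validity flag and the
#' number of acquisition attempts spent.
#'
#' @param relax_hr Resting heart rate, bpm (or `NA` if not acquired).
#' @param relax_gsr Resting skin conductance, microsiemens (or `NA`).
#' @param hr_valid,gsr_valid Logical validity flags per channel.
#' @param hr_attempts,gsr_attempts Acquisition attempts per channel.
#' @param n_samples Samples averaged per completed acquisition (120 = 1 min
#'   at 2 Hz).
#' @return An object of class `whdd_baseline`.
#' @export
baseline_profile <- function(relax_hr = NA_real_, relax_gsr = NA_real_,
                             hr_valid = FALSE, gsr_valid = FALSE,
                             hr_attempts = 0L, gsr_attempts = 0L,
                             n_samples = 120L) {
  structure(list(
    relax_hr = relax_hr, relax_gsr = relax_gsr,
    hr_valid = isTRUE(hr_valid), gsr_valid = isTRUE(gsr_valid),
    hr_attempts = as.integer(hr_attempts),
    gsr_attempts = as.integer(gsr_attempts),
    n_samples = as.integer(n_samples)
  ), class = "whdd_baseline")
}

#' @export
print.whdd_baseline <- function(x, ...) {
  cat("<whdd_baseline>\n")
  cat(sprintf("  resting heart rate : %s bpm (%s, %d attempt%s)\n",
              format(x$relax_hr), if (x$hr_valid) "valid" else "invalid",
              x$hr_attempts, if (x$hr_attempts == 1L) "" else "s"))
  cat(sprintf("  resting conductance: %s uS (%s, %d attempt%s)\n",
              format(x$relax_gsr), if (x$gsr_valid) "valid" else "invalid",
              x$gsr_attempts, if (x$gsr_attempts == 1L) "" else "s"))
  cat(sprintf("  samples per attempt: %d\n", x$n_samples))
  invisible(x)
}

# resting ranges per channel
baseline_range <- function(channel) {
  switch(channel,
         heart_rate = c(50, 90),   # bpm, resting adult
         gsr = c(10, 50),          # uS, resting adult
         stop("unknown channel: ", channel, call. = FALSE))
}

#' Acquire a one-minute resting baseline
#'
#' Consumes 120 consecutive samples (1 min at 2 Hz) from a channel and takes
#' their average as the resting reference. An average of zero (sensor not
#' detecting), a non-finite average, or an average outside the resting range
#' (50--90 bpm for heart rate, 10--50 uS for skin conductance) marks a
#' non-resting or failed acquisition: the minute is discarded and the next
#' 120 samples are tried, up to `max_attempts`. Individual zero samples
#' inside an otherwise valid minute are kept -- only the average is checked.
#'
#' @param stream Numeric vector of channel readings at 2 Hz, or a sample
#'   stream data frame (see [read_sample_stream()]) from which the channel
#'   column is taken.
#' @param channel `"heart_rate"` or `"gsr"`.
#' @param max_attempts Maximum number of one-minute acquisitions before
#'   giving up.
#' @param n_samples Samples per attempt (default 120).
#' @return A [baseline_profile()] with the acquired channel filled in.
#' @section Errors: if every attempt is invalid, an error of class
#'   `whdd_acquisition_failed` is signalled; its condition carries
#'   `last_average` and `attempts` fields.
#' @examples
#' acquire_baseline(rep(60, 120), "heart_rate")
#' @export
acquire_baseline <- function(stream, channel = c("heart_rate", "gsr"),
                             max_attempts = 3L, n_samples = 120L) {
  channel <- match.arg(channel)
  if (is.data.frame(stream)) {
    col <- switch(channel, heart_rate = "hr_bpm", gsr = "gsr_us")
    stream <- stream[[col]]
  }
  if (length(stream) < n_samples) {
    stop("stream provides ", length(stream), " samples; at least ",
         n_samples, " are required per attempt", call. = FALSE)
  }
  rng <- baseline_range(channel)
  avg <- NA_real_
  attempts <- 0L
  valid <- FALSE
  while (attempts < max_attempts &&
         length(stream) >= (attempts + 1L) * n_samples) {
    attempts <- attempts + 1L
    chunk <- stream[((attempts - 1L) * n_samples + 1L):(attempts * n_samples)]
    avg <- mean(chunk)
    if (is.finite(avg) && avg != 0 && avg >= rng[1] && avg <= rng[2]) {
      valid <- TRUE
      break
    }
  }
  if (!valid) {
    cond <- structure(
      class = c("whdd_acquisition_failed", "error", "condition"),
      list(message = sprintf(
             "baseline acquisition failed for %s after %d attempt%s (last average %.3g)",
             channel, attempts, if (attempts == 1L) "" else "s", avg),
           call = sys.call(-1),
           last_average = avg, attempts = attempts, channel = channel))
    stop(cond)
  }
  if (channel == "heart_rate") {
    baseline_profile(relax_hr = avg, hr_valid = TRUE, hr_attempts = attempts,
                     n_samples = n_samples)
  } else {
    baseline_profile(relax_gsr = avg, gsr_valid = TRUE, gsr_attempts = attempts,
                     n_samples = n_samples)
  }
}

#' Acquire both resting baselines from one stream
#'
#' Runs [acquire_baseline()] for heart rate and then for skin conductance on
#' the same pre-run stream (the two sensors sample in sequence on the
#' device; in software both channels of the same epochs are used).
#'
#' @inheritParams acquire_baseline
#' @param stream A sample stream data frame with `hr_bpm` and `gsr_us`
#'   columns.
#' @return A [baseline_profile()] with both channels filled in.
#' @export
acquire_baselines <- function(stream, max_attempts = 3L, n_samples = 120L) {
  hr <- acquire_baseline(stream, "heart_rate", max_attempts, n_samples)
  gsr <- acquire_baseline(stream, "gsr", max_attempts, n_samples)
  baseline_profile(relax_hr = hr$relax_hr, relax_gsr = gsr$relax_gsr,
                   hr_valid = hr$hr_valid, gsr_valid = gsr$gsr_valid,
                   hr_attempts = hr$hr_attempts, gsr_attempts = gsr$gsr_attempts,
                   n_samples = n_samples)
}

#' Write / read a baseline profile as JSON
#'
#' @param baseline A [baseline_profile()].
#' @param path File path.
#' @return `read_baseline()` returns a [baseline_profile()];
#'   `write_baseline()` returns `path` invisibly.
#' @export
write_baseline <- function(baseline, path) {
  jsonlite::write_json(unclass(baseline), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  baseline_profile(
    relax_hr = if (is.null(x$relax_hr)) NA_real_ else x$relax_hr,
    relax_gsr = if (is.null(x$relax_gsr)) NA_real_ else x$relax_gsr,
    hr_valid = isTRUE(x$hr_valid), gsr_valid = isTRUE(x$gsr_valid),
    hr_attempts = x$hr_attempts, gsr_attempts = x$gsr_attempts,
    n_samples = x$n_samples
  )
}
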