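#' Age-predicted maximum heart rate (Tanaka equation)
#'
#' The maximum exercise heart rate of an adult is predicted from age alone as
#' `208 - 0.7 * age`. The rounded value is used as the upper bound of the
#' heart-rate threshold filter.
#'
#' @param age Age in years; must be positive.
#' @param rounded If `TRUE`, round half away from zero to an integer bpm for
#'   threshold use.
#' @return Maximum heart rate in bpm.
#' @examples
#' hr_max(26)            # 189.8
#' hr_max(26, rounded = TRUE)  # 190
#' @export
hr_max <- function(age, rounded = FALSE) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be a positive number of years", call. = FALSE)
  }
  hr <- 208 - 0.7 * age
  if (rounded) round_half_away(hr) else hr
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Filter-cascade configuration
#'
#' Bundles every tunable of the heart-rate and body-temperature filter
#' cascades. Defaults reproduce the device firmware: heart-rate band
#' 50--190 bpm, error dead band \[-10, +25\] bpm with correction gains 1.05
#' (low) and 0.6 (high), consecutive-error budgets 6 and 2, 60-sample
#' windows, hand coefficient alpha = 0.7665 for the skin-to-core conversion,
#' and temperature compensation on \[31, 35\] degC with identity on (35, 40)
#' and a 36.0 degC fallback elsewhere.
#'
#' @param hr_lower,hr_upper Heart-rate threshold band in bpm. If `age` is
#'   given, `hr_upper` defaults to the rounded [hr_max()] for that age.
#' @param age Optional age in years used to derive `hr_upper`.
#' @param err_low_threshold,err_high_threshold Dead-band edges for the
#'   epoch-to-epoch heart-rate error, bpm.
#' @param err_low_gain,err_high_gain Correction gains applied to errors below
#'   / above the dead band.
#' @param low_budget,high_budget Consecutive-error budgets: corrections are
#'   applied while the running counters stay within these budgets, after
#'   which the previous value is held and the counter resets.
#' @param window_len Moving-average window length in samples (60 samples at
#'   2 Hz = 30 s).
#' @param alpha Body-part coefficient for skin-to-core conversion; defaults
#'   to the hand value 0.7665 (the sensor sits on the inner wrist). See
#'   [body_part_alpha()].
#' @param comp_band Closed core-temperature interval (degC) on which the
#'   compensation equation applies.
#' @param identity_band Open interval (degC) passed through unchanged.
#' @param fallback_temp Replacement (degC) for readings outside both bands.
#' @param reset_counters_on_normal If `TRUE`, the consecutive-error counters
#'   also reset whenever the error returns to the dead band (alternative
#'   reading of the firmware; default off).
#' @param use_hold_rule If `TRUE` (default), the temperature stage stores a
#'   newly compensated value only when the deviation from 35 degC changes,
#'   holding the previous slot otherwise.
#' @return An object of class `whdd_filter_config`.
#' @export
filter_config <- function(hr_lower = 50,
                          hr_upper = if (is.null(age)) 190 else hr_max(age, rounded = TRUE),
                          age = NULL,
                          err_low_threshold = -10,
                          err_high_threshold = 25,
                          err_low_gain = 1.05,
                          err_high_gain = 0.6,
                          low_budget = 6,
                          high_budget = 2,
                          window_len = 60,
                          alpha = 0.7665,
                          comp_band = c(31, 35),
                          identity_band = c(35, 40),
                          fallback_temp = 36.0,
                          reset_counters_on_normal = FALSE,
                          use_hold_rule = TRUE) {
  cfg <- list(
    hr_lower = hr_lower, hr_upper = hr_upper, age = age,
    err_low_threshold = err_low_threshold,
    err_high_threshold = err_high_threshold,
    err_low_gain = err_low_gain, err_high_gain = err_high_gain,
    low_budget = low_budget, high_budget = high_budget,
    window_len = as.integer(window_len),
    alpha = alpha,
    comp_band = as.numeric(comp_band),
    identity_band = as.numeric(identity_band),
    fallback_temp = fallback_temp,
    reset_counters_on_normal = isTRUE(reset_counters_on_normal),
    use_hold_rule = isTRUE(use_hold_rule)
  )
  stopifnot(cfg$hr_lower < cfg$hr_upper, cfg$window_len >= 2,
            length(cfg$comp_band) == 2, length(cfg$identity_band) == 2)
  if (cfg$comp_band[2] != cfg$identity_band[1]) {
    stop("compensation band must meet the identity band at 35 degC ",
         "(continuity of the compensation map)", call. = FALSE)
  }
  class(cfg) <- "whdd_filter_config"
  cfg
}

#' @export
print.whdd_filter_config <- function(x, ...) {
  cat("<whdd_filter_config>\n")
  cat(sprintf("  heart rate band : [%g, %g] bpm\n", x$hr_lower, x$hr_upper))
  cat(sprintf("  error dead band : [%g, %g] bpm (gains %g / %g, budgets %d / %d)\n",
              x$err_low_threshold, x$err_high_threshold,
              x$err_low_gain, x$err_high_gain, x$low_budget, x$high_budget))
  cat(sprintf("  window length   : %d samples\n", x$window_len))
  cat(sprintf("  alpha           : %g\n", x$alpha))
  cat(sprintf("  temp bands      : comp [%g, %g], identity (%g, %g), fallback %g degC\n",
              x$comp_band[1], x$comp_band[2],
              x$identity_band[1], x$identity_band[2], x$fallback_temp))
  invisible(x)
}

#' Table of body-part coefficients for skin-to-core conversion
#'
#' Coefficients relating the skin-to-ambient temperature gradient to the
#' core-temperature offset at different measurement sites.
#'
#' @param part One of `"rectal"`, `"head"`, `"torso"`, `"hand"`, `"foot"`.
#' @return The coefficient alpha (dimensionless).
#' @export
body_part_alpha <- function(part = c("hand", "rectal", "head", "torso", "foot")) {
  part <- match.arg(part)
  c(rectal = 0.0699, head = 0.3094, torso = 0.5067,
    hand = 0.7665, foot = 2.1807)[[part]]
}

#' Heart-rate filter state
#'
#' Holds the 60-slot moving-average window, the slot index, the
#' consecutive-error budget counters and the predecessor register of the
#' heart-rate filter cascade. The register is seeded with the user's resting
#' heart rate and, after each emitted window mean, re-seeded with that mean,
#' so the threshold and error stages stay continuous across windows while
#' every window averages exactly `window_len` sensor epochs.
#'
#' @param relax_hr Resting heart rate in bpm (from the pre-run baseline).
#' @param config A [filter_config()].
#' @return An object of class `whdd_hr_state`.
#' @export
hr_filter_state <- function(relax_hr, config = filter_config()) {
  stopifnot(is.numeric(relax_hr), length(relax_hr) == 1, is.finite(relax_hr))
  structure(list(
    window = rep(NA_real_, config$window_len),
    count = 0L,            # next slot to write, 0-based
    full = FALSE,
    mincount = 0L,
    maxcount = 0L,
    prev = as.numeric(relax_hr),
    relax_hr = as.numeric(relax_hr)
  ), class = "whdd_hr_state")
}

# previous stored value: last written slot, or the predecessor register at a
# window boundary
hr_prev <- function(state) {
  if (state$count == 0L) state$prev else state$window[state$count]
}

#' Heart-rate threshold-filter step
#'
#' Stores the raw reading if it lies in the configured band, otherwise
#' repeats the previous stored value (readings the sensor fails to detect
#' arrive as 0 and are rejected the same way). Advances the slot index.
#' This is the first stage of the per-epoch cascade; [hr_error_step()]
#' follows it.
#'
#' @param state A `whdd_hr_state`.
#' @param value Raw heart-rate reading in bpm.
#' @param config A [filter_config()].
#' @return `list(state =, value =)` with the updated state and stored value.
#' @export
hr_threshold_step <- function(state, value, config = filter_config()) {
  if (state$full) {
    stop("heart-rate window overflow: call hr_window_mean() before the next sample",
         call. = FALSE)
  }
  stored <- if (is.finite(value) && value >= config$hr_lower && value <= config$hr_upper) {
    value
  } else {
    hr_prev(state)
  }
  state$window[state$count + 1L] <- stored
  state$count <- state$count + 1L
  if (state$count == config$window_len) state$full <- TRUE
  list(state = state, value = stored)
}

#' Heart-rate error-filter step
#'
#' Compares the threshold-stage output with the previous stored value. An
#' error below -10 bpm is corrected by subtracting `round(error * 1.05)`
#' while the consecutive-low budget (6) lasts; an error above +25 bpm by
#' subtracting `round(error * 0.6)` while the consecutive-high budget (2)
#' lasts. Once a budget is exhausted the previous value is held and the
#' counter resets. Errors inside the dead band leave the value unchanged.
#' Rounding is half away from zero on the bpm scale.
#'
#' @param state A `whdd_hr_state` in which the current epoch's threshold
#'   value has just been stored.
#' @param value The threshold-stage output for the current epoch.
#' @param config A [filter_config()].
#' @return `list(state =, value =)` with the (possibly revised) stored value.
#' @export
hr_error_step <- function(state, value, config = filter_config()) {
  i <- state$count            # slot just written (1-based index i)
  if (i == 0L) stop("hr_error_step() requires a preceding hr_threshold_step()",
                    call. = FALSE)
  prev <- if (i == 1L) state$prev else state$window[i - 1L]
  error <- value - prev
  out <- value
  if (error < config$err_low_threshold) {
    state$mincount <- state$mincount + 1L
    if (state$mincount <= config$low_budget) {
      out <- value - round_half_away(error * config$err_low_gain)
    } else {
      out <- prev
      state$mincount <- 0L
    }
  } else if (error > config$err_high_threshold) {
    state$maxcount <- state$maxcount + 1L
    if (state$maxcount <= config$high_budget) {
      out <- value - round_half_away(error * config$err_high_gain)
    } else {
      out <- prev
      state$maxcount <- 0L
    }
  } else if (config$reset_counters_on_normal) {
    state$mincount <- 0L
    state$maxcount <- 0L
  }
  state$window[i] <- out
  list(state = state, value = out)
}

#' One full heart-rate cascade epoch
#'
#' Threshold stage followed by error stage, in firmware order.
#'
#' @inheritParams hr_threshold_step
#' @return `list(state =, value =)`.
#' @export
hr_step <- function(state, value, config = filter_config()) {
  st <- hr_threshold_step(state, value, config)
  hr_error_step(st$state, st$value, config)
}

#' Heart-rate moving-average window mean
#'
#' Arithmetic mean of the 60 stored slots (the anticipated heart rate
#' emitted once per window). Resets the window: the slot index returns to 0
#' and the predecessor register is re-seeded with the emitted mean.
#'
#' @param state A full `whdd_hr_state`.
#' @return `list(state =, mean =)`.
#' @export
hr_window_mean <- function(state) {
  if (!state$full) {
    stop("heart-rate window is not full (", state$count, " of ",
         length(state$window), " slots)", call. = FALSE)
  }
  m <- mean(state$window)
  state$window[] <- NA_real_
  state$count <- 0L
  state$full <- FALSE
  state$prev <- m
  list(state = state, mean = m)
}

#' Convert skin temperature to core temperature
#'
#' `t_core = t_skin + alpha * (t_skin - t_ambient)`: the skin-to-ambient
#' gradient, scaled by a body-part coefficient, is added back to the skin
#' reading to estimate core temperature.
#'
#' @param t_skin Skin temperature, degC.
#' @param t_ambient Ambient temperature, degC.
#' @param alpha Body-part coefficient (>= 0); see [body_part_alpha()].
#' @return Estimated core temperature, degC. Vectorised.
#' @examples
#' skin_to_core(34, 28, 0.7665)  # 38.599
#' @export
skin_to_core <- function(t_skin, t_ambient, alpha = 0.7665) {
  stopifnot(all(alpha >= 0))
  t_skin + alpha * (t_skin - t_ambient)
}

#' Compensate an estimated core temperature
#'
#' Piecewise map derived from comparison with an ear thermometer: on
#' \[31, 35\] degC the shortfall from 35 is compensated proportionally,
#' `t + (35 - t) * 1.5`; on (35, 40) the value passes unchanged; anything
#' else (sensor failure, off-body reading) is replaced by the average human
#' body temperature 36.0 degC. The map is continuous at 35 degC and sends
#' every real input into \[35, 40).
#'
#' @param t_core Estimated core temperature, degC. Vectorised.
#' @param config A [filter_config()] supplying the bands and fallback.
#' @return Compensated body temperature, degC.
#' @examples
#' temp_compensate(33)   # 36
#' temp_compensate(37)   # 37
#' temp_compensate(45)   # 36
#' @export
temp_compensate <- function(t_core, config = filter_config()) {
  out <- rep(config$fallback_temp, length(t_core))
  comp <- is.finite(t_core) &
    t_core >= config$comp_band[1] & t_core <= config$comp_band[2]
  ident <- is.finite(t_core) &
    t_core > config$identity_band[1] & t_core < config$identity_band[2]
  out[comp] <- t_core[comp] + (35 - t_core[comp]) * 1.5
  out[ident] <- t_core[ident]
  out
}

#' Body-temperature filter state
#'
#' Window, slot index, predecessor register and the hold-difference register
#' of the temperature cascade. The predecessor register starts at the
#' 36.0 degC fallback (no baseline temperature is acquired).
#'
#' @param config A [filter_config()].
#' @return An object of class `whdd_temp_state`.
#' @export
temp_filter_state <- function(config = filter_config()) {
  structure(list(
    window = rep(NA_real_, config$window_len),
    count = 0L,
    full = FALSE,
    temp_diff = 0,
    prev = config$fallback_temp
  ), class = "whdd_temp_state")
}

#' Body-temperature threshold/compensation step
#'
#' Applies [temp_compensate()] with a hold rule: inside the compensation
#' band the newly compensated value is stored only when the deviation
#' `35 - t_core` differs from the last stored deviation; an unchanged
#' deviation repeats the previous slot (suppressing flat-line chatter from
#' the infrared sensor). Identity-band and fallback inputs follow
#' [temp_compensate()] directly.
#'
#' @param state A `whdd_temp_state`.
#' @param t_core Core-temperature estimate from [skin_to_core()], degC.
#' @param config A [filter_config()].
#' @return `list(state =, value =)` with the stored temperature.
#' @export
temp_threshold_step <- function(state, t_core, config = filter_config()) {
  if (state$full) {
    stop("temperature window overflow: call temp_window_mean() before the next sample",
         call. = FALSE)
  }
  prev <- if (state$count == 0L) state$prev else state$window[state$count]
  in_comp <- is.finite(t_core) &&
    t_core >= config$comp_band[1] && t_core <= config$comp_band[2]
  in_ident <- is.finite(t_core) &&
    t_core > config$identity_band[1] && t_core < config$identity_band[2]
  if (in_comp) {
    dev <- 35 - t_core
    if (!config$use_hold_rule || dev != state$temp_diff) {
      state$temp_diff <- dev
      stored <- t_core + dev * 1.5
    } else {
      stored <- prev
    }
  } else if (in_ident) {
    stored <- t_core
  } else {
    stored <- config$fallback_temp
  }
  state$window[state$count + 1L] <- stored
  state$count <- state$count + 1L
  if (state$count == config$window_len) state$full <- TRUE
  list(state = state, value = stored)
}

#' Body-temperature window mean
#'
#' Mean of the 60 stored temperature slots (the body temperature emitted
#' once per window); resets the window like [hr_window_mean()].
#'
#' @param state A full `whdd_temp_state`.
#' @return `list(state =, mean =)`.
#' @export
temp_window_mean <- function(state) {
  if (!state$full) {
    stop("temperature window is not full (", state$count, " of ",
         length(state$window), " slots)", call. = FALSE)
  }
  m <- mean(state$window)
  state$window[] <- NA_real_
  state$count <- 0L
  state$full <- FALSE
  state$prev <- m
  list(state = state, mean = m)
}

#' Run the heart-rate cascade over a whole stream
#'
#' Convenience wrapper: feeds every raw reading through
#' [hr_step()], collecting the per-epoch filtered values and the
#' per-window means.
#'
#' @param hr Numeric vector of raw heart-rate readings, bpm.
#' @param relax_hr Resting heart rate seeding the cascade.
#' @param config A [filter_config()].
#' @return `list(filtered =, window_means =, state =)`; `filtered` has one
#'   value per input epoch, `window_means` one per completed window.
#' @export
filter_heart_rate <- function(hr, relax_hr, config = filter_config()) {
  state <- hr_filter_state(relax_hr, config)
  filtered <- numeric(length(hr))
  means <- numeric(0)
  for (i in seq_along(hr)) {
    st <- hr_step(state, hr[i], config)
    state <- st$state
    filtered[i] <- st$value
    if (state$full) {
      wm <- hr_window_mean(state)
      state <- wm$state
      means <- c(means, wm$mean)
    }
  }
  list(filtered = filtered, window_means = means, state = state)
}

#' Run the body-temperature cascade over a whole stream
#'
#' Converts each skin reading to core temperature via [skin_to_core()],
#' then applies [temp_threshold_step()] per epoch and collects window means.
#'
#' @param t_skin Skin-temperature readings, degC.
#' @param t_ambient Ambient temperature, degC (scalar or per-epoch vector).
#' @param config A [filter_config()].
#' @return `list(filtered =, window_means =, state =)`.
#' @export
filter_temperature <- function(t_skin, t_ambient, config = filter_config()) {
  t_ambient <- rep_len(t_ambient, length(t_skin))
  state <- temp_filter_state(config)
  filtered <- numeric(length(t_skin))
  means <- numeric(0)
  for (i in seq_along(t_skin)) {
    core <- skin_to_core(t_skin[i], t_ambient[i], config$alpha)
    st <- temp_threshold_step(state, core, config)
    state <- st$state
    filtered[i] <- st$value
    if (state$full) {
      wm <- temp_window_mean(state)
      state <- wm$state
      means <- c(means, wm$mean)
    }
  }
  list(filtered = filtered, window_means = means, state = state)
}
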