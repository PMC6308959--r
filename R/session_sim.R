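#' Running-session protocol
#'
#' An ordered list of treadmill/track stages plus the ambient conditions
#' under which the session takes place. Sampling is 2 Hz throughout (one
#' epoch every 0.5 s).
#'
#' @param stages Data frame with columns `speed_kmh` and `duration_s`.
#' @param ambient_temp Ambient temperature, degC.
#' @param humidity Relative humidity, percent.
#' @param sample_rate Sampling rate, Hz.
#' @return An object of class `whdd_protocol`.
#' @export
session_protocol <- function(stages, ambient_temp, humidity, sample_rate = 2) {
  stopifnot(is.data.frame(stages),
            all(c("speed_kmh", "duration_s") %in% names(stages)),
            nrow(stages) >= 1, all(stages$duration_s > 0),
            all(stages$speed_kmh > 0))
  structure(list(stages = stages, ambient_temp = ambient_temp,
                 humidity = humidity, sample_rate = sample_rate),
            class = "whdd_protocol")
}

#' @export
print.whdd_protocol <- function(x, ...) {
  cat("<whdd_protocol>\n")
  cat(sprintf("  %d stage(s), %g s total, %g Hz sampling\n",
              nrow(x$stages), sum(x$stages$duration_s), x$sample_rate))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("    %g km/h for %g s\n",
                x$stages$speed_kmh[i], x$stages$duration_s[i]))
  }
  cat(sprintf("  ambient %g degC, %g%% RH (danger coefficient %g)\n",
              x$ambient_temp, x$humidity,
              danger_coefficient(x$ambient_temp, x$humidity)))
  invisible(x)
}

#' Preset protocols
#'
#' `indoor_protocol()` is the three-stage treadmill session: warm-up at
#' 8 km/h for 10 min, acceleration at 10 km/h for 2 min, intense exercise
#' at 12 km/h for 3 min, in a gym at 28.9 degC / 68.2% RH (danger
#' coefficient 35.72). `outdoor_protocol()` is a stylised evening 2-km
#' track run at 23.5 degC / 80% RH (danger coefficient 31.5).
#'
#' @return A [session_protocol()].
#' @export
indoor_protocol <- function() {
  session_protocol(
    data.frame(speed_kmh = c(8, 10, 12), duration_s = c(600, 120, 180)),
    ambient_temp = 28.9, humidity = 68.2
  )
}

#' @rdname indoor_protocol
#' @export
outdoor_protocol <- function() {
  session_protocol(
    data.frame(speed_kmh = c(9, 10, 11), duration_s = c(300, 300, 120)),
    ambient_temp = 23.5, humidity = 80
  )
}

#' Runner profile
#'
#' Per-runner parameters of the latent physiology model.
#'
#' @param name Profile name (unique within a cohort).
#' @param age Age in years.
#' @param relax_hr Resting heart rate, bpm, in \[50, 90\].
#' @param relax_gsr Resting skin conductance, uS, in \[10, 50\].
#' @param fitness Heart-rate responsiveness in (0, 1\]: the fraction of the
#'   age-predicted maximum ([hr_max()]) toward which the heart rate is
#'   driven at full workload. Deconditioned runners operate closer to their
#'   maximum, so irregular exercisers get values near 1.
#' @param sweat_rate Dimensionless scaling of sweat accumulation (drives the
#'   skin-temperature measurement bias and the conductance decline).
#' @param discomfort_hr_frac Fraction of [hr_max()] above which the runner
#'   presses the feedback button (once per session).
#' @return An object of class `whdd_runner`.
#' @export
runner_profile <- function(name, age, relax_hr = 70, relax_gsr = 25,
                           fitness = 0.85, sweat_rate = 1,
                           discomfort_hr_frac = 0.9) {
  stopifnot(relax_hr >= 50, relax_hr <= 90,
            relax_gsr >= 10, relax_gsr <= 50,
            fitness > 0, fitness <= 1, sweat_rate >= 0,
            discomfort_hr_frac > 0)
  structure(list(name = name, age = age, relax_hr = relax_hr,
                 relax_gsr = relax_gsr, fitness = fitness,
                 sweat_rate = sweat_rate,
                 discomfort_hr_frac = discomfort_hr_frac),
            class = "whdd_runner")
}

#' Sensor artifact model
#'
#' Corruption applied to the latent physiology to produce what the loosely
#' worn sensors would actually report: per-sample dropouts (a 0 reading, the
#' sensor's cannot-detect convention), out-of-band heart-rate spikes from
#' arm motion, additive Gaussian noise, and a sweat-induced depression of
#' the measured skin temperature that grows with accumulated sweat.
#'
#' @param dropout_prob Per-sample probability of a 0 reading (per channel).
#' @param spike_prob Per-sample probability of an out-of-range heart-rate
#'   spike.
#' @param spike_range Two-row matrix of bpm intervals from which spikes are
#'   drawn; the defaults straddle the 50--190 threshold band so the
#'   threshold filter is actually exercised.
#' @param temp_sweat_bias Maximum skin-temperature depression, degC, reached
#'   as sweat saturates.
#' @param noise_sd Named per-channel Gaussian noise SDs (`hr` bpm,
#'   `skin_temp` degC, `gsr` uS).
#' @param seed RNG seed; a session derives per-channel sub-seeds from it so
#'   channels can be regenerated independently.
#' @return An object of class `whdd_artifacts`.
#' @export
artifact_model <- function(dropout_prob = 0.01, spike_prob = 0.02,
                           spike_range = rbind(c(0, 49), c(191, 220)),
                           temp_sweat_bias = 1.0,
                           noise_sd = c(hr = 2, skin_temp = 0.15, gsr = 0.5),
                           seed = 1L) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1,
            spike_prob >= 0, spike_prob <= 1)
  structure(list(dropout_prob = dropout_prob, spike_prob = spike_prob,
                 spike_range = spike_range, temp_sweat_bias = temp_sweat_bias,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "whdd_artifacts")
}

#' Artifact model that leaves the latent signals untouched
#' @export
no_artifacts <- function() {
  artifact_model(dropout_prob = 0, spike_prob = 0, temp_sweat_bias = 0,
                 noise_sd = c(hr = 0, skin_temp = 0, gsr = 0))
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# time constants (s) encode the reaction ordering: heart rate responds
# first, core temperature later, skin conductance last
.tau_hr <- 45
.tau_temp <- 240
.tau_gsr <- 420
.temp_base <- 36.6     # pre-exercise core temperature, degC
.temp_gain <- 2.7      # asymptotic core rise at full workload, degC
.gsr_drop_frac <- 0.6  # asymptotic fractional conductance decline
.sweat_half_s <- 300   # full-effort seconds to ~63% of sweat saturation

#' Simulate one running session
#'
#' Generates the latent physiological truth and the corrupted sensor
#' observations for a staged running session. Latent heart rate relaxes
#' (first-order, 45 s time constant) toward a per-stage target interpolated
#' between the resting rate and `fitness * hr_max(age)` by the stage's
#' relative workload (speed / 12 km/h, capped at 1); latent core
#' temperature relaxes (240 s) toward a workload-dependent asymptote below
#' 40 degC and rises monotonically over the increasing-intensity stages;
#' latent conductance relaxes (420 s) downward as sweating saturates. The
#' observed skin-temperature channel is the inverse skin-to-core mapping of
#' the latent core temperature, depressed by the sweat bias; heart rate and
#' conductance get noise, spikes and dropouts per the artifact model. A
#' feedback event is logged when the latent heart rate first exceeds
#' `discomfort_hr_frac * hr_max(age)`.
#'
#' @param protocol A [session_protocol()].
#' @param runner A [runner_profile()].
#' @param artifacts An [artifact_model()]; use [no_artifacts()] for clean
#'   streams.
#' @param alpha Body-part coefficient of the simulated temperature-sensor
#'   placement (hand/wrist by default).
#' @return An object of class `whdd_session`: a list with `observed` and
#'   `latent` data frames (one row per epoch), an `events` data frame
#'   (`t_s`, `event`), and the generating `protocol`, `runner`,
#'   `artifacts`.
#' @export
simulate_session <- function(protocol, runner, artifacts = artifact_model(),
                             alpha = 0.7665) {
  if (!inherits(protocol, "whdd_protocol") || nrow(protocol$stages) == 0) {
    stop("`protocol` must be a whdd_protocol with at least one stage",
         call. = FALSE)
  }
  stopifnot(inherits(runner, "whdd_runner"), inherits(artifacts, "whdd_artifacts"))
  dt <- 1 / protocol$sample_rate
  n_per_stage <- round(protocol$stages$duration_s * protocol$sample_rate)
  n <- sum(n_per_stage)
  t_s <- seq_len(n) * dt
  effort <- rep(pmin(protocol$stages$speed_kmh / 12, 1), n_per_stage)

  hrmax <- hr_max(runner$age)
  peak_hr <- runner$fitness * hrmax
  hr_target <- runner$relax_hr + effort * (peak_hr - runner$relax_hr)
  temp_target <- .temp_base + .temp_gain * effort
  gsr_target <- runner$relax_gsr *
    (1 - .gsr_drop_frac * pmin(1, effort * runner$sweat_rate))

  hr <- temp <- gsr <- numeric(n)
  h <- runner$relax_hr; tc <- .temp_base; g <- runner$relax_gsr
  for (i in seq_len(n)) {
    h <- h + dt / .tau_hr * (hr_target[i] - h)
    tc <- tc + dt / .tau_temp * (temp_target[i] - tc)
    g <- g + dt / .tau_gsr * (gsr_target[i] - g)
    hr[i] <- h; temp[i] <- tc; gsr[i] <- g
  }

  # cumulative sweat drives the skin-temperature measurement bias
  sweat <- cumsum(effort * runner$sweat_rate * dt)
  bias <- artifacts$temp_sweat_bias * (1 - exp(-sweat / .sweat_half_s))
  skin <- (temp + alpha * protocol$ambient_temp) / (1 + alpha)

  latent <- data.frame(t_s = t_s, hr_bpm = hr, core_temp_c = temp,
                       skin_temp_c = skin, gsr_us = gsr)

  nsd <- artifacts$noise_sd
  sub_seed <- function(k) (artifacts$seed %% 100000L) * 10L + k
  hr_obs <- with_private_seed(sub_seed(1L), {
    x <- hr + if (nsd[["hr"]] > 0) stats::rnorm(n, 0, nsd[["hr"]]) else 0
    if (artifacts$spike_prob > 0) {
      hit <- stats::runif(n) < artifacts$spike_prob
      band <- sample(nrow(artifacts$spike_range), n, replace = TRUE)
      lo <- artifacts$spike_range[band, 1]; hi <- artifacts$spike_range[band, 2]
      x[hit] <- stats::runif(sum(hit), lo[hit], hi[hit])
    }
    if (artifacts$dropout_prob > 0) x[stats::runif(n) < artifacts$dropout_prob] <- 0
    x
  })
  skin_obs <- with_private_seed(sub_seed(2L), {
    x <- skin - bias +
      if (nsd[["skin_temp"]] > 0) stats::rnorm(n, 0, nsd[["skin_temp"]]) else 0
    if (artifacts$dropout_prob > 0) x[stats::runif(n) < artifacts$dropout_prob] <- 0
    x
  })
  gsr_obs <- with_private_seed(sub_seed(3L), {
    x <- pmax(gsr + if (nsd[["gsr"]] > 0) stats::rnorm(n, 0, nsd[["gsr"]]) else 0, 0)
    if (artifacts$dropout_prob > 0) x[stats::runif(n) < artifacts$dropout_prob] <- 0
    x
  })

  observed <- data.frame(t_s = t_s, hr_bpm = hr_obs, skin_temp_c = skin_obs,
                         gsr_us = gsr_obs,
                         amb_temp_c = protocol$ambient_temp,
                         rh_pct = protocol$humidity)

  thr <- runner$discomfort_hr_frac * hrmax
  first <- which(hr > thr)[1]
  events <- if (is.na(first)) {
    data.frame(t_s = numeric(0), event = character(0))
  } else {
    data.frame(t_s = t_s[first], event = "feedback")
  }

  structure(list(observed = observed, latent = latent, events = events,
                 protocol = protocol, runner = runner, artifacts = artifacts,
                 alpha = alpha),
            class = "whdd_session")
}

#' @export
print.whdd_session <- function(x, ...) {
  cat("<whdd_session>", x$runner$name, "\n")
  cat(sprintf("  %d epochs over %g s; latent peak hr %.1f bpm, peak core %.2f degC\n",
              nrow(x$observed), max(x$observed$t_s),
              max(x$latent$hr_bpm), max(x$latent$core_temp_c)))
  if (nrow(x$events)) {
    cat(sprintf("  feedback at %g s\n", x$events$t_s[1]))
  } else {
    cat("  no feedback events\n")
  }
  invisible(x)
}

#' Simulate a cohort of runners
#'
#' One session per profile, each with a seed derived from the artifact
#' model's base seed and the runner's position, so the cohort is
#' reproducible as a whole while sessions stay independent.
#'
#' @param profiles List of [runner_profile()]s with unique names.
#' @param protocol A [session_protocol()] shared by the cohort.
#' @param artifacts An [artifact_model()]; its `seed` seeds the cohort.
#' @param alpha Body-part coefficient, as in [simulate_session()].
#' @return Named list of `whdd_session` objects.
#' @export
make_cohort <- function(profiles, protocol = indoor_protocol(),
                        artifacts = artifact_model(), alpha = 0.7665) {
  stopifnot(length(profiles) >= 1)
  nms <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate profile names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sessions <- lapply(seq_along(profiles), function(i) {
    art <- artifacts
    art$seed <- artifacts$seed + 1000L * i
    simulate_session(protocol, profiles[[i]], art, alpha)
  })
  names(sessions) <- nms
  sessions
}

#' Preset runner cohorts
#'
#' `indoor_cohort()` mirrors the four treadmill participants (ages 25, 37,
#' 23, 23): two habitual exercisers modelled as comfortable (lower
#' heart-rate responsiveness, high discomfort threshold, no feedback
#' expected) and two irregular exercisers modelled as strained (driven near
#' their age-predicted maximum, feedback during the intense stage).
#' `outdoor_cohort()` mirrors the five evening track participants (ages 37,
#' 36, 24, 24, 24). Ages are as reported; the physiological parameters are
#' documented model choices.
#'
#' @return List of [runner_profile()]s.
#' @export
indoor_cohort <- function() {
  list(
    runner_profile("user1", age = 25, relax_hr = 68, relax_gsr = 24,
                   fitness = 0.75, sweat_rate = 1.0, discomfort_hr_frac = 0.95),
    runner_profile("user2", age = 37, relax_hr = 72, relax_gsr = 28,
                   fitness = 0.78, sweat_rate = 1.1, discomfort_hr_frac = 0.95),
    runner_profile("user3", age = 23, relax_hr = 70, relax_gsr = 25,
                   fitness = 0.97, sweat_rate = 1.0, discomfort_hr_frac = 0.82),
    runner_profile("user4", age = 23, relax_hr = 74, relax_gsr = 22,
                   fitness = 0.96, sweat_rate = 0.9, discomfort_hr_frac = 0.84)
  )
}

#' @rdname indoor_cohort
#' @export
outdoor_cohort <- function() {
  list(
    runner_profile("user1", age = 37, relax_hr = 66, relax_gsr = 26,
                   fitness = 0.76, sweat_rate = 1.0, discomfort_hr_frac = 0.95),
    runner_profile("user2", age = 36, relax_hr = 70, relax_gsr = 24,
                   fitness = 0.80, sweat_rate = 1.0, discomfort_hr_frac = 0.93),
    runner_profile("user3", age = 24, relax_hr = 72, relax_gsr = 27,
                   fitness = 0.90, sweat_rate = 1.0, discomfort_hr_frac = 0.88),
    runner_profile("user4", age = 24, relax_hr = 75, relax_gsr = 23,
                   fitness = 0.94, sweat_rate = 1.1, discomfort_hr_frac = 0.85),
    runner_profile("user5", age = 24, relax_hr = 71, relax_gsr = 25,
                   fitness = 0.92, sweat_rate = 1.0, discomfort_hr_frac = 0.86)
  )
}

#' Pre-run resting stream for a runner
#'
#' Generates the quiet pre-exercise stream (constant latent resting values
#' plus channel noise) from which the one-minute baselines are acquired.
#'
#' @param runner A [runner_profile()].
#' @param duration_s Stream duration, s.
#' @param artifacts An [artifact_model()] (noise and dropouts only are
#'   applied; spikes do not occur at rest).
#' @param sample_rate Sampling rate, Hz.
#' @param ambient_temp,humidity Ambient conditions recorded alongside.
#' @return A sample-stream data frame (see [read_sample_stream()]).
#' @export
simulate_rest_stream <- function(runner, duration_s = 120,
                                 artifacts = artifact_model(),
                                 sample_rate = 2,
                                 ambient_temp = 25, humidity = 60) {
  n <- round(duration_s * sample_rate)
  nsd <- artifacts$noise_sd
  with_private_seed(artifacts$seed, {
    hr <- runner$relax_hr +
      if (nsd[["hr"]] > 0) stats::rnorm(n, 0, nsd[["hr"]]) else 0
    gsr <- pmax(runner$relax_gsr +
                  if (nsd[["gsr"]] > 0) stats::rnorm(n, 0, nsd[["gsr"]]) else 0, 0)
    skin <- (.temp_base + 0.7665 * ambient_temp) / 1.7665 +
      if (nsd[["skin_temp"]] > 0) stats::rnorm(n, 0, nsd[["skin_temp"]]) else 0
    if (artifacts$dropout_prob > 0) {
      hr[stats::runif(n) < artifacts$dropout_prob] <- 0
      gsr[stats::runif(n) < artifacts$dropout_prob] <- 0
    }
    data.frame(t_s = seq_len(n) / sample_rate, hr_bpm = hr,
               skin_temp_c = skin, gsr_us = gsr,
               amb_temp_c = ambient_temp, rh_pct = humidity)
  })
}
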