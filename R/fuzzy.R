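#' Environmental danger coefficient
#'
#' Scalar heat-risk index of the surroundings, combining ambient temperature
#' and relative humidity as `temp + rh / 10`. An evening outdoor track at
#' 23.5 degC and 80% humidity scores 31.5; an indoor gym at 28.9 degC and
#' 68.2% scores 35.72.
#'
#' @param amb_temp Ambient temperature, degC.
#' @param rh Relative humidity, percent, in \[0, 100\].
#' @param humidity_weight Weight on the humidity term (default 1/10).
#' @return Dimensionless danger coefficient. Vectorised.
#' @examples
#' danger_coefficient(23.5, 80)    # 31.5
#' danger_coefficient(28.9, 68.2)  # 35.72
#' @export
danger_coefficient <- function(amb_temp, rh, humidity_weight = 0.1) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    stop("`rh` must be a relative humidity in [0, 100] percent", call. = FALSE)
  }
  amb_temp + humidity_weight * rh
}

#' Crisp inputs to the fuzzy risk controller
#'
#' @param heart_rate Filtered heart rate, bpm (> 0).
#' @param body_temp Filtered body temperature, degC, in \[35, 40).
#' @param gsr_delta Change of skin conductance from the resting baseline,
#'   microsiemens (negative when sweating is shutting down).
#' @param danger_coeff Environmental danger coefficient; see
#'   [danger_coefficient()].
#' @return An object of class `whdd_risk_inputs`.
#' @export
risk_inputs <- function(heart_rate, body_temp, gsr_delta, danger_coeff) {
  vals <- c(heart_rate, body_temp, gsr_delta, danger_coeff)
  if (any(!is.finite(vals))) stop("all risk inputs must be finite", call. = FALSE)
  if (heart_rate <= 0) stop("`heart_rate` must be positive", call. = FALSE)
  if (body_temp < 35 || body_temp >= 40) {
    stop("`body_temp` must lie in [35, 40) degC (filtered output range)",
         call. = FALSE)
  }
  structure(list(heart_rate = heart_rate, body_temp = body_temp,
                 gsr_delta = gsr_delta, danger_coeff = danger_coeff),
            class = "whdd_risk_inputs")
}

# trapezoidal membership, params (a, b, c, d); triangles have b == c
mu_trap <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  y <- numeric(length(x))
  up <- x >= a & x < b
  if (b > a) y[up] <- (x[up] - a) / (b - a)
  y[x >= b & x <= cc] <- 1
  dn <- x > cc & x <= d
  if (d > cc) y[dn] <- (d - x[dn]) / (d - cc)
  y
}

# membership of a scalar (clamped to the universe) in every term of an input
fuzzify <- function(value, input) {
  value <- min(max(value, input$universe[1]), input$universe[2])
  vapply(input$terms, function(p) mu_trap(value, p), numeric(1))
}

#' Default fuzzy risk-controller configuration
#'
#' A Mamdani controller with three trapezoidal terms per input over
#' physical universes, a monotone 81-rule table, four output terms centred
#' in the four risk zones of the 0--40 indicator, and centroid
#' defuzzification. The heart-rate partition is anchored at the user's
#' resting heart rate and the age-predicted maximum ([hr_max()]), so the
#' controller adapts to the individual's baseline.
#'
#' Adjacent input terms overlap as staircase trapezoids (their plateaus
#' overlap, so at most one term is on a ramp at any point of the universe
#' and the strongest membership is always 1). Together with the monotone
#' rule table this makes the defuzzified risk non-decreasing in each
#' stress-increasing direction -- a complementary triangular partition
#' would dent the centroid at every term crossover.
#'
#' The rule table maps the severity grades of the four inputs to an output
#' zone through a weighted severity score whose weights (heart rate 0.45,
#' body temperature 0.20, environment 0.30, conductance change 0.05)
#' encode the observed reaction ordering heart rate > body temperature >
#' skin response; a near-maximal heart rate in a severe environment is
#' sufficient to reach the dangerous zone.
#'
#' All of the configuration is data: it can be written to and read from YAML
#' ([write_fuzzy_config()]) and edited freely.
#'
#' @param relax_hr Resting heart rate anchoring the low heart-rate term, bpm.
#' @param age Age in years; sets the high heart-rate anchor via [hr_max()].
#' @param weights Named severity weights for `heart_rate`, `body_temp`,
#'   `gsr_delta`, `danger_coeff` (need not sum to 1).
#' @param resolution Step of the output-universe discretisation used by
#'   centroid defuzzification.
#' @return An object of class `whdd_fuzzy_config`.
#' @export
default_fuzzy_config <- function(relax_hr = 70, age = 26,
                                 weights = c(heart_rate = 0.45,
                                             body_temp = 0.20,
                                             gsr_delta = 0.05,
                                             danger_coeff = 0.30),
                                 resolution = 0.05) {
  M <- hr_max(age, rounded = TRUE)
  r <- relax_hr
  inputs <- list(
    heart_rate = list(
      universe = c(50, 200),
      terms = list(low = c(50, 50, r + 30, r + 60),
                   elevated = c(r, r + 30, 0.90 * M, 0.93 * M),
                   high = c(0.80 * M, 0.90 * M, 200, 200))),
    body_temp = list(
      universe = c(35, 40),
      terms = list(normal = c(35, 35, 36.8, 37.6),
                   elevated = c(36.2, 36.8, 38.4, 39.2),
                   high = c(37.6, 38.4, 40, 40))),
    gsr_delta = list(
      universe = c(-30, 10),
      terms = list(steady = c(-12, -8, 10, 10),
                   declining = c(-22, -16, -8, -2),
                   suppressed = c(-30, -30, -16, -12))),
    danger_coeff = list(
      universe = c(20, 45),
      terms = list(mild = c(20, 20, 28, 32),
                   hot = c(23, 27, 34, 36.5),
                   severe = c(32, 34, 45, 45)))
  )
  output <- list(
    universe = c(0, 40),
    terms = list(safe = c(0, 0, 5, 12),
                 attention = c(8, 15, 15, 22),
                 warning = c(18, 25, 25, 32),
                 dangerous = c(28, 35, 40, 40))
  )
  sev <- expand.grid(heart_rate = 0:2, body_temp = 0:2,
                     gsr_delta = 0:2, danger_coeff = 0:2)
  w <- weights[c("heart_rate", "body_temp", "gsr_delta", "danger_coeff")]
  score <- as.matrix(sev) %*% (w / sum(w)) / 2   # in [0, 1]
  out_idx <- round_half_away(score * 3)          # 0..3
  term_of <- function(input, idx) names(inputs[[input]]$terms)[idx + 1]
  rules <- data.frame(
    heart_rate = term_of("heart_rate", sev$heart_rate),
    body_temp = term_of("body_temp", sev$body_temp),
    gsr_delta = term_of("gsr_delta", sev$gsr_delta),
    danger_coeff = term_of("danger_coeff", sev$danger_coeff),
    risk = names(output$terms)[out_idx + 1],
    stringsAsFactors = FALSE
  )
  structure(list(inputs = inputs, output = output, rules = rules,
                 defuzz = "centroid", resolution = resolution),
            class = "whdd_fuzzy_config")
}

#' @export
print.whdd_fuzzy_config <- function(x, ...) {
  cat("<whdd_fuzzy_config>\n")
  for (nm in names(x$inputs)) {
    inp <- x$inputs[[nm]]
    cat(sprintf("  %-13s [%g, %g]: %s\n", nm, inp$universe[1], inp$universe[2],
                paste(names(inp$terms), collapse = ", ")))
  }
  cat(sprintf("  risk output   [%g, %g]: %s\n", x$output$universe[1],
              x$output$universe[2], paste(names(x$output$terms), collapse = ", ")))
  cat(sprintf("  %d rules, %s defuzzification\n", nrow(x$rules), x$defuzz))
  invisible(x)
}

validate_fuzzy_config <- function(config) {
  if (!inherits(config, "whdd_fuzzy_config")) {
    stop("`config` must be a whdd_fuzzy_config", call. = FALSE)
  }
  if (is.null(config$rules) || nrow(config$rules) == 0) {
    stop("fuzzy configuration has an empty rule table", call. = FALSE)
  }
  for (nm in names(config$inputs)) {
    terms <- config$inputs[[nm]]$terms
    used <- unique(config$rules[[nm]])
    bad <- setdiff(used, names(terms))
    if (length(bad)) {
      stop("rule table refers to unknown ", nm, " term(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad <- setdiff(unique(config$rules$risk), names(config$output$terms))
  if (length(bad)) {
    stop("rule table refers to unknown output term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

# Mamdani inference: min-AND firing, max aggregation, centroid defuzz.
# Returns the crisp risk on the output universe.
fuzzy_risk <- function(heart_rate, body_temp, gsr_delta, danger_coeff, config) {
  crisp <- list(heart_rate = heart_rate, body_temp = body_temp,
                gsr_delta = gsr_delta, danger_coeff = danger_coeff)
  mu <- lapply(names(config$inputs),
               function(nm) fuzzify(crisp[[nm]], config$inputs[[nm]]))
  names(mu) <- names(config$inputs)
  rules <- config$rules
  strength <- pmin(mu$heart_rate[rules$heart_rate],
                   mu$body_temp[rules$body_temp],
                   mu$gsr_delta[rules$gsr_delta],
                   mu$danger_coeff[rules$danger_coeff])
  # strongest firing per output term
  term_strength <- vapply(names(config$output$terms), function(tm) {
    s <- strength[rules$risk == tm]
    if (length(s)) max(s) else 0
  }, numeric(1))
  uni <- config$output$universe
  y <- seq(uni[1], uni[2], by = config$resolution)
  agg <- numeric(length(y))
  for (tm in names(config$output$terms)) {
    if (term_strength[[tm]] > 0) {
      agg <- pmax(agg, pmin(term_strength[[tm]],
                            mu_trap(y, config$output$terms[[tm]])))
    }
  }
  if (sum(agg) <= .Machine$double.eps) return(0)
  risk <- sum(y * agg) / sum(agg)
  min(max(risk, uni[1]), uni[2])
}

#' Alert level for a crisp risk value
#'
#' The 0--40 risk indicator is partitioned into Safe \[0, 10\], Attention
#' (10, 20\], Warning (20, 30\] and Dangerous (30, 40\]. The Warning and
#' Dangerous zones correspond to the device's alert and interdiction modes.
#'
#' @param risk Crisp risk value(s) in \[0, 40\].
#' @return Factor with levels Safe, Attention, Warning, Dangerous.
#' @examples
#' level_from_risk(c(0, 25, 31))
#' @export
level_from_risk <- function(risk) {
  if (any(!is.finite(risk)) || any(risk < 0) || any(risk > 40)) {
    stop("`risk` must lie in [0, 40]", call. = FALSE)
  }
  cut(risk, breaks = c(-Inf, 10, 20, 30, 40),
      labels = c("Safe", "Attention", "Warning", "Dangerous"))
}

#' Assess heat-stroke risk at one epoch
#'
#' Fuzzifies the four crisp inputs, fires the rule table (min-AND), clips
#' and aggregates the output terms (max) and defuzzifies by centroid to a
#' crisp risk indicator in \[0, 40\], then maps it to an alert level.
#'
#' @param inputs A [risk_inputs()].
#' @param config A [default_fuzzy_config()] or a user configuration of the
#'   same shape.
#' @param t_s Optional epoch time in seconds, carried into the result.
#' @return An object of class `whdd_risk_assessment` with fields `risk`,
#'   `level`, `inputs`, `t_s`.
#' @examples
#' assess_risk(risk_inputs(70, 36, 0, 20))
#' @export
assess_risk <- function(inputs, config = default_fuzzy_config(), t_s = NA_real_) {
  if (!inherits(inputs, "whdd_risk_inputs")) {
    stop("`inputs` must be a whdd_risk_inputs", call. = FALSE)
  }
  validate_fuzzy_config(config)
  risk <- fuzzy_risk(inputs$heart_rate, inputs$body_temp,
                     inputs$gsr_delta, inputs$danger_coeff, config)
  structure(list(risk = risk,
                 level = as.character(level_from_risk(risk)),
                 inputs = inputs, t_s = t_s),
            class = "whdd_risk_assessment")
}

#' @export
print.whdd_risk_assessment <- function(x, ...) {
  cat(sprintf("<whdd_risk_assessment> risk %.2f / 40 (%s)%s\n", x$risk, x$level,
              if (is.finite(x$t_s)) sprintf(" at t = %gs", x$t_s) else ""))
  cat(sprintf("  hr %.1f bpm, body temp %.2f degC, gsr delta %+.2f uS, danger %.2f\n",
              x$inputs$heart_rate, x$inputs$body_temp,
              x$inputs$gsr_delta, x$inputs$danger_coeff))
  invisible(x)
}

#' Risk surface over a heart-rate x body-temperature grid
#'
#' Evaluates the crisp risk over the Cartesian grid of heart rates and body
#' temperatures with the conductance change and environmental index held
#' fixed. Used to examine the controller's relative sensitivity: with the
#' default configuration the normalised slope along the heart-rate axis
#' exceeds the slope along the temperature axis.
#'
#' @param config Fuzzy configuration.
#' @param hr_grid Heart-rate values, bpm.
#' @param temp_grid Body-temperature values, degC.
#' @param fixed A [risk_inputs()] supplying `gsr_delta` and `danger_coeff`.
#' @return Numeric matrix of risks, `length(hr_grid)` rows (heart rate) by
#'   `length(temp_grid)` columns (temperature), with dimnames.
#' @export
sensitivity_surface <- function(config, hr_grid, temp_grid,
                                fixed = risk_inputs(70, 36, 0, 30)) {
  validate_fuzzy_config(config)
  out <- matrix(NA_real_, length(hr_grid), length(temp_grid),
                dimnames = list(hr = format(hr_grid), temp = format(temp_grid)))
  for (i in seq_along(hr_grid)) {
    for (j in seq_along(temp_grid)) {
      out[i, j] <- fuzzy_risk(hr_grid[i], temp_grid[j],
                              fixed$gsr_delta, fixed$danger_coeff, config)
    }
  }
  out
}

#' Write / read a fuzzy configuration as YAML
#'
#' @param config A `whdd_fuzzy_config`.
#' @param path File path.
#' @return `read_fuzzy_config()` returns a `whdd_fuzzy_config`;
#'   `write_fuzzy_config()` returns `path` invisibly.
#' @export
write_fuzzy_config <- function(config, path) {
  validate_fuzzy_config(config)
  doc <- list(
    inputs = lapply(config$inputs, function(inp)
      list(universe = inp$universe,
           terms = lapply(inp$terms, as.numeric))),
    output = list(universe = config$output$universe,
                  terms = lapply(config$output$terms, as.numeric)),
    rules = unname(apply(config$rules, 1, as.list)),
    defuzz = config$defuzz,
    resolution = config$resolution
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_fuzzy_config
#' @export
read_fuzzy_config <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(doc$rules, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  cfg <- structure(list(
    inputs = lapply(doc$inputs, function(inp)
      list(universe = as.numeric(inp$universe),
           terms = lapply(inp$terms, as.numeric))),
    output = list(universe = as.numeric(doc$output$universe),
                  terms = lapply(doc$output$terms, as.numeric)),
    rules = rules,
    defuzz = doc$defuzz,
    resolution = doc$resolution
  ), class = "whdd_fuzzy_config")
  validate_fuzzy_config(cfg)
}
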