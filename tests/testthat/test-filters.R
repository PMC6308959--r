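test_that("age-predicted maximum heart rate follows the Tanaka equation", {
  expect_equal(hr_max(26), 189.8)
  expect_equal(hr_max(26, rounded = TRUE), 190)
  expect_equal(hr_max(40), 180)
  expect_error(hr_max(0), "positive")
  expect_error(hr_max(-3), "positive")
})

test_that("threshold stage stores in-band readings and repeats the previous value otherwise", {
  cfg <- filter_config()
  cases <- list(list(value = 200, expected = 80),  # above band
                list(value = 120, expected = 120), # in band
                list(value = 49, expected = 80),   # below band
                list(value = 0, expected = 80))    # sensor failure
  for (cs in cases) {
    st <- hr_threshold_step(hr_filter_state(80, cfg), cs$value, cfg)
    expect_equal(st$value, cs$expected)
    expect_equal(st$state$count, 1L)
  }
})

test_that("error stage corrects out-of-band jumps and is the identity on the dead band", {
  cfg <- filter_config()
  run_one <- function(prev, value) {
    st <- hr_threshold_step(hr_filter_state(prev, cfg), value, cfg)
    hr_error_step(st$state, st$value, cfg)$value
  }
  expect_equal(run_one(100, 130), 130 - round(30 * 0.6))   # 112, high branch
  expect_equal(run_one(100, 80), 80 - round(-20 * 1.05))   # 101, low branch
  expect_equal(run_one(100, 110), 110)                     # dead band
  # property: identity whenever the step error lies in [-10, 25]
  set.seed(11)
  prev <- 100
  state <- hr_filter_state(prev, cfg)
  for (i in 1:50) {
    value <- max(50, min(190, prev + sample(-10:25, 1)))
    st <- hr_step(state, value, cfg)
    expect_equal(st$value, value)
    state <- st$state
    prev <- value
    if (state$full) state <- hr_window_mean(state)$state
  }
})

test_that("consecutive-error budgets hold the previous value and reset once exceeded", {
  cfg <- filter_config()
  state <- hr_filter_state(150, cfg)
  # each feed drops 20 bpm below the running value: every step trips the
  # low branch until the budget of 6 corrections is spent
  for (i in 1:6) {
    prev <- if (state$count == 0L) 150 else state$window[state$count]
    st <- hr_step(state, prev - 20, cfg)
    expect_equal(st$value, (prev - 20) - round(-20 * 1.05))
    state <- st$state
  }
  expect_equal(state$mincount, 6L)
  prev <- state$window[state$count]
  st <- hr_step(state, prev - 20, cfg)      # 7th: budget exhausted
  expect_equal(st$value, prev)
  expect_equal(st$state$mincount, 0L)
})

test_that("optional counter reset on dead-band errors clears the budgets", {
  cfg <- filter_config(reset_counters_on_normal = TRUE)
  state <- hr_filter_state(100, cfg)
  st <- hr_step(state, 80, cfg)      # low-branch trip
  expect_equal(st$state$mincount, 1L)
  st <- hr_step(st$state, st$value + 5, cfg)  # dead band
  expect_equal(st$state$mincount, 0L)
})

test_that("window mean equals a brute-force oracle and resets the window", {
  cfg <- passthrough_config()
  set.seed(21)
  values <- sample(50:190, 60, replace = TRUE)
  state <- hr_filter_state(values[1], cfg)
  for (v in values) state <- hr_step(state, v, cfg)$state
  expect_true(state$full)
  oracle <- sum(values) / 60
  wm <- hr_window_mean(state)
  expect_equal(wm$mean, oracle)
  expect_true(wm$mean >= min(values) && wm$mean <= max(values))
  expect_equal(wm$state$count, 0L)
  expect_equal(wm$state$prev, oracle)   # mean seeds the next window
  expect_error(hr_window_mean(wm$state), "not full")
})

test_that("window overflow without reset is a state error", {
  cfg <- filter_config()
  state <- hr_filter_state(70, cfg)
  for (i in 1:60) state <- hr_threshold_step(state, 70, cfg)$state
  expect_error(hr_threshold_step(state, 70, cfg), "overflow")
})

test_that("threshold-stage outputs stay within the band on arbitrary streams", {
  cfg <- filter_config()
  set.seed(31)
  raw <- sample(c(0, 30, 70, 120, 195, 250), 300, replace = TRUE)
  state <- hr_filter_state(75, cfg)
  for (v in raw) {
    st <- hr_threshold_step(state, v, cfg)
    expect_gte(st$value, 50)
    expect_lte(st$value, 190)
    state <- st$state
    if (state$full) state <- hr_window_mean(state)$state
  }
})

test_that("skin-to-core conversion applies the body-part gradient", {
  expect_equal(skin_to_core(34, 28, 0.7665), 38.599)
  expect_equal(skin_to_core(30, 30, 0.7665), 30)
  expect_equal(skin_to_core(33, 33, body_part_alpha("foot")), 33)
  expect_equal(body_part_alpha("hand"), 0.7665)
  expect_error(skin_to_core(34, 28, -1))
})

test_that("temperature compensation maps every input into [35, 40) and is continuous at 35", {
  expect_equal(temp_compensate(33), 36)
  expect_equal(temp_compensate(37), 37)
  expect_equal(temp_compensate(45), 36)
  expect_equal(temp_compensate(40), 36)      # exact 40 is the fallback
  expect_equal(temp_compensate(35), 35)      # both branches meet at 35
  expect_equal(temp_compensate(35 - 1e-9), 35, tolerance = 1e-6)
  # affine with slope -0.5 on the compensation band
  x <- seq(31, 35, by = 0.25)
  expect_equal(diff(temp_compensate(x)) / diff(x), rep(-0.5, length(x) - 1))
  # global range property
  set.seed(41)
  inputs <- c(runif(200, -10, 60), 30.999, 31, 35, 35.0001, 39.999, 40, 40.001)
  out <- temp_compensate(inputs)
  expect_true(all(out >= 35 & out < 40))
})

test_that("temperature hold rule stores only when the deviation changes", {
  cfg <- filter_config()
  state <- temp_filter_state(cfg)
  st <- temp_threshold_step(state, 33, cfg)     # deviation 2 != 0
  expect_equal(st$value, 36)
  expect_equal(st$state$temp_diff, 2)
  st2 <- temp_threshold_step(st$state, 33, cfg) # deviation unchanged: hold
  expect_equal(st2$value, 36)                   # previous slot repeated
  expect_equal(st2$state$temp_diff, 2)
  st3 <- temp_threshold_step(st2$state, 41, cfg)
  expect_equal(st3$value, 36)                   # fallback branch
  st4 <- temp_threshold_step(st3$state, 37.2, cfg)
  expect_equal(st4$value, 37.2)                 # identity band
})

test_that("temperature window mean matches a brute-force oracle", {
  cfg <- filter_config()
  state <- temp_filter_state(cfg)
  set.seed(51)
  cores <- runif(60, 35.5, 39.5)    # identity band: stored as-is
  for (v in cores) state <- temp_threshold_step(state, v, cfg)$state
  wm <- temp_window_mean(state)
  expect_equal(wm$mean, sum(cores) / 60)
  expect_true(wm$mean >= min(cores) && wm$mean <= max(cores))
  expect_error(temp_window_mean(wm$state), "not full")
})

test_that("full cascade is the identity on clean constant streams", {
  cfg <- filter_config()
  hr <- filter_heart_rate(rep(120, 180), relax_hr = 120, cfg)
  expect_true(all(hr$filtered == 120))
  expect_equal(hr$window_means, rep(120, 3))
  # constant skin temperature whose core estimate sits in the identity band
  skin <- rep(33.26, 180)
  core <- skin_to_core(33.26, 28, cfg$alpha)
  expect_true(core > 35 && core < 40)
  tp <- filter_temperature(skin, 28, cfg)
  expect_equal(tp$filtered, rep(core, 180))
  expect_equal(tp$window_means, rep(core, 3))
})

test_that("the cascade does not hurt under the simulator's artifact model", {
  s <- simulate_session(indoor_protocol(), runner_profile("u", 26),
                        artifact_model(seed = 7))
  f <- filter_heart_rate(s$observed$hr_bpm, s$runner$relax_hr)
  mad_raw <- mean(abs(s$observed$hr_bpm - s$latent$hr_bpm))
  mad_filtered <- mean(abs(f$filtered - s$latent$hr_bpm))
  expect_lte(mad_filtered, mad_raw)
})

test_that("filter config validates band continuity and serialises to YAML", {
  expect_error(filter_config(comp_band = c(31, 34)), "continuity")
  expect_equal(filter_config(age = 40)$hr_upper, 180)
  cfg <- filter_config(alpha = 0.5067, low_budget = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_filter_config(cfg, path)
  expect_equal(read_filter_config(path), cfg)
})
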