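test_that("the indoor protocol produces exactly 1800 epochs at 2 Hz", {
  p <- indoor_protocol()
  expect_equal(p$stages$speed_kmh, c(8, 10, 12))
  expect_equal(p$stages$duration_s, c(600, 120, 180))
  expect_equal(danger_coefficient(p$ambient_temp, p$humidity), 35.72)
  s <- simulate_session(p, runner_profile("u", 26))
  expect_equal(nrow(s$observed), 1800)
  expect_equal(nrow(s$latent), 1800)
  expect_equal(max(s$observed$t_s), 900)
})

test_that("the same seed reproduces bit-identical streams", {
  r <- runner_profile("u", 26)
  a <- simulate_session(indoor_protocol(), r, artifact_model(seed = 5))
  b <- simulate_session(indoor_protocol(), r, artifact_model(seed = 5))
  expect_identical(a$observed, b$observed)
  c <- simulate_session(indoor_protocol(), r, artifact_model(seed = 6))
  expect_false(identical(a$observed, c$observed))
})

test_that("disabling artifacts makes observation identical to latent truth", {
  s <- simulate_session(indoor_protocol(), runner_profile("u", 26),
                        no_artifacts())
  expect_equal(s$observed$hr_bpm, s$latent$hr_bpm)
  expect_equal(s$observed$skin_temp_c, s$latent$skin_temp_c)
  expect_equal(s$observed$gsr_us, s$latent$gsr_us)
})

test_that("latent dynamics respect their physiological bounds and ordering", {
  r <- runner_profile("u", age = 30, fitness = 0.9)
  s <- simulate_session(indoor_protocol(), r, no_artifacts())
  expect_true(all(s$latent$hr_bpm <= r$fitness * hr_max(r$age) + 1e-9))
  expect_true(all(s$latent$core_temp_c < 40))
  expect_true(all(diff(s$latent$core_temp_c) >= -1e-12))  # monotone rise
  expect_true(all(diff(s$latent$gsr_us) <= 1e-12))        # monotone decline
})

test_that("feedback fires at most once and only when a stage target crosses the threshold", {
  strained <- simulate_session(indoor_protocol(),
                               runner_profile("s", 23, fitness = 0.97,
                                              discomfort_hr_frac = 0.82),
                               no_artifacts())
  expect_equal(nrow(strained$events), 1)
  thr <- 0.82 * hr_max(23)
  expect_gt(max(strained$latent$hr_bpm), thr)
  first_above <- strained$latent$t_s[which(strained$latent$hr_bpm > thr)[1]]
  expect_equal(strained$events$t_s, first_above)
  comfortable <- simulate_session(indoor_protocol(),
                                  runner_profile("c", 25, fitness = 0.75,
                                                 discomfort_hr_frac = 0.95),
                                  no_artifacts())
  expect_equal(nrow(comfortable$events), 0)
})

test_that("cohorts are sized, aged and seeded as configured", {
  sessions <- make_cohort(indoor_cohort(), indoor_protocol(),
                          artifact_model(seed = 2))
  expect_length(sessions, 4)
  expect_equal(vapply(sessions, function(s) nrow(s$observed), numeric(1)),
               c(user1 = 1800, user2 = 1800, user3 = 1800, user4 = 1800))
  expect_equal(vapply(sessions, function(s) s$runner$age, numeric(1)),
               c(user1 = 25, user2 = 37, user3 = 23, user4 = 23))
  expect_equal(vapply(outdoor_cohort(), function(p) p$age, numeric(1)),
               c(37, 36, 24, 24, 24))
  out_p <- outdoor_protocol()
  expect_equal(danger_coefficient(out_p$ambient_temp, out_p$humidity), 31.5)
  dup <- list(runner_profile("a", 25), runner_profile("a", 30))
  expect_error(make_cohort(dup, indoor_protocol()), "duplicate")
})

test_that("filtering recovers the latent heart rate better than the raw stream", {
  s <- simulate_session(indoor_protocol(), runner_profile("u", 26),
                        artifact_model(seed = 9))
  f <- filter_heart_rate(s$observed$hr_bpm, s$runner$relax_hr)
  expect_lt(rmse(f$filtered, s$latent$hr_bpm),
            rmse(s$observed$hr_bpm, s$latent$hr_bpm))
})

test_that("the resting stream supports baseline acquisition", {
  r <- runner_profile("u", 26, relax_hr = 72, relax_gsr = 20)
  rest <- simulate_rest_stream(r, duration_s = 120,
                               artifacts = artifact_model(seed = 4))
  expect_equal(nrow(rest), 240)
  bl <- acquire_baselines(rest)
  expect_true(bl$hr_valid && bl$gsr_valid)
  expect_equal(bl$relax_hr, mean(rest$hr_bpm[1:120]))
})
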