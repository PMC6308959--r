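test_that("danger coefficient combines temperature and humidity", {
  expect_equal(danger_coefficient(23.5, 80), 31.5)
  expect_equal(danger_coefficient(28.9, 68.2), 35.72)
  expect_equal(danger_coefficient(0, 0), 0)
  expect_error(danger_coefficient(25, 101), "\\[0, 100\\]")
  expect_error(danger_coefficient(25, -1), "\\[0, 100\\]")
})

test_that("risk zones map totally and consistently onto alert levels", {
  expect_equal(as.character(level_from_risk(c(0, 5, 10))),
               rep("Safe", 3))
  expect_equal(as.character(level_from_risk(c(10.001, 20))),
               rep("Attention", 2))
  expect_equal(as.character(level_from_risk(c(25, 30))),
               rep("Warning", 2))
  expect_equal(as.character(level_from_risk(c(31, 40))),
               rep("Dangerous", 2))
  expect_error(level_from_risk(-0.1), "\\[0, 40\\]")
  expect_error(level_from_risk(40.1), "\\[0, 40\\]")
})

test_that("resting inputs are Safe and saturating inputs Dangerous", {
  resting <- assess_risk(risk_inputs(70, 36, 0, 20))
  expect_equal(resting$level, "Safe")
  expect_lte(resting$risk, 10)
  extreme <- assess_risk(risk_inputs(190, 39.5, -25, 36))
  expect_equal(extreme$level, "Dangerous")
  expect_gt(extreme$risk, 30)
  expect_lte(extreme$risk, 40)
})

test_that("crisp risk is always in [0, 40] over random admissible inputs", {
  cfg <- default_fuzzy_config()
  set.seed(71)
  for (i in 1:60) {
    ri <- risk_inputs(runif(1, 50, 200), runif(1, 35, 39.99),
                      runif(1, -30, 10), runif(1, 20, 45))
    r <- assess_risk(ri, cfg)$risk
    expect_gte(r, 0)
    expect_lte(r, 40)
  }
})

test_that("risk is non-decreasing in heart rate and body temperature", {
  cfg <- default_fuzzy_config()
  hr_grid <- seq(55, 198, by = 2.5)
  temp_grid <- seq(35.05, 39.95, by = 0.2)
  for (fixed in list(risk_inputs(70, 36, -5, 30),
                     risk_inputs(70, 36, -12, 35.72))) {
    s <- sensitivity_surface(cfg, hr_grid, temp_grid, fixed)
    expect_true(all(apply(s, 2, function(col) all(diff(col) >= -1e-9))))
    expect_true(all(apply(s, 1, function(row) all(diff(row) >= -1e-9))))
  }
})

test_that("heart-rate sensitivity exceeds temperature sensitivity centrally", {
  cfg <- default_fuzzy_config()
  hr_grid <- seq(90, 185, by = 5)
  temp_grid <- seq(36, 39.5, by = 0.25)
  s <- sensitivity_surface(cfg, hr_grid, temp_grid,
                           fixed = risk_inputs(70, 36, -5, 35.72))
  hr_span <- diff(range(hr_grid)) / diff(cfg$inputs$heart_rate$universe)
  temp_span <- diff(range(temp_grid)) / diff(cfg$inputs$body_temp$universe)
  sens_hr <- mean(abs(diff(s))) * (length(hr_grid) - 1) / hr_span
  sens_temp <- mean(abs(t(diff(t(s))))) * (length(temp_grid) - 1) / temp_span
  expect_gt(sens_hr, sens_temp)
})

test_that("a single always-firing rule yields a flat surface", {
  cfg <- default_fuzzy_config()
  for (nm in names(cfg$inputs)) {
    u <- cfg$inputs[[nm]]$universe
    cfg$inputs[[nm]]$terms <- list(any = c(u[1], u[1], u[2], u[2]))
  }
  cfg$rules <- data.frame(heart_rate = "any", body_temp = "any",
                          gsr_delta = "any", danger_coeff = "any",
                          risk = "attention", stringsAsFactors = FALSE)
  s <- sensitivity_surface(cfg, c(80, 120, 160), c(36, 37.5, 39))
  expect_equal(max(s) - min(s), 0)
})

test_that("an input with no firing rule defuzzifies to risk 0, level Safe", {
  cfg <- default_fuzzy_config()
  cfg$rules <- cfg$rules[cfg$rules$heart_rate == "high" &
                           cfg$rules$body_temp == "high", ]
  out <- assess_risk(risk_inputs(70, 36, 0, 20), cfg)
  expect_equal(out$risk, 0)
  expect_equal(out$level, "Safe")
})

test_that("configuration errors are caught", {
  cfg <- default_fuzzy_config()
  cfg$rules <- cfg$rules[0, ]
  expect_error(assess_risk(risk_inputs(70, 36, 0, 20), cfg), "empty rule")
  cfg2 <- default_fuzzy_config()
  cfg2$rules$risk[1] <- "lethal"
  expect_error(assess_risk(risk_inputs(70, 36, 0, 20), cfg2), "unknown output")
  expect_error(risk_inputs(0, 36, 0, 20), "positive")
  expect_error(risk_inputs(70, 40, 0, 20), "\\[35, 40\\)")
  expect_error(risk_inputs(70, Inf, 0, 20), "finite")
})

test_that("membership degrees lie in [0, 1] across each universe", {
  cfg <- default_fuzzy_config()
  for (nm in names(cfg$inputs)) {
    u <- cfg$inputs[[nm]]$universe
    xs <- seq(u[1], u[2], length.out = 101)
    for (term in cfg$inputs[[nm]]$terms) {
      mu <- whdd:::mu_trap(xs, term)
      expect_true(all(mu >= 0 & mu <= 1))
    }
  }
})

test_that("fuzzy configuration survives a YAML round trip", {
  cfg <- default_fuzzy_config(relax_hr = 64, age = 31)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fuzzy_config(cfg, path)
  cfg2 <- read_fuzzy_config(path)
  set.seed(81)
  for (i in 1:10) {
    ri <- risk_inputs(runif(1, 55, 195), runif(1, 35.1, 39.9),
                      runif(1, -28, 8), runif(1, 21, 44))
    expect_equal(assess_risk(ri, cfg2)$risk, assess_risk(ri, cfg)$risk)
  }
})
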