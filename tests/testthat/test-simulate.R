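test_that("zero-amplitude moderate streams sit exactly at the centers", {
  regime <- environment_regime(amplitude = list(
    temperature = 0, noise = 0, brightness = 0, humidity = 0, pressure = 0
  ))
  env <- simulate_environment(regime, 30, seed = 1)
  expect_equal(unique(env$temp_c), 26)
  expect_equal(unique(env$noise_db), 60)
  expect_equal(unique(env$brightness_lx), 400)
})

test_that("extreme-high brightness lands where the risk engine reads High", {
  regime <- environment_regime(
    brightness = "extreme-high",
    amplitude = list(
      temperature = 0, noise = 0, brightness = 0,
      humidity = 0, pressure = 0
    )
  )
  env <- simulate_environment(regime, 5, seed = 1)
  expect_equal(unique(env$brightness_lx), 750)
  ctrl <- load_fuzzy_controllers()$brightness
  deg <- fuzzify(ctrl$variables$stimulus, 750)
  expect_equal(names(deg)[which.max(deg)], "High")
})

test_that("environment simulation is deterministic under a fixed seed", {
  regime <- environment_regime()
  expect_identical(
    simulate_environment(regime, 50, seed = 7),
    simulate_environment(regime, 50, seed = 7)
  )
  expect_error(environment_regime(noise = "blaring"),
    class = "sensoryrisk_validation_error"
  )
})

test_that("latent labels follow the protocol scheme with physiology at baseline", {
  cfg <- simulation_config(
    n_children = 1, sessions_per_child = 1, session_length = 60,
    label_noise = 0,
    gains = list(
      gsr_stress = 0, hr_stress = 0, accel_stress = 0,
      gsr_attention = 0, hr_attention = 0, accel_attention = 0
    ),
    phys_noise = list(gsr = 0, hr = 0, accel = 0)
  )
  s <- simulate_child_session(flat_profile(), environment_regime(),
    activity = "relaxing", config = cfg, seed = 3
  )
  latent <- attr(s, "latent")
  expect_equal(latent$stress, "low")
  expect_equal(unique(s$records$gsr), 200)
  expect_equal(unique(s$records$hr_bpm), 90)

  extreme <- environment_regime(noise = "extreme-high")
  s2 <- simulate_child_session(flat_profile(), extreme,
    activity = "task", config = cfg, seed = 3
  )
  expect_equal(attr(s2, "latent")$stress, "high")
})

test_that("sessions are reproducible and GSR responds monotonically to its gain", {
  cfg <- simulation_config(session_length = 60, label_noise = 0)
  reg <- environment_regime(temperature = "extreme-high")
  a <- simulate_child_session(flat_profile(), reg, "task", cfg, seed = 5)
  b <- simulate_child_session(flat_profile(), reg, "task", cfg, seed = 5)
  expect_identical(a$records, b$records)

  gains_hi <- cfg$gains
  gains_hi$gsr_stress <- 120
  cfg_hi <- simulation_config(
    session_length = 60, label_noise = 0,
    gains = gains_hi
  )
  hi <- simulate_child_session(flat_profile(), reg, "task", cfg_hi, seed = 5)
  expect_gt(mean(hi$records$gsr), mean(a$records$gsr))
})

test_that("generate_dataset writes the full session grid plus manifest", {
  out <- withr::local_tempdir()
  cfg <- simulation_config(
    n_children = 4, sessions_per_child = 3, session_length = 60,
    labelled_fraction = 1, label_noise = 0, seed = 2
  )
  ds <- generate_dataset(cfg, out_dir = out)
  expect_length(ds$sessions, 12)
  expect_equal(length(list.files(out, pattern = "\\.csv$")), 12)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(ds$manifest$n_labelled, 12)
  # every session carries assessor labels at labelled_fraction 1
  expect_true(all(!is.na(ds$dataset$assessor_attention)))
})

test_that("the labelled fraction matches its binomial expectation", {
  cfg <- simulation_config(
    n_children = 12, sessions_per_child = 12, session_length = 60,
    labelled_fraction = 222 / 521, seed = 4
  )
  ds <- generate_dataset(cfg)
  frac <- ds$manifest$n_labelled / ds$manifest$n_sessions
  p <- 222 / 521
  tol <- 3 * sqrt(p * (1 - p) / 144)
  expect_lt(abs(frac - p), tol)
})

test_that("the full generation pipeline is deterministic", {
  cfg <- simulation_config(
    n_children = 3, sessions_per_child = 3, session_length = 60, seed = 10
  )
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$dataset, d2$dataset)

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = out1)
  generate_dataset(cfg, out_dir = out2)
  f1 <- list.files(out1, full.names = TRUE)
  f2 <- list.files(out2, full.names = TRUE)
  expect_identical(
    lapply(f1, readLines), lapply(f2, readLines)
  )
})
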