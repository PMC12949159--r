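# Generator contracts: validation, determinism, noise-free limits, truth
# structure, and the raw carriers.

test_that("sim_config validates its invariants", {
  expect_s3_class(default_cfg(), "sim_config")
  expect_error(sim_config(af_rate = -1), class = "mcpet_validation_error")
  expect_error(sim_config(baseline_efforts = c(0, 0.5, 0.75, 1)),
               class = "mcpet_validation_error")
  expect_error(sim_config(baseline_efforts = c(0.5, 1.2, 0.7, 0.9)),
               class = "mcpet_validation_error")
  expect_error(sim_config(bout_gap_s = 10), class = "mcpet_validation_error")
  # non-positive true slope rejected
  expect_error(sim_config(true_intercept = 200, p_iso_max_floor = 150),
               class = "mcpet_validation_error")
})

test_that("identical (config, seed) gives bit-identical outputs at every stage", {
  cfg <- default_cfg()
  s1 <- generate_baseline_session(cfg, 7, emit = "raw")
  s2 <- generate_baseline_session(cfg, 7, emit = "raw")
  expect_identical(s1, s2)
  t1 <- quiet(generate_constant_power_trial(cfg, "resistance", 7, emit = "raw"))
  t2 <- quiet(generate_constant_power_trial(cfg, "resistance", 7, emit = "raw"))
  expect_identical(t1, t2)
  # and a different seed gives different noise
  s3 <- generate_baseline_session(cfg, 8)
  expect_false(identical(s1$bouts, s3$bouts))
})

test_that("noise-free limit: fitted r^2 is exactly 1 and truth is recovered", {
  cfg <- noise_free_cfg()
  ses <- generate_baseline_session(cfg, 3)
  fit <- process_baseline_session(ses, cfg)$fit
  expect_identical(fit$r_squared, 1)
  expect_equal(fit$slope, ses$truth$true_slope, tolerance = 1e-9)
  expect_equal(fit$intercept, ses$truth$true_intercept, tolerance = 1e-6)
})

test_that("generated EMG traces honour the envelope-peak contract", {
  cfg <- default_cfg()
  # zero amplitude -> envelope below 1% of full scale
  tr0 <- generate_emg_trace(rep(0, 3), cfg, seed = 1, carrier = "noise")
  expect_lt(max(rms_envelope(tr0, 200)$values), 0.01 * max(cfg$emg_visit_max_mv))

  # amplitudes a and 2a: recovered per-revolution RMS peak ratio = 2 +/- 5%
  # through the full sigproc path (filter + envelope + segmentation)
  a <- 0.3
  crank <- generate_crank_signal(100, 70, cfg, duration_s = 2 * 60 / 70)
  for (carrier in c("noise", "sine")) {
    tr <- generate_emg_trace(c(a, 2 * a), cfg, seed = 5, carrier = carrier)
    bp <- bout_revolution_peaks(crank, list(tr, tr, tr, tr))
    ratio <- unname(bp$peaks[2, 1] / bp$peaks[1, 1])
    tol <- if (carrier == "noise") 0.05 else 0.005
    expect_equal(ratio, 2, tolerance = tol)
    # absolute recovery too (proportionality constant is 1)
    expect_equal(unname(bp$peaks[1, 1]), a,
                 tolerance = if (carrier == "noise") 0.05 * a else 0.005 * a)
  }

  # fixed seed -> identical trace
  expect_identical(generate_emg_trace(c(a, a), cfg, seed = 9, carrier = "noise"),
                   generate_emg_trace(c(a, a), cfg, seed = 9, carrier = "noise"))
  expect_error(generate_emg_trace(c(-1, 1), cfg), class = "mcpet_validation_error")
})

test_that("generated crank signals advance in 2-degree steps and match power", {
  cfg <- default_cfg()
  crank <- generate_crank_signal(200, 70, cfg, duration_s = 6)
  expect_true(all(diff(crank$angle_deg) == 2))
  expect_equal(nrow(segment_revolutions(crank)), 7)

  # zero power -> all torque samples zero
  crank0 <- generate_crank_signal(0, 70, cfg, duration_s = 3)
  expect_true(all(crank0$torque_left_nm == 0))

  # cadence 0 with power > 0 is an error
  expect_error(generate_crank_signal(100, 0, cfg, duration_s = 3),
               class = "mcpet_validation_error")
})

test_that("constant-power trials respect condition timing and truth invariants", {
  cfg <- default_cfg()
  ctrl <- quiet(generate_constant_power_trial(cfg, "control", 11))
  res <- quiet(generate_constant_power_trial(cfg, "resistance", 11))
  iso <- quiet(generate_constant_power_trial(cfg, "isotime_control", 11))

  # resistance time = control draw x factor; isotime-control truncated there
  expect_equal(res$record$tolerance_s,
               ctrl$record$tolerance_s * cfg$resistance_time_factor,
               tolerance = 1e-9)
  expect_equal(iso$record$tolerance_s, res$record$tolerance_s, tolerance = 1e-9)
  expect_true(iso$record$truncated)
  expect_identical(iso$truth$true_tolerance_time, ctrl$record$tolerance_s)

  # same participant parameters across conditions
  expect_identical(ctrl$record$task_power_w, res$record$task_power_w)
  expect_identical(ctrl$truth$true_slope, res$truth$true_slope)

  # truth structure: fraction starts at 1 and never increases; deficit
  # starts at 0 and never decreases; IRV declines faster with resistance
  tt <- seq(0, ctrl$record$tolerance_s, length.out = 50)
  frac <- ctrl$truth$max_emg_fraction(tt)
  expect_equal(frac[1], 1)
  expect_true(all(diff(frac) <= 0))
  dfc <- ctrl$truth$muscle_deficit(tt)
  expect_identical(dfc[1], 0)
  expect_true(all(diff(dfc) >= 0))
  t_iso <- res$record$tolerance_s
  expect_lt(res$truth$irv(t_iso), ctrl$truth$irv(t_iso))

  # truth sidecar has the documented columns
  expect_named(res$truth_table, c("time_s", "true_max_emg_fraction",
                                  "true_muscle_deficit_w", "true_irv_l"))

  # intolerance detectable in control/resistance, absent in truncated trial
  expect_false(is.na(detect_intolerance(ctrl$cadence)))
  expect_true(is.na(detect_intolerance(iso$cadence)))
  expect_lte(abs(detect_intolerance(ctrl$cadence) - ctrl$record$tolerance_s), 1)
})

test_that("no-fatigue limit: end isokinetic power equals the baseline maximum", {
  cfg <- noise_free_cfg(af_rate = 0, mf_rate = 0)
  tr <- quiet(generate_constant_power_trial(cfg, "control", 4))
  expect_equal(tr$end_bout$power_w, tr$truth$p_iso_max, tolerance = 1e-9)
  expect_identical(tr$end_bout$fr_true, 1)
})

test_that("tolerance draws below the floor are redrawn, with a log", {
  cfg <- default_cfg(tolerance_mean_control = 80, tolerance_sd_control = 40)
  expect_message(
    tt <- draw_tolerance_times(cfg, 200, "control", seed = 3),
    "redraw"
  )
  expect_true(all(tt > cfg$tolerance_floor_s))
})
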