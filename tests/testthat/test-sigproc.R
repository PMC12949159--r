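# EMG conditioning, revolution segmentation, power, peaks, selection and the
# composite fractional EMG.

test_that("band-pass filter matches closed-form Butterworth behaviour", {
  # DC is rejected by the high-pass edge
  dc <- emg_trace(rep(1, 4000))
  expect_lt(max(abs(bandpass_filter(dc)$samples)), 0.01)

  # mid-band passes at unit gain (>= 0.99), deep stop-band at 2 Hz (<= 0.05);
  # forward-backward application squares the magnitude response
  expect_gte(mid_amplitude(bandpass_filter(sine_trace(100))$samples), 0.99)
  expect_lte(mid_amplitude(bandpass_filter(sine_trace(2, duration = 6))$samples), 0.05)

  # closed-form single-pass magnitude at the edges is 1/sqrt(2)
  co <- butter_bandpass(4, 10, 500, fs = 2000)
  gain <- function(f) {
    z <- exp(1i * 2 * pi * f / 2000)
    abs(sum(co$b * z^-(seq_along(co$b) - 1)) / sum(co$a * z^-(seq_along(co$a) - 1)))
  }
  expect_equal(gain(10), 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(gain(500), 1 / sqrt(2), tolerance = 1e-6)
  expect_gte(gain(100), 0.999)

  # an upper edge at/above Nyquist is clipped with a warning
  expect_warning(butter_bandpass(4, 10, 1000, fs = 2000), "Nyquist")
  # refiltering is a contract violation
  expect_error(bandpass_filter(bandpass_filter(sine_trace(100))),
               class = "mcpet_validation_error")
})

test_that("filter + RMS on a mid-band sinusoid of amplitude a gives ~ a/sqrt(2)", {
  for (a in c(0.5, 2)) {
    tr <- bandpass_filter(sine_trace(150, amplitude = a))
    env <- rms_envelope(tr, window = 200)
    expect_equal(mid_amplitude(env$values), a / sqrt(2), tolerance = 1e-3)
  }
})

test_that("rms_envelope matches its definition", {
  # constant input: |c| after warm-up; alternating +a/-a: exactly a
  expect_equal(rms_envelope(rep(-3, 500), 200)[200:500], rep(3, 301))
  expect_equal(rms_envelope(rep(c(2, -2), 250), 10), rep(2, 500))

  # ramp against the brute-force loop oracle, including the partial windows
  x <- as.numeric(1:400)
  env <- rms_envelope(x, 200)
  expect_equal(env, brute_rms(x, 200), tolerance = 1e-12)
  expect_equal(env[400], sqrt(mean((201:400)^2)))

  expect_error(rms_envelope(numeric(0), 10), class = "mcpet_validation_error")
  expect_error(rms_envelope(1:10, 11), class = "mcpet_validation_error")
})

test_that("segment_revolutions counts and characterizes revolutions", {
  cfg <- noise_free_cfg()
  # 70 rpm for 6 s -> 7 complete revolutions at 70 rpm
  crank <- generate_crank_signal(150, 70, cfg, duration_s = 6)
  revs <- segment_revolutions(crank)
  expect_equal(nrow(revs), 7)
  expect_equal(revs$mean_cadence, rep(70, 7), tolerance = 1e-4)
  expect_true(all(abs(revs$left_power - 150) < 0.1))

  # 60 rpm for 5 s -> 5 revolutions
  expect_equal(nrow(segment_revolutions(generate_crank_signal(100, 60, cfg,
                                                              duration_s = 5))), 5)

  # cadence step 70 -> 35 doubles revolution durations after the step
  crank2 <- generate_crank_signal(100, function(t) ifelse(t < 3, 70, 35),
                                  cfg, duration_s = 10)
  revs2 <- segment_revolutions(crank2)
  dur <- revs2$end_time - revs2$start_time
  expect_equal(dur[1], 60 / 70, tolerance = 1e-9)
  expect_equal(dur[nrow(revs2)] / dur[1], 2, tolerance = 1e-9)

  # less than one revolution -> empty
  short <- crank_signal(time_s = (0:89) / 210, angle_deg = seq(0, 178, by = 2),
                        torque_left_nm = rep(1, 90), torque_right_nm = rep(1, 90),
                        omega_rad_s = rep(7.33, 90), mode = rep("isokinetic", 90))
  expect_equal(nrow(segment_revolutions(short)), 0)
})

test_that("instantaneous power is the element-wise product with guards", {
  expect_equal(instantaneous_power(0, 7.33), 0)
  expect_equal(instantaneous_power(50, 70 * 2 * pi / 60), 366.519, tolerance = 1e-3)
  expect_error(instantaneous_power(1:3, 1:2), class = "mcpet_validation_error")

  # revolution-mean of torque x angular velocity reproduces the profile power
  cfg <- noise_free_cfg()
  crank <- generate_crank_signal(200, 70, cfg, duration_s = 6)
  revs <- segment_revolutions(crank)
  p <- instantaneous_power(crank$torque_left_nm, crank$omega_rad_s)
  for (r in seq_len(nrow(revs))) {
    sel <- crank$time_s >= revs$start_time[r] & crank$time_s < revs$end_time[r]
    expect_equal(mean(p[sel]), 200, tolerance = 0.1)
  }
})

test_that("revolution_peak_emg returns the in-span maximum", {
  rev <- data.frame(start_time = 0.5, end_time = 1.5)
  const <- rms_envelope(emg_trace(rep(2, 4000)), 200)
  expect_equal(revolution_peak_emg(const, rev), 2)

  # two-burst revolution: the larger burst plateau wins
  x <- numeric(4000)
  x[1200:1500] <- 1.5 * sqrt(2) * sin(2 * pi * 150 * (1200:1500) / 2000)
  x[2200:2500] <- 3.0 * sqrt(2) * sin(2 * pi * 150 * (2200:2500) / 2000)
  env <- rms_envelope(emg_trace(x), 200)
  expect_equal(revolution_peak_emg(env, rev), 3, tolerance = 0.01)

  expect_error(revolution_peak_emg(const, data.frame(start_time = 5, end_time = 6)),
               class = "mcpet_validation_error")
})

test_that("isokinetic revolution selection follows the 5% window and power tie-breaks", {
  # spec worked example: {62, 69, 70, 71, 70} with 5% window 66.5-73.5
  revs <- make_revs(c(62, 69, 70, 71, 70))
  expect_equal(select_isokinetic_revolutions(revs), c(2, 3, 4))

  # equal cadences: the run with the highest mean power; ties -> earliest
  revs2 <- make_revs(rep(70, 6), power = c(100, 100, 100, 300, 300, 300))
  expect_equal(select_isokinetic_revolutions(revs2), c(4, 5, 6))
  revs3 <- make_revs(rep(70, 6), power = rep(100, 6))
  expect_equal(select_isokinetic_revolutions(revs3), c(1, 2, 3))

  # none qualify -> error naming the best near-miss
  expect_error(select_isokinetic_revolutions(make_revs(rep(60, 5))),
               "near-miss", class = "mcpet_validation_error")
  # non-isokinetic revolutions never qualify
  expect_error(select_isokinetic_revolutions(make_revs(rep(70, 5), iso = rep(FALSE, 5))),
               class = "mcpet_validation_error")
})

test_that("selection equals the exhaustive-scan oracle on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:20, 1)
    revs <- make_revs(
      cadence = runif(n, 60, 80),
      power = runif(n, 50, 400),
      iso = sample(c(TRUE, TRUE, TRUE, FALSE), n, replace = TRUE)
    )
    oracle <- brute_select(revs, 70, 0.05)
    if (is.null(oracle)) {
      expect_error(select_isokinetic_revolutions(revs),
                   class = "mcpet_validation_error")
    } else {
      expect_equal(select_isokinetic_revolutions(revs), oracle)
    }
  }
})

test_that("composite fractional EMG normalizes per muscle then averages", {
  expect_equal(composite_fr_emg(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(composite_fr_emg(c(0.8, 0.6, 1.0, 0.6), rep(1, 4)), 0.75)
  # permutation symmetry
  p <- c(0.3, 0.5, 0.2, 0.9)
  v <- c(0.5, 0.6, 0.4, 1.0)
  o <- sample(4)
  expect_equal(composite_fr_emg(p, v), composite_fr_emg(p[o], v[o]))
  expect_error(composite_fr_emg(p, c(0, 1, 1, 1)), class = "mcpet_validation_error")

  # in (0, 1] whenever the visit maxima cover the bout
  set.seed(7)
  for (i in 1:20) {
    peaks <- matrix(runif(20, 0.05, 1), ncol = 4)
    vmax <- visit_maxima(list(peaks))
    fr <- apply(peaks, 1, composite_fr_emg, visit_max_per_muscle = vmax)
    expect_true(all(fr > 0 & fr <= 1 + 1e-12))
  }
})

test_that("isokinetic_result pairs three-revolution power with fractional EMG", {
  cfg <- noise_free_cfg()
  bout <- max_effort_bout(342, cfg)
  res <- isokinetic_result(bout$crank, bout$traces, bout$visit_max)
  expect_equal(res$p_iso_single_leg, 342, tolerance = 0.1)
  expect_equal(res$p_iso_chainring, 684, tolerance = 0.2)
  expect_equal(res$fr_emg, 1, tolerance = 1e-3)
  expect_length(res$revolutions_used, 3)

  # doubling all torques doubles P_iso and leaves fractional EMG unchanged
  crank2 <- bout$crank
  crank2$torque_left_nm <- 2 * crank2$torque_left_nm
  crank2$torque_right_nm <- 2 * crank2$torque_right_nm
  res2 <- isokinetic_result(crank2, bout$traces, bout$visit_max)
  expect_equal(res2$p_iso_single_leg, 2 * res$p_iso_single_leg, tolerance = 1e-9)
  expect_equal(res2$fr_emg, res$fr_emg, tolerance = 1e-12)

  # chainring power is exactly twice single-leg, always
  expect_identical(res$p_iso_chainring, 2 * res$p_iso_single_leg)
  expect_identical(res2$p_iso_chainring, 2 * res2$p_iso_single_leg)

  # near-zero effort -> near-zero P_iso
  low <- max_effort_bout(0.5, cfg)
  res0 <- isokinetic_result(low$crank, low$traces, low$visit_max)
  expect_lt(res0$p_iso_single_leg, 1)
})
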