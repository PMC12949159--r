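# Shared fixtures and independent oracles. All fixtures are built in code;
# oracles are deliberately brute-force and independent of the implementation
# paths they check.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

default_cfg <- function(...) quiet(sim_config(...))

noise_free_cfg <- function(...) {
  quiet(sim_config(baseline_r2_noise = 0, ic_noise_sd = 0,
                   end_effort_noise = 0, ...))
}

# pure sinusoid as an emg_trace
sine_trace <- function(freq, amplitude = 1, duration = 2, rate = 2000,
                       muscle = "vastus_lateralis") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  emg_trace(amplitude * sin(2 * pi * freq * t), rate = rate, muscle = muscle)
}

# steady-state amplitude of a filtered sinusoid, ignoring edge transients
mid_amplitude <- function(x) {
  n <- length(x)
  max(abs(x[seq(round(n / 3), round(2 * n / 3))]))
}

# brute-force trailing RMS (loop definition, independent of cumsum trick)
brute_rms <- function(x, window) {
  vapply(seq_along(x), function(i) {
    lo <- max(1, i - window + 1)
    sqrt(mean(x[lo:i]^2))
  }, numeric(1))
}

# brute-force 3-revolution window selection oracle
brute_select <- function(revs, target_rpm, tol) {
  best <- NULL
  best_power <- -Inf
  for (s in seq_len(max(nrow(revs) - 2, 0))) {
    idx <- revs$index[s:(s + 2)]
    if (!all(diff(idx) == 1)) next
    if (!all(revs$isokinetic[s:(s + 2)])) next
    if (!all(abs(revs$mean_cadence[s:(s + 2)] - target_rpm) / target_rpm <= tol)) next
    p <- mean(revs$left_power[s:(s + 2)])
    if (p > best_power + 1e-12) {
      best_power <- p
      best <- idx
    }
  }
  best
}

# simple revolutions table for selection tests
make_revs <- function(cadence, power = rep(100, length(cadence)),
                      iso = rep(TRUE, length(cadence))) {
  n <- length(cadence)
  data.frame(
    index = seq_len(n), start_time = seq_len(n) - 1, end_time = seq_len(n),
    mean_cadence = cadence, left_power = power, right_power = power,
    isokinetic = iso
  )
}

# one maximal-effort synthetic bout (crank + 4 traces) at a given single-leg
# power, fr = 1, noise-free sine carrier
max_effort_bout <- function(power_w, cfg = noise_free_cfg(), n_rev = 6) {
  amps <- outer(rep(1, n_rev), cfg$emg_visit_max_mv)
  colnames(amps) <- names(cfg$emg_visit_max_mv)
  crank <- generate_crank_signal(power_w, cfg$cadence_target, cfg,
                                 duration_s = n_rev * 60 / cfg$cadence_target)
  traces <- lapply(names(cfg$emg_visit_max_mv), function(m) {
    generate_emg_trace(amps[, m], cfg, seed = 1, carrier = "sine", muscle = m)
  })
  names(traces) <- names(cfg$emg_visit_max_mv)
  list(crank = crank, traces = traces, visit_max = cfg$emg_visit_max_mv)
}
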