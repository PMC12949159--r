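# Synthetic baseline sessions and constant-power trials with known ground
# truth. The generator states a world: linear EMG-power coupling with
# multiplicative per-revolution noise, linearly growing activation and
# muscle fatigue, condition-dependent tolerance times, and a linear IRV
# decline that is faster under expiratory resistance. Every downstream stage
# can be validated against the emitted truth.

CONDITIONS <- c("control", "resistance", "isotime_control")

condition_index <- function(condition) match(condition, CONDITIONS)

# Participant-level quantities shared by every visit of one participant.
# Drawn in a fixed order from `participant_seed` so that all conditions see
# identical participant parameters. Non-physiological draws are redrawn from
# the continuing stream (logged).
draw_participant_params <- function(config, participant_seed) {
  with_seed(participant_seed, {
    redraw <- function(mean, sd, floor, what) {
      n_redraws <- 0L
      repeat {
        x <- rnorm(1, mean, sd)
        if (x > floor) break
        n_redraws <- n_redraws + 1L
        message(sprintf("redraw %d of %s (drew %.1f <= floor %.1f)",
                        n_redraws, what, x, floor))
      }
      list(value = x, n_redraws = n_redraws)
    }
    p_max <- redraw(config$p_iso_max_mean, config$p_iso_max_sd,
                    config$p_iso_max_floor, "baseline maximal power")
    # task power tracks capacity (the protocol sets it from the individual's
    # ramp test); residual SD chosen so the cohort SD stays ~ task_power_sd
    scale <- p_max$value / config$p_iso_max_mean
    coupled_sd <- config$task_capacity_coupling * config$task_power_mean *
      config$p_iso_max_sd / config$p_iso_max_mean
    resid_sd <- sqrt(max(config$task_power_sd^2 - coupled_sd^2,
                         (0.1 * config$task_power_sd)^2))
    task <- redraw(config$task_power_mean *
                     (1 + config$task_capacity_coupling * (scale - 1)),
                   resid_sd, 60, "task power")
    t_ctrl <- redraw(config$tolerance_mean_control, config$tolerance_sd_control,
                     config$tolerance_floor_s, "tolerance time")
    vo2 <- redraw(config$vo2peak_mean, config$vo2peak_sd, 1.5, "VO2peak")
    slope <- p_max$value - config$true_intercept
    if (slope <= 0) {
      stop_validation("non-positive true EMG-power slope for this participant")
    }
    list(
      p_iso_max = p_max$value,
      slope = slope,
      capacity_scale = scale,
      intercept = config$true_intercept,
      task_power_w = task$value,
      t_control = t_ctrl$value,
      vo2peak = vo2$value,
      n_redraws = p_max$n_redraws + task$n_redraws + t_ctrl$n_redraws +
        vo2$n_redraws
    )
  })
}

#' Draw tolerance times from the generator's distribution
#'
#' Control times are Normal(`tolerance_mean_control`,
#' `tolerance_sd_control`), redrawn while at or below the floor;
#' resistance times are the same participant's control draw multiplied by
#' `resistance_time_factor`.
#'
#' @param config A [sim_config()].
#' @param n Number of participants to draw.
#' @param condition `"control"` or `"resistance"`.
#' @param seed RNG seed for the draw.
#' @return Numeric vector of `n` tolerance times (s).
#' @export
draw_tolerance_times <- function(config, n, condition = c("control", "resistance"),
                                 seed = config$seed) {
  condition <- match.arg(condition)
  check_number(n, "n", min = 1)
  with_seed(seed, {
    t <- rnorm(n, config$tolerance_mean_control, config$tolerance_sd_control)
    while (any(bad <- t <= config$tolerance_floor_s)) {
      message(sprintf("redrawing %d tolerance time(s) at or below %.0f s",
                      sum(bad), config$tolerance_floor_s))
      t[bad] <- rnorm(sum(bad), config$tolerance_mean_control,
                      config$tolerance_sd_control)
    }
    if (condition == "resistance") t <- t * config$resistance_time_factor
    t
  })
}

# Ground truth container ------------------------------------------------

make_truth <- function(params, config, af_rate = 0, mf_rate = 0,
                       tolerance = NA_real_, termination = NA_real_,
                       irv_rate = 0) {
  slope <- params$slope
  frac_floor <- 0.02
  max_emg_fraction <- function(t) pmax(1 - af_rate * pmax(t, 0) / slope, frac_floor)
  muscle_deficit <- function(t) mf_rate * pmax(t, 0)
  irv <- function(t) pmax(config$irv_baseline - irv_rate * pmax(t, 0), 0.05)
  structure(
    list(
      true_slope = slope,
      true_intercept = params$intercept,
      p_iso_max = params$p_iso_max,
      af_rate = af_rate, mf_rate = mf_rate,
      true_tolerance_time = tolerance,
      termination_s = termination,
      max_emg_fraction = max_emg_fraction,
      muscle_deficit = muscle_deficit,
      irv = irv
    ),
    class = "synthetic_truth"
  )
}

#' Ground-truth sidecar table
#'
#' @param truth A `synthetic_truth` object.
#' @param times Evaluation times (s); defaults to every 10 s up to the
#'   termination time when known.
#' @return Data frame with columns `time_s`, `true_max_emg_fraction`,
#'   `true_muscle_deficit_w`, `true_irv_l`.
#' @export
truth_sidecar <- function(truth, times = NULL) {
  if (is.null(times)) {
    end <- if (is.finite(truth$termination_s)) truth$termination_s else 600
    times <- unique(c(seq(0, end, by = 10), end))
  }
  data.frame(
    time_s = times,
    true_max_emg_fraction = truth$max_emg_fraction(times),
    true_muscle_deficit_w = truth$muscle_deficit(times),
    true_irv_l = truth$irv(times)
  )
}

# Raw-signal synthesis ---------------------------------------------------

# Per-revolution modulation window: one burst per revolution with a flat
# plateau of 20% of the revolution (>= the 200-sample RMS window at the
# supported cadences) and raised-cosine tapers, zero between bursts.
emg_burst_window <- function(rev_samples) {
  u <- (seq_len(rev_samples) - 0.5) / rev_samples
  d <- abs(u - 0.5)
  w <- numeric(rev_samples)
  w[d <= 0.10] <- 1
  taper <- d > 0.10 & d <= 0.20
  w[taper] <- 0.5 * (1 + cos(pi * (d[taper] - 0.10) / 0.10))
  w
}

#' Synthesize a raw EMG trace with prescribed per-revolution envelope peaks
#'
#' Emits one activity burst per crank revolution, amplitude-modulated so
#' that the trailing 200-sample RMS envelope peak of each revolution equals
#' the requested amplitude (proportionality constant 1; for the noise
#' carrier each burst is rescaled by its own realized RMS peak to hold this
#' exactly before filtering). The `"noise"` carrier is band-limited
#' (20-450 Hz) zero-mean Gaussian noise, matching the sensors' bandwidth;
#' the `"sine"` carrier is a deterministic 150 Hz tone used for exact,
#' noise-free pipeline validation.
#'
#' @param amplitude_per_revolution Target envelope peaks (mV), one per
#'   revolution, all >= 0.
#' @param config A [sim_config()] (sampling rate, default cadence).
#' @param seed RNG seed for the noise carrier.
#' @param carrier `"noise"` or `"sine"`; defaults to the configured carrier.
#' @param cadence Cadence (rpm) used to size revolutions.
#' @param t0 Start time (s).
#' @param muscle Muscle label for the trace.
#' @return An unfiltered [emg_trace()].
#' @export
generate_emg_trace <- function(amplitude_per_revolution, config, seed = 1,
                               carrier = NULL, cadence = config$cadence_target,
                               t0 = 0, muscle = "vastus_lateralis") {
  if (length(amplitude_per_revolution) == 0 ||
      any(!is.finite(amplitude_per_revolution)) ||
      any(amplitude_per_revolution < 0)) {
    stop_validation("amplitudes must be non-negative and finite")
  }
  carrier <- match.arg(carrier %||% config$emg_carrier, c("noise", "sine"))
  rate <- config$emg_rate
  rev_samples <- round(rate * 60 / cadence)
  if (rev_samples < 250) {
    stop_validation("cadence too high for the 200-sample RMS window: ",
                    rev_samples, " samples per revolution")
  }
  n_rev <- length(amplitude_per_revolution)
  w <- emg_burst_window(rev_samples)
  n <- rev_samples * n_rev
  tt <- (seq_len(n) - 1L) / rate

  if (carrier == "sine") {
    x <- rep(w, n_rev) * rep(amplitude_per_revolution, each = rev_samples) *
      sqrt(2) * sin(2 * pi * 150 * tt)
  } else {
    co <- butter_bandpass(4, 20, 450, fs = rate)
    z <- with_seed(seed, rnorm(n))
    z <- filtfilt_iir(co$b, co$a, z)
    x <- rep(w, n_rev) * z
    for (r in seq_len(n_rev)) {
      idx <- ((r - 1L) * rev_samples + 1L):(r * rev_samples)
      a <- amplitude_per_revolution[r]
      if (a <= 0) {
        x[idx] <- 0
        next
      }
      peak <- max(rms_envelope(x[idx], window = 200))
      x[idx] <- if (peak > 0) x[idx] * (a / peak) else 0
    }
  }
  emg_trace(x, rate = rate, muscle = muscle, filtered = FALSE, t0 = t0)
}

#' Synthesize a crank signal
#'
#' Advances the crank in 2-degree steps. Within each revolution the angular
#' velocity is held at the cadence sampled at the revolution start, and the
#' torque follows a raised-sinusoid shape with two peaks per revolution
#' whose revolution mean equals `power / omega` exactly, so the
#' revolution-mean of torque x angular velocity reproduces the power
#' profile. Left and right cranks are identical.
#'
#' @param power_profile Single-leg power (W): a scalar, a function of time,
#'   or a data frame with columns `time_s` and `value`.
#' @param cadence_profile Cadence (rpm): same forms as `power_profile`;
#'   must be > 0 wherever power > 0.
#' @param config A [sim_config()].
#' @param duration_s Signal duration (s); required when both profiles are
#'   scalars, otherwise defaults to the profile time span.
#' @param mode Ergometer mode for all samples.
#' @param t0 Start time (s).
#' @return A [crank_signal()].
#' @export
generate_crank_signal <- function(power_profile, cadence_profile, config,
                                  duration_s = NULL,
                                  mode = c("isokinetic", "hyperbolic"),
                                  t0 = 0) {
  mode <- match.arg(mode)
  as_fun <- function(p, what) {
    if (is.function(p)) return(p)
    if (is_number(p)) {
      force(p)
      return(function(t) rep(p, length(t)))
    }
    if (is.data.frame(p) && all(c("time_s", "value") %in% names(p))) {
      return(stats::approxfun(p$time_s, p$value, rule = 2))
    }
    stop_validation(what, " must be a scalar, function, or data frame(time_s, value)")
  }
  span <- function(p) if (is.data.frame(p)) max(p$time_s) - t0 else NA_real_
  duration_s <- duration_s %||% max(span(power_profile), span(cadence_profile),
                                    na.rm = TRUE)
  if (!is_number(duration_s) || duration_s <= 0) {
    stop_validation("duration_s must be supplied (and > 0) with scalar profiles")
  }
  pow_f <- as_fun(power_profile, "power_profile")
  cad_f <- as_fun(cadence_profile, "cadence_profile")

  step_deg <- 2
  n_per_rev <- 360 / step_deg
  t <- t0
  angle0 <- 0
  out <- list()
  r <- 0L
  while (t < t0 + duration_s - 1e-9) {
    r <- r + 1L
    cad <- cad_f(t)[1]
    pow <- pow_f(t)[1]
    if (pow < 0) stop_validation("power profile must be non-negative")
    if (cad <= 0) {
      if (pow > 0) {
        stop_validation(sprintf(
          "cadence is 0 at t = %.2f s while power > 0", t))
      }
      stop_validation("cannot synthesise a stationary crank (cadence <= 0)")
    }
    omega <- cad * pi / 30
    dt <- (step_deg * pi / 180) / omega
    theta <- (seq_len(n_per_rev) - 1L) * step_deg
    torque <- (pow / omega) * (1 + 0.9 * sin(2 * theta * pi / 180))
    out[[r]] <- data.frame(
      time_s = t + (seq_len(n_per_rev) - 1L) * dt,
      angle_deg = angle0 + theta,
      torque = torque,
      omega = omega
    )
    t <- t + n_per_rev * dt
    angle0 <- angle0 + 360
  }
  all <- do.call(rbind, out)
  crank_signal(
    time_s = all$time_s, angle_deg = all$angle_deg,
    torque_left_nm = all$torque, torque_right_nm = all$torque,
    omega_rad_s = all$omega, mode = rep(mode, nrow(all))
  )
}

# Shared bout synthesis: per-revolution per-muscle target amplitudes for a
# bout at true fractional EMG `fr_true`, with multiplicative noise shared
# across muscles within a revolution.
bout_amplitudes <- function(fr_true, config, eps) {
  frac <- pmax(fr_true * (1 + eps), 1e-6)
  amps <- outer(frac, config$emg_visit_max_mv)
  colnames(amps) <- MUSCLES
  amps
}

bout_raw <- function(amplitudes, power_w, config, seed, t0, carrier) {
  crank <- generate_crank_signal(
    power_w, config$cadence_target, config,
    duration_s = nrow(amplitudes) * 60 / config$cadence_target,
    mode = "isokinetic", t0 = t0
  )
  traces <- lapply(seq_along(MUSCLES), function(m) {
    generate_emg_trace(
      amplitudes[, m], config, seed = seed + m, carrier = carrier,
      cadence = config$cadence_target, t0 = t0, muscle = MUSCLES[m]
    )
  })
  names(traces) <- MUSCLES
  list(crank = crank, traces = traces)
}

trial_carrier <- function(config) {
  if (config$baseline_r2_noise == 0) "sine" else config$emg_carrier
}

#' Generate a synthetic baseline session
#'
#' Eight (by default) short isokinetic bouts at the configured effort
#' fractions, separated by at least 30 s of unloaded cycling. Per-revolution
#' EMG amplitude is `(power - intercept) / slope * (1 + eps)` with
#' `eps ~ Normal(0, baseline_r2_noise)` shared across the four muscles of a
#' revolution; bout powers carry no noise (the instrumented crank is treated
#' as exact).
#'
#' @param config A [sim_config()].
#' @param participant_seed Seed identifying the participant; fixes both the
#'   participant parameters and the session noise.
#' @param emit `"summary"` returns per-revolution amplitude targets only
#'   (fast); `"raw"` additionally synthesizes the full EMG traces and crank
#'   records for every bout.
#' @param noise_stream Integer offset separating the noise of repeated
#'   visits by the same participant (one visit per condition).
#' @return Object of class `baseline_session`: `params`, `bouts` (effort,
#'   single-leg power, start time, revolution x muscle amplitude matrix),
#'   optional `raw` (crank + traces per bout), and `truth`.
#' @export
generate_baseline_session <- function(config, participant_seed,
                                      emit = c("summary", "raw"),
                                      noise_stream = 0L) {
  emit <- match.arg(emit)
  validate_sim_config(config)
  params <- draw_participant_params(config, participant_seed)
  n_bouts <- length(config$baseline_efforts)
  n_rev <- config$revolutions_per_bout
  eps <- with_seed(participant_seed + 11000L + 97L * noise_stream, {
    matrix(rnorm(n_bouts * n_rev, 0, config$baseline_r2_noise), nrow = n_bouts)
  })
  bout_dur <- n_rev * 60 / config$cadence_target
  carrier <- trial_carrier(config)
  bouts <- vector("list", n_bouts)
  raw <- if (emit == "raw") vector("list", n_bouts) else NULL
  for (j in seq_len(n_bouts)) {
    e <- config$baseline_efforts[j]
    power <- e * params$p_iso_max
    fr_true <- (power - params$intercept) / params$slope
    t0 <- (j - 1) * (bout_dur + config$bout_gap_s)
    amps <- bout_amplitudes(fr_true, config, eps[j, ])
    bouts[[j]] <- list(effort = e, power_w = power, fr_true = fr_true,
                       start_time = t0, amplitudes = amps)
    if (emit == "raw") {
      raw[[j]] <- bout_raw(amps, power, config,
                           seed = participant_seed + 13000L +
                             97L * noise_stream + 10L * j,
                           t0 = t0, carrier = carrier)
    }
  }
  structure(
    list(participant_seed = participant_seed, params = params, bouts = bouts,
         raw = raw, truth = make_truth(params, config)),
    class = "baseline_session"
  )
}

#' Generate a synthetic constant-power trial
#'
#' Constant-power cycling to the limit of tolerance under one of three
#' conditions, ending in a ~5 s maximal isokinetic phase. The control
#' tolerance time is drawn per participant; the resistance trial lasts
#' `resistance_time_factor` times that draw; the isotime-control trial is
#' the control condition truncated at the resistance duration. Activation
#' fatigue grows as `af_rate * t` (W, i.e. maximal evocable EMG fraction
#' `1 - af_rate * t / slope`) and the muscle power deficit as `mf_rate * t`;
#' IRV declines linearly at the condition rate. Breath-by-breath gas
#' exchange, duplicate IC manoeuvres (baseline / isotime / limit of
#' tolerance) and Borg ratings are emitted alongside a 1 Hz cadence record
#' whose sub-60 rpm dwell marks the limit of tolerance.
#'
#' @inheritParams generate_baseline_session
#' @param condition `"control"`, `"resistance"` or `"isotime_control"`.
#' @return Object of class `trial`: `record` (condition, task power,
#'   tolerance time, Borg table, VO2peak), `cadence`, `breaths`,
#'   `ic_manoeuvres`, `end_bout` (amplitudes, true end power/fraction,
#'   optional raw signals), `truth` and `truth_table`.
#' @export
generate_constant_power_trial <- function(config,
                                          condition = c("control", "resistance",
                                                        "isotime_control"),
                                          participant_seed,
                                          emit = c("summary", "raw"),
                                          noise_stream = NULL) {
  condition <- match.arg(condition)
  emit <- match.arg(emit)
  validate_sim_config(config)
  params <- draw_participant_params(config, participant_seed)
  ci <- condition_index(condition)
  noise_stream <- noise_stream %||% ci

  t_ctrl <- params$t_control
  t_res <- t_ctrl * config$resistance_time_factor
  term <- switch(condition, control = t_ctrl, resistance = t_res,
                 isotime_control = t_res)
  t_iso <- t_res
  truncated <- condition == "isotime_control"

  af_rate <- params$capacity_scale *
    if (condition == "resistance") config$af_rate_resistance else config$af_rate
  mf_rate <- params$capacity_scale *
    if (condition == "resistance") config$mf_rate_resistance else config$mf_rate
  irv_rate <- if (condition == "resistance") {
    config$irv_decline_rate_resistance
  } else {
    config$irv_decline_rate_control
  }
  vt_max <- if (condition == "resistance") config$vt_max_resistance else config$vt_max_control
  borg_d_rate <- if (condition == "resistance") {
    config$borg_dyspnoea_rate_resistance
  } else {
    config$borg_dyspnoea_rate_control
  }
  borg_l_rate <- if (condition == "resistance") {
    config$borg_leg_rate_resistance
  } else {
    config$borg_leg_rate_control
  }

  truth <- make_truth(params, config, af_rate = af_rate, mf_rate = mf_rate,
                      tolerance = if (truncated) t_ctrl else term,
                      termination = term, irv_rate = irv_rate)

  # end-exercise maximal isokinetic bout
  n_rev <- config$revolutions_per_bout
  cond_seed <- participant_seed + 40000L + 1000L * ci + 7L * noise_stream
  eps <- with_seed(cond_seed, rnorm(n_rev, 0, config$baseline_r2_noise))
  fr_end <- truth$max_emg_fraction(term)
  # the delivered maximal effort varies a few percent around the true
  # evocable power (test-retest variability of maximal voluntary efforts)
  effort_nu <- with_seed(cond_seed + 950L,
                         rnorm(1, 0, config$end_effort_noise))
  p_end_true <- max(params$slope * fr_end + params$intercept -
                      truth$muscle_deficit(term), 1)
  p_end <- p_end_true * (1 + effort_nu)
  end_amps <- bout_amplitudes(fr_end, config, eps)
  end_bout <- list(
    start_time = term + 8, fr_true = fr_end, power_w = p_end,
    amplitudes = end_amps
  )
  if (emit == "raw") {
    end_bout$raw <- bout_raw(end_amps, p_end, config,
                             seed = cond_seed + 500L, t0 = term + 8,
                             carrier = trial_carrier(config))
  }

  # cadence record (1 Hz): task phase at target, then a sub-threshold dwell
  # at the limit of tolerance and the commanded isokinetic finale. A
  # truncated (isotime-control) trial ends by protocol, not failure, so its
  # cadence never drops below threshold.
  times <- seq(0, ceiling(term) + 13)
  cadence_rpm <- if (truncated) {
    rep(config$cadence_target, length(times))
  } else {
    ifelse(times < term, config$cadence_target,
           ifelse(times < term + 8, 54, config$cadence_target))
  }
  cadence <- data.frame(time_s = times, cadence_rpm = cadence_rpm)

  # breath-by-breath table from 120 s pre-exercise to termination
  vt_of <- function(t) {
    ifelse(t < 0, config$vt_rest,
           config$vt_rest + (vt_max - config$vt_rest) * (1 - exp(-t / config$vt_tau)))
  }
  rr_of <- function(t) ifelse(t < 0, 14, 14 + 24 * (1 - exp(-t / 60)))
  vo2_of <- function(t) {
    ifelse(t < 0, 0.4, 0.4 + (params$vo2peak - 0.4) * (1 - exp(-t / 40)))
  }
  bt <- -120
  breath_times <- numeric(0)
  while (bt <= term + 0.5) {
    breath_times <- c(breath_times, bt)
    bt <- bt + 60 / rr_of(bt)
  }
  breaths <- data.frame(
    time_s = breath_times,
    vt_l = vt_of(breath_times),
    ve_l_min = vt_of(breath_times) * rr_of(breath_times),
    vo2_l_min = vo2_of(breath_times),
    vco2_l_min = 1.05 * vo2_of(breath_times)
  )

  # duplicate IC manoeuvres; measured volume = true IRV + true VT + noise
  stage_times <- list(baseline = c(-40, -20),
                      isotime = c(t_iso - 8, t_iso),
                      limit_of_tolerance = c(term - 8, term))
  ic_true <- function(t) truth$irv(t) + vt_of(t)
  man <- do.call(rbind, lapply(names(stage_times), function(st) {
    data.frame(time_s = stage_times[[st]], stage = st, replicate = 1:2,
               stringsAsFactors = FALSE)
  }))
  ic_noise <- with_seed(cond_seed + 900L, rnorm(nrow(man), 0, config$ic_noise_sd))
  man$inspired_volume_l <- pmax(ic_true(man$time_s) + ic_noise, 0.5)

  round_half <- function(x) round(2 * pmin(x, 10)) / 2
  borg <- data.frame(
    stage = c("baseline", "isotime", "limit_of_tolerance"),
    time_s = c(0, t_iso, term),
    dyspnoea = round_half(0.5 + borg_d_rate * c(0, t_iso, term)),
    leg_effort = round_half(0.5 + borg_l_rate * c(0, t_iso, term)),
    stringsAsFactors = FALSE
  )
  vo2_meas <- params$vo2peak + with_seed(cond_seed + 901L, rnorm(1, 0, 0.08))

  record <- list(
    condition = condition, participant_seed = participant_seed,
    task_power_w = params$task_power_w, tolerance_s = term,
    truncated = truncated, vo2peak_l_min = vo2_meas, borg = borg,
    expiratory_resistance = if (condition == "resistance") {
      config$expiratory_resistance
    } else {
      0
    },
    n_redraws = params$n_redraws
  )
  structure(
    list(record = record, cadence = cadence, breaths = breaths,
         ic_manoeuvres = man, end_bout = end_bout, truth = truth,
         truth_table = truth_sidecar(truth)),
    class = "trial"
  )
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf(
    "<trial> %s: task %s W, tolerance %s s%s; end P_iso %s W (fr %s)\n",
    x$record$condition, fmt_num(x$record$task_power_w),
    fmt_num(x$record$tolerance_s, 1),
    if (x$record$truncated) " (truncated at isotime)" else "",
    fmt_num(x$end_bout$power_w), fmt_num(x$end_bout$fr_true, 3)
  ))
  invisible(x)
}
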