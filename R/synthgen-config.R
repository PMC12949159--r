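# Simulation configuration: the stated world the generator emulates.
# Defaults encode the group means and dispersions of the study design this
# pipeline targets (tolerance times, baseline power, scatter of the
# EMG-power relationship, dynamic-hyperinflation kinetics); the methods
# vignette derives each calibrated value.

#' Simulation configuration
#'
#' All tunable parameters of the synthetic-trial generator, with defaults
#' calibrated to the group statistics the pipeline is designed around. Key
#' calibrations:
#'
#' * `baseline_r2_noise` is the SD of the multiplicative Gaussian noise
#'   applied per revolution to the EMG amplitude, calibrated so that a
#'   session's fitted baseline r-squared averages 0.96. The small-noise
#'   analytic value is `sqrt(3)/12 = 0.144` (bout-level SD 1/12 after
#'   averaging the 3 revolutions paired with each bout); the default 0.167
#'   comes from a numerical calibration of the full generator + fit, which
#'   accounts for the upward bias of an 8-point sample r-squared (see the
#'   methods vignette).
#' * Control tolerance time is Normal(575, 137) s; the resistance trial of
#'   the same participant lasts `resistance_time_factor` (487/575) times
#'   their control draw, and the isotime-control trial is truncated at the
#'   resistance duration.
#' * `af_rate` and `mf_rate` are the linear growth rates (W/s) of
#'   activation and muscle fatigue, identical across conditions by default
#'   (the expiratory load acts only through tolerance time, IRV decline and
#'   Borg growth); condition overrides are available for constructed
#'   scenarios.
#'
#' @param n_participants Cohort size.
#' @param seed Base RNG seed; participant `i` uses `seed + i`.
#' @param cadence_target Isokinetic cadence (rpm).
#' @param emg_rate EMG sampling rate (Hz).
#' @param baseline_efforts Effort fractions of the baseline bouts, each in
#'   (0, 1]; default 25/50/75/100% each twice (8 bouts).
#' @param baseline_r2_noise Multiplicative per-revolution EMG noise SD.
#' @param tolerance_mean_control,tolerance_sd_control Control tolerance time
#'   distribution (s).
#' @param tolerance_floor_s Tolerance draws at or below this are redrawn
#'   from an incremented stream (logged via message).
#' @param resistance_time_factor Resistance tolerance time as a fraction of
#'   the participant's control draw.
#' @param expiratory_resistance Imposed expiratory resistance
#'   (cmH2O/L/s; 7 in the resistance condition, 0 otherwise). Informational:
#'   the load acts on the generator only through the condition-specific
#'   kinetics below.
#' @param af_rate,mf_rate Activation / muscle fatigue growth (W/s) for a
#'   participant of mean capacity; within a participant the rates scale
#'   with their relative maximal power (`p_iso_max / p_iso_max_mean`), so
#'   the maximal evocable EMG fraction declines identically across the
#'   cohort and power reserves stay physiological.
#' @param af_rate_resistance,mf_rate_resistance Optional overrides for the
#'   resistance condition (default: same as control).
#' @param end_effort_noise CV of the end-exercise maximal isokinetic power
#'   (test-retest variability of a maximal voluntary effort); default 3%.
#' @param task_capacity_coupling How strongly task power tracks the
#'   participant's capacity (0 = independent, 1 = fully proportional); the
#'   residual SD is derived so the cohort task-power SD stays at
#'   `task_power_sd`.
#' @param p_iso_max_mean,p_iso_max_sd Single-leg baseline maximal isokinetic
#'   power distribution (W); draws below `p_iso_max_floor` are redrawn.
#' @param true_intercept Intercept of the true EMG-power line (W).
#' @param task_power_mean,task_power_sd Constant task power (chainring W).
#' @param vo2peak_mean,vo2peak_sd Peak oxygen uptake (L/min).
#' @param irv_baseline Resting inspiratory reserve volume (L).
#' @param irv_decline_rate_control,irv_decline_rate_resistance IRV decline
#'   (L/s) during exercise; the resistance rate is faster (more dynamic
#'   hyperinflation).
#' @param vt_rest,vt_max_control,vt_max_resistance,vt_tau Tidal-volume
#'   profile: exponential rise from `vt_rest` to the condition plateau with
#'   time constant `vt_tau` (s).
#' @param ic_noise_sd Measurement noise SD of an IC manoeuvre (L).
#' @param borg_dyspnoea_rate_control,borg_dyspnoea_rate_resistance,
#'   borg_leg_rate_control,borg_leg_rate_resistance Borg CR-10 growth rates
#'   (units/s) from a common 0.5 start, capped at 10.
#' @param revolutions_per_bout Revolutions per ~5 s isokinetic bout.
#' @param bout_gap_s Unloaded-cycling gap between baseline bouts (s), >= 30.
#' @param emg_visit_max_mv Per-muscle RMS amplitude (mV) at maximal effort.
#' @param emg_carrier Carrier for raw EMG synthesis: `"noise"` (band-limited
#'   20-450 Hz noise, realistic) or `"sine"` (deterministic mid-band tone).
#'   The noise-free limit (`baseline_r2_noise = 0`) always uses the sine
#'   carrier so that generated data are fully deterministic and the pipeline
#'   recovers the ground truth exactly.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 14,
                       seed = 1,
                       cadence_target = 70,
                       emg_rate = 2000,
                       baseline_efforts = rep(c(0.25, 0.5, 0.75, 1), 2),
                       baseline_r2_noise = 0.167,
                       tolerance_mean_control = 575,
                       tolerance_sd_control = 137,
                       tolerance_floor_s = 60,
                       resistance_time_factor = 487 / 575,
                       expiratory_resistance = 7,
                       af_rate = 0.21,
                       mf_rate = 0.057,
                       af_rate_resistance = NULL,
                       mf_rate_resistance = NULL,
                       p_iso_max_mean = 342,
                       p_iso_max_sd = 108,
                       p_iso_max_floor = 150,
                       true_intercept = 0,
                       task_power_mean = 193,
                       task_power_sd = 47,
                       task_capacity_coupling = 0.6,
                       end_effort_noise = 0.03,
                       vo2peak_mean = 3.5,
                       vo2peak_sd = 0.85,
                       irv_baseline = 2.6,
                       irv_decline_rate_control = 0.0038,
                       irv_decline_rate_resistance = 0.0049,
                       vt_rest = 0.9,
                       vt_max_control = 2.9,
                       vt_max_resistance = 3.2,
                       vt_tau = 120,
                       ic_noise_sd = 0.05,
                       borg_dyspnoea_rate_control = 0.014,
                       borg_dyspnoea_rate_resistance = 0.0164,
                       borg_leg_rate_control = 0.0148,
                       borg_leg_rate_resistance = 0.0164,
                       revolutions_per_bout = 6,
                       bout_gap_s = 30,
                       emg_visit_max_mv = c(vastus_lateralis = 0.45,
                                            rectus_femoris = 0.35,
                                            vastus_medialis = 0.50,
                                            lateral_gastrocnemius = 0.30),
                       emg_carrier = c("noise", "sine")) {
  cfg <- list(
    n_participants = n_participants, seed = seed,
    cadence_target = cadence_target, emg_rate = emg_rate,
    baseline_efforts = baseline_efforts,
    baseline_r2_noise = baseline_r2_noise,
    tolerance_mean_control = tolerance_mean_control,
    tolerance_sd_control = tolerance_sd_control,
    tolerance_floor_s = tolerance_floor_s,
    resistance_time_factor = resistance_time_factor,
    expiratory_resistance = expiratory_resistance,
    af_rate = af_rate, mf_rate = mf_rate,
    af_rate_resistance = af_rate_resistance %||% af_rate,
    mf_rate_resistance = mf_rate_resistance %||% mf_rate,
    p_iso_max_mean = p_iso_max_mean, p_iso_max_sd = p_iso_max_sd,
    p_iso_max_floor = p_iso_max_floor, true_intercept = true_intercept,
    task_power_mean = task_power_mean, task_power_sd = task_power_sd,
    task_capacity_coupling = task_capacity_coupling,
    end_effort_noise = end_effort_noise,
    vo2peak_mean = vo2peak_mean, vo2peak_sd = vo2peak_sd,
    irv_baseline = irv_baseline,
    irv_decline_rate_control = irv_decline_rate_control,
    irv_decline_rate_resistance = irv_decline_rate_resistance,
    vt_rest = vt_rest, vt_max_control = vt_max_control,
    vt_max_resistance = vt_max_resistance, vt_tau = vt_tau,
    ic_noise_sd = ic_noise_sd,
    borg_dyspnoea_rate_control = borg_dyspnoea_rate_control,
    borg_dyspnoea_rate_resistance = borg_dyspnoea_rate_resistance,
    borg_leg_rate_control = borg_leg_rate_control,
    borg_leg_rate_resistance = borg_leg_rate_resistance,
    revolutions_per_bout = as.integer(revolutions_per_bout),
    bout_gap_s = bout_gap_s,
    emg_visit_max_mv = emg_visit_max_mv,
    emg_carrier = match.arg(emg_carrier)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_number(cfg$n_participants, "n_participants", min = 1)
  check_number(cfg$seed, "seed")
  check_number(cfg$cadence_target, "cadence_target", min = 0, strict_min = TRUE)
  check_number(cfg$emg_rate, "emg_rate", min = 0, strict_min = TRUE)
  if (length(cfg$baseline_efforts) < 4 ||
      any(cfg$baseline_efforts <= 0 | cfg$baseline_efforts > 1)) {
    stop_validation("baseline_efforts must be >= 4 fractions in (0, 1]")
  }
  for (nm in c("baseline_r2_noise", "tolerance_sd_control", "af_rate",
               "mf_rate", "af_rate_resistance", "mf_rate_resistance",
               "irv_decline_rate_control", "irv_decline_rate_resistance",
               "ic_noise_sd", "p_iso_max_sd", "task_power_sd", "vo2peak_sd",
               "end_effort_noise", "task_capacity_coupling",
               "expiratory_resistance", "borg_dyspnoea_rate_control",
               "borg_dyspnoea_rate_resistance", "borg_leg_rate_control",
               "borg_leg_rate_resistance")) {
    check_number(cfg[[nm]], nm, min = 0)
  }
  check_number(cfg$tolerance_mean_control, "tolerance_mean_control",
               min = 0, strict_min = TRUE)
  check_number(cfg$resistance_time_factor, "resistance_time_factor",
               min = 0, strict_min = TRUE)
  check_number(cfg$bout_gap_s, "bout_gap_s", min = 30)
  check_number(cfg$revolutions_per_bout, "revolutions_per_bout", min = 3)
  if (cfg$p_iso_max_floor - cfg$true_intercept <= 0) {
    stop_validation("non-positive true EMG-power slope: p_iso_max_floor must ",
                    "exceed true_intercept")
  }
  if (length(cfg$emg_visit_max_mv) != 4 || any(cfg$emg_visit_max_mv <= 0)) {
    stop_validation("emg_visit_max_mv must be 4 positive amplitudes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-30s %s\n", nm, paste(format(val, digits = 6), collapse = ", ")))
  }
  invisible(x)
}

# every defaulted/tuned parameter, one line each, for run logs
config_log_lines <- function(cfg) {
  vapply(names(cfg), function(nm) {
    sprintf("param %s = %s", nm,
            paste(format(cfg[[nm]], digits = 10), collapse = ","))
  }, character(1))
}
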