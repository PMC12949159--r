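# Visit-level and cohort-level analysis: glue the signal-processing,
# fatigue, lung-mechanics and statistics stages into the full pipeline, for
# synthetic visits ("summary" amplitudes or fully synthesized raw signals)
# and, via the same code paths, for any data organised in the package's
# table schemas.

# Per-bout peak RMS table from either representation. In the summary
# representation the stored amplitude targets ARE the per-revolution peaks
# (the raw path recovers them through filtering + enveloping), and the
# revolution table is reconstructed from the bout's constant power/cadence.
bout_peak_table <- function(bout, raw, config, target_rpm, tolerance_fraction,
                            filter_low, filter_high, filter_order, rms_window) {
  if (!is.null(raw)) {
    bp <- bout_revolution_peaks(raw$crank, raw$traces, low = filter_low,
                                high = filter_high, order = filter_order,
                                window = rms_window)
    return(bp)
  }
  n_rev <- nrow(bout$amplitudes)
  revs <- data.frame(
    index = seq_len(n_rev),
    start_time = bout$start_time + (seq_len(n_rev) - 1) * 60 / config$cadence_target,
    end_time = bout$start_time + seq_len(n_rev) * 60 / config$cadence_target,
    mean_cadence = config$cadence_target,
    left_power = bout$power_w,
    right_power = bout$power_w,
    isokinetic = TRUE
  )
  list(revolutions = revs, peaks = bout$amplitudes)
}

select_and_pair <- function(bp, visit_max, target_rpm, tolerance_fraction) {
  sel <- select_isokinetic_revolutions(bp$revolutions, target_rpm = target_rpm,
                                       tolerance_fraction = tolerance_fraction)
  rows <- match(sel, bp$revolutions$index)
  p_iso <- mean(bp$revolutions$left_power[rows])
  fr <- mean(vapply(rows, function(i) {
    composite_fr_emg(bp$peaks[i, ], visit_max)
  }, numeric(1)))
  list(p_iso = p_iso, fr_emg = fr, revolutions_used = sel)
}

#' Fit the baseline relationship of a synthetic session
#'
#' Runs the per-bout pairing (visit maxima, composite fractional EMG,
#' three-revolution isokinetic power) over the session's bouts and fits the
#' baseline EMG-power regression.
#'
#' @param session A [generate_baseline_session()] result.
#' @param config The [sim_config()] used to generate it.
#' @param extra_peaks Optional list of additional revolution x muscle peak
#'   matrices (e.g. the end-exercise bout) to include in the visit maxima.
#' @param target_rpm,tolerance_fraction,filter_low,filter_high,filter_order,rms_window
#'   Processing settings (defaults match the acquisition conventions).
#' @return List with `fit` (a [baseline_relationship()]), `points`, and
#'   `visit_max`.
#' @export
process_baseline_session <- function(session, config, extra_peaks = NULL,
                                     target_rpm = config$cadence_target,
                                     tolerance_fraction = 0.05,
                                     filter_low = 10, filter_high = 500,
                                     filter_order = 4, rms_window = 200) {
  if (!inherits(session, "baseline_session")) {
    stop_validation("session must be a baseline_session")
  }
  bps <- lapply(seq_along(session$bouts), function(j) {
    bout_peak_table(session$bouts[[j]], session$raw[[j]], config, target_rpm,
                    tolerance_fraction, filter_low, filter_high, filter_order,
                    rms_window)
  })
  all_peaks <- c(lapply(bps, `[[`, "peaks"), extra_peaks)
  visit_max <- visit_maxima(all_peaks)
  pts <- do.call(rbind, lapply(bps, function(bp) {
    pr <- select_and_pair(bp, visit_max, target_rpm, tolerance_fraction)
    data.frame(fr_emg = pr$fr_emg, p_iso_w = pr$p_iso)
  }))
  list(fit = fit_baseline(pts), points = pts, visit_max = visit_max)
}

#' Analyse one synthetic visit (baseline session + constant-power trial)
#'
#' The full pipeline for one laboratory visit: visit maxima over all
#' isokinetic bouts (baseline efforts and the end-exercise effort), the
#' baseline EMG-power fit, the end-exercise isokinetic result, the fatigue
#' decomposition, power reserve, the detected limit of tolerance, and the
#' operating lung volumes per stage.
#'
#' @param session A [generate_baseline_session()] result for this visit.
#' @param trial A [generate_constant_power_trial()] result.
#' @param config The shared [sim_config()].
#' @inheritParams process_baseline_session
#' @return List with `fit`, `indices` ([decompose_fatigue()] output),
#'   `end_result`, `power_reserve_w`, `t_intolerance_s`, `volumes` (one
#'   [stage_volumes()] per stage) and `record`.
#' @export
analyze_visit <- function(session, trial, config,
                          target_rpm = config$cadence_target,
                          tolerance_fraction = 0.05, filter_low = 10,
                          filter_high = 500, filter_order = 4,
                          rms_window = 200) {
  if (!inherits(trial, "trial")) stop_validation("trial must be a trial object")
  end_bp <- bout_peak_table(trial$end_bout, trial$end_bout$raw, config,
                            target_rpm, tolerance_fraction, filter_low,
                            filter_high, filter_order, rms_window)
  base <- process_baseline_session(
    session, config, extra_peaks = list(end_bp$peaks),
    target_rpm = target_rpm, tolerance_fraction = tolerance_fraction,
    filter_low = filter_low, filter_high = filter_high,
    filter_order = filter_order, rms_window = rms_window
  )
  endp <- select_and_pair(end_bp, base$visit_max, target_rpm,
                          tolerance_fraction)
  indices <- decompose_fatigue(base$fit, end_p_iso = endp$p_iso,
                               end_fr_emg = endp$fr_emg)
  reserve <- power_reserve(2 * endp$p_iso, trial$record$task_power_w)
  t_int <- detect_intolerance(trial$cadence)
  volumes <- lapply(unique(trial$ic_manoeuvres$stage), function(st) {
    stage_volumes(trial$breaths, trial$ic_manoeuvres, st)
  })
  names(volumes) <- unique(trial$ic_manoeuvres$stage)
  list(fit = base$fit, indices = indices, end_result = endp,
       power_reserve_w = reserve, t_intolerance_s = t_int,
       volumes = volumes, record = trial$record)
}

visit_endpoint_row <- function(participant, visit) {
  lot <- visit$volumes[["limit_of_tolerance"]]
  borg <- visit$record$borg
  lot_borg <- borg[borg$stage == "limit_of_tolerance", ]
  data.frame(
    participant = participant,
    condition = visit$record$condition,
    tolerance_s = if (is.na(visit$t_intolerance_s)) {
      visit$record$tolerance_s # truncated trials end by protocol, not failure
    } else {
      visit$t_intolerance_s
    },
    pf_w = visit$indices$pf,
    af_w = visit$indices$af,
    mf_w = visit$indices$mf,
    clamp_active = visit$indices$clamp_active,
    power_reserve_w = visit$power_reserve_w,
    ic_l = lot$ic_l,
    irv_l = lot$irv_l,
    dyspnoea = lot_borg$dyspnoea,
    leg_effort = lot_borg$leg_effort,
    vo2peak_l_min = visit$record$vo2peak_l_min,
    r_squared_baseline = visit$fit$r_squared,
    stringsAsFactors = FALSE
  )
}

#' Simulate and analyse a full cohort
#'
#' Generates `n_participants` participants, each with one visit (baseline
#' session + trial) per condition, runs the full analysis pipeline on every
#' visit, and returns the cohort endpoints table consumed by
#' [study_report()].
#'
#' @param config A [sim_config()].
#' @param emit `"summary"` (fast, default) or `"raw"` to exercise the raw
#'   signal path for every visit.
#' @param conditions Conditions to simulate.
#' @return Data frame, one row per participant x condition, with fatigue,
#'   power-reserve, lung-volume, Borg and baseline-fit endpoints.
#' @export
cohort_endpoints <- function(config, emit = "summary",
                             conditions = CONDITIONS) {
  rows <- list()
  for (i in seq_len(config$n_participants)) {
    pseed <- config$seed + i
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      session <- generate_baseline_session(config, pseed, emit = emit,
                                           noise_stream = ci)
      trial <- generate_constant_power_trial(config, cond, pseed, emit = emit)
      visit <- analyze_visit(session, trial, config)
      rows[[length(rows) + 1L]] <- visit_endpoint_row(i, visit)
    }
  }
  do.call(rbind, rows)
}

#' Run a full synthetic study
#'
#' Convenience wrapper: [cohort_endpoints()] followed by [study_report()].
#'
#' @inheritParams cohort_endpoints
#' @return List with `endpoints` and `report`.
#' @export
run_study <- function(config, emit = "summary") {
  endpoints <- cohort_endpoints(config, emit = emit)
  list(endpoints = endpoints, report = study_report(endpoints))
}
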