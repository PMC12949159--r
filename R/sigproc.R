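# Signal processing for mCPET recordings: EMG conditioning, crank-revolution
# segmentation, per-revolution power and peak RMS EMG, and the composite
# fractional EMG paired with three-revolution isokinetic power.

MUSCLES <- c("vastus_lateralis", "rectus_femoris", "vastus_medialis",
             "lateral_gastrocnemius")
MUSCLE_COLS <- c(vastus_lateralis = "vl_mv", rectus_femoris = "rf_mv",
                 vastus_medialis = "vm_mv", lateral_gastrocnemius = "lg_mv")

#' Surface EMG trace
#'
#' Container for a single-muscle surface EMG record.
#'
#' @param samples Numeric vector of voltages (mV).
#' @param rate Sampling rate in Hz (2000 for the supported sensors).
#' @param muscle One of `"vastus_lateralis"`, `"rectus_femoris"`,
#'   `"vastus_medialis"`, `"lateral_gastrocnemius"`.
#' @param filtered Has the band-pass already been applied?
#' @param t0 Time of the first sample (s).
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(samples, rate = 2000, muscle = "vastus_lateralis",
                      filtered = FALSE, t0 = 0) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop_validation("samples must be a non-empty numeric vector")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_validation("EMG samples must be finite")
  }
  check_number(rate, "rate", min = 0, strict_min = TRUE)
  muscle <- match.arg(muscle, MUSCLES)
  structure(
    list(samples = as.numeric(samples), rate = rate, muscle = muscle,
         filtered = isTRUE(filtered), t0 = t0),
    class = "emg_trace"
  )
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf(
    "<emg_trace> %s: %d samples @ %g Hz (%.2f s), %sfiltered\n",
    x$muscle, length(x$samples), x$rate, length(x$samples) / x$rate,
    if (x$filtered) "" else "un"
  ))
  invisible(x)
}

emg_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Crank signal
#'
#' Angle-indexed record of torque and angular velocity from an instrumented
#' crank, sampled every 2 degrees of crank rotation.
#'
#' @param time_s Sample times (s), non-decreasing.
#' @param angle_deg Cumulative crank angle (degrees), non-decreasing.
#' @param torque_left_nm,torque_right_nm Crank torques (N m).
#' @param omega_rad_s Angular velocity (rad/s), non-negative.
#' @param mode Per-sample ergometer mode, `"hyperbolic"` or `"isokinetic"`.
#' @return A data frame of class `crank_signal`.
#' @export
crank_signal <- function(time_s, angle_deg, torque_left_nm, torque_right_nm,
                         omega_rad_s, mode) {
  n <- length(time_s)
  lens <- c(length(angle_deg), length(torque_left_nm), length(torque_right_nm),
            length(omega_rad_s), length(mode))
  if (any(lens != n)) stop_validation("crank series must have equal length")
  if (n == 0) stop_validation("crank signal must be non-empty")
  if (is.unsorted(angle_deg)) stop_validation("crank angle must be non-decreasing")
  if (any(omega_rad_s < 0)) stop_validation("angular velocity must be >= 0")
  if (!all(mode %in% c("hyperbolic", "isokinetic"))) {
    stop_validation("mode must be 'hyperbolic' or 'isokinetic'")
  }
  structure(
    data.frame(time_s = time_s, angle_deg = angle_deg,
               torque_left_nm = torque_left_nm,
               torque_right_nm = torque_right_nm,
               omega_rad_s = omega_rad_s, mode = mode,
               stringsAsFactors = FALSE),
    class = c("crank_signal", "data.frame")
  )
}

#' Band-pass filter an EMG trace
#'
#' Applies a Butterworth band-pass (default 10-500 Hz, prototype order 4)
#' forward and backward, giving zero phase shift so envelope timing stays
#' aligned with the crank record. An upper edge at or above Nyquist is
#' clipped to 0.99 x Nyquist with a warning; the sensors' own 20-450 Hz
#' bandwidth makes the numerical edge immaterial at a 2000 Hz sampling rate.
#'
#' @param trace An unfiltered [emg_trace()].
#' @param low,high Band edges (Hz).
#' @param order Prototype filter order.
#' @return The trace with conditioned samples and `filtered = TRUE`.
#' @export
bandpass_filter <- function(trace, low = 10, high = 500, order = 4) {
  if (!inherits(trace, "emg_trace")) stop_validation("trace must be an emg_trace")
  if (trace$filtered) stop_validation("trace is already filtered")
  co <- butter_bandpass(order = order, low = low, high = high, fs = trace$rate)
  out <- trace
  out$samples <- filtfilt_iir(co$b, co$a, trace$samples)
  out$filtered <- TRUE
  out
}

#' Moving root-mean-square envelope
#'
#' Smooths a rectified-equivalent EMG signal with a trailing (causal)
#' 200-sample RMS window: element `i` is the RMS of the window ending at
#' sample `i`. The first `window - 1` elements use the partial window, so
#' the output has the input's length. The trailing alignment is a
#' documented choice; pass `align = "center"` for a centred window.
#'
#' @param x An [emg_trace()] or numeric vector.
#' @param window Window length in samples (default 200).
#' @param align `"trailing"` (default) or `"center"`.
#' @return For an `emg_trace`, an object of class `emg_envelope` (fields
#'   `values`, `rate`, `t0`, `muscle`, `window`); for a numeric vector, a
#'   numeric vector.
#' @export
rms_envelope <- function(x, window = 200, align = c("trailing", "center")) {
  align <- match.arg(align)
  values <- if (inherits(x, "emg_trace")) x$samples else x
  if (!is.numeric(values) || length(values) == 0) {
    stop_validation("cannot compute an RMS envelope of an empty series")
  }
  window <- as.integer(window)
  if (window < 1L) stop_validation("window must be >= 1 sample")
  n <- length(values)
  if (window > n) stop_validation("window (", window, ") exceeds trace length (", n, ")")
  cs <- cumsum(values^2)
  total <- cs - c(rep(0, window), cs[seq_len(n - window)])
  counts <- pmin(seq_len(n), window)
  env <- sqrt(total / counts)
  if (align == "center") {
    shift <- window %/% 2L
    env <- c(env[seq(shift + 1L, n)], rep(env[n], shift))
  }
  if (inherits(x, "emg_trace")) {
    structure(
      list(values = env, rate = x$rate, t0 = x$t0, muscle = x$muscle,
           window = window),
      class = "emg_envelope"
    )
  } else {
    env
  }
}

#' Segment a crank record into complete revolutions
#'
#' One row per contiguous 360 degrees of cumulative crank angle, starting at
#' the first sample; a trailing partial revolution is dropped. Revolution
#' mean power is energy-based (integral of torque x angular velocity over
#' the revolution divided by its duration), which reduces to the plain mean
#' of instantaneous power at constant cadence.
#'
#' @param crank A [crank_signal()].
#' @return A data frame with columns `index`, `start_time`, `end_time`,
#'   `mean_cadence` (rpm), `left_power` (W), `right_power` (W) and
#'   `isokinetic` (all samples in isokinetic mode). Empty when the record
#'   holds less than one full revolution.
#' @export
segment_revolutions <- function(crank) {
  if (!inherits(crank, "crank_signal")) stop_validation("crank must be a crank_signal")
  ang <- crank$angle_deg - crank$angle_deg[1]
  n <- nrow(crank)
  step <- if (n > 1) stats::median(diff(crank$angle_deg)) else 0
  rev_id <- floor(ang / 360 + 1e-9)
  last_rev <- max(rev_id)
  # a revolution is complete if a later revolution starts, or its samples
  # span the full 360 degrees given the angular step
  complete_last <- (max(ang[rev_id == last_rev]) - last_rev * 360 + step) >= 360 - 1e-6
  keep_max <- if (complete_last) last_rev else last_rev - 1L
  if (keep_max < 0) {
    return(data.frame(index = integer(), start_time = numeric(),
                      end_time = numeric(), mean_cadence = numeric(),
                      left_power = numeric(), right_power = numeric(),
                      isokinetic = logical()))
  }
  dt <- diff(crank$time_s)
  dt <- c(dt, if (n > 1) dt[n - 1] else 0)
  keep <- rev_id <= keep_max
  f <- factor(rev_id[keep], levels = 0:keep_max)
  first_idx <- match(0:keep_max, rev_id)
  start_time <- crank$time_s[first_idx]
  next_first <- match(1:(keep_max + 1L), rev_id)
  end_time <- ifelse(is.na(next_first),
                     crank$time_s[n] + dt[n],
                     crank$time_s[next_first])
  dur <- end_time - start_time
  e_left <- rowsum((crank$torque_left_nm * crank$omega_rad_s * dt)[keep], f)
  e_right <- rowsum((crank$torque_right_nm * crank$omega_rad_s * dt)[keep], f)
  t_sum <- rowsum(dt[keep], f)
  iso <- tapply(crank$mode[keep] == "isokinetic", f, all)
  data.frame(
    index = 1:(keep_max + 1L),
    start_time = start_time,
    end_time = end_time,
    mean_cadence = 60 / dur,
    left_power = as.numeric(e_left / t_sum),
    right_power = as.numeric(e_right / t_sum),
    isokinetic = as.logical(iso),
    row.names = NULL
  )
}

#' Instantaneous crank power
#'
#' @param torque Torque series (N m).
#' @param angular_velocity Angular velocity series (rad/s).
#' @return Element-wise power in W.
#' @examples
#' instantaneous_power(50, 70 * 2 * pi / 60) # 70 rpm
#' @export
instantaneous_power <- function(torque, angular_velocity) {
  if (length(torque) != length(angular_velocity)) {
    stop_validation("torque and angular velocity must have equal length")
  }
  if (anyNA(torque) || anyNA(angular_velocity) ||
      any(!is.finite(torque)) || any(!is.finite(angular_velocity))) {
    stop_validation("torque and angular velocity must be finite")
  }
  torque * angular_velocity
}

#' Peak envelope value within one revolution
#'
#' @param envelope An `emg_envelope` (from [rms_envelope()]).
#' @param revolution A one-row slice of [segment_revolutions()] output.
#' @return The maximum envelope value (mV) in `[start_time, end_time)`.
#' @export
revolution_peak_emg <- function(envelope, revolution) {
  if (!inherits(envelope, "emg_envelope")) {
    stop_validation("envelope must come from rms_envelope() on an emg_trace")
  }
  times <- envelope$t0 + (seq_along(envelope$values) - 1L) / envelope$rate
  sel <- times >= revolution$start_time & times < revolution$end_time
  if (!any(sel)) {
    stop_validation(sprintf(
      "no envelope samples in revolution span [%.3f, %.3f) s",
      revolution$start_time, revolution$end_time
    ))
  }
  max(envelope$values[sel])
}

#' Select three consecutive well-constrained isokinetic revolutions
#'
#' Qualifying runs are three consecutive revolutions, all in isokinetic
#' mode, each with mean cadence within `tolerance_fraction` of the target.
#' Among qualifying runs the one with the highest mean left-crank power is
#' taken (maximal-effort intent), with ties broken by the earliest run.
#'
#' @param revolutions Output of [segment_revolutions()].
#' @param target_rpm Commanded isokinetic cadence (rpm).
#' @param tolerance_fraction Allowed relative cadence deviation (default 5%).
#' @return Integer vector of the three selected `index` values.
#' @export
select_isokinetic_revolutions <- function(revolutions, target_rpm = 70,
                                          tolerance_fraction = 0.05) {
  check_number(target_rpm, "target_rpm", min = 0, strict_min = TRUE)
  check_number(tolerance_fraction, "tolerance_fraction", min = 0)
  iso <- revolutions[revolutions$isokinetic, , drop = FALSE]
  if (nrow(iso) < 3) {
    stop_validation("need at least 3 isokinetic revolutions, have ", nrow(iso))
  }
  ok <- abs(iso$mean_cadence - target_rpm) / target_rpm <= tolerance_fraction
  consecutive <- diff(iso$index, lag = 2) == 2
  starts <- which(consecutive & ok[-((nrow(iso) - 1):nrow(iso))] &
                    ok[-c(1, nrow(iso))] & ok[-(1:2)])
  if (length(starts) == 0) {
    run_starts <- which(consecutive)
    if (length(run_starts) > 0) {
      dev <- vapply(run_starts, function(s) {
        max(abs(iso$mean_cadence[s:(s + 2)] - target_rpm) / target_rpm)
      }, numeric(1))
      best <- run_starts[which.min(dev)]
      stop_validation(sprintf(
        paste0("no run of 3 consecutive isokinetic revolutions within %.1f%% of ",
               "%g rpm; best near-miss: revolutions %d-%d at %s rpm"),
        100 * tolerance_fraction, target_rpm, iso$index[best],
        iso$index[best + 2],
        paste(sprintf("%.1f", iso$mean_cadence[best:(best + 2)]), collapse = ", ")
      ))
    }
    stop_validation("no run of 3 consecutive isokinetic revolutions found")
  }
  power <- vapply(starts, function(s) mean(iso$left_power[s:(s + 2)]), numeric(1))
  best <- starts[which.max(power)] # which.max is first-wins: earliest on ties
  iso$index[best:(best + 2)]
}

#' Composite fractional EMG over four muscles
#'
#' Each muscle's per-revolution peak RMS value is normalized to its own
#' visit maximum; the composite is the unweighted mean of the four
#' fractions.
#'
#' @param per_muscle_peaks Numeric vector of 4 peak RMS values (mV).
#' @param visit_max_per_muscle Numeric vector of 4 visit maxima (mV), > 0.
#' @return Dimensionless composite fractional EMG.
#' @examples
#' composite_fr_emg(c(0.8, 0.6, 1.0, 0.6), c(1, 1, 1, 1)) # 0.75
#' @export
composite_fr_emg <- function(per_muscle_peaks, visit_max_per_muscle) {
  if (length(per_muscle_peaks) != 4 || length(visit_max_per_muscle) != 4) {
    stop_validation("expected peaks and visit maxima for exactly 4 muscles")
  }
  if (any(!is.finite(per_muscle_peaks)) || any(!is.finite(visit_max_per_muscle))) {
    stop_validation("peaks and visit maxima must be finite")
  }
  if (any(visit_max_per_muscle <= 0)) {
    stop_validation("all visit maxima must be > 0")
  }
  mean(per_muscle_peaks / visit_max_per_muscle)
}

#' Per-muscle visit maxima of per-revolution RMS peaks
#'
#' The normalization denominator for fractional EMG: the per-muscle maximum
#' of per-revolution RMS peaks over all isokinetic bouts of the visit
#' (baseline efforts plus the end-exercise effort).
#'
#' @param peak_matrices List of revolution-by-muscle peak matrices, one per
#'   bout (as returned by [bout_revolution_peaks()]).
#' @return Named numeric vector of 4 per-muscle maxima.
#' @export
visit_maxima <- function(peak_matrices) {
  if (length(peak_matrices) == 0) stop_validation("no bouts supplied")
  stacked <- do.call(rbind, peak_matrices)
  if (ncol(stacked) != 4) stop_validation("peak matrices must have 4 muscle columns")
  apply(stacked, 2, max)
}

#' Per-revolution peak RMS EMG for every revolution of a bout
#'
#' Conditions the four EMG traces (band-pass + RMS envelope, unless already
#' filtered), segments the crank record, and returns the peak envelope value
#' of every complete revolution for every muscle, alongside the revolution
#' table. Used both to accumulate visit maxima and by [isokinetic_result()].
#'
#' @param crank A [crank_signal()].
#' @param traces List of 4 [emg_trace()] objects (one per muscle).
#' @param low,high,order Band-pass settings (see [bandpass_filter()]).
#' @param window RMS window in samples.
#' @return List with `revolutions` (data frame) and `peaks`
#'   (revolution x muscle matrix, mV).
#' @export
bout_revolution_peaks <- function(crank, traces, low = 10, high = 500,
                                  order = 4, window = 200) {
  if (length(traces) != 4) stop_validation("expected 4 EMG traces")
  revs <- segment_revolutions(crank)
  if (nrow(revs) == 0) stop_validation("crank record holds less than one revolution")
  envs <- lapply(traces, function(tr) {
    if (!inherits(tr, "emg_trace")) stop_validation("traces must be emg_trace objects")
    if (!tr$filtered) tr <- bandpass_filter(tr, low = low, high = high, order = order)
    rms_envelope(tr, window = window)
  })
  peaks <- vapply(envs, function(env) {
    vapply(seq_len(nrow(revs)), function(i) {
      revolution_peak_emg(env, revs[i, ])
    }, numeric(1))
  }, numeric(nrow(revs)))
  peaks <- matrix(peaks, nrow = nrow(revs), ncol = 4,
                  dimnames = list(NULL, vapply(traces, `[[`, "", "muscle")))
  list(revolutions = revs, peaks = peaks)
}

#' Three-revolution isokinetic power paired with fractional EMG
#'
#' Runs the full per-bout pipeline: select the three consecutive
#' well-constrained isokinetic revolutions, average the left-crank
#' revolution power over them (single-leg P_iso), report twice one-leg
#' power at the chainring, and pair the power with the mean of the three
#' per-revolution composite fractional EMG values.
#'
#' @inheritParams bout_revolution_peaks
#' @param visit_max_per_muscle Named numeric vector of 4 visit maxima (mV).
#' @param target_rpm,tolerance_fraction Revolution selection settings.
#' @return An object of class `isokinetic_result` with fields
#'   `p_iso_single_leg`, `p_iso_chainring`, `fr_emg`, `revolutions_used`.
#' @export
isokinetic_result <- function(crank, traces, visit_max_per_muscle,
                              target_rpm = 70, tolerance_fraction = 0.05,
                              low = 10, high = 500, order = 4, window = 200) {
  bp <- bout_revolution_peaks(crank, traces, low = low, high = high,
                              order = order, window = window)
  sel <- select_isokinetic_revolutions(bp$revolutions, target_rpm = target_rpm,
                                       tolerance_fraction = tolerance_fraction)
  rows <- match(sel, bp$revolutions$index)
  p_iso <- mean(bp$revolutions$left_power[rows])
  fr <- mean(vapply(rows, function(i) {
    composite_fr_emg(bp$peaks[i, ], visit_max_per_muscle)
  }, numeric(1)))
  structure(
    list(p_iso_single_leg = p_iso, p_iso_chainring = 2 * p_iso, fr_emg = fr,
         revolutions_used = sel, peaks = bp$peaks[rows, , drop = FALSE]),
    class = "isokinetic_result"
  )
}

#' @export
print.isokinetic_result <- function(x, ...) {
  cat(sprintf(
    "<isokinetic_result> P_iso %s W single-leg (%s W chainring), Fr.EMG %s, revolutions %s\n",
    fmt_num(x$p_iso_single_leg), fmt_num(x$p_iso_chainring),
    fmt_num(x$fr_emg, 3), paste(x$revolutions_used, collapse = ",")
  ))
  invisible(x)
}
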