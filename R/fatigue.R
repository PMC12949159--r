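# Fatigue apportionment: the baseline relationship between fractional EMG
# and single-leg isokinetic power, and the decomposition of the power lost
# at the limit of tolerance into activation fatigue (the power equivalent of
# reduced maximal evocable EMG, mapped through the baseline slope) and
# muscle fatigue (the residual power deficit at the measured EMG).

#' Baseline EMG-power relationship
#'
#' Constructor for the fitted (or worked-example) baseline relationship
#' between composite fractional EMG and single-leg isokinetic power:
#' `P = slope * fr_emg + intercept`.
#'
#' @param slope W per unit fractional EMG; must be > 0.
#' @param intercept W.
#' @param max_point Numeric `c(fr_emg =, p_iso_w =)`: the baseline
#'   (fatigue-free) maximum point.
#' @param r_squared Squared Pearson correlation of the fit (NA when
#'   constructed from summary values rather than fitted).
#' @param n_points Number of effort points behind the fit.
#' @return An object of class `baseline_relationship`.
#' @export
baseline_relationship <- function(slope, intercept, max_point,
                                  r_squared = NA_real_, n_points = NA_integer_) {
  check_number(slope, "slope", min = 0, strict_min = TRUE)
  check_number(intercept, "intercept")
  if (length(max_point) != 2 || any(!is.finite(max_point))) {
    stop_validation("max_point must be c(fr_emg, p_iso_w)")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop_validation("r_squared must lie in [0, 1]")
  }
  structure(
    list(slope = slope, intercept = intercept,
         max_point = c(fr_emg = unname(max_point[1]),
                       p_iso_w = unname(max_point[2])),
         r_squared = r_squared, n_points = n_points),
    class = "baseline_relationship"
  )
}

#' Fit the baseline EMG-power relationship
#'
#' Ordinary least squares with a free intercept of single-leg isokinetic
#' power on composite fractional EMG over the baseline variable-effort
#' bouts. A fitted slope that is not positive indicates a non-physiological
#' session and is rejected.
#'
#' @param points Data frame (or 2-column matrix) with columns `fr_emg` and
#'   `p_iso_w`, one row per bout; at least 4 points with spread in `fr_emg`.
#' @return A [baseline_relationship()] with `r_squared` equal to the squared
#'   Pearson correlation and `max_point` the point with the largest
#'   `fr_emg`.
#' @examples
#' pts <- data.frame(fr_emg = c(0.25, 0.5, 0.75, 1), p_iso_w = 600 * c(0.25, 0.5, 0.75, 1))
#' fit_baseline(pts)
#' @export
fit_baseline <- function(points) {
  if (is.matrix(points)) {
    points <- data.frame(fr_emg = points[, 1], p_iso_w = points[, 2])
  }
  if (!all(c("fr_emg", "p_iso_w") %in% names(points))) {
    stop_validation("points must have columns fr_emg and p_iso_w")
  }
  x <- points$fr_emg
  y <- points$p_iso_w
  if (length(x) < 4) stop_validation("need at least 4 baseline points, have ", length(x))
  if (anyNA(x) || anyNA(y)) stop_validation("baseline points must be complete")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop_validation("fractional EMG values have no spread")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  if (slope <= 0) {
    stop_validation("fitted baseline slope is not positive (",
                    fmt_num(slope), " W); non-physiological session")
  }
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (sd(y) > 0) cor(x, y)^2 else NA_real_
  imax <- which.max(x)
  baseline_relationship(
    slope = slope, intercept = intercept,
    max_point = c(x[imax], y[imax]),
    r_squared = r2, n_points = length(x)
  )
}

#' @export
print.baseline_relationship <- function(x, ...) {
  cat(sprintf(
    "<baseline_relationship> P = %s * Fr.EMG + %s W (r^2 = %s, n = %s); max point (%s, %s W)\n",
    fmt_num(x$slope), fmt_num(x$intercept),
    ifelse(is.na(x$r_squared), "NA", fmt_num(x$r_squared, 3)),
    x$n_points, fmt_num(x$max_point["fr_emg"], 3), fmt_num(x$max_point["p_iso_w"])
  ))
  invisible(x)
}

#' Decompose performance fatigue into activation and muscle fatigue
#'
#' Performance fatigue (PF) is the drop in single-leg isokinetic power from
#' the baseline (fatigue-free) maximum point to the end-exercise maximal
#' effort. Activation fatigue (AF) is the power equivalent of the drop in
#' composite fractional EMG from the baseline maximum point, mapped through
#' the baseline slope. Muscle fatigue is the balance, `MF = max(0, PF - AF)`
#' (the only clamp applied): the deficit in power at the measured EMG. AF is
#' reported unclamped and may be negative when end-exercise EMG exceeds the
#' baseline maximum.
#'
#' @param baseline A [baseline_relationship()].
#' @param end_p_iso Single-leg isokinetic power at the trial endpoint (W).
#' @param end_fr_emg Composite fractional EMG at the trial endpoint.
#' @return An object of class `fatigue_indices` with `pf`, `af`, `mf` (all
#'   single-leg W), the endpoint and baseline-maximum states, and
#'   `clamp_active`.
#' @examples
#' bl <- baseline_relationship(342, 0, c(fr_emg = 1, p_iso_w = 342))
#' decompose_fatigue(bl, end_p_iso = 342 - 146, end_fr_emg = 1 - 127 / 342)
#' @export
decompose_fatigue <- function(baseline, end_p_iso, end_fr_emg) {
  if (!inherits(baseline, "baseline_relationship")) {
    stop_validation("baseline must be a baseline_relationship")
  }
  check_number(end_p_iso, "end_p_iso", min = 0, strict_min = TRUE)
  check_number(end_fr_emg, "end_fr_emg", min = 0, strict_min = TRUE)
  pf <- unname(baseline$max_point["p_iso_w"]) - end_p_iso
  af <- baseline$slope * (unname(baseline$max_point["fr_emg"]) - end_fr_emg)
  mf <- max(0, pf - af)
  structure(
    list(pf = pf, af = af, mf = mf,
         p_iso_baseline_max = unname(baseline$max_point["p_iso_w"]),
         p_iso_end = end_p_iso,
         fr_emg_baseline_max = unname(baseline$max_point["fr_emg"]),
         fr_emg_end = end_fr_emg,
         clamp_active = (pf - af) < 0),
    class = "fatigue_indices"
  )
}

#' @export
print.fatigue_indices <- function(x, ...) {
  cat(sprintf(
    "<fatigue_indices> PF %s W | AF %s W | MF %s W%s (single-leg; P_iso %s -> %s W)\n",
    fmt_num(x$pf), fmt_num(x$af), fmt_num(x$mf),
    if (x$clamp_active) " [clamped]" else "",
    fmt_num(x$p_iso_baseline_max), fmt_num(x$p_iso_end)
  ))
  invisible(x)
}

#' Detect the limit of tolerance from the cadence record
#'
#' The limit of tolerance is the failure to maintain a minimum pedalling
#' cadence (default 60 rpm) for at least `dwell_s` seconds. The returned
#' timestamp is the start of the first sub-threshold dwell: the moment the
#' task could no longer be sustained.
#'
#' @param cadence Data frame with columns `time_s` and `cadence_rpm`, or a
#'   numeric cadence vector combined with `time`.
#' @param time Sample times (s) when `cadence` is a plain vector. Sampling
#'   must be at least 1 Hz.
#' @param threshold_rpm Minimum cadence (rpm).
#' @param dwell_s Required continuous sub-threshold duration (s).
#' @return The intolerance time (s), or `NA_real_` if never reached.
#' @export
detect_intolerance <- function(cadence, time = NULL, threshold_rpm = 60,
                               dwell_s = 5) {
  if (is.data.frame(cadence)) {
    if (!all(c("time_s", "cadence_rpm") %in% names(cadence))) {
      stop_validation("cadence data frame needs columns time_s and cadence_rpm")
    }
    time <- cadence$time_s
    cadence <- cadence$cadence_rpm
  }
  if (length(cadence) != length(time)) {
    stop_validation("cadence and time must have equal length")
  }
  if (length(cadence) < 2) return(NA_real_)
  if (stats::median(diff(time)) > 1 + 1e-9) {
    stop_validation("cadence must be sampled at >= 1 Hz to resolve the dwell")
  }
  below <- cadence < threshold_rpm
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(cadence)
  for (k in which(r$values)) {
    covered_until <- if (ends[k] < n) time[ends[k] + 1L] else time[n]
    if (covered_until - time[starts[k]] >= dwell_s) {
      return(time[starts[k]])
    }
  }
  NA_real_
}

#' Locomotor power reserve at intolerance
#'
#' The margin between the maximal ~5 s isokinetic power still evocable at
#' the limit of tolerance (chainring, i.e. twice one-leg, W) and the power
#' the task demanded.
#'
#' @param p_iso_chainring_end Chainring isokinetic power at intolerance (W).
#' @param task_power Task (flywheel) power requirement (W).
#' @return Power reserve in W; negative values (end power below the task
#'   requirement) are flagged with a warning.
#' @examples
#' power_reserve(399, 193) # 206 W
#' @export
power_reserve <- function(p_iso_chainring_end, task_power) {
  check_number(p_iso_chainring_end, "p_iso_chainring_end", min = 0)
  check_number(task_power, "task_power", min = 0)
  reserve <- p_iso_chainring_end - task_power
  if (reserve < 0) {
    warning(sprintf(
      "negative power reserve (%.1f W): end isokinetic power below task power",
      reserve
    ))
  }
  reserve
}
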