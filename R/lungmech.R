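# Operating lung volumes during exercise: inspiratory capacity (IC) from
# duplicate interleaved spirometry manoeuvres, the matched 20 s mean tidal
# volume (VT), and the inspiratory reserve volume IRV = IC - VT. Falling
# IC/IRV under expiratory loading is the signature of dynamic hyperinflation.

LUNG_STAGES <- c("baseline", "isotime", "limit_of_tolerance")

#' Mean tidal volume over the 20 s preceding a manoeuvre
#'
#' The tidal volume matched to an IC manoeuvre is the unweighted mean of
#' breaths whose time falls in the half-open window
#' `(manoeuvre_time - 20, manoeuvre_time]`.
#'
#' @param breaths Data frame with at least `time_s` and `vt_l` (breath times
#'   strictly increasing, VT > 0).
#' @param manoeuvre_time Cue time of the IC manoeuvre (s).
#' @param window_s Averaging window length (s), default 20.
#' @return Mean tidal volume (L).
#' @export
tidal_volume_20s <- function(breaths, manoeuvre_time, window_s = 20) {
  if (!all(c("time_s", "vt_l") %in% names(breaths))) {
    stop_validation("breaths must have columns time_s and vt_l")
  }
  check_number(manoeuvre_time, "manoeuvre_time")
  sel <- breaths$time_s > manoeuvre_time - window_s &
    breaths$time_s <= manoeuvre_time
  if (!any(sel)) {
    stop_validation(sprintf(
      "no breaths in the %g s window preceding the manoeuvre at %.1f s",
      window_s, manoeuvre_time
    ))
  }
  mean(breaths$vt_l[sel])
}

#' Inspiratory capacity from duplicate manoeuvres
#'
#' IC manoeuvres are performed in duplicate at each stage; the stage IC is
#' their mean. Replicates differing by more than 10% of their mean are
#' flagged as discordant (reconciliation by mean, flagged, is a documented
#' choice), and a single available replicate is flagged as such.
#'
#' @param inspired_volumes Numeric vector of 1 or 2 replicate inspired
#'   volumes (L, EELV to TLC), all > 0.
#' @param discordance_threshold Relative difference that triggers the
#'   discordance flag (default 0.10).
#' @return List with `ic_l`, `n_replicates`, `discordant`, `flags`.
#' @examples
#' inspiratory_capacity(c(3.30, 3.34)) # mean 3.32 L
#' @export
inspiratory_capacity <- function(inspired_volumes, discordance_threshold = 0.1) {
  v <- inspired_volumes[is.finite(inspired_volumes)]
  if (length(v) == 0) stop_validation("no usable IC replicates")
  if (length(v) > 2) stop_validation("at most 2 IC replicates expected, got ", length(v))
  if (any(v <= 0)) stop_validation("inspired volumes must be > 0")
  ic <- mean(v)
  flags <- character()
  discordant <- FALSE
  if (length(v) == 1) {
    flags <- c(flags, "single_replicate")
  } else if (abs(diff(v)) / ic > discordance_threshold) {
    discordant <- TRUE
    flags <- c(flags, "discordant_replicates")
  }
  list(ic_l = ic, n_replicates = length(v), discordant = discordant,
       flags = flags)
}

#' Operating lung volumes at one stage
#'
#' Combines the stage's duplicate IC manoeuvres with the breath table: the
#' stage IC is the replicate mean, the stage VT is the mean of the 20 s
#' tidal-volume means matched to each manoeuvre, and `IRV = IC - VT`
#' exactly. A negative IRV is physiologically near-zero operating reserve;
#' it is flagged, never clamped, so condition deltas stay unbiased.
#'
#' @param breaths Breath table (`time_s`, `vt_l`, ...).
#' @param manoeuvres Manoeuvre table with columns `time_s`, `stage`,
#'   `replicate`, `inspired_volume_l`.
#' @param stage One of `"baseline"`, `"isotime"`, `"limit_of_tolerance"`.
#' @param discordance_threshold Passed to [inspiratory_capacity()].
#' @return An object of class `lung_volumes`: `stage`, `ic_l`, `vt20_l`,
#'   `irv_l`, `flags`.
#' @export
stage_volumes <- function(breaths, manoeuvres, stage,
                          discordance_threshold = 0.1) {
  stage <- match.arg(stage, LUNG_STAGES)
  need <- c("time_s", "stage", "replicate", "inspired_volume_l")
  if (!all(need %in% names(manoeuvres))) {
    stop_validation("manoeuvres must have columns ",
                    paste(need, collapse = ", "))
  }
  rows <- manoeuvres[manoeuvres$stage == stage, , drop = FALSE]
  if (nrow(rows) == 0) stop_validation("no IC manoeuvres at stage '", stage, "'")
  ic <- inspiratory_capacity(rows$inspired_volume_l,
                             discordance_threshold = discordance_threshold)
  vt <- mean(vapply(rows$time_s, function(tm) {
    tidal_volume_20s(breaths, tm)
  }, numeric(1)))
  irv <- ic$ic_l - vt
  flags <- ic$flags
  if (irv < 0) flags <- c(flags, "negative_irv")
  structure(
    list(stage = stage, ic_l = ic$ic_l, vt20_l = vt, irv_l = irv,
         flags = flags),
    class = "lung_volumes"
  )
}

#' @export
print.lung_volumes <- function(x, ...) {
  cat(sprintf(
    "<lung_volumes> %s: IC %s L, VT(20 s) %s L, IRV %s L%s\n",
    x$stage, fmt_num(x$ic_l), fmt_num(x$vt20_l), fmt_num(x$irv_l),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Dynamic-hyperinflation deltas between conditions
#'
#' Condition differences at the isotime comparison, oriented as
#' resistance-at-its-limit minus isotime-control; a more negative delta IRV
#' means more dynamic hyperinflation under the expiratory load.
#'
#' @param resistance_lot [stage_volumes()] result for the resistance trial
#'   at its limit of tolerance.
#' @param isotime_control [stage_volumes()] result for the isotime-control
#'   trial endpoint.
#' @return List with `delta_ic_l` and `delta_irv_l` (L).
#' @export
hyperinflation_delta <- function(resistance_lot, isotime_control) {
  for (x in list(resistance_lot, isotime_control)) {
    if (!inherits(x, "lung_volumes")) {
      stop_validation("inputs must be lung_volumes objects")
    }
  }
  list(
    delta_ic_l = resistance_lot$ic_l - isotime_control$ic_l,
    delta_irv_l = resistance_lot$irv_l - isotime_control$irv_l
  )
}
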