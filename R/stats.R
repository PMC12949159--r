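# Paired-comparison inference and study-level report tables: dependent
# t-tests with the 95% CI of the difference, Pearson correlations between
# fatigue deltas and hyperinflation deltas, percent-change summaries, and
# the isotime alignment between paired trials.

#' Dependent (paired) Student's t-test
#'
#' Two-sided t-test on per-pair differences `a - b`, with the 95% (or
#' chosen level) confidence interval of the mean difference,
#' `mean_diff +/- t_{1-alpha/2, n-1} * SE`.
#'
#' @param a,b Paired measurement vectors of equal length (n >= 3).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `paired_result`: `mean_a`, `mean_b`, `mean_diff`,
#'   `t_stat`, `df`, `p_value`, `ci_low`, `ci_high`, `n`.
#' @export
paired_t <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop_validation("a and b must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  if (n < 3) stop_validation("need at least 3 complete pairs, have ", n)
  d <- a - b
  sdd <- sd(d)
  if (sdd == 0) {
    stop_validation("zero variance of paired differences: t statistic undefined")
  }
  se <- sdd / sqrt(n)
  tstat <- mean(d) / se
  df <- n - 1L
  p <- 2 * pt(-abs(tstat), df)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(mean_a = mean(a), mean_b = mean(b), mean_diff = mean(d),
         t_stat = tstat, df = df, p_value = p,
         ci_low = mean(d) - tcrit * se, ci_high = mean(d) + tcrit * se,
         n = n, conf_level = conf_level),
    class = "paired_result"
  )
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf(
    "<paired_result> mean diff %s (%g%% CI %s, %s); t(%d) = %s, P = %s, n = %d\n",
    fmt_num(x$mean_diff), 100 * x$conf_level, fmt_num(x$ci_low),
    fmt_num(x$ci_high), x$df, fmt_num(x$t_stat), format.pval(x$p_value, digits = 3),
    x$n
  ))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with non-zero
#'   variance. Incomplete pairs are dropped.
#' @return Object of class `corr_result`: `r`, `r_squared`, `p_value`
#'   (two-sided, from the t transform on n - 2 df), `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 complete pairs, have ", n)
  if (sd(x) == 0 || sd(y) == 0) {
    stop_validation("zero variance: correlation undefined")
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), n - 2)
  }
  structure(
    list(r = r, r_squared = r^2, p_value = p, n = n),
    class = "corr_result"
  )
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("<corr_result> r = %s (r^2 = %s), P = %s, n = %d\n",
              fmt_num(x$r, 3), fmt_num(x$r_squared, 3),
              format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}

#' Percent reduction of tolerance time
#'
#' @param control Control-condition value (> 0).
#' @param resistance Loaded-condition value.
#' @return `100 * (control - resistance) / control`.
#' @examples
#' percent_reduction(575, 487) # ~15.3%
#' @export
percent_reduction <- function(control, resistance) {
  check_number(control, "control", min = 0, strict_min = TRUE)
  check_number(resistance, "resistance")
  100 * (control - resistance) / control
}

#' Isotime alignment between paired trials
#'
#' The isotime-control comparison point is the tolerance time of the
#' participant's expiratory-resistance trial: the control trial's
#' measurements at that time are the isotime-control values.
#'
#' @param resistance_trial Resistance-trial tolerance time (s), or a trial
#'   object with `record$tolerance_s`.
#' @param control_trial Control-trial tolerance time (s) or trial object.
#' @return The isotime (s), with attribute `protocol_violation = TRUE` (and
#'   a warning) when the control trial ended before the resistance time.
#' @export
isotime_align <- function(resistance_trial, control_trial) {
  get_time <- function(x) {
    if (is.list(x) && !is.null(x$record$tolerance_s)) x$record$tolerance_s
    else if (is_number(x)) x
    else stop_validation("trials must be trial objects or numeric times")
  }
  t_res <- get_time(resistance_trial)
  t_con <- get_time(control_trial)
  out <- t_res
  if (t_con < t_res) {
    warning(sprintf(
      "control trial (%.1f s) shorter than resistance tolerance time (%.1f s): protocol violation",
      t_con, t_res
    ))
    attr(out, "protocol_violation") <- TRUE
  }
  out
}

# endpoint columns required of a cohort endpoints table
ENDPOINT_COLS <- c("participant", "condition", "tolerance_s", "pf_w", "af_w",
                   "mf_w", "power_reserve_w", "ic_l", "irv_l", "dyspnoea",
                   "leg_effort", "vo2peak_l_min")

#' Study-level comparison report
#'
#' Assembles the two-condition comparison tables from a cohort endpoints
#' table (one row per participant x condition): paired comparisons of
#' tolerance time and peak oxygen uptake (control vs. resistance) and of the
#' fatigue indices, power reserve, lung volumes and Borg ratings
#' (resistance at its limit vs. isotime-control), plus Pearson correlations
#' of the fatigue and leg-effort deltas against the IRV delta. Pairs are
#' deleted listwise per comparison and the per-comparison n is always
#' reported. No multiple-testing correction is applied.
#'
#' @param endpoints Data frame with columns `participant`, `condition`
#'   (`control`, `resistance`, `isotime_control`), `tolerance_s`, `pf_w`,
#'   `af_w`, `mf_w`, `power_reserve_w`, `ic_l`, `irv_l`, `dyspnoea`,
#'   `leg_effort`, `vo2peak_l_min`.
#' @param min_pairs Comparisons with fewer complete pairs are skipped with a
#'   note (default 3).
#' @return Object of class `study_report`: data frames `comparisons` and
#'   `correlations`, plus `notes`.
#' @export
study_report <- function(endpoints, min_pairs = 3) {
  missing_cols <- setdiff(ENDPOINT_COLS, names(endpoints))
  if (length(missing_cols) > 0) {
    stop_validation("endpoints table missing columns: ",
                    paste(missing_cols, collapse = ", "))
  }
  if (length(unique(endpoints$participant)) < 3) {
    stop_validation("need at least 3 participants with paired data")
  }
  wide <- function(var, cond) {
    rows <- endpoints[endpoints$condition == cond, c("participant", var)]
    rows[match(sort(unique(endpoints$participant)), rows$participant), var]
  }
  specs <- list(
    list(endpoint = "tolerance_time_s", var = "tolerance_s",
         a = "control", b = "resistance"),
    list(endpoint = "vo2peak_l_min", var = "vo2peak_l_min",
         a = "control", b = "resistance"),
    list(endpoint = "performance_fatigue_w", var = "pf_w",
         a = "resistance", b = "isotime_control"),
    list(endpoint = "activation_fatigue_w", var = "af_w",
         a = "resistance", b = "isotime_control"),
    list(endpoint = "muscle_fatigue_w", var = "mf_w",
         a = "resistance", b = "isotime_control"),
    list(endpoint = "power_reserve_w", var = "power_reserve_w",
         a = "isotime_control", b = "resistance"),
    list(endpoint = "ic_l", var = "ic_l",
         a = "resistance", b = "isotime_control"),
    list(endpoint = "irv_l", var = "irv_l",
         a = "resistance", b = "isotime_control"),
    list(endpoint = "dyspnoea_borg", var = "dyspnoea",
         a = "resistance", b = "isotime_control"),
    list(endpoint = "leg_effort_borg", var = "leg_effort",
         a = "resistance", b = "isotime_control")
  )
  notes <- character()
  rows <- list()
  for (sp in specs) {
    va <- wide(sp$var, sp$a)
    vb <- wide(sp$var, sp$b)
    keep <- is.finite(va) & is.finite(vb)
    if (sum(keep) < min_pairs) {
      notes <- c(notes, paste0(sp$endpoint, ": skipped (", sum(keep),
                               " complete pairs)"))
      next
    }
    res <- tryCatch(paired_t(va[keep], vb[keep]), error = function(e) e)
    if (inherits(res, "error")) {
      notes <- c(notes, paste0(sp$endpoint, ": ", conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      endpoint = sp$endpoint, condition_a = sp$a, condition_b = sp$b,
      n = res$n, mean_a = res$mean_a, mean_b = res$mean_b,
      mean_diff = res$mean_diff, ci_low = res$ci_low, ci_high = res$ci_high,
      t = res$t_stat, df = res$df, p = res$p_value,
      stringsAsFactors = FALSE
    )
  }
  comparisons <- do.call(rbind, rows)

  # correlations of condition deltas (resistance - isotime_control) vs. delta IRV
  delta <- function(var) wide(var, "resistance") - wide(var, "isotime_control")
  d_irv <- delta("irv_l")
  corr_rows <- list()
  for (var in c("pf_w", "af_w", "mf_w", "leg_effort")) {
    dx <- delta(var)
    keep <- is.finite(dx) & is.finite(d_irv)
    if (sum(keep) < min_pairs) {
      notes <- c(notes, paste0("delta_", var, " vs delta_irv: skipped"))
      next
    }
    cr <- tryCatch(pearson_corr(dx[keep], d_irv[keep]), error = function(e) e)
    if (inherits(cr, "error")) {
      notes <- c(notes, paste0("delta_", var, " vs delta_irv: ",
                               conditionMessage(cr)))
      next
    }
    corr_rows[[length(corr_rows) + 1L]] <- data.frame(
      pair = paste0("delta_", var, "_vs_delta_irv"), n = cr$n, r = cr$r,
      r_squared = cr$r_squared, p = cr$p_value, stringsAsFactors = FALSE
    )
  }
  correlations <- do.call(rbind, corr_rows)
  structure(
    list(comparisons = comparisons, correlations = correlations,
         notes = c(notes, "two-sided tests; no multiple-testing correction")),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("Study report: paired comparisons\n")
  if (!is.null(x$comparisons)) {
    print(cbind(
      x$comparisons[, c("endpoint", "condition_a", "condition_b", "n")],
      round(x$comparisons[, c("mean_a", "mean_b", "mean_diff", "ci_low",
                              "ci_high", "t", "p")], 3)
    ), row.names = FALSE)
  }
  cat("\nCorrelations of condition deltas vs delta IRV\n")
  if (!is.null(x$correlations)) {
    print(cbind(x$correlations[, c("pair", "n")],
                round(x$correlations[, c("r", "r_squared", "p")], 3)),
          row.names = FALSE)
  }
  if (length(x$notes)) cat("\nNotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
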