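#' Piecewise-linear potassium curve
#'
#' A patient's potassium trajectory reconstructed by linear interpolation
#' between measurements, the basis of every time-in-range statistic.
#'
#' @param time Measurement times, hours (strictly increasing after sorting;
#'   duplicate timestamps are an error).
#' @param potassium Measured values, mmol/L.
#' @param stay Optional `c(admission, discharge)` in hours; defaults to the
#'   span from first to last measurement, which is then used as the
#'   ICU-stay denominator for prevalence.
#' @return An object of class `potassium_curve`.
#' @examples
#' pc <- potassium_curve(c(0, 4), c(3.0, 4.0))
#' curve_value(pc, 2)  # 3.5: threshold crossed at t = 2 h
#' @export
potassium_curve <- function(time, potassium, stay = NULL) {
  stopifnot(length(time) == length(potassium), length(time) >= 1L)
  if (any(!is.finite(time)) || any(!is.finite(potassium)))
    stop("non-finite measurement data", call. = FALSE)
  ord <- order(time)
  time <- time[ord]; potassium <- potassium[ord]
  if (any(diff(time) <= 0))
    stop("duplicate measurement timestamps", call. = FALSE)
  if (is.null(stay)) stay <- range(time)
  stopifnot(length(stay) == 2L, stay[1] <= stay[2])
  structure(list(time = time, potassium = potassium,
                 stay = as.numeric(stay)),
            class = "potassium_curve")
}

#' @export
print.potassium_curve <- function(x, ...) {
  cat(sprintf("potassium curve: %d knots over %.1f-%.1f h, K %.1f-%.1f mmol/L\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              min(x$potassium), max(x$potassium)))
  invisible(x)
}

#' Evaluate a potassium curve
#'
#' @param curve A [potassium_curve()].
#' @param t Times (h); values outside the knot span are `NA`.
#' @return Interpolated potassium, mmol/L.
#' @export
curve_value <- function(curve, t) {
  if (length(curve$time) == 1L)
    return(ifelse(abs(t - curve$time) < 1e-9, curve$potassium, NA_real_))
  stats::approx(curve$time, curve$potassium, xout = t, rule = 1)$y
}

# exact time a linear segment spends strictly below threshold L
seg_time_below <- function(t1, t2, v1, v2, L) {
  if (v1 < L && v2 < L) return(t2 - t1)
  if (v1 >= L && v2 >= L) return(0)
  tc <- t1 + (L - v1) / (v2 - v1) * (t2 - t1)
  if (v1 < L) tc - t1 else t2 - tc
}

#' Time-in-range prevalence of dyskalemia for one curve
#'
#' The prevalence of hypokalemia (hyperkalemia) is the duration the
#' interpolated curve spends below `low` (above `high`) divided by the total
#' duration of ICU stay. Threshold crossings are solved analytically on each
#' linear segment; a knot exactly at the threshold contributes zero duration.
#'
#' @param curve A [potassium_curve()].
#' @param low Hypokalemia threshold, mmol/L (default 3.5).
#' @param high Hyperkalemia threshold, mmol/L (default 5.0).
#' @return Named vector `c(hypo, hyper)` in percent, or `c(NA, NA)` (with a
#'   warning) for a zero-duration curve, which a cohort aggregate must
#'   exclude and count.
#' @examples
#' curve_prevalence(potassium_curve(c(0, 4), c(3.0, 4.0)))  # hypo 50%
#' @export
curve_prevalence <- function(curve, low = 3.5, high = 5.0) {
  stopifnot(inherits(curve, "potassium_curve"))
  total <- curve$stay[2] - curve$stay[1]
  if (total <= 0) {
    warning("zero-duration curve: prevalence undefined", call. = FALSE)
    return(c(hypo = NA_real_, hyper = NA_real_))
  }
  d <- dyskalemia_durations(curve, low, high)
  c(hypo = 100 * d[["below"]] / total, hyper = 100 * d[["above"]] / total)
}

# absolute durations below `low` / above `high` over the knot span
dyskalemia_durations <- function(curve, low, high) {
  tt <- curve$time; vv <- curve$potassium
  below <- 0; above <- 0
  if (length(tt) > 1L) {
    for (i in seq_len(length(tt) - 1L)) {
      below <- below + seg_time_below(tt[i], tt[i + 1L], vv[i], vv[i + 1L], low)
      # v > high  <=>  -v < -high, strictness preserved
      above <- above + seg_time_below(tt[i], tt[i + 1L], -vv[i], -vv[i + 1L], -high)
    }
  }
  c(below = below, above = above)
}

#' Measurement-level incidence of dyskalemia
#'
#' Fraction of individual measurements below `low` (above `high`) among all
#' measurements taken after the first `exclude_before` hours of ICU
#' admission, pooled over the cohort. Values exactly at a threshold count as
#' in range.
#'
#' @param measurements Data frame with columns `time_h` and
#'   `potassium_mmol_l` (a `patient_id` column is allowed and ignored:
#'   counting is pooled).
#' @param low,high Thresholds, mmol/L (defaults 3.5 / 5.0).
#' @param exclude_before Hours after admission to discard (default 8).
#' @return Named vector `c(hypo, hyper, n)`: percentages and the pooled
#'   measurement count. `NA` percentages (with a warning) when no
#'   measurement survives the cutoff.
#' @export
incidence <- function(measurements, low = 3.5, high = 5.0,
                      exclude_before = 8) {
  stopifnot(all(c("time_h", "potassium_mmol_l") %in% names(measurements)))
  k <- measurements$potassium_mmol_l[measurements$time_h > exclude_before]
  if (!length(k)) {
    warning("no measurements after the exclusion window: incidence undefined",
            call. = FALSE)
    return(c(hypo = NA_real_, hyper = NA_real_, n = 0))
  }
  c(hypo = 100 * mean(k < low), hyper = 100 * mean(k > high), n = length(k))
}

#' Odds ratio for two proportions with Woolf confidence interval
#'
#' The point estimate is the ratio of odds, `[p1/(1-p1)] / [p2/(1-p2)]`,
#' independent of the group sizes. The 95% CI uses the log-OR normal
#' approximation (Woolf) with cell counts reconstructed as `round(p * n)`.
#' Degenerate proportions (0 or 1) fall back to a 0.5 continuity-corrected
#' estimate with a warning.
#'
#' @param p1,p2 Proportions in (0, 1) (group 1 = reference numerator).
#' @param n1,n2 Group sizes used for the CI.
#' @param conf_level Confidence level (default 0.95).
#' @return Named vector `c(or, ci_low, ci_high)`.
#' @examples
#' odds_ratio(0.024, 15857, 0.017, 37717)  # OR 1.4
#' @export
odds_ratio <- function(p1, n1, p2, n2, conf_level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  a <- round(p1 * n1); b <- n1 - a
  c_ <- round(p2 * n2); d <- n2 - c_
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1) || min(a, b, c_, d) == 0) {
    warning("degenerate proportion: using 0.5 continuity correction",
            call. = FALSE)
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    or <- (a / b) / (c_ / d)
  } else {
    or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

#' Percentile bands of potassium over a time grid
#'
#' At each grid time, evaluates every curve whose measurement span covers the
#' time and returns empirical percentiles (linear-interpolation definition,
#' `stats::quantile` type 7). Grid points covered by no curve are `NA`.
#'
#' @param curves List of [potassium_curve()] objects (non-empty).
#' @param time_grid Times, hours.
#' @param percentiles Percentiles to report (default 5, 25, 50, 75, 95).
#' @return Data frame with `time_h`, one `p<q>` column per percentile, and
#'   `n_curves` (curves covering each grid point).
#' @export
percentile_bands <- function(curves, time_grid = 0:24,
                             percentiles = c(5, 25, 50, 75, 95)) {
  if (!length(curves)) stop("empty cohort", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(time_grid),
                ncol = length(percentiles))
  ncov <- integer(length(time_grid))
  for (j in seq_along(time_grid)) {
    t <- time_grid[j]
    vals <- vapply(curves, function(cu) {
      if (t >= cu$time[1] - 1e-9 && t <= cu$time[length(cu$time)] + 1e-9)
        curve_value(cu, min(max(t, cu$time[1]), cu$time[length(cu$time)]))
      else NA_real_
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    ncov[j] <- length(vals)
    if (length(vals))
      out[j, ] <- stats::quantile(vals, percentiles / 100, type = 7,
                                  names = FALSE)
  }
  df <- data.frame(time_h = time_grid, out)
  names(df) <- c("time_h", paste0("p", percentiles))
  df$n_curves <- ncov
  df
}

cohort_curves <- function(measurements) {
  stopifnot(all(c("patient_id", "time_h", "potassium_mmol_l") %in%
                  names(measurements)))
  lapply(split(measurements, measurements$patient_id), function(d)
    potassium_curve(d$time_h, d$potassium_mmol_l))
}

arm_summary <- function(measurements, low, high, marked_high, exclude_before) {
  curves <- cohort_curves(measurements)
  stays <- vapply(curves, function(cu) cu$stay[2] - cu$stay[1], numeric(1))
  usable <- stays > 0
  if (!any(usable)) stop("arm with zero total stay", call. = FALSE)
  durs <- t(vapply(curves[usable], dyskalemia_durations, numeric(2),
                   low = low, high = high))
  marked <- vapply(curves[usable], function(cu)
    dyskalemia_durations(cu, low, marked_high)[["above"]], numeric(1))
  total_stay <- sum(stays[usable])
  per_patient_prev <- 100 * rowSums(durs) / stays[usable]
  inc <- incidence(measurements, low, high, exclude_before)
  list(
    n_patients = length(curves),
    n_excluded = sum(!usable),
    n_measurements = nrow(measurements),
    incidence_hypo = inc[["hypo"]], incidence_hyper = inc[["hyper"]],
    incidence_n = inc[["n"]],
    prevalence_hypo = 100 * sum(durs[, "below"]) / total_stay,
    prevalence_hyper = 100 * sum(durs[, "above"]) / total_stay,
    prevalence_marked_hyper = 100 * sum(marked) / total_stay,
    measurements_per_patient_day = nrow(measurements) / (total_stay / 24),
    per_patient_prevalence = per_patient_prev,
    out_of_range_count = sum(measurements$potassium_mmol_l < low |
                               measurements$potassium_mmol_l > high),
    curves = curves[usable]
  )
}

#' Before/after cohort comparison
#'
#' Reproduces the study-style analysis on two arms of measurement logs:
#' pooled dyskalemia incidence (after the first 8 h), time-in-range
#' prevalence including marked hyperkalemia (> 6.0 mmol/L), odds ratios with
#' Woolf 95% CIs (arm 1 odds over arm 2 odds), measurements per patient-day,
#' potassium percentile bands over the first ICU day, a chi-square test on
#' out-of-range measurement counts and a Mann-Whitney U test on the
#' per-patient prevalence distributions. Kurtosis of the per-patient
#' prevalence decides whether the report presents mean (SD) or median (IQR).
#'
#' @param before,after Measurement logs (data frames with `patient_id`,
#'   `time_h`, `potassium_mmol_l`), e.g. from [run_cohort()]; `before` is the
#'   physician-driven arm in the study design.
#' @param low,high,marked_high Thresholds, mmol/L (3.5, 5.0, 6.0).
#' @param exclude_before Incidence exclusion window, h (8).
#' @param band_grid Time grid for percentile bands (first ICU day).
#' @param chisq_correct Apply Yates correction to the chi-square test
#'   (default `FALSE`: the counts are large).
#' @return An object of class `cohort_report`.
#' @export
compare_arms <- function(before, after, low = 3.5, high = 5.0,
                         marked_high = 6.0, exclude_before = 8,
                         band_grid = 0:24, chisq_correct = FALSE) {
  if (is.list(before) && !is.data.frame(before)) before <- before$measurements
  if (is.list(after) && !is.data.frame(after)) after <- after$measurements
  if (!NROW(before) || !NROW(after)) stop("both arms must be non-empty",
                                          call. = FALSE)
  s1 <- arm_summary(before, low, high, marked_high, exclude_before)
  s2 <- arm_summary(after, low, high, marked_high, exclude_before)

  or_pair <- function(x1, x2, n1, n2)
    odds_ratio(x1 / 100, n1, x2 / 100, n2)
  ors <- list(
    incidence_hypo = or_pair(s1$incidence_hypo, s2$incidence_hypo,
                             s1$incidence_n, s2$incidence_n),
    incidence_hyper = or_pair(s1$incidence_hyper, s2$incidence_hyper,
                              s1$incidence_n, s2$incidence_n),
    prevalence_hypo = or_pair(s1$prevalence_hypo, s2$prevalence_hypo,
                              s1$n_measurements, s2$n_measurements),
    prevalence_hyper = or_pair(s1$prevalence_hyper, s2$prevalence_hyper,
                               s1$n_measurements, s2$n_measurements),
    prevalence_marked_hyper = or_pair(
      s1$prevalence_marked_hyper, s2$prevalence_marked_hyper,
      s1$n_measurements, s2$n_measurements)
  )

  tab <- rbind(c(s1$out_of_range_count,
                 s1$n_measurements - s1$out_of_range_count),
               c(s2$out_of_range_count,
                 s2$n_measurements - s2$out_of_range_count))
  chisq_p <- if (identical(tab[1, ], tab[2, ])) 1
  else suppressWarnings(stats::chisq.test(tab, correct = chisq_correct)$p.value)
  mw_p <- suppressWarnings(stats::wilcox.test(
    s1$per_patient_prevalence, s2$per_patient_prevalence)$p.value)

  kurt <- e1071::kurtosis(c(s1$per_patient_prevalence,
                            s2$per_patient_prevalence), type = 2)
  presentation <- if (is.finite(kurt) && abs(kurt) > 2) "median_iqr"
  else "mean_sd"

  bands <- rbind(
    cbind(arm = "before", percentile_bands(s1$curves, band_grid)),
    cbind(arm = "after", percentile_bands(s2$curves, band_grid))
  )

  structure(list(
    arms = list(
      before = s1[c("n_patients", "n_excluded", "n_measurements",
                    "incidence_hypo", "incidence_hyper", "incidence_n",
                    "prevalence_hypo", "prevalence_hyper",
                    "prevalence_marked_hyper",
                    "measurements_per_patient_day")],
      after = s2[c("n_patients", "n_excluded", "n_measurements",
                   "incidence_hypo", "incidence_hyper", "incidence_n",
                   "prevalence_hypo", "prevalence_hyper",
                   "prevalence_marked_hyper",
                   "measurements_per_patient_day")]
    ),
    odds_ratios = ors,
    chisq_p = chisq_p,
    mann_whitney_p = mw_p,
    per_patient_prevalence_kurtosis = kurt,
    presentation = presentation,
    bands = bands,
    thresholds = c(low = low, high = high, marked_high = marked_high,
                   exclude_before = exclude_before)
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Before/after potassium regulation report\n")
  fmt <- function(a) sprintf(
    "  %-7s n=%d (excl. %d), %d measurements, %.1f meas/patient-day\n          incidence  hypo %.2f%%  hyper %.2f%%\n          prevalence hypo %.2f%%  hyper %.2f%%  marked hyper %.2f%%\n",
    a$lbl, a$n_patients, a$n_excluded, a$n_measurements,
    a$measurements_per_patient_day, a$incidence_hypo, a$incidence_hyper,
    a$prevalence_hypo, a$prevalence_hyper, a$prevalence_marked_hyper)
  cat(fmt(c(x$arms$before, lbl = "before:")))
  cat(fmt(c(x$arms$after, lbl = "after:")))
  for (nm in names(x$odds_ratios)) {
    o <- x$odds_ratios[[nm]]
    cat(sprintf("  OR %-24s %.2f (95%% CI %.2f-%.2f)\n", nm,
                o[["or"]], o[["ci_low"]], o[["ci_high"]]))
  }
  cat(sprintf("  chi-square p = %.3g, Mann-Whitney p = %.3g (%s)\n",
              x$chisq_p, x$mann_whitney_p, x$presentation))
  invisible(x)
}
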