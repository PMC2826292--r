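#' Advisor configuration
#'
#' Bundles every tunable constant of the GRIP-II potassium recommendation
#' algorithm. Defaults reproduce the published protocol; any field may be
#' overridden, e.g. to adapt the sliding scale to a differently concentrated
#' potassium solution.
#'
#' @param pump_rate_per_clearance mmol/h of pump rate per unit clearance
#'   fraction; the within-range rule converges to
#'   `pump_rate_per_clearance * clearance` (default 4).
#' @param convergence_weight Smoothing weight in (0, 1] pulling the
#'   within-range advice from the recent mean infusion rate toward
#'   `pump_rate_per_clearance * clearance` (default 0.5; see the methods
#'   vignette for why 0.5 rather than a smaller weight).
#' @param scale_low_k,scale_low_rate Lower anchor of the hypokalemia sliding
#'   scale: potassium 2.0 mmol/L maps to 20 mmol/h.
#' @param scale_high_k,scale_high_rate Upper anchor: potassium 3.5 mmol/L maps
#'   to 6 mmol/h.
#' @param alert_low,alert_high Potassium bounds (mmol/L) outside which the
#'   attending physician must be notified, normal renal function (2.8 / 6.0).
#' @param alert_low_renal,alert_high_renal Same bounds under renal failure
#'   (2.6 / 5.8).
#' @param high_rate_alert Advised infusion rates above this (mmol/h) trigger
#'   physician notification (12).
#' @param renal_gfr_cutoff Estimated creatinine clearance (mL/min) below which
#'   renal function is considered impaired (30).
#' @param renal_diuresis_cutoff Diuresis rate (mL/h) below which renal
#'   function is considered impaired (30).
#' @param target_low,target_high Preferred potassium range, mmol/L
#'   (3.8 - 4.5).
#' @param target_lowering Amount (mmol/L) by which both target bounds are
#'   lowered for renally impaired patients (0.2).
#' @param gfr_full,diuresis_full GFR (mL/min) and diuresis (mL/h) at or above
#'   which the corresponding clearance component is 1 (100 and 60); below,
#'   each component falls linearly to 0.
#' @param rrt_clearance_bonus Added to the clearance fraction when the patient
#'   is on renal replacement therapy (0.5).
#' @param interval_alert,interval_out_of_range,interval_in_range Hours to the
#'   next potassium measurement when a marked-abnormal alert is present (1),
#'   for hypo-/hyperkalemia without alert (2), and for normokalemia (4). The
#'   defaults give a stable patient about six measurements per day.
#' @param mean_window Lookback (h) for the mean recent infusion rate (8).
#' @param rate_resolution Pump rate granularity, mmol/h (0.5; a 1 mmol/mL
#'   potassium chloride solution makes rates map 1:1 to mL/h).
#'
#' @return An object of class `advisor_config` (a named list).
#' @examples
#' cfg <- advisor_config()
#' cfg$target_low
#' @export
advisor_config <- function(pump_rate_per_clearance = 4,
                           convergence_weight = 0.5,
                           scale_low_k = 2.0, scale_low_rate = 20,
                           scale_high_k = 3.5, scale_high_rate = 6,
                           alert_low = 2.8, alert_high = 6.0,
                           alert_low_renal = 2.6, alert_high_renal = 5.8,
                           high_rate_alert = 12,
                           renal_gfr_cutoff = 30, renal_diuresis_cutoff = 30,
                           target_low = 3.8, target_high = 4.5,
                           target_lowering = 0.2,
                           gfr_full = 100, diuresis_full = 60,
                           rrt_clearance_bonus = 0.5,
                           interval_alert = 1, interval_out_of_range = 2,
                           interval_in_range = 4,
                           mean_window = 8,
                           rate_resolution = 0.5) {
  cfg <- list(
    pump_rate_per_clearance = pump_rate_per_clearance,
    convergence_weight = convergence_weight,
    scale_low_k = scale_low_k, scale_low_rate = scale_low_rate,
    scale_high_k = scale_high_k, scale_high_rate = scale_high_rate,
    alert_low = alert_low, alert_high = alert_high,
    alert_low_renal = alert_low_renal, alert_high_renal = alert_high_renal,
    high_rate_alert = high_rate_alert,
    renal_gfr_cutoff = renal_gfr_cutoff,
    renal_diuresis_cutoff = renal_diuresis_cutoff,
    target_low = target_low, target_high = target_high,
    target_lowering = target_lowering,
    gfr_full = gfr_full, diuresis_full = diuresis_full,
    rrt_clearance_bonus = rrt_clearance_bonus,
    interval_alert = interval_alert,
    interval_out_of_range = interval_out_of_range,
    interval_in_range = interval_in_range,
    mean_window = mean_window,
    rate_resolution = rate_resolution
  )
  validate_advisor_config(cfg)
  structure(cfg, class = "advisor_config")
}

validate_advisor_config <- function(cfg) {
  num_fields <- setdiff(names(cfg), character())
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("advisor_config field '", f, "' must be a single finite number",
           call. = FALSE)
  }
  stopifnot(
    cfg$convergence_weight > 0, cfg$convergence_weight <= 1,
    cfg$target_low < cfg$target_high,
    cfg$alert_low_renal < cfg$alert_low,
    cfg$alert_high_renal < cfg$alert_high,
    cfg$scale_low_k < cfg$scale_high_k,
    cfg$rate_resolution > 0,
    cfg$mean_window > 0
  )
  pos <- c("pump_rate_per_clearance", "alert_low", "alert_high",
           "alert_low_renal", "alert_high_renal", "high_rate_alert",
           "renal_gfr_cutoff", "renal_diuresis_cutoff", "target_lowering",
           "gfr_full", "diuresis_full", "interval_alert",
           "interval_out_of_range", "interval_in_range")
  for (f in pos) if (cfg[[f]] <= 0)
    stop("advisor_config field '", f, "' must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.advisor_config <- function(x, ...) {
  cat("GRIP-II advisor configuration\n")
  cat(sprintf("  target range          : %.1f - %.1f mmol/L (-%.1f if renal impairment)\n",
              x$target_low, x$target_high, x$target_lowering))
  cat(sprintf("  sliding scale         : K %.1f -> %g mmol/h, K %.1f -> %g mmol/h\n",
              x$scale_low_k, x$scale_low_rate, x$scale_high_k, x$scale_high_rate))
  cat(sprintf("  within-range pull     : %g mmol/h per unit clearance (weight %g)\n",
              x$pump_rate_per_clearance, x$convergence_weight))
  cat(sprintf("  physician alerts      : K <%.1f / >%.1f (renal <%.1f / >%.1f), rate >%g mmol/h\n",
              x$alert_low, x$alert_high, x$alert_low_renal, x$alert_high_renal,
              x$high_rate_alert))
  cat(sprintf("  measurement intervals : alert %gh, out-of-range %gh, in-range %gh\n",
              x$interval_alert, x$interval_out_of_range, x$interval_in_range))
  invisible(x)
}

# round a rate to the pump resolution (round-half-to-even on the grid, i.e.
# base R rounding of x / resolution)
round_rate <- function(rate, resolution) {
  round(rate / resolution) * resolution
}
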