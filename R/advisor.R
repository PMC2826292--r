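#' Clinical context for one dosing decision
#'
#' Captures everything the advisor sees at a decision point: the last
#' potassium and creatinine measurements, demographics for the
#' Cockcroft-Gault estimate, the nurse-entered 6-hour diuresis, the renal
#' replacement therapy flag, and the recent potassium infusion log.
#'
#' @param potassium Last measured potassium, mmol/L (> 0).
#' @param creatinine Last creatinine, umol/L, or `NA` if unavailable.
#' @param age Age in years.
#' @param weight Weight in kg.
#' @param sex `"male"` or `"female"` (abbreviations accepted).
#' @param diuresis_6h Urine output over the last 6 hours, mL, or `NA`.
#' @param on_rrt Is the patient on renal replacement therapy / hemofiltration?
#' @param infusion_log Data frame with columns `start_h`, `end_h`,
#'   `rate_mmol_h`: the potassium infusion history. Intervals must be
#'   non-overlapping and lie within `[admission_time, now]`. `NULL` means no
#'   recorded infusion.
#' @param admission_time ICU admission time, hours (default 0).
#' @param now Decision time, hours since the same origin.
#'
#' @return An object of class `advisory_context`.
#' @examples
#' advisory_context(potassium = 3.2, creatinine = 90, age = 61, weight = 80,
#'                  sex = "m", diuresis_6h = 300, now = 10)
#' @export
advisory_context <- function(potassium, creatinine = NA_real_, age, weight,
                             sex = c("male", "female"), diuresis_6h = NA_real_,
                             on_rrt = FALSE, infusion_log = NULL,
                             admission_time = 0, now = admission_time) {
  sex <- match_sex(sex)
  ctx <- structure(list(
    potassium = as.numeric(potassium),
    creatinine = as.numeric(creatinine),
    age = as.numeric(age),
    weight = as.numeric(weight),
    sex = sex,
    diuresis_6h = as.numeric(diuresis_6h),
    on_rrt = isTRUE(on_rrt),
    infusion_log = normalize_infusion_log(infusion_log),
    admission_time = as.numeric(admission_time),
    now = as.numeric(now)
  ), class = "advisory_context")
  validate_advisory_context(ctx)
  ctx
}

match_sex <- function(sex) {
  s <- tolower(as.character(sex)[1L])
  if (s %in% c("m", "male")) return("male")
  if (s %in% c("f", "female")) return("female")
  stop("sex must be 'male' or 'female'", call. = FALSE)
}

normalize_infusion_log <- function(log) {
  if (is.null(log) || NROW(log) == 0L) {
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      rate_mmol_h = numeric(0)))
  }
  log <- as.data.frame(log)
  need <- c("start_h", "end_h", "rate_mmol_h")
  if (!all(need %in% names(log)))
    stop("infusion log needs columns start_h, end_h, rate_mmol_h",
         call. = FALSE)
  log <- log[order(log$start_h), need, drop = FALSE]
  rownames(log) <- NULL
  log
}

validate_advisory_context <- function(ctx) {
  if (!is.finite(ctx$potassium) || ctx$potassium <= 0)
    stop("potassium must be a positive number (mmol/L)", call. = FALSE)
  if (!is.finite(ctx$weight) || ctx$weight <= 0)
    stop("weight must be positive (kg)", call. = FALSE)
  if (!is.finite(ctx$age) || ctx$age < 0)
    stop("age must be >= 0", call. = FALSE)
  if (is.finite(ctx$diuresis_6h) && ctx$diuresis_6h < 0)
    stop("diuresis_6h must be >= 0 (mL over 6 h)", call. = FALSE)
  if (is.finite(ctx$creatinine) && ctx$creatinine <= 0)
    stop("creatinine must be positive (umol/L)", call. = FALSE)
  if (ctx$now < ctx$admission_time)
    stop("now must be >= admission_time", call. = FALSE)
  log <- ctx$infusion_log
  if (nrow(log)) {
    if (any(!is.finite(as.matrix(log))))
      stop("infusion log contains non-finite values", call. = FALSE)
    if (any(log$end_h <= log$start_h))
      stop("infusion log intervals must have end_h > start_h", call. = FALSE)
    if (any(log$rate_mmol_h < 0))
      stop("infusion rates must be >= 0", call. = FALSE)
    if (any(log$start_h < ctx$admission_time - 1e-9) ||
        any(log$end_h > ctx$now + 1e-9))
      stop("infusion log intervals must lie within [admission_time, now]",
           call. = FALSE)
    if (nrow(log) > 1L &&
        any(log$start_h[-1L] < log$end_h[-nrow(log)] - 1e-9))
      stop("infusion log intervals must not overlap", call. = FALSE)
  }
  invisible(ctx)
}

#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (mL/min) from age, weight, sex and serum
#' creatinine. Creatinine is taken in umol/L and converted internally to
#' mg/dL (factor 88.4). The estimate is floored at 0 for ages above 140.
#'
#' @param age Years.
#' @param weight kg (> 0).
#' @param sex `"male"` or `"female"`.
#' @param creatinine umol/L (> 0).
#' @return Estimated clearance, mL/min.
#' @examples
#' cockcroft_gault(60, 70, "male", 88.4)    # 77.8
#' cockcroft_gault(60, 70, "female", 88.4)  # 66.1
#' @export
cockcroft_gault <- function(age, weight, sex, creatinine) {
  sex <- match_sex(sex)
  if (!is.finite(creatinine) || creatinine <= 0)
    stop("creatinine must be positive (umol/L)", call. = FALSE)
  if (!is.finite(weight) || weight <= 0)
    stop("weight must be positive (kg)", call. = FALSE)
  creat_mg_dl <- creatinine / 88.4
  cl <- ((140 - age) * weight) / (72 * creat_mg_dl)
  if (sex == "female") cl <- cl * 0.85
  max(0, cl)
}

#' Potassium clearance fraction
#'
#' The patient's potassium elimination capacity as a fraction of a normal
#' person's. The fraction is 1 by default and falls linearly with a GFR below
#' 100 mL/min or a diuresis below 60 mL/h (the lower of the two components
#' wins); hemofiltration adds 0.5.
#'
#' @param gfr Estimated creatinine clearance, mL/min (`NA` to ignore).
#' @param diuresis_rate Urine output rate, mL/h (`NA` to ignore).
#' @param on_rrt On renal replacement therapy?
#' @param config An [advisor_config()].
#' @return Dimensionless clearance fraction (>= 0).
#' @examples
#' clearance_fraction(120, 6)               # 0.1
#' clearance_fraction(0, 0, on_rrt = TRUE)  # 0.5
#' @export
clearance_fraction <- function(gfr, diuresis_rate, on_rrt = FALSE,
                               config = advisor_config()) {
  if (is.finite(gfr) && gfr < 0) stop("gfr must be >= 0", call. = FALSE)
  if (is.finite(diuresis_rate) && diuresis_rate < 0)
    stop("diuresis_rate must be >= 0", call. = FALSE)
  components <- 1
  if (is.finite(gfr)) components <- c(components, gfr / config$gfr_full)
  if (is.finite(diuresis_rate))
    components <- c(components, diuresis_rate / config$diuresis_full)
  base <- min(components)
  if (isTRUE(on_rrt)) base + config$rrt_clearance_bonus else base
}

#' Renal impairment check
#'
#' A patient is renally impaired when the estimated creatinine clearance is
#' below 30 mL/min or the diuresis below 30 mL/h. Missing values fall back to
#' the remaining signal; with both missing, normal renal function is assumed.
#'
#' @inheritParams clearance_fraction
#' @return `TRUE` or `FALSE`.
#' @export
is_renal_impaired <- function(gfr, diuresis_rate, config = advisor_config()) {
  if (is.finite(gfr) && gfr < 0) stop("gfr must be >= 0", call. = FALSE)
  if (is.finite(diuresis_rate) && diuresis_rate < 0)
    stop("diuresis_rate must be >= 0", call. = FALSE)
  (is.finite(gfr) && gfr < config$renal_gfr_cutoff) ||
    (is.finite(diuresis_rate) && diuresis_rate < config$renal_diuresis_cutoff)
}

#' Target potassium range
#'
#' The preferred range is 3.8 - 4.5 mmol/L; for renally impaired patients both
#' bounds are lowered by 0.2 mmol/L.
#'
#' @param renal_impaired Logical.
#' @param config An [advisor_config()].
#' @return Named numeric vector `c(low, high)` in mmol/L.
#' @export
target_range <- function(renal_impaired = FALSE, config = advisor_config()) {
  shift <- if (isTRUE(renal_impaired)) config$target_lowering else 0
  c(low = config$target_low - shift, high = config$target_high - shift)
}

#' Classify a potassium value against the target range
#'
#' @param potassium mmol/L (> 0).
#' @param target `c(low, high)` from [target_range()].
#' @return One of `"hypokalemia"`, `"normokalemia"`, `"hyperkalemia"`.
#'   The target bounds themselves are normokalemic.
#' @export
classify_potassium <- function(potassium, target = target_range()) {
  if (!is.finite(potassium) || potassium <= 0)
    stop("potassium must be a positive number", call. = FALSE)
  if (potassium < target[["low"]]) "hypokalemia"
  else if (potassium > target[["high"]]) "hyperkalemia"
  else "normokalemia"
}

#' Sliding-scale starting rate for hypokalemia
#'
#' Linear dose scale through the protocol anchors: potassium 2.0 mmol/L maps
#' to 20 mmol/h and 3.5 mmol/L to 6 mmol/h. Below 2.0 the rate is clamped at
#' 20; between 3.5 and the lower target bound the line is extended. The
#' result is rounded to the pump resolution and never negative.
#'
#' @param potassium mmol/L; must be below `target["low"]` (the rule only
#'   applies in the hypokalemic state).
#' @param target `c(low, high)`.
#' @param config An [advisor_config()].
#' @return Advised starting rate, mmol/h.
#' @examples
#' sliding_scale_rate(2.0)   # 20
#' sliding_scale_rate(3.5)   # 6
#' @export
sliding_scale_rate <- function(potassium, target = target_range(),
                               config = advisor_config()) {
  if (!is.finite(potassium) || potassium <= 0)
    stop("potassium must be a positive number", call. = FALSE)
  if (potassium >= target[["low"]])
    stop("sliding_scale_rate applies only below the target range (K = ",
         potassium, ", target low = ", target[["low"]], ")", call. = FALSE)
  slope <- (config$scale_high_rate - config$scale_low_rate) /
    (config$scale_high_k - config$scale_low_k)
  raw <- config$scale_low_rate + slope * (potassium - config$scale_low_k)
  raw <- min(raw, config$scale_low_rate)  # clamp below the low anchor
  max(0, round_rate(raw, config$rate_resolution))
}

#' Time-weighted mean infusion rate over the recent window
#'
#' Mean potassium infusion rate over the last `window` hours, or since
#' admission, whichever span is shorter. Gaps in the log count as rate 0; an
#' empty lookback span (decision at admission) yields 0.
#'
#' @param infusion_log Data frame with `start_h`, `end_h`, `rate_mmol_h`.
#' @param admission_time,now Hours; `now >= admission_time`.
#' @param window Lookback, hours (default 8).
#' @return Mean rate, mmol/h.
#' @export
mean_recent_rate <- function(infusion_log, admission_time, now, window = 8) {
  if (now < admission_time)
    stop("now must be >= admission_time", call. = FALSE)
  log <- normalize_infusion_log(infusion_log)
  if (nrow(log) &&
      (any(log$start_h < admission_time - 1e-9) || any(log$end_h > now + 1e-9)))
    stop("infusion log intervals must lie within [admission_time, now]",
         call. = FALSE)
  from <- max(now - window, admission_time)
  span <- now - from
  if (span <= 0) return(0)
  if (!nrow(log)) return(0)
  lo <- pmax(log$start_h, from)
  hi <- pmin(log$end_h, now)
  dur <- pmax(0, hi - lo)
  sum(dur * log$rate_mmol_h) / span
}

#' Within-range pump-rate advice
#'
#' When the potassium is in the target range the advice starts from the mean
#' infusion rate over the last 8 hours and pulls it toward
#' `pump_rate_per_clearance * clearance` (4 mmol/h per unit clearance):
#' `(1 - w) * mean_8h + w * 4 * clearance` with smoothing weight `w`. Under
#' repeated application the advice converges geometrically to `4 * clearance`,
#' which is an exact fixed point; a clearance of 1 makes the pump converge to
#' 4 mmol/h, a clearance of 0.25 to 1 mmol/h. The returned value is not
#' rounded; [advise()] rounds the final recommendation to the pump
#' resolution.
#'
#' @param mean_8h Mean recent infusion rate, mmol/h (>= 0).
#' @param clearance Clearance fraction (>= 0).
#' @param config An [advisor_config()].
#' @return Advised rate, mmol/h.
#' @examples
#' within_range_rate(4, 1)      # 4: fixed point at clearance 1
#' within_range_rate(1, 0.25)   # 1: fixed point at clearance 0.25
#' @export
within_range_rate <- function(mean_8h, clearance, config = advisor_config()) {
  if (!is.finite(mean_8h) || mean_8h < 0)
    stop("mean_8h must be >= 0", call. = FALSE)
  if (!is.finite(clearance) || clearance < 0)
    stop("clearance must be >= 0", call. = FALSE)
  w <- config$convergence_weight
  (1 - w) * mean_8h + w * config$pump_rate_per_clearance * clearance
}

#' Physician-notification alerts
#'
#' Marked abnormal potassium (below 2.8 or above 6.0 mmol/L; below 2.6 or
#' above 5.8 under renal failure) and advised infusion rates over 12 mmol/h
#' require prompt notification of the attending physician.
#'
#' @param potassium mmol/L.
#' @param renal_impaired Logical; selects the renal-failure thresholds.
#' @param advised_rate mmol/h.
#' @param config An [advisor_config()].
#' @return Character vector, a subset of
#'   `c("marked_abnormal_potassium", "high_infusion_rate")`.
#' @export
check_alerts <- function(potassium, renal_impaired, advised_rate,
                         config = advisor_config()) {
  lo <- if (isTRUE(renal_impaired)) config$alert_low_renal else config$alert_low
  hi <- if (isTRUE(renal_impaired)) config$alert_high_renal else config$alert_high
  alerts <- character(0)
  if (potassium < lo || potassium > hi)
    alerts <- c(alerts, "marked_abnormal_potassium")
  if (advised_rate > config$high_rate_alert)
    alerts <- c(alerts, "high_infusion_rate")
  alerts
}

#' Time to the next potassium measurement
#'
#' 1 h when a marked-abnormal-potassium alert is present, 2 h for hypo- or
#' hyperkalemia without alert, 4 h for normokalemia; a stable patient is thus
#' measured about six times a day.
#'
#' @param state Classification from [classify_potassium()].
#' @param alerts Alert vector from [check_alerts()].
#' @param config An [advisor_config()].
#' @return Hours to the next measurement.
#' @export
next_interval <- function(state, alerts = character(0),
                          config = advisor_config()) {
  state <- match.arg(state, c("hypokalemia", "normokalemia", "hyperkalemia"))
  if ("marked_abnormal_potassium" %in% alerts) return(config$interval_alert)
  if (state == "normokalemia") config$interval_in_range
  else config$interval_out_of_range
}

#' One GRIP-II potassium recommendation
#'
#' Runs the full decision sequence for one measurement: renal assessment
#' (Cockcroft-Gault clearance, clearance fraction, impairment check), target
#' range, state classification, rate computation (sliding scale when
#' hypokalemic, smoothing toward 4 x clearance when in range, zero when
#' hyperkalemic), physician alerts and the next-measurement interval. The
#' final rate is rounded to the pump resolution. The function is
#' deterministic: identical contexts yield identical advice.
#'
#' Missing creatinine falls back to a diuresis-only renal assessment and vice
#' versa; with both missing, normal renal function is assumed and a warning
#' raised. Potassium is never clipped or corrected silently.
#'
#' @param ctx An [advisory_context()].
#' @param config An [advisor_config()].
#' @return An object of class `advice`: list with `rate` (mmol/h),
#'   `next_interval` (h), `state`, `alerts`, `clearance_fraction`, `target`,
#'   `renal_impaired`, `gfr`.
#' @examples
#' ctx <- advisory_context(potassium = 4.0, creatinine = 88.4, age = 60,
#'                         weight = 70, sex = "m", diuresis_6h = 540,
#'                         now = 12,
#'                         infusion_log = data.frame(start_h = 4, end_h = 12,
#'                                                   rate_mmol_h = 4))
#' advise(ctx)
#' @export
advise <- function(ctx, config = advisor_config()) {
  stopifnot(inherits(ctx, "advisory_context"))
  validate_advisory_context(ctx)

  gfr <- if (is.finite(ctx$creatinine))
    cockcroft_gault(ctx$age, ctx$weight, ctx$sex, ctx$creatinine)
  else NA_real_
  diuresis_rate <- if (is.finite(ctx$diuresis_6h)) ctx$diuresis_6h / 6
  else NA_real_
  if (!is.finite(gfr) && !is.finite(diuresis_rate))
    warning("no creatinine and no diuresis available; assuming normal renal function",
            call. = FALSE)

  cf <- clearance_fraction(gfr, diuresis_rate, ctx$on_rrt, config)
  impaired <- is_renal_impaired(gfr, diuresis_rate, config)
  target <- target_range(impaired, config)
  state <- classify_potassium(ctx$potassium, target)

  rate <- switch(state,
    hypokalemia = sliding_scale_rate(ctx$potassium, target, config),
    normokalemia = {
      m <- mean_recent_rate(ctx$infusion_log, ctx$admission_time, ctx$now,
                            config$mean_window)
      round_rate(within_range_rate(m, cf, config), config$rate_resolution)
    },
    hyperkalemia = 0
  )
  rate <- max(0, rate)

  alerts <- check_alerts(ctx$potassium, impaired, rate, config)
  structure(list(
    rate = rate,
    next_interval = next_interval(state, alerts, config),
    state = state,
    alerts = alerts,
    clearance_fraction = cf,
    target = target,
    renal_impaired = impaired,
    gfr = gfr
  ), class = "advice")
}

#' @export
print.advice <- function(x, ...) {
  cat(advice_label(x), sep = "\n")
  invisible(x)
}
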