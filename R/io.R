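#' Read a cohort measurement CSV
#'
#' Expects a comma-separated, dot-decimal, UTF-8 file with a mandatory header
#' `patient_id,time_h,potassium_mmol_l`. Rows are sorted by time within
#' patient; malformed rows (non-numeric values, negative times, non-positive
#' potassium) are rejected with their row numbers.
#'
#' @param path File path.
#' @return Data frame with columns `patient_id`, `time_h`,
#'   `potassium_mmol_l`, sorted by patient then time.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_h", "potassium_mmol_l")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "),
         call. = FALSE)
  time <- suppressWarnings(as.numeric(d$time_h))
  pot <- suppressWarnings(as.numeric(d$potassium_mmol_l))
  bad <- which(!is.finite(time) | !is.finite(pot) | time < 0 | pot <= 0)
  if (length(bad))
    stop("malformed measurement rows (after header): ",
         paste(bad, collapse = ", "), call. = FALSE)
  d$time_h <- time; d$potassium_mmol_l <- pot
  d <- d[order(d$patient_id, d$time_h), need, drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read an infusion-history CSV
#'
#' Header `start_h,end_h,rate_mmol_h` (a leading `patient_id` column is
#' accepted for cohort files). Malformed rows are rejected with row numbers.
#'
#' @param path File path.
#' @return Data frame usable as an `infusion_log`.
#' @export
read_infusions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_h", "end_h", "rate_mmol_h")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("malformed rows in column ", col, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    d[[col]] <- v
  }
  if (any(d$rate_mmol_h < 0)) stop("negative infusion rate", call. = FALSE)
  keep <- intersect(c("patient_id", need), names(d))
  ord <- if ("patient_id" %in% keep) order(d$patient_id, d$start_h)
  else order(d$start_h)
  d <- d[ord, keep, drop = FALSE]
  rownames(d) <- NULL
  d
}

# deterministic CSV writer: fixed decimal formatting, LF endings
write_table_csv <- function(d, path, digits = 6) {
  num <- vapply(d, is.numeric, logical(1))
  for (col in names(d)[num])
    d[[col]] <- formatC(d[[col]], digits = digits, format = "g")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = ","), con, sep = "\n")
  if (nrow(d))
    writeLines(do.call(paste, c(unname(as.list(d)), sep = ",")), con,
               sep = "\n")
  invisible(path)
}

#' Serialize advice as JSON
#'
#' Stable key order, suitable for machine consumption; round-trips through
#' [jsonlite::fromJSON()] without loss.
#'
#' @param advice An `advice` object from [advise()].
#' @return A JSON string.
#' @export
write_advice <- function(advice) {
  stopifnot(inherits(advice, "advice"))
  jsonlite::toJSON(list(
    rate_mmol_h = advice$rate,
    next_interval_h = advice$next_interval,
    state = advice$state,
    alerts = I(as.character(advice$alerts)),  # always a JSON array
    clearance_fraction = advice$clearance_fraction,
    target_low = advice$target[["low"]],
    target_high = advice$target[["high"]]
  ), auto_unbox = TRUE, digits = NA)
}

#' Render advice as a pump label
#'
#' Human-readable block mirroring the label printed for the nurse: pump rate,
#' time to the next measurement, and alert lines in upper case.
#'
#' @param advice An `advice` object.
#' @return Character vector of label lines.
#' @export
advice_label <- function(advice) {
  stopifnot(inherits(advice, "advice"))
  lines <- c(
    sprintf("POTASSIUM PUMP RATE: %.1f mmol/h", advice$rate),
    sprintf("NEXT MEASUREMENT IN: %g h", advice$next_interval),
    sprintf("state: %s (target %.1f-%.1f mmol/L, clearance %.2f)",
            advice$state, advice$target[["low"]], advice$target[["high"]],
            advice$clearance_fraction)
  )
  if (length(advice$alerts))
    lines <- c(lines, paste0("!! ", toupper(gsub("_", " ", advice$alerts))))
  lines
}

#' Load advisor configuration overrides from JSON
#'
#' A flat JSON object whose keys override [advisor_config()] defaults;
#' unknown keys are an error.
#'
#' @param path JSON file path.
#' @return An `advisor_config`.
#' @export
read_advisor_config <- function(path) {
  ov <- jsonlite::fromJSON(path)
  defaults <- formals(advisor_config)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(advisor_config, ov)
}

#' Write a simulation run to disk
#'
#' Writes `measurements.csv`, `infusions.csv`, `patients.csv` and a
#' `manifest.json` (config snapshot, seed, package version) into `dir`. The
#' writers are deterministic: identical runs give byte-identical files.
#'
#' @param run Output of [run_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The [simulation_config()] used.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(run$measurements, file.path(dir, "measurements.csv"))
  write_table_csv(run$infusions, file.path(dir, "infusions.csv"))
  write_table_csv(run$patients, file.path(dir, "patients.csv"))
  manifest <- list(
    tool = "gripk",
    version = as.character(utils::packageVersion("gripk")),
    config = unclass(config),
    seed = config$seed
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Serialize a cohort report as JSON
#'
#' @param report A `cohort_report` from [compare_arms()].
#' @return A JSON string.
#' @export
write_report <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  jsonlite::toJSON(list(
    arms = report$arms,
    odds_ratios = lapply(report$odds_ratios, as.list),
    chisq_p = report$chisq_p,
    mann_whitney_p = report$mann_whitney_p,
    presentation = report$presentation,
    thresholds = as.list(report$thresholds)
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
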