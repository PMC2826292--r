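#' Virtual ICU patient: one-compartment potassium kinetics
#'
#' Kinetic constants of the virtual-patient model used for closed-loop
#' testing. Plasma potassium follows
#' \deqn{dC/dt = (R + B + H (C_{set} - C) - CL_0 f C) / V}
#' with infusion rate R (mmol/h), endogenous input B (mmol/h), transcellular
#' buffering H (L/h) toward a set point, renal elimination `CL0 * f * C`
#' scaled by the clearance fraction f, and distribution volume V (L), plus
#' Gaussian process noise. The default calibration puts the steady state at
#' 4.2 mmol/L under a 2.3 mmol/h infusion (the typical administered rate at
#' full clearance) and at 3.5 mmol/L with no infusion, so untreated patients
#' drift hypokalemic.
#'
#' @param volume Distribution volume V, L (> 0).
#' @param renal_clearance Renal clearance at clearance fraction 1, L/h (> 0).
#' @param buffering Transcellular buffering H, L/h (> 0).
#' @param set_point Buffering set point, mmol/L.
#' @param endogenous_input Endogenous/enteral potassium input B, mmol/h.
#' @param clearance_fraction Dimensionless renal clearance fraction f (>= 0).
#' @param process_noise_sd Process noise, mmol/L per sqrt(h) (>= 0).
#' @param measurement_noise_sd Analyzer noise SD, mmol/L (>= 0).
#' @param initial_potassium Plasma potassium at admission, mmol/L.
#'
#' @return An object of class `virtual_patient_params`.
#' @examples
#' p <- virtual_patient_params()
#' steady_state_potassium(p, infusion_rate = 2.3)  # ~4.2
#' @export
virtual_patient_params <- function(volume = 15,
                                   renal_clearance = 2.286,
                                   buffering = 1.0,
                                   set_point = 4.2,
                                   endogenous_input = 7.3,
                                   clearance_fraction = 1,
                                   process_noise_sd = 0.15,
                                   measurement_noise_sd = 0.05,
                                   initial_potassium = 4.0) {
  p <- structure(list(
    volume = volume, renal_clearance = renal_clearance,
    buffering = buffering, set_point = set_point,
    endogenous_input = endogenous_input,
    clearance_fraction = clearance_fraction,
    process_noise_sd = process_noise_sd,
    measurement_noise_sd = measurement_noise_sd,
    initial_potassium = initial_potassium
  ), class = "virtual_patient_params")
  stopifnot(p$volume > 0, p$renal_clearance > 0, p$buffering > 0,
            p$clearance_fraction >= 0, p$process_noise_sd >= 0,
            p$measurement_noise_sd >= 0, p$initial_potassium > 0)
  p
}

#' @export
print.virtual_patient_params <- function(x, ...) {
  cat(sprintf(
    "virtual patient: V=%.1f L, CL0=%.3f L/h, H=%.2f L/h, B=%.2f mmol/h,\n  set point %.2f mmol/L, clearance fraction %.2f, K0 %.2f mmol/L\n",
    x$volume, x$renal_clearance, x$buffering, x$endogenous_input,
    x$set_point, x$clearance_fraction, x$initial_potassium))
  invisible(x)
}

#' Closed-form steady state of the kinetic model
#'
#' @param params A [virtual_patient_params()].
#' @param infusion_rate Constant infusion rate R, mmol/h.
#' @return Steady-state potassium
#'   `(R + B + H * set_point) / (H + CL0 * f)`, mmol/L.
#' @export
steady_state_potassium <- function(params, infusion_rate = 0) {
  (infusion_rate + params$endogenous_input +
     params$buffering * params$set_point) /
    (params$buffering + params$renal_clearance * params$clearance_fraction)
}

# deterministic drift over one step (no noise, no floor)
step_drift <- function(C, params, infusion_rate, dt) {
  C + dt * (infusion_rate + params$endogenous_input +
              params$buffering * (params$set_point - C) -
              params$renal_clearance * params$clearance_fraction * C) /
    params$volume
}

#' Advance the virtual patient by one time step
#'
#' Euler-Maruyama step of the kinetic model with Gaussian process noise
#' (`process_noise_sd * sqrt(dt)`), floored at 0.5 mmol/L. Draws from the
#' current R random stream; set the seed for reproducibility.
#'
#' @param potassium Current plasma potassium C, mmol/L.
#' @param params A [virtual_patient_params()].
#' @param infusion_rate mmol/h.
#' @param dt Step, hours (must be <= 0.25).
#' @return New plasma potassium, mmol/L.
#' @export
step_patient <- function(potassium, params, infusion_rate, dt) {
  if (!is.finite(potassium) || !is.finite(infusion_rate) || !is.finite(dt))
    stop("non-finite simulation state", call. = FALSE)
  if (dt <= 0 || dt > 0.25)
    stop("dt must be in (0, 0.25] h", call. = FALSE)
  C <- step_drift(potassium, params, infusion_rate, dt)
  if (params$process_noise_sd > 0)
    C <- C + stats::rnorm(1L, 0, params$process_noise_sd * sqrt(dt))
  if (!is.finite(C)) stop("simulation produced non-finite potassium",
                          call. = FALSE)
  max(0.5, C)
}

#' Simulated point-of-care potassium measurement
#'
#' Adds analyzer noise and rounds to the 0.1 mmol/L reporting resolution of a
#' bedside blood-gas analyzer.
#'
#' @param potassium True plasma potassium, mmol/L (> 0).
#' @param params A [virtual_patient_params()].
#' @return Measured potassium, mmol/L.
#' @export
measure_potassium <- function(potassium, params) {
  stopifnot(potassium > 0)
  v <- potassium
  if (params$measurement_noise_sd > 0)
    v <- v + stats::rnorm(1L, 0, params$measurement_noise_sd)
  max(0.1, round(v, 1))
}

#' Simulation configuration
#'
#' @param n_patients Cohort size.
#' @param duration Simulated ICU stay per patient, hours.
#' @param dt Integration step, hours (default 0.005, small enough that halving
#'   it perturbs a noise-free trajectory by well under 1e-3 mmol/L even for
#'   the steepest sliding-scale transients; must be <= 0.25).
#' @param seed Master seed; fixes cohort sampling and every per-patient noise
#'   stream end-to-end.
#' @param controller `"grip2"` or `"physician"`.
#' @param admission_mean,admission_sd Admission potassium distribution
#'   (mmol/L), truncated to `[2.0, 6.5]`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 100, duration = 120, dt = 0.005,
                              seed = 1, controller = c("grip2", "physician"),
                              admission_mean = 4.0, admission_sd = 0.4) {
  controller <- match.arg(controller)
  stopifnot(n_patients > 0, duration > 0, dt > 0, dt <= 0.25)
  structure(list(n_patients = as.integer(n_patients), duration = duration,
                 dt = dt, seed = as.integer(seed), controller = controller,
                 admission_mean = admission_mean, admission_sd = admission_sd),
            class = "simulation_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# deterministic per-patient stream seed below 2^31
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + 7919 * as.numeric(i)) %% 2147483629)
}

#' Sample a heterogeneous virtual cohort
#'
#' Draws `n` virtual patients with admission potassium ~ Normal(4.0, 0.4)
#' truncated to `[2.0, 6.5]`, about 11% with acute kidney injury (high
#' creatinine, oliguria; roughly 5% of the cohort on renal replacement
#' therapy) and individual kinetic constants around the calibrated defaults.
#' Each patient's kinetic clearance fraction is derived from their own
#' covariates through [clearance_fraction()], so the advisor's renal
#' assessment and the simulated physiology agree. Impaired patients get a
#' reduced endogenous potassium input, emulating dietary potassium
#' restriction in kidney injury.
#'
#' @param n Cohort size (> 0).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param arm Optional label stored on the cohort (sampling does not depend
#'   on it, so both study arms can share one cohort).
#' @return A list of patients, each a list with `params`
#'   ([virtual_patient_params()]), `covariates` (age, weight, sex,
#'   creatinine, diuresis_6h, on_rrt) and `sim_seed`.
#' @export
make_cohort <- function(n, seed = 1, arm = NULL) {
  stopifnot(n > 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    admission_k <- rnorm_trunc(1, 4.0, 0.4, 2.0, 6.5)
    age <- rnorm_trunc(1, 62, 15, 18, 90)
    weight <- rnorm_trunc(1, 78, 15, 45, 130)
    sex <- if (stats::runif(1) < 0.66) "male" else "female"
    impaired <- stats::runif(1) < 0.11
    if (impaired) {
      creatinine <- rnorm_trunc(1, 250, 60, 130, 500)
      diuresis_6h <- stats::runif(1, 40, 170)   # 7-28 mL/h: oliguric
      on_rrt <- stats::runif(1) < 0.45
      endo <- rnorm_trunc(1, 4.5, 0.7, 2.5, 6.5)  # restricted K intake
    } else {
      creatinine <- rnorm_trunc(1, 90, 15, 50, 120)
      diuresis_6h <- rnorm_trunc(1, 500, 150, 200, 1200)
      on_rrt <- FALSE
      endo <- rnorm_trunc(1, 7.3, 0.7, 5.0, 9.6)
    }
    gfr <- cockcroft_gault(age, weight, sex, creatinine)
    f <- clearance_fraction(gfr, diuresis_6h / 6, on_rrt)
    params <- virtual_patient_params(
      volume = rnorm_trunc(1, 15, 1.5, 10, 20),
      endogenous_input = endo,
      set_point = rnorm_trunc(1, 4.2, 0.1, 3.9, 4.5),
      clearance_fraction = f,
      initial_potassium = admission_k
    )
    cohort[[i]] <- list(
      params = params,
      covariates = list(age = age, weight = weight, sex = sex,
                        creatinine = creatinine, diuresis_6h = diuresis_6h,
                        on_rrt = on_rrt),
      sim_seed = derive_seed(seed, i)
    )
  }
  attr(cohort, "arm") <- arm
  attr(cohort, "seed") <- as.integer(seed)
  cohort
}

#' GRIP-II closed-loop controller
#'
#' Controller-protocol wrapper around [advise()]: at each measurement it
#' builds the advisory context from the patient covariates and the infusion
#' log so far, and applies the advised rate immediately with the advised
#' next-measurement interval.
#'
#' @param measurement Measured potassium, mmol/L.
#' @param time Hours since admission.
#' @param state Controller state; must carry `covariates`, `config`
#'   (an [advisor_config()]) and `infusion_log`.
#' @return List with `rate`, `effective_time`, `next_time`, `state`.
#' @export
grip2_controller <- function(measurement, time, state) {
  cov <- state$covariates
  ctx <- advisory_context(
    potassium = measurement, creatinine = cov$creatinine,
    age = cov$age, weight = cov$weight, sex = cov$sex,
    diuresis_6h = cov$diuresis_6h, on_rrt = cov$on_rrt,
    infusion_log = state$infusion_log, admission_time = 0, now = time
  )
  adv <- advise(ctx, state$config)
  list(rate = adv$rate, effective_time = time,
       next_time = time + adv$next_interval, state = state)
}

physician_dose <- function(potassium) {
  # coarse sliding-scale-like choice at 2 mmol/h resolution
  raw <- 20 - (14 / 1.5) * (potassium - 2.0)
  min(20, max(2, 2 * round(raw / 2)))
}

#' Physician-driven baseline controller
#'
#' Emulates pre-protocol practice: the infusion rate is revised once a day at
#' the morning review (in-range values leave the rate unchanged; hypokalemia
#' below the 3.8 mmol/L target is dosed on a coarse 2 mmol/h sliding scale;
#' above 5.0 mmol/L the infusion is stopped). Between reviews only a
#' distinctly abnormal value (below 3.0 or above 5.5 mmol/L) triggers a
#' telephone consult whose rate change takes effect after a one-hour delay.
#' Measurements are taken every 4 hours.
#'
#' @inheritParams grip2_controller
#' @param state Controller state with `current_rate` and `next_review`
#'   (initialised to 0 by [run_closed_loop()]).
#' @return List with `rate`, `effective_time`, `next_time`, `state`.
#' @export
physician_controller <- function(measurement, time, state) {
  rate <- state$current_rate
  eff <- time
  if (time >= state$next_review - 1e-9) {
    if (measurement > 5.0) rate <- 0
    else if (measurement < 3.8) rate <- physician_dose(measurement)
    state$next_review <- state$next_review + 24
  } else if (measurement < 3.0) {
    rate <- physician_dose(measurement)
    eff <- time + 1
  } else if (measurement > 5.5) {
    rate <- 0
    eff <- time + 1
  }
  state$current_rate <- rate
  list(rate = rate, effective_time = eff, next_time = time + 4, state = state)
}

#' Run one virtual patient in closed loop
#'
#' Alternates Euler-Maruyama integration of the kinetic model with controller
#' calls at controller-scheduled measurement times. The GRIP-II controller
#' applies its advice immediately; the physician emulator may defer a rate
#' change (consult delay). Fully reproducible given `seed`.
#'
#' @param patient A cohort element from [make_cohort()], or a bare
#'   [virtual_patient_params()] (then `covariates` must be supplied for the
#'   GRIP-II controller).
#' @param config A [simulation_config()] (its `controller` field is
#'   overridden by `controller` if given).
#' @param controller `"grip2"`, `"physician"`, or a function following the
#'   controller protocol.
#' @param advisor_cfg An [advisor_config()] for the GRIP-II controller.
#' @param covariates Clinical covariates when `patient` is bare params.
#' @param seed Per-run seed; defaults to the patient's `sim_seed` or the
#'   config seed.
#' @param initial_rate Infusion rate running at admission (default 0).
#' @return List with data frames `measurements` (`time_h`,
#'   `potassium_mmol_l`), `infusions` (`start_h`, `end_h`, `rate_mmol_h`,
#'   tiling `[0, duration]` without overlap) and `trajectory` (`time_h`,
#'   `potassium_true`).
#' @export
run_closed_loop <- function(patient, config = simulation_config(),
                            controller = config$controller,
                            advisor_cfg = advisor_config(),
                            covariates = NULL, seed = NULL,
                            initial_rate = 0) {
  if (inherits(patient, "virtual_patient_params"))
    patient <- list(params = patient, covariates = covariates,
                    sim_seed = config$seed)
  params <- patient$params
  if (is.null(seed)) seed <- patient$sim_seed %||% config$seed

  ctrl_fun <- controller
  if (is.character(controller)) {
    ctrl_fun <- switch(match.arg(controller, c("grip2", "physician")),
                       grip2 = grip2_controller,
                       physician = physician_controller)
  }
  state <- list(covariates = patient$covariates, config = advisor_cfg,
                infusion_log = NULL, current_rate = initial_rate,
                next_review = 0)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  dt <- config$dt
  n_steps <- ceiling(config$duration / dt)
  noise <- if (params$process_noise_sd > 0)
    stats::rnorm(n_steps, 0, params$process_noise_sd * sqrt(dt))
  else numeric(n_steps)

  C <- params$initial_potassium
  traj <- numeric(n_steps + 1L); traj[1L] <- C
  rate <- initial_rate
  pending <- NULL
  next_meas <- 0
  meas_t <- numeric(0); meas_v <- numeric(0)
  seg_start <- numeric(0); seg_rate <- numeric(0); seg_end <- numeric(0)
  cur_start <- 0

  close_segment <- function(t_now, new_rate) {
    if (t_now > cur_start + 1e-12) {
      seg_start[length(seg_start) + 1L] <<- cur_start
      seg_end[length(seg_end) + 1L] <<- t_now
      seg_rate[length(seg_rate) + 1L] <<- rate
    }
    cur_start <<- t_now
    rate <<- new_rate
  }

  for (i in seq_len(n_steps + 1L)) {
    t <- (i - 1L) * dt
    if (!is.null(pending) && t >= pending$time - 1e-9) {
      close_segment(t, pending$rate)
      pending <- NULL
    }
    if (t <= config$duration + 1e-9 && t >= next_meas - 1e-9) {
      K <- measure_potassium(C, params)
      meas_t[length(meas_t) + 1L] <- t
      meas_v[length(meas_v) + 1L] <- K
      # log as seen by the controller: closed segments plus the running one
      log_df <- data.frame(start_h = c(seg_start, if (t > cur_start + 1e-12) cur_start),
                           end_h = c(seg_end, if (t > cur_start + 1e-12) t),
                           rate_mmol_h = c(seg_rate, if (t > cur_start + 1e-12) rate))
      state$infusion_log <- log_df
      res <- tryCatch(ctrl_fun(K, t, state), error = function(e)
        stop("controller failed at t=", t, " h: ", conditionMessage(e),
             call. = FALSE))
      state <- res$state
      next_meas <- res$next_time
      if (res$effective_time <= t + 1e-9) {
        if (res$rate != rate) close_segment(t, res$rate)
      } else if (res$rate != rate) {
        pending <- list(rate = res$rate, time = res$effective_time)
      }
    }
    if (i <= n_steps) {
      C <- step_drift(C, params, rate, dt) + noise[i]
      if (!is.finite(C))
        stop("simulation produced non-finite potassium", call. = FALSE)
      C <- max(0.5, C)
      traj[i + 1L] <- C
    }
  }
  close_segment(n_steps * dt, 0)

  list(
    measurements = data.frame(time_h = meas_t, potassium_mmol_l = meas_v),
    infusions = data.frame(start_h = seg_start, end_h = seg_end,
                           rate_mmol_h = seg_rate),
    trajectory = data.frame(time_h = (0:n_steps) * dt, potassium_true = traj)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a whole cohort in closed loop
#'
#' @param cohort From [make_cohort()].
#' @param config A [simulation_config()].
#' @param controller `"grip2"` or `"physician"` (defaults to the config).
#' @param advisor_cfg An [advisor_config()].
#' @return List of data frames `measurements` (`patient_id`, `time_h`,
#'   `potassium_mmol_l`), `infusions` (`patient_id`, `start_h`, `end_h`,
#'   `rate_mmol_h`) and `patients` (covariates and clearance fraction).
#' @export
run_cohort <- function(cohort, config = simulation_config(),
                       controller = config$controller,
                       advisor_cfg = advisor_config()) {
  meas <- vector("list", length(cohort))
  inf <- vector("list", length(cohort))
  pat <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    run <- run_closed_loop(cohort[[i]], config, controller, advisor_cfg)
    meas[[i]] <- cbind(patient_id = i, run$measurements)
    inf[[i]] <- cbind(patient_id = i, run$infusions)
    cv <- cohort[[i]]$covariates
    pat[[i]] <- data.frame(
      patient_id = i, age = cv$age, weight = cv$weight, sex = cv$sex,
      creatinine = cv$creatinine, diuresis_6h = cv$diuresis_6h,
      on_rrt = cv$on_rrt,
      clearance_fraction = cohort[[i]]$params$clearance_fraction,
      admission_potassium = cohort[[i]]$params$initial_potassium
    )
  }
  list(measurements = do.call(rbind, meas),
       infusions = do.call(rbind, inf),
       patients = do.call(rbind, pat))
}
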