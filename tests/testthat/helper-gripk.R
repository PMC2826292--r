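# shared fixtures and independent oracles, built in code

# covariates of a patient with unambiguously normal renal function
# (Cockcroft-Gault ~163 mL/min, diuresis 90 mL/h -> clearance fraction 1)
normal_covariates <- function() {
  list(age = 40, weight = 80, sex = "male", creatinine = 60,
       diuresis_6h = 540, on_rrt = FALSE)
}

# brute-force oracle for the time-weighted mean infusion rate: sample the
# step function at 1-second midpoints over the lookback span
brute_mean_rate <- function(log, admission, now, window = 8) {
  from <- max(now - window, admission)
  if (now - from <= 0) return(0)
  sec <- 1 / 3600
  t <- seq(from + sec / 2, now, by = sec)
  r <- numeric(length(t))
  for (i in seq_len(nrow(log))) {
    inside <- t >= log$start_h[i] & t < log$end_h[i]
    r[inside] <- log$rate_mmol_h[i]
  }
  mean(r)
}

# brute-force prevalence oracle: resample the interpolated curve at
# 1-second midpoints and count
brute_prevalence <- function(curve, low = 3.5, high = 5.0) {
  sec <- 1 / 3600
  t0 <- curve$time[1]; t1 <- curve$time[length(curve$time)]
  t <- seq(t0 + sec / 2, t1, by = sec)
  v <- approx(curve$time, curve$potassium, xout = t)$y
  total <- curve$stay[2] - curve$stay[1]
  c(hypo = 100 * sum(v < low) * sec / total,
    hyper = 100 * sum(v > high) * sec / total)
}

# random piecewise-linear potassium curve on a whole-second knot grid
random_curve <- function(n_knots = sample(8:25, 1), duration = runif(1, 12, 48)) {
  times <- sort(sample(seq(0, round(duration * 3600)), n_knots)) / 3600
  while (any(diff(times) <= 0))
    times <- sort(sample(seq(0, round(duration * 3600)), n_knots)) / 3600
  k <- 4 + cumsum(rnorm(n_knots, 0, 0.5))
  k <- pmin(6.5, pmax(2.2, k))
  potassium_curve(times, k)
}
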