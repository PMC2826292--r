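test_that("Cockcroft-Gault clearance matches hand evaluation", {
  expect_equal(cockcroft_gault(60, 70, "male", 88.4), 5600 / 72,
               tolerance = 1e-10)
  expect_equal(cockcroft_gault(60, 70, "female", 88.4), 5600 / 72 * 0.85,
               tolerance = 1e-10)
  expect_equal(cockcroft_gault(140, 70, "male", 100), 0)
  expect_equal(cockcroft_gault(150, 70, "male", 100), 0)  # floored
  expect_error(cockcroft_gault(60, 70, "male", 0), "creatinine")
  expect_error(cockcroft_gault(60, -1, "male", 90), "weight")
})

test_that("clearance fraction is the capped min of linear components plus RRT bonus", {
  expect_equal(clearance_fraction(120, 6), 0.1)
  expect_equal(clearance_fraction(120, 90), 1.0)
  expect_equal(clearance_fraction(0, 0, on_rrt = TRUE), 0.5)
  expect_equal(clearance_fraction(50, 90), 0.5)         # GFR-limited
  expect_equal(clearance_fraction(50, 90, on_rrt = TRUE), 1.0)
  expect_equal(clearance_fraction(NA, 30), 0.5)          # diuresis-only
  expect_equal(clearance_fraction(80, NA), 0.8)          # GFR-only
  expect_equal(clearance_fraction(NA, NA), 1)            # both missing
  expect_error(clearance_fraction(-1, 10), "gfr")
})

test_that("renal impairment uses strict 30/30 cutoffs with fallbacks", {
  expect_true(is_renal_impaired(25, 50))
  expect_true(is_renal_impaired(80, 20))
  expect_false(is_renal_impaired(30, 30))  # boundary is not impaired
  expect_false(is_renal_impaired(NA, NA))
  expect_true(is_renal_impaired(NA, 10))
})

test_that("target range is 3.8-4.5, lowered by exactly 0.2 at both ends when impaired", {
  expect_equal(target_range(FALSE), c(low = 3.8, high = 4.5))
  expect_equal(target_range(TRUE), c(low = 3.6, high = 4.3))
  expect_equal(target_range(FALSE) - target_range(TRUE),
               c(low = 0.2, high = 0.2))
})

test_that("classification is strict outside the target range, inclusive at bounds", {
  tr <- target_range(FALSE)
  expect_equal(classify_potassium(3.7, tr), "hypokalemia")
  expect_equal(classify_potassium(4.6, tr), "hyperkalemia")
  expect_equal(classify_potassium(3.8, tr), "normokalemia")
  expect_equal(classify_potassium(4.5, tr), "normokalemia")
  expect_error(classify_potassium(-1, tr), "potassium")
})

test_that("sliding scale passes through both anchors and is monotone non-increasing", {
  expect_equal(sliding_scale_rate(2.0), 20)
  expect_equal(sliding_scale_rate(3.5), 6)
  expect_equal(sliding_scale_rate(2.75), 13)   # midpoint of the line
  expect_equal(sliding_scale_rate(1.5), 20)    # clamped below the low anchor
  expect_equal(sliding_scale_rate(3.65), 4.5)  # extended toward target low
  grid <- seq(1.2, 3.75, by = 0.05)
  rates <- vapply(grid, sliding_scale_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_true(all(rates >= 0 & is.finite(rates)))
  expect_error(sliding_scale_rate(3.9), "below the target range")
})

test_that("mean recent rate is a time-weighted mean with gaps as zero", {
  full <- data.frame(start_h = 0, end_h = 8, rate_mmol_h = 2)
  expect_equal(mean_recent_rate(full, 0, 8), 2)
  step <- data.frame(start_h = c(0, 4), end_h = c(4, 8),
                     rate_mmol_h = c(0, 4))
  expect_equal(mean_recent_rate(step, 0, 8), 2)
  since <- data.frame(start_h = 0, end_h = 2, rate_mmol_h = 3)
  expect_equal(mean_recent_rate(since, 0, 2), 3)   # shorter-than-window stay
  expect_equal(mean_recent_rate(NULL, 0, 0), 0)    # empty lookback span
  gap <- data.frame(start_h = 2, end_h = 6, rate_mmol_h = 6)
  expect_equal(mean_recent_rate(gap, 0, 8), 3)     # 4 h at 6, 4 h gap
  outside <- data.frame(start_h = -1, end_h = 2, rate_mmol_h = 1)
  expect_error(mean_recent_rate(outside, 0, 8), "within")
})

test_that("mean recent rate agrees with a 1-second brute-force integral", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    # non-overlapping intervals on a 0.01 h grid inside [0, 12]
    bounds <- sort(sample(seq(0, 1200), 2 * n)) / 100
    log <- data.frame(start_h = bounds[seq(1, 2 * n, 2)],
                      end_h = bounds[seq(2, 2 * n, 2)],
                      rate_mmol_h = round(runif(n, 0, 15), 1))
    now <- 12
    expect_equal(mean_recent_rate(log, 0, now),
                 brute_mean_rate(log, 0, now),
                 tolerance = 1e-6)
  }
})

test_that("within-range rule has 4*clearance as exact fixed point and converges geometrically", {
  expect_identical(within_range_rate(4, 1), 4)
  expect_identical(within_range_rate(1, 0.25), 1)
  cfg25 <- advisor_config(convergence_weight = 0.25)
  expect_equal(within_range_rate(8, 1, cfg25), 0.75 * 8 + 0.25 * 4)
  for (f in c(0.25, 0.6, 1)) {
    for (m0 in c(0, 2.3, 10, 20)) {
      lim <- 4 * f
      m <- m0
      w <- advisor_config()$convergence_weight
      for (n in 1:40) {
        m <- within_range_rate(m, f)
        expect_lte(abs(m - lim), (1 - w)^n * abs(m0 - lim) + 1e-12)
      }
      expect_equal(m, lim, tolerance = 1e-6)
    }
  }
  expect_error(within_range_rate(-1, 1), "mean_8h")
})

test_that("physician alerts fire outside the printed windows and above 12 mmol/h", {
  expect_equal(check_alerts(2.7, FALSE, 11), "marked_abnormal_potassium")
  expect_equal(check_alerts(2.7, TRUE, 11), character(0))
  expect_setequal(check_alerts(2.5, FALSE, 14),
                  c("marked_abnormal_potassium", "high_infusion_rate"))
  expect_equal(check_alerts(6.1, FALSE, 0), "marked_abnormal_potassium")
  expect_equal(check_alerts(5.9, TRUE, 0), "marked_abnormal_potassium")
  expect_equal(check_alerts(5.9, FALSE, 0), character(0))
  expect_equal(check_alerts(4.0, FALSE, 12), character(0))  # strict > 12
})

test_that("measurement intervals follow the 1/2/4 h table", {
  expect_equal(next_interval("normokalemia"), 4)
  expect_equal(next_interval("hypokalemia"), 2)
  expect_equal(next_interval("hyperkalemia", "marked_abnormal_potassium"), 1)
  cfg <- advisor_config(interval_in_range = 6)
  expect_equal(next_interval("normokalemia", config = cfg), 6)
})

test_that("advise composes the full decision sequence", {
  # severe hypokalemia: sliding-scale anchor plus both alerts
  ctx <- advisory_context(potassium = 2.0, creatinine = 90, age = 61,
                          weight = 80, sex = "m", diuresis_6h = 300)
  a <- advise(ctx)
  expect_equal(a$rate, 20)
  expect_setequal(a$alerts, c("marked_abnormal_potassium",
                              "high_infusion_rate"))
  expect_equal(a$next_interval, 1)
  expect_equal(a$state, "hypokalemia")

  # in range at the fixed point: keep 4 mmol/h, measure again in 4 h
  cov <- normal_covariates()
  ctx2 <- advisory_context(potassium = 4.0, creatinine = cov$creatinine,
                           age = cov$age, weight = cov$weight, sex = cov$sex,
                           diuresis_6h = cov$diuresis_6h, now = 12,
                           infusion_log = data.frame(start_h = 0, end_h = 12,
                                                     rate_mmol_h = 4))
  a2 <- advise(ctx2)
  expect_equal(a2$clearance_fraction, 1)
  expect_equal(a2$rate, 4)
  expect_equal(a2$alerts, character(0))
  expect_equal(a2$next_interval, 4)

  # hyperkalemia always stops the pump
  ctx3 <- advisory_context(potassium = 5.2, creatinine = 90, age = 61,
                           weight = 80, sex = "m", diuresis_6h = 300)
  expect_equal(advise(ctx3)$rate, 0)
  expect_equal(advise(ctx3)$state, "hyperkalemia")

  # purity: identical contexts agree bit-for-bit
  expect_identical(advise(ctx), advise(ctx))
})

test_that("advise falls back gracefully on missing renal inputs", {
  ctx <- advisory_context(potassium = 4.0, creatinine = NA, age = 61,
                          weight = 80, sex = "m", diuresis_6h = NA)
  expect_warning(a <- advise(ctx), "normal renal function")
  expect_equal(a$clearance_fraction, 1)
  expect_false(a$renal_impaired)
  ctx2 <- advisory_context(potassium = 4.0, creatinine = NA, age = 61,
                           weight = 80, sex = "m", diuresis_6h = 60)
  a2 <- advise(ctx2)  # diuresis-only: 10 mL/h -> impaired, clearance 1/6
  expect_true(a2$renal_impaired)
  expect_equal(a2$clearance_fraction, 10 / 60)
  expect_equal(a2$target, c(low = 3.6, high = 4.3))
})

test_that("advised rates are non-negative, finite, and zero under hyperkalemia", {
  set.seed(3)
  for (i in 1:60) {
    ctx <- advisory_context(
      potassium = runif(1, 1.5, 7.5), creatinine = runif(1, 40, 400),
      age = runif(1, 18, 95), weight = runif(1, 45, 130),
      sex = sample(c("m", "f"), 1), diuresis_6h = runif(1, 0, 900),
      on_rrt = runif(1) < 0.1)
    a <- advise(ctx)
    expect_true(is.finite(a$rate) && a$rate >= 0)
    if (a$state == "hyperkalemia") expect_equal(a$rate, 0)
    if (a$rate > 12) expect_true("high_infusion_rate" %in% a$alerts)
  }
})
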