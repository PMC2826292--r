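test_that("linear interpolation crosses thresholds where algebra says", {
  pc <- potassium_curve(c(0, 4), c(3.0, 4.0))
  expect_equal(curve_value(pc, 2), 3.5)            # crossing at t = 2 h
  expect_equal(curve_value(pc, 2), mean(c(3.0, 4.0)))
  flat <- potassium_curve(c(0, 5, 9), c(4.1, 4.1, 4.1))
  expect_equal(curve_value(flat, c(1, 7)), c(4.1, 4.1))
  expect_error(potassium_curve(c(0, 0, 4), c(3, 3.2, 4)), "duplicate")
})

test_that("analytic prevalence solves segment crossings exactly", {
  pc <- potassium_curve(c(0, 4), c(3.0, 4.0))
  expect_equal(curve_prevalence(pc), c(hypo = 50, hyper = 0))
  inr <- potassium_curve(c(0, 6, 12), c(3.9, 4.4, 3.8))
  expect_equal(curve_prevalence(inr), c(hypo = 0, hyper = 0))
  # knot grazing the threshold contributes zero duration
  graze <- potassium_curve(c(0, 2, 4), c(4.0, 3.5, 4.0))
  expect_equal(curve_prevalence(graze), c(hypo = 0, hyper = 0))
  expect_warning(p1 <- curve_prevalence(potassium_curve(3, 4.0)),
                 "zero-duration")
  expect_true(all(is.na(p1)))
})

test_that("analytic prevalence agrees with 1-second brute-force resampling", {
  set.seed(42)
  for (i in 1:100) {
    cu <- random_curve()
    a <- curve_prevalence(cu)
    b <- brute_prevalence(cu)
    expect_lt(max(abs(a - b)), 0.01)  # percentage points
  }
})

test_that("prevalence and incidence are invariant under time translation", {
  set.seed(7)
  cu <- random_curve()
  shifted <- potassium_curve(cu$time + 37.5, cu$potassium)
  expect_equal(curve_prevalence(cu), curve_prevalence(shifted))
  m <- data.frame(time_h = c(9, 13, 17), potassium_mmol_l = c(3.4, 4.0, 5.2))
  m2 <- transform(m, time_h = time_h + 100)
  expect_equal(incidence(m, exclude_before = 8)[c("hypo", "hyper")],
               incidence(m2, exclude_before = 108)[c("hypo", "hyper")])
})

test_that("incidence counts strict threshold violations after the first 8 h", {
  m <- data.frame(time_h = c(9, 13, 17), potassium_mmol_l = c(3.4, 4.0, 5.2))
  inc <- incidence(m)
  expect_equal(inc[["hypo"]], 100 / 3, tolerance = 1e-10)
  expect_equal(inc[["hyper"]], 100 / 3, tolerance = 1e-10)
  expect_equal(inc[["n"]], 3)
})

test_that("incidence edge cases: cutoff, boundary values, empty window", {
  # exactly at the thresholds is in range
  m <- data.frame(time_h = c(10, 12), potassium_mmol_l = c(3.5, 5.0))
  expect_equal(unname(incidence(m)[c("hypo", "hyper")]), c(0, 0))
  early <- data.frame(time_h = c(1, 5), potassium_mmol_l = c(3.0, 3.2))
  expect_warning(res <- incidence(early), "undefined")
  expect_true(all(is.na(res[c("hypo", "hyper")])))
  lots <- data.frame(time_h = seq(9, 108.9, by = 0.1),
                     potassium_mmol_l = rep(4.2, 1000))
  expect_equal(unname(incidence(lots)[c("hypo", "hyper")]), c(0, 0))
})

test_that("odds ratios reproduce the published incidence contrasts", {
  or_hypo <- odds_ratio(0.024, 15857, 0.017, 37717)
  expect_equal(round(or_hypo[["or"]], 1), 1.4)
  or_hyper <- odds_ratio(0.074, 15857, 0.048, 37717)
  expect_equal(round(or_hyper[["or"]], 1), 1.6)
  expect_lt(or_hypo[["ci_low"]], or_hypo[["or"]])
  expect_lt(or_hypo[["or"]], or_hypo[["ci_high"]])
})

test_that("odds-ratio algebra: identity, exact reciprocity, continuity fallback", {
  expect_equal(odds_ratio(0.05, 500, 0.05, 500)[["or"]], 1)
  a <- odds_ratio(0.13, 700, 0.06, 900)[["or"]]
  b <- odds_ratio(0.06, 900, 0.13, 700)[["or"]]
  expect_equal(a * b, 1, tolerance = 1e-12)  # exact up to one ulp
  expect_warning(deg <- odds_ratio(0, 100, 0.1, 100), "continuity")
  expect_true(is.finite(deg[["or"]]) && deg[["or"]] > 0)
})

test_that("percentile bands are monotone and handle coverage gaps", {
  same <- replicate(5, potassium_curve(c(0, 24), c(4.0, 4.4)),
                    simplify = FALSE)
  b <- percentile_bands(same, time_grid = c(0, 12, 24))
  expect_equal(b$p5, b$p95)
  expect_equal(b$p50, c(4.0, 4.2, 4.4))
  three <- list(potassium_curve(c(0, 10), c(3, 3)),
                potassium_curve(c(0, 10), c(4, 4)),
                potassium_curve(c(0, 10), c(5, 5)))
  expect_equal(percentile_bands(three, 5)$p50, 4)
  short <- list(potassium_curve(c(0, 6), c(4, 4)))
  bs <- percentile_bands(short, c(3, 12))
  expect_true(is.na(bs$p50[2]) && bs$n_curves[2] == 0)
  set.seed(8)
  rand <- replicate(30, random_curve(), simplify = FALSE)
  br <- percentile_bands(rand, seq(0, 12, by = 2))
  ok <- stats::complete.cases(br[, c("p5", "p25", "p50", "p75", "p95")])
  expect_true(all(br$p5[ok] <= br$p25[ok] & br$p25[ok] <= br$p50[ok] &
                  br$p50[ok] <= br$p75[ok] & br$p75[ok] <= br$p95[ok]))
  expect_error(percentile_bands(list(), 0:4), "empty")
})

test_that("identical arms compare as null: ORs 1, chi-square p 1", {
  set.seed(14)
  arm <- do.call(rbind, lapply(1:12, function(id) {
    cu <- random_curve()
    data.frame(patient_id = id, time_h = cu$time, potassium_mmol_l = cu$potassium)
  }))
  rep <- suppressWarnings(compare_arms(arm, arm))
  for (o in rep$odds_ratios) expect_equal(o[["or"]], 1)
  expect_equal(rep$chisq_p, 1)
  props <- unlist(rep$arms)
  props <- props[grepl("incidence_h|prevalence", names(props))]
  expect_true(all(props >= 0 & props <= 100))
  expect_identical(rep$arms$before, rep$arms$after)
})

test_that("a worse arm shows elevated odds ratios in the expected direction", {
  set.seed(15)
  mk <- function(center, id0) do.call(rbind, lapply(1:15, function(i) {
    t <- sort(runif(12, 0, 48))
    data.frame(patient_id = id0 + i, time_h = t,
               potassium_mmol_l = center + cumsum(rnorm(12, 0, 0.25)))
  }))
  loose <- mk(4.6, 0)    # drifts high: more hyperkalemia
  tight <- mk(4.15, 100)
  rep <- suppressWarnings(compare_arms(loose, tight))
  expect_gt(rep$odds_ratios$prevalence_hyper[["or"]], 1)
  expect_gt(rep$arms$before$prevalence_hyper, rep$arms$after$prevalence_hyper)
  expect_true(rep$mann_whitney_p >= 0 && rep$mann_whitney_p <= 1)
})
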