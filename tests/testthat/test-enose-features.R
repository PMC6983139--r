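test_that("time-domain statistics match their defining formulas", {
  expect_equal(trace_variance(c(1, 2, 3)), 2 / 3, tolerance = 1e-12)
  expect_equal(trace_variance(rep(5, 75)), 0)
  # homogeneity: scaling by k scales the variance by k^2
  set.seed(1); x <- runif(75)
  expect_equal(trace_variance(3 * x), 9 * trace_variance(x),
               tolerance = 1e-12)

  expect_equal(trace_integral(rep(2, 75)), 150)
  expect_equal(trace_integral(c(1, 2, 3)), 6)
  expect_equal(trace_integral(rep(0, 10)), 0)

  expect_equal(trace_steady_state_average(c(0, 0, 5, 7), t0 = 2), 6)
  expect_equal(trace_steady_state_average(rep(3, 75)), 3)
  # independent of pre-onset values
  y <- x; y[1:55] <- 0
  expect_equal(trace_steady_state_average(x, 55),
               trace_steady_state_average(y, 55))

  expect_equal(trace_average_differential(1:75), 1)
  expect_equal(trace_average_differential(rep(4, 20)), 0)
  # telescoping identity
  expect_equal(trace_average_differential(x),
               (x[75] - x[1]) / 74, tolerance = 1e-12)

  expect_equal(trace_kurtosis(rep(c(-1, 1), 10)), -2, tolerance = 1e-12)
  set.seed(2); g <- rnorm(2e5)
  expect_lt(abs(trace_kurtosis(g)), 0.05)
  expect_error(trace_kurtosis(rep(1, 10)), "degenerate")

  expect_equal(trace_skewness(c(0, 0, 1)), sqrt(6) * sqrt(0.5),
               tolerance = 1e-10)
  expect_equal(round(trace_skewness(c(0, 0, 1)), 4), 1.7321)
  expect_equal(trace_skewness(c(1, 2, 3, 4)), 0, tolerance = 1e-12)
  expect_equal(trace_skewness(-x), -trace_skewness(x), tolerance = 1e-12)
  expect_error(trace_skewness(rep(2, 10)), "degenerate")
})

test_that("statistics agree with literal-loop references on random traces", {
  set.seed(123)
  for (rep in 1:200) {
    x <- runif(75, 0.5, 3) + rnorm(75, 0, 0.2)
    expect_equal(trace_variance(x), oracle_var(x), tolerance = 1e-12)
    expect_equal(trace_integral(x), oracle_inv(x), tolerance = 1e-12)
    expect_equal(trace_steady_state_average(x, 55), oracle_rsav(x, 55),
                 tolerance = 1e-12)
    expect_equal(trace_average_differential(x), oracle_adv(x),
                 tolerance = 1e-12)
    expect_stat_match(trace_kurtosis(x), oracle_kurt(x))
    expect_stat_match(trace_skewness(x), oracle_skew(x))
  }
})

test_that("a record yields exactly 60 name-keyed time-domain features", {
  rec <- simulate_enose(20, 1, seed = 8)
  td <- extract_time_domain(rec)
  expect_length(td, 60)
  expect_true(all(td[paste0("VAR_f", 0:9)] >= 0))
  expect_named(td[1:3], c("VAR_f0", "VAR_f1", "VAR_f2"))
  # permuting sensor columns does not change named values
  perm <- rec
  perm$traces <- rec$traces[, sample(10)]
  expect_equal(sort(names(extract_time_domain(perm))), sort(names(td)))
  expect_equal(extract_time_domain(perm)[names(td)], td)
  # degenerate trace policy: error names the sensor, sentinel warns
  flat <- rec
  flat$traces[, "f3"] <- 1
  expect_error(extract_time_domain(flat), "f3")
  expect_warning(trace_kurtosis(rep(1, 10), degenerate = "zero"),
                 "degenerate")
  expect_warning(trace_skewness(rep(1, 10), degenerate = "zero"),
                 "degenerate")
  td0 <- suppressWarnings(extract_time_domain(flat, degenerate = "zero"))
  expect_equal(td0[["KURT_f3"]], 0)
  expect_equal(td0[["SKEW_f3"]], 0)
})

test_that("CWT energy summaries behave as quadratic energy functionals", {
  rec <- simulate_enose(20, 1, seed = 9)
  rec$traces[] <- 0
  s0 <- extract_cwt_summary(rec)
  expect_equal(unname(s0$S), rep(0, 10))
  expect_equal(s0$WM, 0)
  expect_equal(s0$WA, 0)
  # one nonzero sensor with energy s -> WM = s, WA = s/10
  one <- rec
  set.seed(3)
  one$traces[, "f5"] <- rnorm(75)
  s1 <- extract_cwt_summary(one)
  expect_gt(s1$S[["f5"]], 0)
  expect_equal(s1$WM, s1$S[["f5"]])
  expect_equal(s1$WA, s1$S[["f5"]] / 10)
  # quadratic homogeneity: doubling one trace quadruples its energy
  two <- one
  two$traces[, "f5"] <- 2 * one$traces[, "f5"]
  s2 <- extract_cwt_summary(two)
  expect_equal(s2$S[["f5"]], 4 * s1$S[["f5"]], tolerance = 1e-12)
  expect_error(extract_cwt_summary(rec, wavelet = "nope"), "unknown wavelet")
})

test_that("WM/WA ordering invariants hold on random records", {
  for (seed in 1:5) {
    rec <- simulate_enose(10 + 3 * seed, seed %% 10 + 1, seed = seed)
    s <- extract_cwt_summary(rec)
    expect_gte(s$WA, 0)
    expect_gte(s$WM, s$WA)
    expect_equal(s$WM, max(s$S))
    expect_equal(s$WA, mean(s$S))
  }
})

test_that("the e-nose feature table has 62 feature columns", {
  ds <- simulate_tea_dataset(seed = 2, n_samples = 10, cubes = FALSE)
  tab <- extract_enose_features(ds$enose, ds$truth)
  expect_equal(nrow(tab), 10)
  expect_length(feature_names(tab), 62)
  expect_true(all(c("WM", "WA", "TP_percent") %in% names(tab)))
})
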