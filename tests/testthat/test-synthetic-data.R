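test_that("variety design table reproduces the study totals", {
  v <- default_variety_table()
  expect_equal(nrow(v), 10)
  expect_equal(sum(v$n), 110)
  expect_equal(sum(v$n == 10), 8)
  expect_equal(sum(v$n == 15), 2)
  expect_equal(round(sum(v$n * v$tp_mean) / sum(v$n), 2), 18.78)
  expect_equal(min(v$tp_min), 10.65)
  expect_equal(max(v$tp_max), 29.65)
  expect_setequal(unique(v$category), c("black", "green", "yellow"))
})

test_that("polyphenol draws follow the truncated-normal variety model", {
  v <- default_variety_table()
  hm <- v[v$variety == "Huangshan Maofeng (Anhui)", ]
  x <- draw_tp(hm, n = 10000, seed = 42)
  expect_true(all(x >= hm$tp_min & x <= hm$tp_max))
  # mean within 3 SE of the design mean (the generator re-centres the
  # truncated distribution onto the published mean)
  se <- sd(x) / sqrt(10000)
  expect_lt(abs(mean(x) - hm$tp_mean), 3 * se)
  # sd -> 0 limit returns the mean exactly
  degen <- hm; degen$tp_sd <- 0
  expect_identical(draw_tp(degen, n = 5), rep(hm$tp_mean, 5))
})

test_that("titration conversion is Eq-faithful and linear", {
  expect_equal(titration_to_tp(A = 3, B = 3, omega = 1, m = 1,
                               V1 = 50, V2 = 25), 0)
  x1 <- titration_to_tp(A = 11, B = 1, omega = 2, m = 1, V1 = 10, V2 = 10)
  expect_equal(x1, 10 * 2 * 0.00582 / 0.318, tolerance = 1e-12)
  expect_equal(round(x1, 5), 0.36604)
  # doubling the permanganate difference doubles X; doubling mass halves it
  expect_equal(titration_to_tp(21, 1, 2, 1, 10, 10), 2 * x1)
  expect_equal(titration_to_tp(11, 1, 2, 2, 10, 10), x1 / 2)
  expect_error(titration_to_tp(11, 1, 2, 0, 10, 10), "mass")
  expect_error(titration_to_tp(11, 1, 2, 1, 10, 0), "volumes")
})

test_that("noise-free sensor traces follow the saturating-rise model", {
  nz <- tea_noise(off = TRUE)
  rec <- simulate_enose(20, variety_index = 2, noise = nz)
  p <- enose_response_params()
  off <- teafuse:::variety_amp_offset(2)
  a <- p$sign * (p$base + p$slope * 20) * (1 + off)
  plateau <- 1 + a
  # plateau ordering: W1W (f6) above every other positive sensor
  expect_true(plateau[7] > max(plateau[-7]))
  # signed deviations from 1 per sensor class
  pos <- p$column[p$sensor %in% c("W5S", "W1S", "W1W", "W2S", "W2W")]
  neg <- p$column[p$sensor %in% c("W1C", "W3C", "W5C")]
  final <- rec$traces[75, ]
  expect_true(all(final[pos] > 1))
  expect_true(all(final[neg] < 1))
  # steady-state average within 2% of the closed-form plateau
  for (j in 1:10) {
    rsav <- trace_steady_state_average(rec$traces[, j], t0 = 55)
    expect_lt(abs(rsav - plateau[j]) / abs(a[j]), 0.02)
  }
})

test_that("generation is deterministic under a fixed seed", {
  r1 <- simulate_enose(17.3, 4, seed = 99)
  r2 <- simulate_enose(17.3, 4, seed = 99)
  expect_identical(r1, r2)
  c1 <- simulate_cube(17.3, 4, dim = c(16, 16), seed = 99)
  c2 <- simulate_cube(17.3, 4, dim = c(16, 16), seed = 99)
  expect_identical(c1, c2)
  d1 <- simulate_tea_dataset(seed = 5, cubes = FALSE)
  d2 <- simulate_tea_dataset(seed = 5, cubes = FALSE)
  expect_identical(d1, d2)
})

test_that("cube absorption at 1106 nm deepens with polyphenol content", {
  v <- default_variety_table()[5, ]
  nz <- tea_noise(off = TRUE)
  lo <- simulate_cube(v$tp_min, 5, noise = nz, seed = 7)
  hi <- simulate_cube(v$tp_max, 5, noise = nz, seed = 7)
  band <- which.min(abs(lo$wavelengths - 1106))
  m_lo <- mean(extract_roi_spectrum(lo)$reflectance[band])
  m_hi <- mean(extract_roi_spectrum(hi)$reflectance[band])
  expect_lt(m_hi, m_lo)
  # texture off and noise off -> spatially flat at every band
  flat <- simulate_cube(20, 1, dim = c(8, 8), noise = nz, texture = FALSE)
  per_band_range <- apply(flat$data, 3, function(b) diff(range(b)))
  expect_equal(max(per_band_range), 0)
})

test_that("dataset reproduces per-variety statistics and monotone RSAV", {
  v <- default_variety_table()
  ds <- simulate_tea_dataset(seed = 11, noise = tea_noise(off = TRUE),
                             cubes = FALSE)
  expect_equal(nrow(ds$truth), 110)
  for (i in seq_len(nrow(v))) {
    tp <- ds$truth$TP_percent[ds$truth$variety == v$variety[i]]
    expect_equal(length(tp), v$n[i])
    se <- v$tp_sd[i] / sqrt(v$n[i])
    expect_lt(abs(mean(tp) - v$tp_mean[i]), 4 * se)
    expect_true(all(tp >= v$tp_min[i] & tp <= v$tp_max[i]))
  }
  # noise-free: the RSAV of every sensor is strictly monotone in tp
  # within a variety (by construction of the affine amplitude model)
  one <- ds$truth[ds$truth$variety == v$variety[3], ]
  ord <- order(one$TP_percent)
  rsav <- sapply(one$sample_id[ord], function(id) {
    trace_steady_state_average(ds$enose[[id]]$traces[, "f6"], 55)
  })
  expect_true(all(diff(rsav) > 0))
})

test_that("a simulated dataset writes and reads back through the formats", {
  d <- withr::local_tempdir()
  v <- default_variety_table()
  v$n <- rep(4L, 10)  # desk-scale copy of the design
  ds <- simulate_tea_dataset(varieties = v, seed = 3, cubes = TRUE,
                             cube_dim = c(8, 8),
                             cube_wavelengths = seq(908, 1700, 32),
                             out_dir = d)
  expect_true(file.exists(file.path(d, "enose.csv")))
  expect_true(file.exists(file.path(d, "truth.csv")))
  back <- read_enose_csv(file.path(d, "enose.csv"))
  expect_length(back, 40)
  cube <- read_envi_cube(file.path(d, "cubes", "S001.hdr"))
  expect_identical(cube$data, ds$cubes[[1]]$data)
})
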