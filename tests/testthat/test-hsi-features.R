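test_that("ROI spectrum is the centered-window band mean", {
  wl <- seq(908, 1700, 100)
  uni <- new_cube_for_test(array(0.4, c(9, 9, length(wl))), wl)
  expect_equal(extract_roi_spectrum(uni, 5)$reflectance,
               rep(0.4, length(wl)))
  # ROI pixels 1, border 0: centered 5x5 window of a 9x9 image is rows
  # and cols 3..7
  arr <- array(0, c(9, 9, length(wl)))
  arr[3:7, 3:7, ] <- 1
  framed <- new_cube_for_test(arr, wl)
  expect_equal(extract_roi_spectrum(framed, 5)$reflectance,
               rep(1, length(wl)))
  # random cube agrees with the double-loop oracle
  set.seed(5)
  arr2 <- array(runif(11 * 13 * 4), c(11, 13, 4))
  rnd <- new_cube_for_test(arr2, wl[1:4])
  got <- extract_roi_spectrum(rnd, 6)$reflectance
  ix <- teafuse:::roi_indices(11, 13, 6)
  want <- sapply(1:4, function(b) oracle_roi_mean(arr2[ix$rows, ix$cols, b]))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(extract_roi_spectrum(rnd, 50), "ROI larger")
})

test_that("spectral cropping keeps the closed wavelength interval", {
  cube <- simulate_cube(20, 1, dim = c(8, 8), seed = 1)
  spec <- extract_roi_spectrum(cube, 4)
  crp <- crop_spectrum(spec, 944, 1688)
  expect_true(all(crp$wavelengths >= 944 & crp$wavelengths <= 1688))
  expect_true(944 %in% crp$wavelengths && 1688 %in% crp$wavelengths)
  full <- crop_spectrum(spec, min(spec$wavelengths), max(spec$wavelengths))
  expect_equal(full$reflectance, spec$reflectance)
  expect_error(crop_spectrum(spec, 1, 2), "no bands")
})

test_that("SPA picks minimally collinear, informative wavelength pairs", {
  # mutually orthogonal centred columns with distinct norms; target built
  # from the two strongest columns
  set.seed(11)
  n <- 12
  Q <- qr.Q(qr(matrix(rnorm(n * n, 0, 1), n, n)))
  X <- Q[, 1:6] %*% diag(c(6, 5, 4, 3, 2, 1))
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- X[, 1] + 0.5 * X[, 2] + 18
  wl <- seq(1000, 1100, 20)
  sel <- spa_select(X, y, wl, k = 2)
  expect_equal(sel$indices, c(1, 2))
  # a duplicated column is never selected twice
  Xd <- cbind(X[, 1], X[, 1], X[, 2:4])
  sel2 <- spa_select(Xd, y, wl[1:5], k = 3)
  expect_false(all(c(1, 2) %in% sel2$indices))
  expect_error(spa_select(X, y, wl, k = 7), "k exceeds")
})

test_that("SPA agrees with the exhaustive chain oracle on small problems", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 15; p <- 8
    X <- matrix(runif(n * p), n, p)
    y <- 10 + 3 * X[, 3] - 2 * X[, 6] + rnorm(n, 0, 0.1)
    for (k in 2:3) {
      got <- spa_select(X, y, seq_len(p), k = k)
      expect_equal(got$indices, oracle_spa(X, y, k))
    }
  }
})

test_that("sub-band energies satisfy Parseval for every filter", {
  set.seed(31)
  for (wname in c("db1", "db2", "db4", "db8")) {
    for (side in c(32, 64)) {
      img <- matrix(rnorm(side * side), side, side)
      dec <- dwt2(img, wavelet = wname, levels = 2)
      expect_equal(subband_energy_total(dec), sum(img^2),
                   tolerance = 1e-9, info = paste(wname, side))
    }
  }
  expect_error(dwt2(matrix(0, 2, 2), levels = 2), "too small")
  expect_error(dwt2(matrix(0, 8, 8), wavelet = "sym5"), "unknown wavelet")
})

test_that("wavelet energy/entropy features scale and degenerate correctly", {
  expect_equal(unname(wavelet_subband_features(matrix(3.7, 16, 16))),
               rep(0, 12))
  set.seed(7)
  img <- matrix(runif(50 * 50, 0.2, 0.9), 50, 50)
  f1 <- wavelet_subband_features(img)
  f3 <- wavelet_subband_features(3 * img)
  we <- grepl("_WE$", names(f1))
  expect_equal(f3[we], 9 * f1[we], tolerance = 1e-10)
  expect_equal(f3[!we], f1[!we], tolerance = 1e-10)
  expect_true(all(f1[we] >= 0))
  expect_true(all(is.finite(f1)))
  # a 1x1 sub-band concentrates all energy in one coefficient: entropy 0
  tiny <- wavelet_subband_features(matrix(rnorm(4), 2, 2),
                                   wavelet = "db1", levels = 1)
  expect_equal(unname(tiny[c("LH1_WEN", "HL1_WEN", "HH1_WEN")]),
               rep(0, 3))
})

test_that("cube feature extraction yields the 24 named band features", {
  cube <- simulate_cube(22, 4, seed = 13)
  f <- extract_hsi_features(cube)
  expect_length(f, 24)
  expect_true(all(c("B1_HL1_WE", "B1_LH1_WE", "B2_HL2_WE",
                    "B2_LH1_WEN") %in% names(f)))
  # locality: altering bands far from 1106/1375 nm leaves features alone
  other <- cube
  touched <- which(!(abs(cube$wavelengths - 1106) < 2 |
                       abs(cube$wavelengths - 1375) < 2))
  other$data[, , touched] <- other$data[, , touched] + 0.05
  expect_identical(extract_hsi_features(other), f)
  expect_error(extract_hsi_features(cube, c(920, 1375)),
               "outside the cropped range")
})
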