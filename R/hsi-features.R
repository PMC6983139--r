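# ROI spectra, spectral cropping, SPA wavelength selection, and 2-level
# wavelet energy/entropy features of band images.

# Centered ROI row/col index ranges: top-left at (floor((H-r)/2),
# floor((W-r)/2)), 0-based — i.e. rows floor((H-r)/2)+1 .. +r in R.
roi_indices <- function(H, W, roi_size) {
  stop_if(roi_size > H || roi_size > W, "ROI larger than image")
  r0 <- floor((H - roi_size) / 2)
  c0 <- floor((W - roi_size) / 2)
  list(rows = (r0 + 1):(r0 + roi_size), cols = (c0 + 1):(c0 + roi_size))
}

#' Mean ROI spectrum of a cube
#'
#' Averages reflectance over the centered `roi_size` x `roi_size` pixel
#' window at every band, giving the sample's representative spectrum.
#'
#' @param cube A `spectral_cube`.
#' @param roi_size ROI side length in pixels (default 50).
#' @return A `roi_spectrum`: list with `wavelengths` (nm) and
#'   `reflectance`.
#' @export
extract_roi_spectrum <- function(cube, roi_size = 50) {
  d <- dim(cube$data)
  ix <- roi_indices(d[1], d[2], roi_size)
  refl <- apply(cube$data[ix$rows, ix$cols, , drop = FALSE], 3, mean)
  stop_if(any(!is.finite(refl)), "non-finite reflectance in ROI")
  structure(list(wavelengths = cube$wavelengths, reflectance = refl),
            class = "roi_spectrum")
}

#' @export
print.roi_spectrum <- function(x, ...) {
  cat(sprintf("<roi_spectrum> %d bands, %.0f-%.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Crop a spectrum to a wavelength window
#'
#' Retains bands with `low <= lambda <= high` (closed interval). The ends
#' of line-scan NIR spectra are noise-dominated; the default working
#' window downstream is 944--1688 nm.
#'
#' @param spec A `roi_spectrum`.
#' @param low,high Window bounds in nm.
#' @return The cropped `roi_spectrum`.
#' @export
crop_spectrum <- function(spec, low = 944, high = 1688) {
  stop_if(low >= high, "low must be < high")
  keep <- spec$wavelengths >= low & spec$wavelengths <= high
  stop_if(!any(keep), "no bands inside [", low, ", ", high, "] nm")
  structure(list(wavelengths = spec$wavelengths[keep],
                 reflectance = spec$reflectance[keep]),
            class = "roi_spectrum")
}

#' Successive projections algorithm for wavelength selection
#'
#' Classical SPA over the columns of a (samples x bands) spectral matrix:
#' from every candidate start band, a projection chain is grown by
#' repeatedly selecting the band whose column has maximal norm orthogonal
#' to the span of the bands already in the chain (ties broken by lowest
#' band index). Each k-band chain is then scored by the RMSE of an
#' ordinary multilinear regression fitted on a calibration part and
#' evaluated on a validation part; the chain with minimal validation RMSE
#' wins. Columns are mean-centred before the projections. Fully
#' deterministic: the internal calibration/validation split is
#' systematic — samples ordered by target, every third held out.
#'
#' @param X Numeric matrix, samples x bands.
#' @param y Target vector (polyphenol %, length `nrow(X)`).
#' @param wavelengths Band wavelengths (nm), length `ncol(X)`.
#' @param k Number of bands to select.
#' @return List: `wavelengths` (ascending), `indices`, `rmse` (winning
#'   validation RMSE), `start` (winning start band index).
#' @export
spa_select <- function(X, y, wavelengths, k = 2) {
  stop_if(!is.matrix(X), "X must be a matrix")
  p <- ncol(X)
  stop_if(k > p, "k exceeds band count")
  stop_if(nrow(X) < 2, "need at least 2 samples")
  stop_if(length(wavelengths) != p, "wavelength axis mismatch")
  ord <- order(y)
  val <- ord[seq(2, length(ord), by = 3)]
  cal <- setdiff(seq_along(y), val)
  Xc <- scale(X[cal, , drop = FALSE], center = TRUE, scale = FALSE)
  chains <- lapply(seq_len(p), function(j0) spa_chain(Xc, j0, k))
  scores <- vapply(chains, function(ch) {
    fit <- lm(y[cal] ~ X[cal, ch, drop = FALSE])
    co <- coef(fit)
    co[is.na(co)] <- 0  # collinear chains: drop the redundant direction
    pred <- cbind(1, X[val, ch, drop = FALSE]) %*% co
    sqrt(mean((y[val] - pred)^2))
  }, numeric(1))
  best <- which.min(scores)  # which.min takes the first (lowest start) tie
  sel <- sort(chains[[best]])
  list(wavelengths = wavelengths[sel], indices = sel,
       rmse = scores[best], start = best)
}

# Projection chain of length k from start column j0 (columns already
# centred). Gram-Schmidt style: repeatedly deflate the residual matrix by
# the last selected column, then take the max-norm column.
spa_chain <- function(Xc, j0, k) {
  R <- Xc
  sel <- j0
  while (length(sel) < k) {
    v <- R[, sel[length(sel)]]
    vv <- sum(v^2)
    if (vv > 0) {
      R <- R - v %*% crossprod(v, R) / vv
    }
    norms <- colSums(R^2)
    norms[sel] <- -Inf  # zero residual; never selected twice
    sel <- c(sel, which.max(norms))  # which.max: first max = lowest index
  }
  sel
}

#' Wavelet energy and entropy of one band image
#'
#' Two-level Daubechies DWT ([dwt2()]) of a band image; for each detail
#' sub-band `Lambda` in LH, HL, HH at levels 1 and 2:
#' \describe{
#'   \item{WE}{mean squared coefficient,
#'     \eqn{\frac{1}{MN}\sum |I^\Lambda_{mn}|^2}, with M x N the sub-band
#'     size.}
#'   \item{WEN}{normalised-energy Shannon entropy,
#'     \eqn{-\frac{1}{MN}\sum p_{mn} \log_2 p_{mn}} with
#'     \eqn{p_{mn} = (I^\Lambda_{mn})^2 / \sum (I^\Lambda)^2} and
#'     \eqn{0 \log 0 := 0}; an all-zero sub-band has WEN = 0.}
#' }
#'
#' @param img Numeric matrix (band image), at least 4 x 4.
#' @param wavelet Daubechies filter name, default `"db4"`.
#' @param levels Decomposition depth, default 2.
#' @return Named numeric vector of 12 values `"<Lambda><level>_<WE|WEN>"`
#'   (e.g. `HL1_WE`, `LH2_WEN`).
#' @export
wavelet_subband_features <- function(img, wavelet = "db4", levels = 2) {
  dec <- dwt2(img, wavelet = wavelet, levels = levels)
  # sub-bands whose energy is pure floating-point residue (a constant
  # image leaves ~1e-33 in the detail bands) count as zero for the
  # entropy
  floor_energy <- sum(img^2) * 1e-24
  out <- numeric(0)
  for (lev in seq_len(levels)) {
    for (lam in c("LH", "HL", "HH")) {
      coefs <- dec$levels[[lev]][[lam]]
      e <- coefs^2
      tot <- sum(e)
      we <- mean(e)
      if (tot > floor_energy) {
        p <- e / tot
        terms <- ifelse(p > 0, p * log2(p), 0)
        wen <- -sum(terms) / length(p)
      } else {
        wen <- 0
      }
      out[paste0(lam, lev, "_WE")] <- we
      out[paste0(lam, lev, "_WEN")] <- wen
    }
  }
  out
}

#' 24 wavelet features of a cube at two informative wavelengths
#'
#' Snaps each requested wavelength to the nearest band inside the working
#' window, crops the centered ROI of that band image, and computes the 12
#' sub-band energy/entropy values of [wavelet_subband_features()] per
#' band: 2 bands x 3 orientations x 2 levels x 2 measures = 24 features
#' named `B{b}_{Lambda}{level}_{WE|WEN}` (`B1` is the lower wavelength).
#'
#' @param cube A `spectral_cube`.
#' @param feature_wavelengths Two wavelengths in nm (default 1106 and
#'   1375).
#' @param roi_size ROI side length (default 50).
#' @param crop_range Working window in nm; requested wavelengths must lie
#'   inside it.
#' @param wavelet,levels Passed to [wavelet_subband_features()].
#' @return Named numeric vector of 24 features.
#' @export
extract_hsi_features <- function(cube, feature_wavelengths = c(1106, 1375),
                                 roi_size = 50, crop_range = c(944, 1688),
                                 wavelet = "db4", levels = 2) {
  stop_if(length(feature_wavelengths) != 2, "exactly 2 feature wavelengths")
  fw <- sort(feature_wavelengths)
  stop_if(any(fw < crop_range[1] | fw > crop_range[2]),
          "feature wavelength outside the cropped range [",
          crop_range[1], ", ", crop_range[2], "] nm")
  axis_keep <- cube$wavelengths >= crop_range[1] &
    cube$wavelengths <= crop_range[2]
  wl <- cube$wavelengths[axis_keep]
  stop_if(length(wl) == 0, "no bands inside the crop range")
  d <- dim(cube$data)
  ix <- roi_indices(d[1], d[2], roi_size)
  out <- numeric(0)
  for (b in 1:2) {
    band_local <- which.min(abs(wl - fw[b]))
    band <- which(axis_keep)[band_local]
    img <- cube$data[ix$rows, ix$cols, band]
    feats <- wavelet_subband_features(img, wavelet = wavelet, levels = levels)
    names(feats) <- paste0("B", b, "_", names(feats))
    out <- c(out, feats)
  }
  out
}

#' HSI feature table for a dataset
#'
#' Streams over a dataset's cubes (regenerating each from the seed when
#' they are not kept in memory), extracts the 24 wavelet features per
#' sample, and returns a feature table joined with the target.
#'
#' @param ds A `tea_dataset`.
#' @param feature_wavelengths Two wavelengths (nm), or `"auto"` to derive
#'   them with [spa_select()] from the cropped ROI spectra.
#' @param roi_size,crop_range,wavelet Passed through.
#' @return Feature table data.frame with `sample_id`, 24 features,
#'   `TP_percent`; the wavelengths used are attached as attribute
#'   `"feature_wavelengths"`.
#' @export
extract_hsi_features_dataset <- function(ds,
                                         feature_wavelengths = c(1106, 1375),
                                         roi_size = 50,
                                         crop_range = c(944, 1688),
                                         wavelet = "db4") {
  n <- nrow(ds$truth)
  get_cube <- function(i) {
    if (!is.null(ds$cubes)) ds$cubes[[i]] else sample_cube(ds, i)
  }
  auto <- identical(feature_wavelengths, "auto")
  spectra <- NULL
  if (auto) {
    specs <- lapply(seq_len(n), function(i) {
      crop_spectrum(extract_roi_spectrum(get_cube(i), roi_size),
                    crop_range[1], crop_range[2])
    })
    spectra <- do.call(rbind, lapply(specs, `[[`, "reflectance"))
    sel <- spa_select(spectra, ds$truth$TP_percent,
                      specs[[1]]$wavelengths, k = 2)
    feature_wavelengths <- sel$wavelengths
  }
  rows <- lapply(seq_len(n), function(i) {
    feats <- extract_hsi_features(get_cube(i), feature_wavelengths,
                                  roi_size = roi_size,
                                  crop_range = crop_range,
                                  wavelet = wavelet)
    data.frame(sample_id = ds$truth$sample_id[i], as.list(feats),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$TP_percent <- ds$truth$TP_percent
  validate_feature_table(out)
  attr(out, "feature_wavelengths") <- feature_wavelengths
  out
}
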