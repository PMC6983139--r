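# Orthonormal Daubechies DWT with periodized boundaries, in 1-D and 2-D.
# Periodization keeps the transform exactly orthogonal, so sub-band
# energies partition the image energy (Parseval) to machine precision on
# even-length inputs.

# Scaling (low-pass analysis) filters, standard published coefficients.
daubechies_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852,
          0.030841381835560764, -0.18703481171909309,
          -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401)
)

wavelet_filter <- function(wavelet) {
  g <- daubechies_filters[[wavelet]]
  stop_if(is.null(g), "unknown wavelet: ", wavelet,
          " (available: ", paste(names(daubechies_filters), collapse = ", "), ")")
  L <- length(g)
  list(lo = g, hi = rev(g) * (-1)^(seq_len(L) - 1))
}

# One-level periodized analysis of a vector. Odd lengths are first
# extended by one circularly-wrapped sample (documented behaviour; exact
# orthogonality holds for even lengths).
dwt_step_1d <- function(x, filt) {
  n <- length(x)
  if (n %% 2 == 1) {
    x <- c(x, x[1])
    n <- n + 1
  }
  L <- length(filt$lo)
  half <- n / 2
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], half, L)
  list(a = as.vector(xm %*% filt$lo), d = as.vector(xm %*% filt$hi))
}

# One-level 2-D separable step: rows then columns. matrix(..., nrow = )
# keeps sub-band orientation even when a dimension collapses to 1.
dwt_step_2d <- function(img, filt) {
  # transform each row
  row_res <- lapply(seq_len(nrow(img)),
                    function(i) dwt_step_1d(img[i, ], filt))
  hw <- length(row_res[[1]]$a)
  Lr <- t(matrix(vapply(row_res, `[[`, numeric(hw), "a"), nrow = hw))
  Hr <- t(matrix(vapply(row_res, `[[`, numeric(hw), "d"), nrow = hw))
  # then each column
  colpass <- function(m) {
    res <- lapply(seq_len(ncol(m)), function(j) dwt_step_1d(m[, j], filt))
    hh <- length(res[[1]]$a)
    list(lo = matrix(vapply(res, `[[`, numeric(hh), "a"), nrow = hh),
         hi = matrix(vapply(res, `[[`, numeric(hh), "d"), nrow = hh))
  }
  l <- colpass(Lr)
  h <- colpass(Hr)
  # LL: low rows + low cols; HL: high along rows (horizontal detail);
  # LH: high along columns (vertical detail); HH: diagonal detail.
  list(LL = l$lo, HL = h$lo, LH = l$hi, HH = h$hi)
}

#' Multi-level 2-D discrete wavelet decomposition
#'
#' Separable periodized orthonormal DWT of a matrix with a Daubechies
#' filter. At each level the approximation is split into `LL`, and the
#' detail sub-bands `LH` (vertical), `HL` (horizontal) and `HH`
#' (diagonal); the next level recurses on `LL`. Periodized boundaries
#' keep the decomposition orthogonal, so the total energy of all
#' sub-bands equals the image energy (for even side lengths at every
#' level); odd intermediate lengths are circularly extended by one
#' sample.
#'
#' @param img Numeric matrix, at least 4 x 4 for 2 levels.
#' @param wavelet One of `"db1"`, `"db2"`, `"db4"`, `"db8"`.
#' @param levels Number of decomposition levels.
#' @return List with one entry per level (`LH`, `HL`, `HH` matrices) and
#'   the final approximation `LL`.
#' @export
dwt2 <- function(img, wavelet = "db4", levels = 2) {
  stop_if(!is.matrix(img) || !is.numeric(img), "img must be a numeric matrix")
  stop_if(!is_count(levels), "levels must be a positive integer")
  stop_if(min(dim(img)) < 2^levels,
          "image too small for ", levels, " decomposition levels")
  filt <- wavelet_filter(wavelet)
  out <- list(levels = vector("list", levels))
  a <- img
  for (lev in seq_len(levels)) {
    st <- dwt_step_2d(a, filt)
    out$levels[[lev]] <- st[c("LH", "HL", "HH")]
    a <- st$LL
  }
  out$LL <- a
  out$wavelet <- wavelet
  out
}
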