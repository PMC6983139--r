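# Independent literal-loop reference implementations used as oracles.
# These deliberately mirror the defining formulas term by term and share
# no code with the package internals.

oracle_var <- function(c) {
  N <- length(c); cbar <- sum(c) / N
  acc <- 0
  for (i in 1:N) acc <- acc + (c[i] - cbar)^2
  acc / N
}

oracle_inv <- function(c, dt = 1) {
  acc <- 0
  for (i in seq_along(c)) acc <- acc + c[i] * dt
  acc
}

oracle_rsav <- function(c, t0) {
  N <- length(c)
  acc <- 0
  for (i in (t0 + 1):N) acc <- acc + c[i]
  acc / (N - t0)
}

oracle_adv <- function(c, dt = 1) {
  N <- length(c)
  acc <- 0
  for (i in 1:(N - 1)) acc <- acc + (c[i + 1] - c[i]) / dt
  acc / (N - 1)
}

oracle_kurt <- function(c) {
  N <- length(c); cbar <- sum(c) / N
  m2 <- 0; m4 <- 0
  for (i in 1:N) {
    m2 <- m2 + (c[i] - cbar)^2 / N
    m4 <- m4 + (c[i] - cbar)^4 / N
  }
  m4 / m2^2 - 3
}

oracle_skew <- function(c) {
  N <- length(c); cbar <- sum(c) / N
  m2 <- 0; m3 <- 0
  for (i in 1:N) {
    m2 <- m2 + (c[i] - cbar)^2 / N
    m3 <- m3 + (c[i] - cbar)^3 / N
  }
  sqrt(N * (N - 1)) / (N - 2) * m3 / m2^(3 / 2)
}

# Brute-force double-loop ROI average of one band image.
oracle_roi_mean <- function(img) {
  acc <- 0
  for (m in seq_len(nrow(img))) {
    for (n in seq_len(ncol(img))) acc <- acc + img[m, n]
  }
  acc / (nrow(img) * ncol(img))
}

# Exhaustive SPA oracle: literal projection chains from every start
# column plus MLR scoring, written independently of spa_select().
oracle_spa <- function(X, y, k) {
  ord <- order(y)
  val <- ord[seq(2, length(ord), by = 3)]
  cal <- setdiff(seq_along(y), val)
  Xc <- scale(X[cal, , drop = FALSE], center = TRUE, scale = FALSE)
  p <- ncol(X)
  best_rmse <- Inf; best_sel <- NULL
  for (j0 in 1:p) {
    sel <- j0
    R <- Xc
    while (length(sel) < k) {
      v <- R[, sel[length(sel)]]
      if (sum(v^2) > 0) {
        for (j in 1:p) {
          R[, j] <- R[, j] - v * sum(v * R[, j]) / sum(v^2)
        }
      }
      norms <- apply(R, 2, function(z) sum(z^2))
      norms[sel] <- -Inf
      sel <- c(sel, which.max(norms))
    }
    fit <- lm(y[cal] ~ X[cal, sel, drop = FALSE])
    co <- coef(fit); co[is.na(co)] <- 0
    pred <- cbind(1, X[val, sel, drop = FALSE]) %*% co
    rmse <- sqrt(mean((y[val] - pred)^2))
    if (rmse < best_rmse - 1e-12) {
      best_rmse <- rmse
      best_sel <- sort(sel)
    }
  }
  best_sel
}

# Total sub-band energy of a dwt2 decomposition, approximation included.
subband_energy_total <- function(dec) {
  e <- sum(dec$LL^2)
  for (lev in dec$levels) {
    for (lam in c("LH", "HL", "HH")) e <- e + sum(lev[[lam]]^2)
  }
  e
}

# 1e-12 comparison with an absolute floor at unit scale, for the
# dimensionless shape statistics: skewness/kurtosis near zero suffer
# catastrophic cancellation in the third/fourth central moment, so two
# correct summation orders can disagree at ~1e-12 of a ~1e-4 value
# while agreeing to 1e-15 on the statistic's O(1) natural scale.
expect_stat_match <- function(actual, expected, tol = 1e-12) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1), tol)
}

new_cube_for_test <- function(arr, wl) {
  teafuse:::new_spectral_cube(arr, wl)
}

# Small random feature table with a planted linear target.
make_linear_table <- function(n, p = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p)
  colnames(x) <- paste0("x", seq_len(p))
  out <- data.frame(sample_id = sprintf("s%03d", seq_len(n)), x,
                    stringsAsFactors = FALSE)
  out$TP_percent <- 12 + 6 * x[, 1] + rnorm(n, 0, noise_sd)
  out
}
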