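# Time-domain statistics and continuous-wavelet energy summaries of
# gas-sensor response curves.

check_trace <- function(values) {
  stop_if(!is.numeric(values) || length(values) < 2,
          "trace must be a numeric vector of length >= 2")
  stop_if(any(!is.finite(values)), "trace contains non-finite values")
  invisible(values)
}

#' Time-domain statistics of a sensor response curve
#'
#' The six per-sensor statistics summarising one conductance-ratio trace
#' `c_1..c_N` (N = 75 at 1 Hz):
#' \describe{
#'   \item{`trace_variance`}{population variance, divisor N.}
#'   \item{`trace_integral`}{rectangle-rule integral
#'     \eqn{\sum_i c_i \Delta t} (total response).}
#'   \item{`trace_steady_state_average`}{RSAV: mean of the values with
#'     index > `t0`, i.e. divisor `N - t0` — the plateau level after the
#'     sensor stabilises (default onset 55 s).}
#'   \item{`trace_average_differential`}{mean forward difference per
#'     second, which telescopes to
#'     \eqn{(c_N - c_1)/((N-1)\Delta t)}.}
#'   \item{`trace_kurtosis`}{excess kurtosis \eqn{m_4/m_2^2 - 3} with
#'     population moments.}
#'   \item{`trace_skewness`}{adjusted Fisher--Pearson coefficient
#'     \eqn{\sqrt{N(N-1)}/(N-2)\; m_3/m_2^{3/2}}.}
#' }
#' Kurtosis and skewness are undefined on a zero-variance trace; by
#' default this is an error, or a sentinel 0 with a warning when
#' `degenerate = "zero"`.
#'
#' @param values Numeric trace.
#' @param dt Sampling interval in seconds (default 1).
#' @param t0 Steady-state onset index (seconds into the trace; values at
#'   indices `t0+1 .. N` enter the RSAV).
#' @param degenerate For kurtosis/skewness on constant traces: "error"
#'   (default) or "zero".
#' @return A single numeric value.
#' @name trace_statistics
NULL

#' @rdname trace_statistics
#' @export
trace_variance <- function(values) {
  check_trace(values)
  mean((values - mean(values))^2)
}

#' @rdname trace_statistics
#' @export
trace_integral <- function(values, dt = 1) {
  check_trace(values)
  sum(values) * dt
}

#' @rdname trace_statistics
#' @export
trace_steady_state_average <- function(values, t0 = 55) {
  check_trace(values)
  N <- length(values)
  stop_if(t0 < 1 || t0 >= N, "t0 must satisfy 0 < t0 < N")
  mean(values[(t0 + 1):N])
}

#' @rdname trace_statistics
#' @export
trace_average_differential <- function(values, dt = 1) {
  check_trace(values)
  N <- length(values)
  mean(diff(values)) / dt
}

moments_23_4 <- function(values) {
  d <- values - mean(values)
  c(m2 = mean(d^2), m3 = mean(d^3), m4 = mean(d^4))
}

#' @rdname trace_statistics
#' @export
trace_kurtosis <- function(values, degenerate = c("error", "zero")) {
  check_trace(values)
  degenerate <- match.arg(degenerate)
  m <- moments_23_4(values)
  if (m[["m2"]] == 0) {
    if (degenerate == "zero") {
      warning("degenerate trace: zero variance, kurtosis set to 0")
      return(0)
    }
    stop("degenerate trace: zero variance, kurtosis undefined",
         call. = FALSE)
  }
  m[["m4"]] / m[["m2"]]^2 - 3
}

#' @rdname trace_statistics
#' @export
trace_skewness <- function(values, degenerate = c("error", "zero")) {
  check_trace(values)
  degenerate <- match.arg(degenerate)
  N <- length(values)
  stop_if(N < 3, "skewness needs N >= 3")
  m <- moments_23_4(values)
  if (m[["m2"]] == 0) {
    if (degenerate == "zero") {
      warning("degenerate trace: zero variance, skewness set to 0")
      return(0)
    }
    stop("degenerate trace: zero variance, skewness undefined",
         call. = FALSE)
  }
  sqrt(N * (N - 1)) / (N - 2) * m[["m3"]] / m[["m2"]]^1.5
}

td_families <- c("VAR", "INV", "RSAV", "ADV", "KURT", "SKEW")

#' Extract the 60 time-domain features of an e-nose record
#'
#' Applies the six statistics of [trace_statistics] to each of the 10
#' sensor traces, yielding a named vector of exactly 60 features
#' `<FAMILY>_<sensor>` with family-major, sensor-minor order
#' (`VAR_f0 .. VAR_f9, INV_f0, ...`). Output is keyed by name, so the
#' sensor order of the input record is immaterial.
#'
#' @param record An `enose_record`.
#' @param t0 Steady-state onset (s) for the RSAV, default 55.
#' @param degenerate Passed to kurtosis/skewness; errors carry the sensor
#'   name.
#' @return Named numeric vector of length 60.
#' @export
extract_time_domain <- function(record, t0 = 55,
                                degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  tr <- record$traces
  stop_if(ncol(tr) != 10, "record must have 10 sensor traces")
  cols <- colnames(tr)
  out <- numeric(0)
  fns <- list(
    VAR  = function(x) trace_variance(x),
    INV  = function(x) trace_integral(x, dt = record$dt),
    RSAV = function(x) trace_steady_state_average(x, t0 = t0),
    ADV  = function(x) trace_average_differential(x, dt = record$dt),
    KURT = function(x) trace_kurtosis(x, degenerate = degenerate),
    SKEW = function(x) trace_skewness(x, degenerate = degenerate)
  )
  for (fam in td_families) {
    for (s in cols) {
      val <- tryCatch(fns[[fam]](tr[, s]), error = function(e) {
        stop(fam, "_", s, ": ", conditionMessage(e), call. = FALSE)
      })
      out[paste0(fam, "_", s)] <- val
    }
  }
  stopifnot(length(out) == 60)
  out
}

# ---- continuous wavelet transform ----------------------------------------

#' Mexican-hat (Ricker) mother wavelet
#'
#' \eqn{\psi(t) = \frac{2}{\sqrt{3}\,\pi^{1/4}} (1 - t^2) e^{-t^2/2}},
#' the normalised second derivative of a Gaussian.
#' @param t Numeric.
#' @return \eqn{\psi(t)}.
#' @export
mexican_hat <- function(t) {
  2 / (sqrt(3) * pi^0.25) * (1 - t^2) * exp(-t^2 / 2)
}

#' Continuous wavelet transform at given scales
#'
#' Direct-convolution CWT of a finite discrete signal:
#' \deqn{C(a, b) = \frac{1}{\sqrt{a}} \sum_{t=1}^{N} x_t\,
#'   \psi\!\left(\frac{t - b}{a}\right),}
#' for every translation `b = 1..N` and each scale `a`. The signal is
#' implicitly zero-padded outside its support (relevant once `a`
#' approaches or exceeds N).
#'
#' @param x Numeric signal.
#' @param scales Positive scale factors (dyadic `2^(1:10)` in this
#'   pipeline).
#' @param wavelet Mother wavelet name; only `"mexh"` (Mexican hat) is
#'   implemented.
#' @return `length(scales)` x `length(x)` matrix of coefficients, rows in
#'   scale order.
#' @export
cwt_trace <- function(x, scales = 2^(1:10), wavelet = "mexh") {
  check_trace(x)
  psi <- switch(wavelet,
                mexh = mexican_hat,
                stop("unknown wavelet: ", wavelet, call. = FALSE))
  stop_if(any(scales <= 0), "scales must be positive")
  N <- length(x)
  out <- matrix(0, length(scales), N)
  idx <- seq_len(N)
  for (si in seq_along(scales)) {
    a <- scales[si]
    # kernel values psi((t - b)/a) for lag t - b in -(N-1)..(N-1)
    lags <- -(N - 1):(N - 1)
    ker <- psi(lags / a) / sqrt(a)
    for (b in idx) {
      out[si, b] <- sum(x * ker[idx - b + N])
    }
  }
  out
}

#' Per-sensor CWT energies and their array-level summaries
#'
#' For each sensor trace the CWT is evaluated at the dyadic scales
#' `2^1 .. 2^10`; each coefficient's energy is its square, and the sensor
#' energy `S_j` is the sum over the full scale x time plane. The two
#' array-level summaries appended to the feature set are `WM = max_j S_j`
#' and `WA = mean_j S_j`.
#'
#' @param record An `enose_record`.
#' @param wavelet Mother-wavelet name (see [cwt_trace()]).
#' @param scales Scale factors, default `2^(1:10)`.
#' @return A `cwt_summary`: list with `S` (named per-sensor energies),
#'   `WM`, `WA`, `wavelet`, `scales`.
#' @export
extract_cwt_summary <- function(record, wavelet = "mexh",
                                scales = 2^(1:10)) {
  tr <- record$traces
  S <- vapply(colnames(tr), function(s) {
    sum(cwt_trace(tr[, s], scales = scales, wavelet = wavelet)^2)
  }, numeric(1))
  structure(list(S = S, WM = max(S), WA = mean(S),
                 wavelet = wavelet, scales = scales),
            class = "cwt_summary")
}

#' @export
print.cwt_summary <- function(x, ...) {
  cat("<cwt_summary>", x$wavelet, "wavelet,", length(x$scales),
      "scales\n  WM =", format(x$WM), " WA =", format(x$WA), "\n")
  invisible(x)
}

#' Full e-nose feature table for a set of records
#'
#' Binds the 60 time-domain features and the two CWT summaries (WM, WA)
#' of each record into a feature table (62 feature columns), optionally
#' joined with the ground-truth target.
#'
#' @param records List of `enose_record`.
#' @param truth Optional data.frame with `sample_id` and `TP_percent`.
#' @param t0 RSAV onset (s).
#' @param wavelet CWT mother wavelet.
#' @return Feature table data.frame (`sample_id`, 62 features, and
#'   `TP_percent` when `truth` is given).
#' @export
extract_enose_features <- function(records, truth = NULL, t0 = 55,
                                   wavelet = "mexh") {
  rows <- lapply(records, function(r) {
    td <- extract_time_domain(r, t0 = t0)
    cw <- extract_cwt_summary(r, wavelet = wavelet)
    data.frame(sample_id = r$sample_id, as.list(td),
               WM = cw$WM, WA = cw$WA,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(truth)) {
    out$TP_percent <- truth$TP_percent[match(out$sample_id, truth$sample_id)]
  }
  validate_feature_table(out)
  out
}
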