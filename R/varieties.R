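#' Sensor names of the 10-element metal-oxide array
#'
#' The PEN3-style gas-sensor array columns `f0`..`f9` correspond, in order,
#' to the sensors W1C, W5S, W3C, W6S, W5C, W1S, W1W, W2S, W2W, W3S. Each
#' sensor is selective for a volatile class (aromatics, nitrogen oxides,
#' sulfur organics, ...); the response recorded per sensor is the
#' dimensionless conductance ratio G/G0.
#'
#' @return Named character vector of length 10: names `f0`..`f9`, values the
#'   sensor names.
#' @export
#' @examples
#' enose_sensor_names()[["f6"]]  # "W1W"
enose_sensor_names <- function() {
  c(f0 = "W1C", f1 = "W5S", f2 = "W3C", f3 = "W6S", f4 = "W5C",
    f5 = "W1S", f6 = "W1W", f7 = "W2S", f8 = "W2W", f9 = "W3S")
}

#' Reference sampling design: 10 tea varieties across 3 categories
#'
#' Returns the per-variety polyphenol statistics of the cross-category
#' sampling design the generator emulates: 10 varieties (4 black, 2 green,
#' 4 yellow teas), 10 or 15 samples each, 110 samples in total, with
#' per-variety mean, SD and observed range of tea polyphenol content in
#' mass percent.
#'
#' @return A data.frame with columns `variety`, `category`, `n`, `tp_min`,
#'   `tp_max`, `tp_mean`, `tp_sd`. Row order is fixed and used as the
#'   variety index elsewhere.
#' @seealso [draw_tp()], [simulate_tea_dataset()]
#' @export
#' @examples
#' v <- default_variety_table()
#' sum(v$n)  # 110
default_variety_table <- function() {
  v <- data.frame(
    variety = c("Zhengshan Xiaozhong (Fujian)",
                "Qimen Black Tea (Anhui Huangshan)",
                "Qimen Black Tea (Anhui Qimen)",
                "JinJunMei (Fujian)",
                "Huangshan Maofeng (Anhui)",
                "Liuan Guapian (Anhui)",
                "Junshan Yinzhen (Hunan)",
                "Huoshan Huangya Tea (Anhui)",
                "Mengding Huangya Tea (Sichuan)",
                "Pingyang Huangtang Tea (Zhejiang)"),
    category = c(rep("black", 4), rep("green", 2), rep("yellow", 4)),
    n        = c(10, 10, 10, 10, 15, 15, 10, 10, 10, 10),
    tp_min   = c(10.65, 13.66, 16.51, 12.62, 25.32, 27.42,
                 14.55, 11.88, 11.36, 13.34),
    tp_max   = c(13.21, 16.54, 22.85, 19.16, 29.41, 29.65,
                 19.60, 16.65, 16.35, 19.36),
    tp_mean  = c(11.832, 15.196, 18.789, 16.990, 26.485, 28.535,
                 16.340, 13.862, 14.334, 16.735),
    tp_sd    = c(0.850, 0.810, 1.567, 1.788, 1.195, 0.632,
                 1.863, 1.367, 1.738, 2.231),
    stringsAsFactors = FALSE
  )
  validate_variety_table(v)
  v
}

validate_variety_table <- function(v) {
  stop_if(!is.data.frame(v), "variety table must be a data.frame")
  needed <- c("variety", "category", "n", "tp_min", "tp_max", "tp_mean", "tp_sd")
  missing <- setdiff(needed, names(v))
  stop_if(length(missing) > 0,
          "variety table lacks columns: ", paste(missing, collapse = ", "))
  stop_if(any(v$n <= 0), "variety sample counts must be positive")
  stop_if(any(v$tp_sd <= 0), "variety SDs must be positive")
  stop_if(any(v$tp_mean < v$tp_min | v$tp_mean > v$tp_max),
          "variety mean must lie inside its range")
  stop_if(anyDuplicated(v$variety) > 0, "duplicate variety names")
  invisible(v)
}

#' Draw polyphenol contents for one variety
#'
#' Samples tea polyphenol content (%) from a normal distribution with the
#' variety's SD, truncated to the variety's observed range. The truncated
#' normal reconciles the three published summaries (mean, SD, hard range)
#' in one distribution; because several ranges are asymmetric about the
#' mean, the location parameter is re-centred (numerically) so that the
#' mean of the *truncated* distribution equals the published variety
#' mean — published means are means of observed, range-limited values.
#'
#' @param spec One row of [default_variety_table()] (or a list with fields
#'   `tp_mean`, `tp_sd`, `tp_min`, `tp_max`).
#' @param n Number of draws.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length `n`, all values in `[tp_min, tp_max]`.
#' @export
#' @examples
#' v <- default_variety_table()
#' draw_tp(v[5, ], n = 3, seed = 1)
draw_tp <- function(spec, n = 1, seed = NULL) {
  stop_if(!is_count(n), "n must be a positive integer")
  mu <- spec$tp_mean; s <- spec$tp_sd
  lo <- spec$tp_min;  hi <- spec$tp_max
  stop_if(!is.finite(mu) || !is.finite(s) || s < 0, "invalid variety spec")
  if (s == 0) return(rep(mu, n))
  mu_adj <- truncnorm_location(mu, s, lo, hi)
  with_seed(seed, {
    # inverse-CDF truncated normal
    plo <- pnorm((lo - mu_adj) / s)
    phi <- pnorm((hi - mu_adj) / s)
    u <- runif(n, plo, phi)
    pmin(pmax(mu_adj + s * qnorm(u), lo), hi)
  })
}

# Mean of a Normal(mu, s) truncated to [lo, hi].
truncnorm_mean <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  mu + s * (stats::dnorm(a) - stats::dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Location parameter whose [lo, hi]-truncated mean equals target_mean.
truncnorm_location <- function(target_mean, s, lo, hi) {
  stats::uniroot(function(m) truncnorm_mean(m, s, lo, hi) - target_mean,
                 lower = lo - 6 * s, upper = hi + 6 * s,
                 tol = 1e-10)$root
}

#' Convert a permanganate titration measurement to polyphenol content
#'
#' Polyphenol content (mass %) from direct potassium-permanganate
#' titration:
#' \deqn{X = \frac{(A - B)\,\omega\, k}{m} \cdot \frac{V_1}{V_2}}
#' where `A` and `B` are the permanganate volumes (mL) consumed by the
#' sample and by the blank, `omega` the permanganate concentration (%),
#' `m` the sample mass (g), `V1` the total test-solution volume (mL), `V2`
#' the aliquot volume (mL) actually titrated, and `k = 0.00582/0.318` the
#' conventional permanganate-to-polyphenol conversion factor
#' ([tp_titration_factor]).
#'
#' @param A,B Permanganate volumes (mL), sample and blank; `A >= B` for a
#'   nonnegative content.
#' @param omega Permanganate concentration (%).
#' @param m Sample mass (g), > 0.
#' @param V1,V2 Test-solution and aliquot volumes (mL), > 0.
#' @return Polyphenol content X in %.
#' @export
#' @examples
#' titration_to_tp(A = 11, B = 1, omega = 2, m = 1, V1 = 100, V2 = 100)
titration_to_tp <- function(A, B, omega, m, V1, V2) {
  stop_if(any(m <= 0), "sample mass m must be > 0")
  stop_if(any(V2 <= 0) || any(V1 <= 0), "volumes V1, V2 must be > 0")
  stop_if(any(omega < 0), "permanganate concentration must be >= 0")
  ((A - B) * omega * tp_titration_factor) / m * (V1 / V2)
}

#' Permanganate-to-polyphenol conversion factor
#'
#' The conventional constant 0.00582/0.318 used in direct-titration
#' polyphenol determination; kept symbolic rather than pre-multiplied.
#' @export
tp_titration_factor <- 0.00582 / 0.318
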