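# Synthetic paired e-nose / hyperspectral data with the statistical
# structure of the 110-sample cross-category study design.

#' Kinetic and sensitivity parameters of the simulated sensor array
#'
#' Per-sensor parameters of the saturating-exponential response model used
#' by [simulate_enose()]: response sign (positive deviation from the
#' baseline ratio 1 for W5S, W1S, W1W, W2S, W2W; negative for W1C, W3C,
#' W5C; near zero for W6S, W3S), baseline amplitude, amplitude slope per
#' unit polyphenol %, and rise time constant `tau` (s). All `tau` satisfy
#' `1 - exp(-55/tau) >= 0.98`, so every trace is within 2% of its plateau
#' by 55 s.
#'
#' @return data.frame with one row per sensor `f0`..`f9`.
#' @export
enose_response_params <- function() {
  data.frame(
    column = paste0("f", 0:9),
    sensor = unname(enose_sensor_names()),
    sign   = c(-1,  1, -1,  1, -1,  1,  1,  1,  1,  1),
    base   = c(0.050, 0.400, 0.040, 0.015, 0.060,
               0.300, 0.800, 0.250, 0.350, 0.012),
    slope  = c(0.0040, 0.0400, 0.0030, 0.0012, 0.0050,
               0.0300, 0.0600, 0.0250, 0.0300, 0.0010),
    tau    = c(12, 10, 11, 9, 12, 10, 13, 11, 10, 9),
    stringsAsFactors = FALSE
  )
}

# Deterministic variety-level relative offset on sensor amplitudes:
# different varieties of equal polyphenol content still smell different.
variety_amp_offset <- function(variety_index, n_sensors = 10L) {
  0.08 * sin(0.7 * variety_index * (seq_len(n_sensors) + 1))
}

#' Default noise model of the generator
#'
#' Noise components applied by [simulate_enose()] and [simulate_cube()]:
#' \describe{
#'   \item{trace_sd}{i.i.d. relative Gaussian noise on each trace point.}
#'   \item{drift_sd}{per-sample multiplicative drift common to all 10
#'     sensors (headspace concentration / instrument sensitivity drift).}
#'   \item{amp_jitter_sd}{independent per-sensor relative amplitude
#'     jitter.}
#'   \item{cube_sd}{pixelwise reflectance noise SD inside the clean
#'     spectral window; inflated 4x outside 944--1688 nm.}
#'   \item{depth_jitter_sd}{per-sample relative jitter on absorption
#'     depths.}
#'   \item{texture_jitter_sd}{per-sample relative jitter on the texture
#'     amplitude.}
#' }
#' `tea_noise(off = TRUE)` zeroes every component (the deterministic
#' limit used by construction-based tests).
#'
#' @param off Logical; if TRUE return an all-zero noise model.
#' @return Named list of noise SDs.
#' @export
tea_noise <- function(off = FALSE) {
  if (off) {
    list(trace_sd = 0, drift_sd = 0, amp_jitter_sd = 0,
         cube_sd = 0, depth_jitter_sd = 0, texture_jitter_sd = 0)
  } else {
    list(trace_sd = 0.01, drift_sd = 0.06, amp_jitter_sd = 0.05,
         cube_sd = 0.01, depth_jitter_sd = 0.10, texture_jitter_sd = 0.15)
  }
}

#' Simulate one electronic-nose record
#'
#' Generates the 10 conductance-ratio traces of one sample under a
#' single-time-constant saturating rise,
#' \deqn{c_j(t) = 1 + a_j \{1 - e^{-t/\tau_j}\}\,(1 + \epsilon_t),}
#' sampled at 1 Hz for 75 s. The plateau amplitude is affine in
#' polyphenol content with a deterministic variety-level offset and
#' multiplicative sample-level noise:
#' `a_j = sign_j (base_j + slope_j tp) (1 + off_vj) (1 + drift) (1 + jitter_j)`.
#' With all noise components zero the steady-state average of each trace
#' is an exact affine, strictly monotone function of `tp` within a
#' variety — the hook that makes parameter-recovery tests meaningful.
#'
#' @param tp Polyphenol content (%), > 0.
#' @param variety_index Integer 1..10, row of [default_variety_table()]
#'   (drives the deterministic variety offset).
#' @param noise Noise model from [tea_noise()].
#' @param sample_id Sample identifier stored in the record.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return An `enose_record`: list with `sample_id`, `traces` (75 x 10
#'   matrix, columns `f0`..`f9`), `time` (1..75 s), `dt` (1 s).
#' @export
simulate_enose <- function(tp, variety_index = 1L, noise = tea_noise(),
                           sample_id = "s1", seed = NULL) {
  stop_if(!is.numeric(tp) || length(tp) != 1L || tp <= 0, "tp must be > 0")
  p <- enose_response_params()
  tt <- seq_len(75)
  off <- variety_amp_offset(variety_index)
  with_seed(seed, {
    drift <- rnorm(1, 0, noise$drift_sd)
    jit <- rnorm(10, 0, noise$amp_jitter_sd)
    traces <- matrix(NA_real_, 75, 10, dimnames = list(NULL, p$column))
    for (j in seq_len(10)) {
      a <- p$sign[j] * (p$base[j] + p$slope[j] * tp) *
        (1 + off[j]) * (1 + drift) * (1 + jit[j])
      rise <- 1 - exp(-tt / p$tau[j])
      eps <- rnorm(75, 0, noise$trace_sd)
      traces[, j] <- 1 + a * rise * (1 + eps)
    }
    new_enose_record(sample_id, traces)
  })
}

new_enose_record <- function(sample_id, traces) {
  stopifnot(is.matrix(traces), nrow(traces) == 75, ncol(traces) == 10)
  structure(list(sample_id = as.character(sample_id), traces = traces,
                 time = seq_len(nrow(traces)), dt = 1),
            class = "enose_record")
}

#' @export
print.enose_record <- function(x, ...) {
  cat("<enose_record> sample", x$sample_id, "-", ncol(x$traces),
      "sensors x", nrow(x$traces), "s at", x$dt, "Hz\n")
  invisible(x)
}

# Smooth NIR baseline reflectance, dimensionless in ~[0.6, 0.85].
cube_baseline <- function(wl) {
  0.72 + 0.06 * cos(2 * pi * (wl - 908) / 800) - 0.04 * ((wl - 1300) / 400)^2
}

#' Simulate one hyperspectral reflectance cube
#'
#' Builds an H x W x B reflectance cube over 908--1700 nm (2 nm grid by
#' default) as a smooth baseline minus two Gaussian absorption features
#' centred at 1106 nm and 1375 nm whose depths increase affinely with
#' polyphenol content, multiplied by a zero-mean high-frequency spatial
#' texture field whose amplitude also increases with `tp` (so detail
#' sub-band energies carry compositional signal), plus heteroscedastic
#' pixel noise inflated 4x outside the 944--1688 nm window (motivating the
#' spectral crop). Values are clipped to [0, 1].
#'
#' @param tp Polyphenol content (%), > 0.
#' @param variety_index Integer 1..10 (reserved for variety-level texture
#'   phases).
#' @param dim Spatial size `c(H, W)`; default 64 x 64.
#' @param wavelengths Wavelength axis in nm, strictly increasing.
#' @param noise Noise model from [tea_noise()].
#' @param texture Logical; FALSE gives a spatially flat cube.
#' @param seed Optional seed.
#' @return A `spectral_cube`: list with `data` (H x W x B array) and
#'   `wavelengths` (nm).
#' @export
simulate_cube <- function(tp, variety_index = 1L, dim = c(64, 64),
                          wavelengths = seq(908, 1700, by = 2),
                          noise = tea_noise(), texture = TRUE,
                          seed = NULL) {
  stop_if(!is.numeric(tp) || length(tp) != 1L || tp <= 0, "tp must be > 0")
  H <- dim[1]; W <- dim[2]; B <- length(wavelengths)
  with_seed(seed, {
    depth_jit <- rnorm(1, 0, noise$depth_jitter_sd)
    tex_jit <- rnorm(1, 0, noise$texture_jitter_sd)
    d1 <- (0.010 + 0.0035 * tp) * (1 + depth_jit)
    d2 <- (0.008 + 0.0030 * tp) * (1 + depth_jit)
    spec <- cube_baseline(wavelengths) -
      d1 * exp(-(wavelengths - 1106)^2 / (2 * 30^2)) -
      d2 * exp(-(wavelengths - 1375)^2 / (2 * 40^2))
    if (texture) {
      ph <- runif(3, 0, 2 * pi)
      xs <- matrix(seq_len(W), H, W, byrow = TRUE)
      ys <- matrix(seq_len(H), H, W)
      P <- sin(2 * pi * xs / 5 + ph[1]) * cos(2 * pi * ys / 7 + ph[2]) +
        0.8 * sin(2 * pi * (xs + ys) / 4 + ph[3])
      P <- P - mean(P)
      P <- P / sqrt(mean(P^2))
      amp <- (0.02 + 0.004 * tp) * (1 + tex_jit)
      field <- 1 + amp * P
    } else {
      field <- matrix(1, H, W)
    }
    cube <- outer(field, spec)  # H x W x B
    if (noise$cube_sd > 0) {
      sds <- noise$cube_sd * (1 + 3 * (wavelengths < 944 | wavelengths > 1688))
      eps <- array(rnorm(H * W * B), c(H, W, B))
      eps <- sweep(eps, 3, sds, `*`)
      cube <- cube + eps
    }
    cube[cube < 0] <- 0
    cube[cube > 1] <- 1
    new_spectral_cube(cube, wavelengths)
  })
}

new_spectral_cube <- function(data, wavelengths) {
  stop_if(length(dim(data)) != 3, "cube data must be a 3-d array")
  stop_if(length(wavelengths) != dim(data)[3],
          "wavelength axis length must equal band count")
  stop_if(is.unsorted(wavelengths, strictly = TRUE),
          "wavelength axis must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# Allocate n samples across varieties proportionally to the design counts
# (largest-remainder rounding, at least 1 per variety).
allocate_samples <- function(varieties, n_samples) {
  if (is.null(n_samples)) return(varieties$n)
  stop_if(!is_count(n_samples) || n_samples < nrow(varieties),
          "n_samples must be an integer >= number of varieties")
  w <- varieties$n / sum(varieties$n)
  alloc <- pmax(1L, floor(w * n_samples))
  while (sum(alloc) < n_samples) {
    frac <- w * n_samples - alloc
    i <- which.max(frac)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n_samples) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] - 1L
  }
  alloc
}

#' Simulate a full paired tea dataset
#'
#' Draws per-sample polyphenol contents from each variety's truncated
#' normal, then generates a paired e-nose record and (optionally) a
#' hyperspectral cube per sample. Per-sample child seeds are derived from
#' `seed`, so the dataset is bit-reproducible.
#'
#' For large runs keep `cubes = FALSE` and stream cubes one at a time via
#' [sample_cube()] (a 110-cube dataset holds ~1.4 GB of reflectance), or
#' pass `out_dir` to write everything to disk in the on-disk formats
#' (`enose.csv`, `truth.csv`, `cubes/<id>.hdr/.img`).
#'
#' @param varieties Variety design table; see [default_variety_table()].
#' @param seed Integer seed for the whole dataset.
#' @param n_samples Total samples; `NULL` (default) uses the design counts
#'   (110 for the default table).
#' @param noise Noise model from [tea_noise()].
#' @param cubes Logical; generate and keep cubes in memory.
#' @param cube_dim,cube_wavelengths Cube geometry passed to
#'   [simulate_cube()].
#' @param out_dir Optional directory to write `enose.csv`, `truth.csv`
#'   and ENVI cubes to.
#' @return A `tea_dataset`: list with `truth` (data.frame: sample_id,
#'   variety, category, variety_index, TP_percent), `enose` (list of
#'   `enose_record`), `cubes` (list of `spectral_cube` or NULL), `seed`,
#'   `noise`, `cube_dim`, `cube_wavelengths`.
#' @export
#' @examples
#' d <- simulate_tea_dataset(seed = 1, cubes = FALSE)
#' nrow(d$truth)  # 110
simulate_tea_dataset <- function(varieties = default_variety_table(),
                                 seed = 1L, n_samples = NULL,
                                 noise = tea_noise(), cubes = FALSE,
                                 cube_dim = c(64, 64),
                                 cube_wavelengths = seq(908, 1700, by = 2),
                                 out_dir = NULL) {
  validate_variety_table(varieties)
  counts <- allocate_samples(varieties, n_samples)
  rows <- list(); k <- 0L
  for (vi in seq_len(nrow(varieties))) {
    tps <- draw_tp(varieties[vi, ], n = counts[vi],
                   seed = child_seed(seed, vi))
    for (s in seq_len(counts[vi])) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = sprintf("S%03d", k),
        variety = varieties$variety[vi],
        category = varieties$category[vi],
        variety_index = vi,
        TP_percent = tps[s],
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)
  enose <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    enose[[i]] <- simulate_enose(truth$TP_percent[i], truth$variety_index[i],
                                 noise = noise,
                                 sample_id = truth$sample_id[i],
                                 seed = child_seed(seed, 10000 + i))
  }
  names(enose) <- truth$sample_id
  ds <- structure(list(truth = truth, enose = enose, cubes = NULL,
                       seed = seed, noise = noise, cube_dim = cube_dim,
                       cube_wavelengths = cube_wavelengths),
                  class = "tea_dataset")
  if (cubes) {
    ds$cubes <- lapply(seq_len(nrow(truth)), function(i) sample_cube(ds, i))
    names(ds$cubes) <- truth$sample_id
  }
  if (!is.null(out_dir)) write_tea_dataset(ds, out_dir)
  ds
}

#' Regenerate the hyperspectral cube of one dataset sample
#'
#' Cubes are a deterministic function of the dataset seed and sample
#' index, so they can be produced on demand (streaming) instead of being
#' held in memory.
#'
#' @param ds A `tea_dataset`.
#' @param i Sample index (row of `ds$truth`).
#' @return A `spectral_cube`.
#' @export
sample_cube <- function(ds, i) {
  simulate_cube(ds$truth$TP_percent[i], ds$truth$variety_index[i],
                dim = ds$cube_dim, wavelengths = ds$cube_wavelengths,
                noise = ds$noise,
                seed = child_seed(ds$seed, 20000 + i))
}

#' @export
print.tea_dataset <- function(x, ...) {
  cat("<tea_dataset>", nrow(x$truth), "samples,",
      length(unique(x$truth$variety)), "varieties; seed", x$seed, "\n")
  cat("  TP range:", sprintf("%.2f-%.2f %%", min(x$truth$TP_percent),
                             max(x$truth$TP_percent)), "\n")
  invisible(x)
}

#' Write a simulated dataset in the on-disk formats
#'
#' Writes `enose.csv` (long-form traces), `truth.csv` (sample_id, variety,
#' TP_percent) and one ENVI cube per sample under `cubes/`.
#'
#' @param ds A `tea_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_tea_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_enose_csv(ds$enose, file.path(out_dir, "enose.csv"))
  write.csv(ds$truth[, c("sample_id", "variety", "TP_percent")],
            file.path(out_dir, "truth.csv"), row.names = FALSE)
  cube_dir <- file.path(out_dir, "cubes")
  dir.create(cube_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(ds$truth))) {
    cube <- if (!is.null(ds$cubes)) ds$cubes[[i]] else sample_cube(ds, i)
    write_envi_cube(cube, file.path(cube_dir, ds$truth$sample_id[i]))
  }
  invisible(out_dir)
}
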