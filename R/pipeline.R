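# End-to-end study: simulate -> extract -> select -> fuse -> fit -> score.

#' Run the full fusion study on one synthetic dataset
#'
#' Simulates a paired dataset under the reference design, extracts the 62
#' e-nose features (60 time-domain + WM/WA) and 24 HSI wavelet features,
#' splits stratified by variety, runs both selection rules on the
#' calibration set only (no leakage), fuses the retained sets, and fits
#' grid-searched regressors on each requested feature set, reporting
#' calibration and validation R2, adjusted R2 and RMSE.
#'
#' Cubes are streamed one at a time, so memory stays flat. The three
#' feature sets mirror the comparison design: `"enose"` (20 variables:
#' 18 selected time-domain + WM + WA), `"hsi"` (6 correlation-selected
#' wavelet features), `"fusion"` (all 26).
#'
#' @param seed Integer seed controlling the dataset and every downstream
#'   stochastic step.
#' @param algorithms Subset of `c("gridsvr", "rf", "xgboost")`.
#' @param feature_sets Subset of `c("enose", "hsi", "fusion")`.
#' @param granularity Grid granularity, `"default"` or `"coarse"` (see
#'   [model_grid()]).
#' @param noise Generator noise model ([tea_noise()]).
#' @param feature_wavelengths Two wavelengths (nm) for the HSI features,
#'   or `"auto"` to re-derive them by SPA on the dataset.
#' @param varieties Variety design table.
#' @param n_samples Total samples (`NULL` = design counts, 110).
#' @return A `tp_fusion_study`: list with `results` (one row per
#'   algorithm x feature set: variables, R2/adjusted R2/RMSE for both
#'   sets), `selection` (the two `selection_result`s and the
#'   `fused_feature_set`), `split`, `tables` (feature tables), `truth`,
#'   `models`, `seed`.
#' @export
#' @examples
#' \donttest{
#' st <- tp_fusion_study(seed = 7, algorithms = "xgboost",
#'                       feature_sets = c("hsi", "fusion"),
#'                       granularity = "coarse")
#' st$results
#' }
tp_fusion_study <- function(seed = 1L,
                            algorithms = c("gridsvr", "rf", "xgboost"),
                            feature_sets = c("enose", "hsi", "fusion"),
                            granularity = c("default", "coarse"),
                            noise = tea_noise(),
                            feature_wavelengths = c(1106, 1375),
                            varieties = default_variety_table(),
                            n_samples = NULL) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  granularity <- match.arg(granularity)

  ds <- simulate_tea_dataset(varieties = varieties, seed = seed,
                             n_samples = n_samples, noise = noise,
                             cubes = FALSE)
  enose_tab <- extract_enose_features(ds$enose, ds$truth)
  hsi_tab <- extract_hsi_features_dataset(ds, feature_wavelengths)
  split <- stratified_split(ds$truth, seed = child_seed(seed, 31))

  cal_ids <- split$calibration_ids
  enose_cal <- enose_tab[enose_tab$sample_id %in% cal_ids, ]
  hsi_cal <- hsi_tab[hsi_tab$sample_id %in% cal_ids, ]
  enose_sel <- importance_select_enose(enose_cal, seed = child_seed(seed, 32))
  hsi_sel <- correlation_select_hsi(hsi_cal)
  fused <- fuse_features(enose_sel, hsi_sel)

  full <- merge(enose_tab[, setdiff(names(enose_tab), "TP_percent")],
                hsi_tab, by = "sample_id", sort = FALSE)
  set_features <- list(enose = fused$enose_names, hsi = fused$hsi_names,
                       fusion = fused$fused)

  results <- list(); models <- list()
  for (fs in feature_sets) {
    feats <- set_features[[fs]]
    tab <- full[, c("sample_id", feats, "TP_percent")]
    cal <- tab[tab$sample_id %in% cal_ids, ]
    val <- tab[tab$sample_id %in% split$validation_ids, ]
    for (alg in algorithms) {
      m <- tp_train(cal, alg, grid = model_grid(alg, granularity),
                    seed = child_seed(seed, 33))
      ev <- evaluate_model(m, cal, val)
      models[[paste(alg, fs, sep = ".")]] <- m
      results[[paste(alg, fs, sep = ".")]] <- data.frame(
        algorithm = alg, features = fs, variables = length(feats),
        cal_R2 = ev$R2[1], cal_adjusted_R2 = ev$adjusted_R2[1],
        cal_RMSE = ev$RMSE[1],
        val_R2 = ev$R2[2], val_adjusted_R2 = ev$adjusted_R2[2],
        val_RMSE = ev$RMSE[2],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  structure(list(results = res,
                 selection = list(enose = enose_sel, hsi = hsi_sel,
                                  fused = fused),
                 split = split,
                 tables = list(enose = enose_tab, hsi = hsi_tab,
                               full = full),
                 truth = ds$truth, models = models, seed = seed),
            class = "tp_fusion_study")
}

#' @export
print.tp_fusion_study <- function(x, ...) {
  cat("<tp_fusion_study> seed", x$seed, "-", nrow(x$truth), "samples\n")
  print.data.frame(x$results, row.names = FALSE, digits = 3)
  invisible(x)
}
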