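# Feature selection: boosted-tree split-count importance for e-nose
# time-domain features, Pearson correlation for HSI features, and fusion.

#' Split-count importance selection of e-nose sensors, per family
#'
#' For each of the six time-domain families (VAR, INV, RSAV, ADV, KURT,
#' SKEW) a gradient-boosted-tree regressor is fitted on that family's 10
#' sensor features against the polyphenol target, and each feature is
#' scored by its F-score: the number of times it is used to split a tree
#' node across the ensemble. The top `ceil(fraction * 10)` sensors per
#' family are retained (3 per family at the default 30%, 18 names in
#' all), ties broken by sensor order. One model per family (rather than
#' one 60-feature model) makes the per-family retention rule exact.
#'
#' @param table Feature table holding the 60 time-domain features and
#'   `TP_percent`.
#' @param fraction Retained share of the 10 sensors per family, in (0, 1].
#' @param seed Seed for the boosted-tree fits.
#' @param nrounds,params Boosting configuration of the scorer (defaults:
#'   100 rounds, eta 0.1, depth 3).
#' @return A `selection_result`: list with `method = "importance"`,
#'   `scores` (named split counts, all 60 features), `retained` (ordered
#'   names), `fraction`.
#' @export
importance_select_enose <- function(table, fraction = 0.30, seed = 1L,
                                    nrounds = 100,
                                    params = list(eta = 0.1, max_depth = 3)) {
  validate_feature_table(table)
  stop_if(!("TP_percent" %in% names(table)), "table lacks TP_percent target")
  stop_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  sensors <- paste0("f", 0:9)
  scores <- numeric(0)
  retained <- character(0)
  for (fam in td_families) {
    cols <- paste0(fam, "_", sensors)
    missing <- setdiff(cols, names(table))
    stop_if(length(missing) > 0,
            "missing family columns: ", paste(missing, collapse = ", "))
    x <- as.matrix(table[, cols])
    counts <- xgb_split_counts(x, table$TP_percent,
                               seed = child_seed(seed, match(fam, td_families)),
                               nrounds = nrounds, params = params)
    scores[cols] <- counts[cols]
    keep_n <- ceiling(fraction * length(cols))
    ord <- order(-counts[cols])  # stable: ties keep sensor order
    retained <- c(retained, cols[ord[seq_len(keep_n)]])
  }
  new_selection_result("importance", scores, retained, fraction)
}

# Fit a small boosted-tree regressor and count per-feature node splits.
xgb_split_counts <- function(x, y, seed, nrounds, params) {
  counts <- setNames(numeric(ncol(x)), colnames(x))
  with_seed(seed, {
    dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    bst <- xgboost::xgb.train(
      params = c(params, list(nthread = 1)),
      data = dm, nrounds = nrounds, verbose = 0
    )
    tr <- xgboost::xgb.model.dt.tree(model = bst)
    used <- tr$Feature[tr$Feature != "Leaf"]
    tab <- table(used)
    counts[names(tab)] <- as.numeric(tab)
  })
  counts
}

#' Pearson-correlation selection of HSI features
#'
#' Scores each of the 24 wavelet features by its Pearson correlation with
#' the polyphenol target and retains the top `round(fraction * 24)` by
#' absolute value (6 at the default 25%), ties broken by name order.
#' Signed correlations are kept in the scores. A zero-variance feature
#' has no defined correlation; it is scored 0 with a warning.
#'
#' @param table Feature table with the HSI features and `TP_percent`.
#' @param fraction Retained share, in (0, 1].
#' @return A `selection_result` with `method = "correlation"`.
#' @export
correlation_select_hsi <- function(table, fraction = 0.25) {
  validate_feature_table(table)
  stop_if(!("TP_percent" %in% names(table)), "table lacks TP_percent target")
  stop_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  feats <- feature_names(table)
  y <- table$TP_percent
  scores <- vapply(feats, function(f) {
    x <- table[[f]]
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero-variance feature ", f, ": correlation undefined, scored 0")
      return(0)
    }
    cor(x, y)
  }, numeric(1))
  keep_n <- round(fraction * length(feats))
  ord <- order(-abs(scores))  # order() is stable: ties keep name order
  retained <- feats[ord[seq_len(keep_n)]]
  new_selection_result("correlation", scores, retained, fraction)
}

new_selection_result <- function(method, scores, retained, fraction) {
  stopifnot(all(retained %in% names(scores)), all(is.finite(scores)))
  structure(list(method = method, scores = scores, retained = retained,
                 fraction = fraction),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$method, "-", length(x$retained), "of",
      length(x$scores), "features retained (fraction",
      format(x$fraction), ")\n")
  cat("  ", paste(head(x$retained, 8), collapse = ", "),
      if (length(x$retained) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Fuse the retained e-nose and HSI feature sets
#'
#' Concatenates, in order: the selected time-domain names, the two CWT
#' array summaries WM and WA (which bypass selection — they are
#' array-level, not per-sensor, features), then the selected HSI names.
#' The standard run yields 18 + 2 + 6 = 26 fused features.
#'
#' @param enose_sel `selection_result` from [importance_select_enose()].
#' @param hsi_sel `selection_result` from [correlation_select_hsi()].
#' @param cwt_names Names of the appended CWT summaries.
#' @return A `fused_feature_set`: list with `enose_names`, `hsi_names`,
#'   `fused` (ordered names).
#' @export
fuse_features <- function(enose_sel, hsi_sel, cwt_names = c("WM", "WA")) {
  enose_names <- c(enose_sel$retained, cwt_names)
  hsi_names <- hsi_sel$retained
  if (length(hsi_names) == 0) {
    warning("empty HSI selection; fused set is e-nose only")
  }
  fused <- c(enose_names, hsi_names)
  stop_if(anyDuplicated(fused) > 0,
          "feature name collision between modalities: ",
          paste(unique(fused[duplicated(fused)]), collapse = ", "))
  structure(list(enose_names = enose_names, hsi_names = hsi_names,
                 fused = fused),
            class = "fused_feature_set")
}

#' @export
print.fused_feature_set <- function(x, ...) {
  cat("<fused_feature_set>", length(x$fused), "features (",
      length(x$enose_names), "e-nose +", length(x$hsi_names), "HSI )\n")
  invisible(x)
}
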