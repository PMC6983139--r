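# On-disk formats: long-form e-nose CSV, ENVI cubes, feature-table CSV.

#' E-nose CSV dialect
#'
#' Column naming of the long-form sensor-trace CSV: one row per sample per
#' second, a sample-id column, a time column (1 s steps), and ten sensor
#' columns `f0`..`f9` in fixed array order (W1C, W5S, W3C, W6S, W5C, W1S,
#' W1W, W2S, W2W, W3S).
#'
#' @param sample_id_column,time_column Column labels.
#' @param sensor_columns Ten sensor column labels in array order.
#' @return An `enose_dialect` list.
#' @export
enose_dialect <- function(sample_id_column = "sample_id",
                          time_column = "t",
                          sensor_columns = paste0("f", 0:9)) {
  stop_if(length(sensor_columns) != 10, "exactly 10 sensor columns required")
  structure(list(sample_id_column = sample_id_column,
                 time_column = time_column,
                 sensor_columns = sensor_columns),
            class = "enose_dialect")
}

#' Read electronic-nose records from a long-form CSV
#'
#' Expects one row per (sample, second): a sample-id column, a time column
#' with a strictly increasing unit-step axis of length 75 per sample, and
#' ten numeric sensor columns. Any violation is rejected with the
#' offending sample named; rows are never silently dropped.
#'
#' @param path CSV path.
#' @param dialect An [enose_dialect()].
#' @return Named list of `enose_record`, one per distinct sample id, in
#'   order of first appearance.
#' @export
read_enose_csv <- function(path, dialect = enose_dialect()) {
  stop_if(!file.exists(path), "no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c(dialect$sample_id_column, dialect$time_column,
              dialect$sensor_columns)
  missing <- setdiff(needed, names(df))
  stop_if(length(missing) > 0,
          "missing column(s): ", paste(missing, collapse = ", "))
  for (col in c(dialect$time_column, dialect$sensor_columns)) {
    stop_if(!is.numeric(df[[col]]),
            "non-numeric values in column ", col)
  }
  ids <- unique(df[[dialect$sample_id_column]])
  records <- vector("list", length(ids))
  names(records) <- ids
  for (id in ids) {
    sub <- df[df[[dialect$sample_id_column]] == id, , drop = FALSE]
    stop_if(nrow(sub) != 75,
            "sample ", id, ": expected 75 rows, found ", nrow(sub))
    tdiff <- diff(sub[[dialect$time_column]])
    stop_if(any(tdiff != 1),
            "sample ", id, ": time axis must increase in unit steps")
    traces <- as.matrix(sub[, dialect$sensor_columns, drop = FALSE])
    stop_if(any(!is.finite(traces)),
            "sample ", id, ": non-finite sensor values")
    colnames(traces) <- dialect$sensor_columns
    rownames(traces) <- NULL
    records[[id]] <- new_enose_record(id, traces)
  }
  records
}

#' Write electronic-nose records to a long-form CSV
#'
#' Inverse of [read_enose_csv()]; the pair is a lossless round trip at 12
#' significant digits.
#'
#' @param records List of `enose_record` (or a single record).
#' @param path Output CSV path.
#' @param dialect An [enose_dialect()].
#' @return `path`, invisibly.
#' @export
write_enose_csv <- function(records, path, dialect = enose_dialect()) {
  if (inherits(records, "enose_record")) records <- list(records)
  blocks <- lapply(records, function(r) {
    out <- data.frame(id = rep(r$sample_id, nrow(r$traces)),
                      t = r$time, stringsAsFactors = FALSE)
    names(out) <- c(dialect$sample_id_column, dialect$time_column)
    tr <- r$traces
    colnames(tr) <- dialect$sensor_columns
    cbind(out, as.data.frame(tr))
  })
  df <- do.call(rbind, blocks)
  rownames(df) <- NULL
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- ENVI cubes -----------------------------------------------------------

envi_data_types <- c(`4` = "numeric", `5` = "numeric")  # float32, float64
envi_type_size <- c(`4` = 4L, `5` = 8L)

#' Read a hyperspectral cube from an ENVI header/binary pair
#'
#' Supports the flat-binary ENVI convention: a text `.hdr` describing
#' `samples` (width), `lines` (height), `bands`, `data type` (4 =
#' float32, 5 = float64), `interleave` (bsq/bil/bip), `byte order`, and a
#' `wavelength = {...}` block; plus the raw binary alongside it. The
#' wavelength list is mandatory (band images are addressed by nm
#' throughout the pipeline).
#'
#' @param header_path Path to the `.hdr` file (or the binary; the pair is
#'   resolved either way).
#' @return A `spectral_cube` (data array is lines x samples x bands).
#' @export
read_envi_cube <- function(header_path) {
  hdr_path <- if (grepl("\\.hdr$", header_path)) header_path
              else paste0(header_path, ".hdr")
  stop_if(!file.exists(hdr_path), "no such ENVI header: ", hdr_path)
  img_path <- sub("\\.hdr$", ".img", hdr_path)
  if (!file.exists(img_path)) {
    img_path <- sub("\\.hdr$", "", hdr_path)
  }
  stop_if(!file.exists(img_path), "ENVI binary missing for ", hdr_path)
  hdr <- parse_envi_header(hdr_path)
  for (f in c("samples", "lines", "bands", "data type", "interleave")) {
    stop_if(is.null(hdr[[f]]), "ENVI header lacks field '", f, "'")
  }
  stop_if(is.null(hdr[["wavelength"]]), "ENVI header lacks wavelength metadata")
  W <- as.integer(hdr[["samples"]]); H <- as.integer(hdr[["lines"]])
  B <- as.integer(hdr[["bands"]])
  wl <- as.numeric(hdr[["wavelength"]])
  stop_if(length(wl) != B,
          "header declares ", B, " bands but ", length(wl), " wavelengths")
  dtype <- as.character(as.integer(hdr[["data type"]]))
  stop_if(!dtype %in% names(envi_type_size),
          "unsupported ENVI data type ", dtype, " (only 4/float32, 5/float64)")
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1) "big" else "little"
  n <- H * W * B
  size <- envi_type_size[[dtype]]
  stop_if(file.size(img_path) != n * size,
          "ENVI binary size does not match header dimensions")
  raw_vals <- readBin(img_path, what = "numeric", n = n, size = size,
                      endian = endian)
  interleave <- tolower(hdr[["interleave"]])
  data <- switch(interleave,
    # file order fastest..slowest: bsq = sample, line, band
    bsq = aperm(array(raw_vals, c(W, H, B)), c(2, 1, 3)),
    # bil = sample, band, line
    bil = aperm(array(raw_vals, c(W, B, H)), c(3, 1, 2)),
    # bip = band, sample, line
    bip = aperm(array(raw_vals, c(B, W, H)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave, call. = FALSE)
  )
  new_spectral_cube(data, wl)
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stop_if(length(lines) == 0 || !grepl("^ENVI", lines[1]),
          "not an ENVI header: ", path)
  txt <- paste(lines[-1], collapse = "\n")
  fields <- list()
  # split at newlines that start a "key =" pattern
  pos <- gregexpr("(?m)^[a-zA-Z][a-zA-Z0-9 _]*=", paste0(txt, "\n"),
                  perl = TRUE)[[1]]
  starts <- as.integer(pos)
  if (starts[1] == -1) return(fields)
  ends <- c(starts[-1] - 1L, nchar(txt))
  for (i in seq_along(starts)) {
    chunk <- substr(txt, starts[i], ends[i])
    key <- trimws(sub("=.*", "", chunk))
    val <- trimws(sub("^[^=]*=", "", chunk))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
    }
    fields[[tolower(key)]] <- val
  }
  fields
}

#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' @param cube A `spectral_cube`.
#' @param path Output path without extension; writes `<path>.hdr` and
#'   `<path>.img`.
#' @param interleave One of "bsq", "bil", "bip".
#' @param data_type 5 (float64, lossless; default) or 4 (float32).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                            data_type = 5) {
  interleave <- match.arg(interleave)
  stop_if(!data_type %in% c(4, 5), "data_type must be 4 or 5")
  d <- dim(cube$data)
  H <- d[1]; W <- d[2]; B <- d[3]
  vals <- switch(interleave,
    bsq = as.numeric(aperm(cube$data, c(2, 1, 3))),
    bil = as.numeric(aperm(cube$data, c(2, 3, 1))),
    bip = as.numeric(aperm(cube$data, c(3, 2, 1)))
  )
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    paste0("samples = ", W),
    paste0("lines = ", H),
    paste0("bands = ", B),
    "header offset = 0",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                 collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  writeBin(vals, paste0(path, ".img"), size = envi_type_size[[as.character(data_type)]],
           endian = "little")
  invisible(path)
}

# ---- feature tables -------------------------------------------------------

#' Read or write a feature table
#'
#' A feature table is a data.frame with a `sample_id` column, one or more
#' named numeric feature columns, and optionally the target column
#' `TP_percent`. The CSV round trip is lossless to 12 significant digits.
#' Duplicate feature names, duplicate sample ids, and empty feature sets
#' are rejected.
#'
#' @param path CSV path.
#' @return `read_feature_table`: a validated data.frame.
#' @export
read_feature_table <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_feature_table(raw)
  raw
}

#' @rdname read_feature_table
#' @param table Feature table to write.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_feature_table <- function(table) {
  stop_if(!is.data.frame(table), "feature table must be a data.frame")
  stop_if(!"sample_id" %in% names(table),
          "feature table needs a sample_id column")
  stop_if(anyDuplicated(names(table)) > 0,
          "duplicate column names: ",
          paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  stop_if(anyDuplicated(table$sample_id) > 0, "duplicate sample ids")
  feats <- feature_names(table)
  stop_if(length(feats) == 0, "feature table has no feature columns")
  for (f in feats) {
    stop_if(!is.numeric(table[[f]]), "feature column ", f, " is not numeric")
  }
  invisible(table)
}

#' Feature column names of a feature table
#'
#' All columns except `sample_id` and the target `TP_percent`.
#' @param table A feature table.
#' @return Character vector of feature names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("sample_id", "TP_percent"))
}
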