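#' Read an accelerometer recording from delimited text
#'
#' Accepts comma- or tab-separated files (auto-detected) with either three
#' numeric columns (x, y, z; `rate` required) or four (time, x, y, z; rate
#' inferred from the median time step, which must be uniform within 1%).
#' A header line of non-numeric column names is tolerated and skipped.
#'
#' @param path file path
#' @param rate sampling rate in Hz; required for 3-column files
#' @param unit_hint unit recorded in the file: "g", "m_s2" or "unknown"
#' @param source_id recording identifier; defaults to the file base name
#' @return an [acc_trace()] with samples in file order
#' @export
read_trace <- function(path, rate = NULL, unit_hint = "unknown",
                       source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  skip <- if (any(is.na(suppressWarnings(as.numeric(first))))) 1L else 0L
  body <- lines[(skip + 1L):length(lines)]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(body, sep, fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3))
    stop("format error in ", path, ": line ", which(ncols < 3)[1] + skip,
         " has fewer than 3 columns")
  if (length(unique(ncols)) > 1)
    stop("format error in ", path, ": inconsistent column count at line ",
         which(ncols != ncols[1])[1] + skip)
  nc <- ncols[1]
  if (nc > 4) stop("format error in ", path, ": expected 3 or 4 columns, got ", nc)
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / nc)
    stop("parse error in ", path, ": non-numeric value at line ", bad_row + skip)
  }
  m <- matrix(vals, ncol = nc, byrow = TRUE)
  if (nc == 4) {
    dt <- diff(m[, 1])
    if (length(dt) < 1) stop("rate error in ", path, ": need >= 2 samples to infer rate")
    med <- median(dt)
    if (med <= 0 || any(abs(dt - med) > 0.01 * med))
      stop("rate error in ", path, ": time column not uniform within 1%")
    rate <- 1 / med
    m <- m[, 2:4, drop = FALSE]
  } else {
    if (is.null(rate)) stop("rate is required for 3-column files")
  }
  acc_trace(m, rate = rate, unit = unit_hint, source_id = source_id)
}

#' Read an expert score label table
#'
#' @param path CSV with header
#'   `source_id,block_index,subject_id,site,condition,score`
#' @return data.frame with those columns; scores validated to 0-4 and
#'   (source_id, block_index) required unique
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("source_id", "block_index", "subject_id", "site", "condition", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("label table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$score %in% 0:4)) stop("scores must be integers in 0..4")
  key <- paste(df$source_id, df$block_index)
  if (anyDuplicated(key)) stop("duplicate (source_id, block_index) in label table")
  df[need]
}

# format numerics with full precision, NA -> empty field
format_full <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- ""
      df[[nm]] <- v
    }
  }
  df
}

#' Write per-block feature vectors (and optional per-tap table) to CSV
#'
#' One row per block, in the fixed documented column order (see
#' [feature_columns()]); missing values are written as empty fields.
#' Numeric values are written with 17 significant digits so the table
#' round-trips losslessly through [read_features()]. When a per-tap long
#' table is supplied it is written next to `path` with a `_taps.csv`
#' suffix (one row per tap per feature).
#'
#' @param features data.frame of block feature vectors
#' @param path output CSV path
#' @param tap_table optional long data.frame of per-tap feature values
#' @return `path`, invisibly
#' @export
write_features <- function(features, path, tap_table = NULL) {
  if (is.null(features) || nrow(features) == 0) {
    warning("no feature rows to write; emitting header-only file")
    cols <- if (!is.null(features)) names(features) else feature_columns()
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  write.table(format_full(features), path, sep = ",", row.names = FALSE,
              quote = FALSE, na = "")
  if (!is.null(tap_table)) {
    tpath <- sub("\\.csv$", "_taps.csv", path)
    if (identical(tpath, path)) tpath <- paste0(path, "_taps.csv")
    write.table(format_full(tap_table), tpath, sep = ",", row.names = FALSE,
                quote = FALSE, na = "")
  }
  invisible(path)
}

#' Read back a feature table written by [write_features()]
#'
#' @param path CSV path
#' @return data.frame; empty fields become NA
#' @export
read_features <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   na.strings = "", colClasses = NA)
  num <- setdiff(names(df), c("source_id", "subject_id", "site", "condition",
                              "hand", "feature", "rule_applied"))
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write score predictions to CSV
#'
#' @param predictions data.frame with columns source_id, block_index,
#'   predicted_score, rule_applied (posterior columns pass through)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_predictions <- function(predictions, path) {
  write.table(format_full(predictions), path, sep = ",", row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}
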