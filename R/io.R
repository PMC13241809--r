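# File formats: long-format observation CSV/TSV, laterality-table CSV with a
# schema header, and chart persistence as an NPY binary array (age column +
# centile columns) mirrored by a CSV and a JSON sidecar.

LI_SCHEMA <- "wmasym-li/1"

#' Read a long-format observation table
#'
#' Accepts either a bilateral table (columns `left_value`, `right_value`) or
#' a laterality table (column `li`), plus the covariate columns. Unknown sex
#' or handedness codes are coerced to `"unknown"` and counted; rows with an
#' unparseable age or LI are rejected with their line numbers. Counts and
#' rejected line numbers are returned in the `"ingest_report"` attribute.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension, or
#'   set `sep`). A leading `#`-comment schema line is permitted.
#' @param sep field separator; default by extension.
#' @return typed data.frame with an `"ingest_report"` attribute.
#' @export
read_observations <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = TRUE)
  base_cols <- c("subject_id", "age_years", "sex", "cohort_id")
  if (!all(base_cols %in% names(df))) {
    stop("missing required column(s): ",
         paste(setdiff(base_cols, names(df)), collapse = ", "))
  }
  bilateral <- all(c("left_value", "right_value") %in% names(df))
  if (!bilateral && !"li" %in% names(df)) {
    stop("file must have either left_value/right_value or li columns")
  }

  coerce_num <- function(x) suppressWarnings(as.numeric(x))
  df$age_years <- coerce_num(df$age_years)
  value_cols <- if (bilateral) c("left_value", "right_value") else "li"
  for (cc in value_cols) df[[cc]] <- coerce_num(df[[cc]])

  bad <- !is.finite(df$age_years) | df$age_years < 0
  for (cc in value_cols) bad <- bad | !is.finite(df[[cc]])
  rejected_lines <- which(bad) + 1L  # +1 for the header line

  sex_raw <- tolower(as.character(df$sex))
  sex_bad <- !sex_raw %in% c("female", "male")
  df$sex <- ifelse(sex_bad, "unknown", sex_raw)
  if ("handedness" %in% names(df)) {
    hand_raw <- tolower(as.character(df$handedness))
    hand_bad <- !hand_raw %in% c("right", "left", "ambidextrous")
    df$handedness <- ifelse(hand_bad, "unknown", hand_raw)
  } else {
    df$handedness <- "unknown"
    hand_bad <- logical(nrow(df))
  }

  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ingest_report") <- list(
    n_read = nrow(df), n_kept = nrow(out),
    rejected_lines = rejected_lines,
    n_sex_coerced = sum(sex_bad & !bad),
    n_handedness_coerced = sum(hand_bad & !bad),
    layout = if (bilateral) "bilateral" else "li"
  )
  if (length(rejected_lines) > 0) {
    message(length(rejected_lines), " malformed row(s) rejected (lines ",
            paste(utils::head(rejected_lines, 5), collapse = ", "),
            if (length(rejected_lines) > 5) ", ..." else "", ")")
  }
  out
}

#' Write a table as CSV with a schema header line
#'
#' Numeric columns are formatted at 9 significant digits so that write/read
#' round-trips are stable.
#'
#' @param df data.frame.
#' @param path output path.
#' @param schema schema tag written as a leading `#` comment line.
#' @export
write_table_csv <- function(df, path, schema = LI_SCHEMA) {
  out <- df
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) out[[cc]] <- fmt_num(out[[cc]])
  }
  con <- file(path, "wb")  # binary mode: LF line endings on all platforms
  on.exit(close(con))
  writeLines(paste0("#schema=", schema), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal NPY (v1.0) float64 serialization --------------------------------
# Format: magic "\x93NUMPY", version 1.0, little-endian uint16 header length,
# then a Python dict literal padded with spaces to a 64-byte boundary and
# terminated by \n, then the array body in C (row-major) order.

#' Write a numeric matrix as an NPY file
#'
#' Little-endian float64, C-order, NPY format version 1.0 - readable with
#' `numpy.load`.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @export
write_npy <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(mat), ncol(mat))
  # total = 6 magic + 2 version + 2 hlen + header, padded to a multiple of 64
  unpadded <- 10L + nchar(header, type = "bytes") + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2,
           endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(mat)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY file written by [write_npy()]
#'
#' Supports the subset this package writes: version 1.0, `<f8`, 2-D,
#' C-order.
#'
#' @param path NPY file path.
#' @return numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not an NPY file: ", path)
  }
  ver <- readBin(con, "raw", 2)
  if (ver[1] != as.raw(1)) stop("unsupported NPY version")
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'<f8'", header, fixed = TRUE)) stop("unsupported dtype")
  if (grepl("'fortran_order': True", header, fixed = TRUE)) {
    stop("Fortran-order arrays not supported")
  }
  shape <- regmatches(header, regexpr("\\(([0-9]+), ?([0-9]+)\\)", header))
  dims <- as.integer(strsplit(gsub("[() ]", "", shape), ",")[[1]])
  x <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  matrix(x, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Persist a centile chart (NPY + CSV mirror + JSON sidecar)
#'
#' Writes `<prefix>.npy` (first column the age grid, remaining columns the
#' centile levels in ascending order), `<prefix>.csv` (same layout, headed),
#' and `<prefix>.json` (levels, context, FP specs, BIC, n). Reading the trio
#' back with [read_chart()] reproduces the chart bit-exactly.
#'
#' @param chart a `centile_chart`.
#' @param prefix output path prefix (directories created as needed).
#' @return invisibly, the three paths written.
#' @export
write_chart <- function(chart, prefix) {
  stopifnot(inherits(chart, "centile_chart"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  arr <- cbind(age = chart$age_grid, chart$values)
  npy <- paste0(prefix, ".npy")
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  write_npy(arr, npy)

  df <- as.data.frame(arr)
  con <- file(csv, "wb")
  writeLines(paste0("#schema=wmasym-chart/1"), con)
  utils::write.table(
    cbind(age = sprintf("%.17g", df$age),
          apply(df[, -1, drop = FALSE], 2, function(x) sprintf("%.17g", x))),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)

  jsonlite::write_json(list(
    tract = chart$tract, feature = chart$feature,
    context = chart$context, levels = chart$levels,
    spec_mu = chart$spec_mu, spec_sigma = chart$spec_sigma,
    bic = chart$bic, n = chart$n,
    columns = c("age", sprintf("p%g", chart$levels))
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(npy = npy, csv = csv, json = js))
}

#' Persist a fitted normative model as JSON
#'
#' Serializes the FP specifications, all coefficients (including cohort
#' offsets and penalty variances) and the fit metadata; [read_model()]
#' reconstructs a `normative_model` whose predictions match the original.
#' The weighted-least-squares covariance block is included so prediction
#' standard errors survive the round trip.
#'
#' @param model a `normative_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  x <- unclass(model)
  x$spec_mu <- model$spec_mu$powers
  x$spec_sigma <- model$spec_sigma$powers
  for (f in c("coef_mu", "coef_sigma", "u_mu", "u_sigma")) {
    x[[f]] <- as.list(model[[f]])  # named lists serialize as JSON objects
  }
  x$vcov_mu <- as.vector(model$vcov_mu)
  x$vcov_dim <- nrow(model$vcov_mu)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spec_mu <- fp_spec(x$spec_mu %||% numeric(0))
  x$spec_sigma <- fp_spec(x$spec_sigma %||% numeric(0))
  for (f in c("coef_mu", "coef_sigma", "u_mu", "u_sigma")) {
    x[[f]] <- unlist(x[[f]]) %||% stats::setNames(numeric(0), character(0))
  }
  x$vcov_mu <- matrix(x$vcov_mu, x$vcov_dim, x$vcov_dim)
  x$vcov_dim <- NULL
  x$age_range <- as.numeric(x$age_range)
  class(x) <- "normative_model"
  x
}

#' Read back a persisted centile chart
#'
#' @param prefix the path prefix used in [write_chart()].
#' @return a `centile_chart`.
#' @export
read_chart <- function(prefix) {
  arr <- read_npy(paste0(prefix, ".npy"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  values <- arr[, -1, drop = FALSE]
  colnames(values) <- sprintf("p%g", meta$levels)
  structure(list(
    tract = meta$tract, feature = meta$feature,
    context = as.list(meta$context),
    age_grid = arr[, 1], levels = as.numeric(meta$levels), values = values,
    spec_mu = meta$spec_mu, spec_sigma = meta$spec_sigma,
    bic = meta$bic, n = meta$n
  ), class = "centile_chart")
}
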