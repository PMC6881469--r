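# Shared CSV plumbing. All tabular files are plain comma-separated text with
# a header row; numeric cells are written with 10 significant digits, which
# bounds the text round-trip error at 5e-10 relative.

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file is missing column(s): ", paste(miss, collapse = ", "))
}

coerce_numeric <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(v))
      if (length(bad))
        stop(what, " file: non-numeric value in column '", cl, "' at data row ",
             bad[1])
      v <- vn
    }
    if (anyNA(v) && nrow(df) > 0)
      stop(what, " file: missing value in column '", cl, "'")
    df[[cl]] <- v
  }
  df
}

read_csv_checked <- function(path, required, numeric_cols, what,
                             colClasses = NA) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = colClasses)
  check_schema(df, required, what)
  coerce_numeric(df, numeric_cols, what)
}

write_csv_fmt <- function(df, path, numeric_cols) {
  out <- df
  for (cl in intersect(numeric_cols, names(out))) out[[cl]] <- fmt_num(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write CV trace files
#'
#' CSV dialect `potential_V,current_uA,branch`.
#'
#' @param path File path.
#' @param scan A CV scan data frame (see [simulate_cv()]).
#' @return `read_cv_csv` returns a `cv_scan` data frame; `write_cv_csv`
#'   invisibly returns the path.
#' @export
read_cv_csv <- function(path) {
  df <- read_csv_checked(path, c("potential_V", "current_uA", "branch"),
                         c("potential_V", "current_uA"), "CV trace")
  class(df) <- c("cv_scan", "data.frame")
  df
}

#' @rdname read_cv_csv
#' @export
write_cv_csv <- function(scan, path) {
  check_schema(scan, c("potential_V", "current_uA", "branch"), "CV trace")
  write_csv_fmt(as.data.frame(scan), path, c("potential_V", "current_uA"))
}

#' Read and write impedance spectrum files
#'
#' CSV dialect `frequency_Hz,z_re_ohm,z_im_ohm`.
#'
#' @param path File path.
#' @param spectrum An impedance spectrum data frame (see
#'   [simulate_impedance()]).
#' @return `read_impedance_csv` returns an `impedance_spectrum` data frame;
#'   `write_impedance_csv` invisibly returns the path.
#' @export
read_impedance_csv <- function(path) {
  df <- read_csv_checked(path, c("frequency_Hz", "z_re_ohm", "z_im_ohm"),
                         c("frequency_Hz", "z_re_ohm", "z_im_ohm"),
                         "impedance")
  class(df) <- c("impedance_spectrum", "data.frame")
  df
}

#' @rdname read_impedance_csv
#' @export
write_impedance_csv <- function(spectrum, path) {
  check_schema(spectrum, c("frequency_Hz", "z_re_ohm", "z_im_ohm"), "impedance")
  write_csv_fmt(as.data.frame(spectrum), path,
                c("frequency_Hz", "z_re_ohm", "z_im_ohm"))
}

#' Read and write labeled response dataset files
#'
#' CSV dialect `e_coli,m_capsulatus,s_oneidensis,pollutant,concentration_uM`
#' (a `level_uM` column is preserved when present).
#'
#' @param path File path.
#' @param data A labeled dataset (see [generate_dataset()]).
#' @return `read_dataset_csv` returns a data frame; `write_dataset_csv`
#'   invisibly returns the path.
#' @export
read_dataset_csv <- function(path) {
  req <- c("e_coli", "m_capsulatus", "s_oneidensis", "pollutant",
           "concentration_uM")
  num <- c("e_coli", "m_capsulatus", "s_oneidensis", "concentration_uM")
  df <- read_csv_checked(path, req, num, "dataset")
  if ("level_uM" %in% names(df)) df <- coerce_numeric(df, "level_uM", "dataset")
  df
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(data, path) {
  req <- c("e_coli", "m_capsulatus", "s_oneidensis", "pollutant",
           "concentration_uM")
  check_schema(data, req, "dataset")
  keep <- intersect(c(req, "level_uM"), names(data))
  write_csv_fmt(data[, keep],
                path, c("e_coli", "m_capsulatus", "s_oneidensis",
                        "concentration_uM", "level_uM"))
}

#' Read and write pollutant call files
#'
#' CSV dialect
#' `e_coli,m_capsulatus,s_oneidensis,codeword,pollutant,level_uM`.
#'
#' @param path File path.
#' @param data The responses the calls were made on (channel columns).
#' @param calls A calls data frame (see [predict.sensor_ann()]).
#' @return `read_calls_csv` returns a data frame; `write_calls_csv`
#'   invisibly returns the path.
#' @export
read_calls_csv <- function(path) {
  req <- c("e_coli", "m_capsulatus", "s_oneidensis", "codeword", "pollutant",
           "level_uM")
  read_csv_checked(path, req,
                   c("e_coli", "m_capsulatus", "s_oneidensis", "level_uM"),
                   "calls", colClasses = c(codeword = "character"))
}

#' @rdname read_calls_csv
#' @export
write_calls_csv <- function(data, calls, path) {
  out <- cbind(as.data.frame(response_matrix(data)),
               calls[, c("codeword", "pollutant", "level_uM")])
  names(out)[1:3] <- channel_names()
  write_csv_fmt(out, path, c("e_coli", "m_capsulatus", "s_oneidensis",
                             "level_uM"))
}

#' Save and load a fitted network
#'
#' Stores the configuration, weight vector and training history as JSON text.
#' Numeric values are serialized at full precision, so a save/load cycle
#' reproduces the network bit-exactly.
#'
#' @param object A fitted `sensor_ann` (or a raw [train_lm()] result).
#' @param path File path.
#' @return `read_ann_model` returns a `sensor_ann`; `write_ann_model`
#'   invisibly returns the path.
#' @export
write_ann_model <- function(object, path) {
  payload <- list(
    format = "inhibisense_ann",
    version = 1L,
    config = unclass(object$config),
    weights_hex = format_hex(object$weights),
    history_hex = format_hex(object$history),
    mse = object$mse,
    mse_hex = format_hex(object$mse),
    epochs = object$epochs,
    stop_reason = object$stop_reason
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (is.null(payload$format) || payload$format != "inhibisense_ann")
    stop("not an inhibisense model file: ", path)
  cfg <- do.call(ann_config, payload$config[names(formals(ann_config))])
  mse <- if (!is.null(payload$mse_hex)) parse_hex(payload$mse_hex) else payload$mse
  structure(list(weights = parse_hex(payload$weights_hex), config = cfg,
                 mse = mse, history = parse_hex(payload$history_hex),
                 epochs = payload$epochs, stop_reason = payload$stop_reason,
                 training = NULL),
            class = "sensor_ann")
}

# doubles <-> lossless hex text (bit-exact round trip)
format_hex <- function(x) sprintf("%a", x)
parse_hex <- function(s) {
  if (!length(s)) return(numeric(0))
  vapply(s, function(v) strtoi_hex_double(v), numeric(1), USE.NAMES = FALSE)
}
strtoi_hex_double <- function(v) as.numeric(v)
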