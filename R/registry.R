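#' Pollutant registry
#'
#' The twelve pollutants sensed by the array, in the canonical order used by
#' the class codebook, together with their chemical group. The order is the
#' row order of the packaged test-set table (see [load_table1()]): three heavy
#' metals, three pesticides, six petrochemicals (ethanol, used as a co-solvent
#' for the hydrocarbons, is kept in the petrochemical group).
#'
#' @return A data frame with columns `pollutant`, `group` and `index`
#'   (zero-based position in the codebook ordering).
#' @examples
#' pollutant_registry()
#' @export
pollutant_registry <- function() {
  data.frame(
    pollutant = c("Hg2+", "Pb2+", "Cd2+",
                  "atrazine", "simazine", "DDVP",
                  "hexane", "octane", "pentane", "toluene", "pyrene", "ethanol"),
    group = rep(c("heavy_metals", "pesticides", "petrochemicals"), c(3, 3, 6)),
    index = 0:11,
    stringsAsFactors = FALSE
  )
}

#' Quantized concentration grid
#'
#' The five concentration levels the sensor array was calibrated at, in
#' micromolar: 0.1, 1, 10, 100 and 1000 (i.e. 1 mM).
#'
#' @return Numeric vector of length 5 (ascending).
#' @export
concentration_levels <- function() c(0.1, 1, 10, 100, 1000)

#' Bacterial channel names
#'
#' Column names used throughout for the three sensing channels, in fixed
#' order: *E. coli*, *M. capsulatus* (Bath), *S. oneidensis*.
#'
#' @return Character vector of length 3.
#' @export
channel_names <- function() c("e_coli", "m_capsulatus", "s_oneidensis")

#' Class codebook
#'
#' The 6-bit binary codebook jointly encoding pollutant identity (12 classes)
#' and quantized concentration level (5 levels). Classes are enumerated
#' sequentially in registry order with five levels per pollutant, so the code
#' integer for pollutant index `p` (0-based) at level index `c` (0-based) is
#' `5*p + c + 1`, rendered as a zero-padded 6-digit binary string. Under this
#' scheme atrazine at 1 uM carries `010001` and pyrene at 100 uM carries
#' `110110`.
#'
#' @return A data frame with 60 rows and columns `pollutant`, `group`,
#'   `level_uM`, `code` (integer 1..60) and `codeword` (6-character string).
#' @seealso [encode_class()], [decode_output()]
#' @export
codebook <- function() {
  reg <- pollutant_registry()
  lv <- concentration_levels()
  cb <- data.frame(
    pollutant = rep(reg$pollutant, each = length(lv)),
    group = rep(reg$group, each = length(lv)),
    level_uM = rep(lv, times = nrow(reg)),
    stringsAsFactors = FALSE
  )
  cb$code <- 5L * rep(reg$index, each = length(lv)) + rep(0:4, times = nrow(reg)) + 1L
  cb$codeword <- int_to_codeword(cb$code)
  cb
}

# integer 1..60 -> zero-padded 6-bit binary string (vectorized)
int_to_codeword <- function(k) {
  stopifnot(all(k >= 0), all(k < 64))
  bits <- vapply(k, function(x) paste(rev(as.integer(intToBits(x)[1:6])), collapse = ""),
                 character(1))
  bits
}

codeword_to_int <- function(w) {
  strtoi(w, base = 2L)
}

#' Encode a (pollutant, level) class as its 6-bit codeword
#'
#' @param pollutant Pollutant name (see [pollutant_registry()]) or 0-based
#'   pollutant index.
#' @param level_uM Concentration level in uM — must be one of
#'   [concentration_levels()] — or 0-based level index if `as_index = TRUE`.
#' @param as_index Interpret both arguments as 0-based indices.
#' @return The 6-character binary codeword.
#' @examples
#' encode_class("atrazine", 1)    # "010001"
#' encode_class("pyrene", 100)    # "110110"
#' @export
encode_class <- function(pollutant, level_uM, as_index = FALSE) {
  reg <- pollutant_registry()
  lv <- concentration_levels()
  if (as_index) {
    p <- as.integer(pollutant); cl <- as.integer(level_uM)
  } else {
    p <- reg$index[match(pollutant, reg$pollutant)]
    cl <- match(level_uM, lv) - 1L
  }
  if (anyNA(p) || any(p < 0L) || any(p > 11L))
    stop("unknown pollutant: ", paste(pollutant, collapse = ", "))
  if (anyNA(cl) || any(cl < 0L) || any(cl > 4L))
    stop("concentration level not on the 5-level grid: ",
         paste(level_uM, collapse = ", "))
  int_to_codeword(5L * p + cl + 1L)
}

#' Decode continuous network outputs into a pollutant call
#'
#' Thresholds each of the six outputs at 0.5 to a bit. If the resulting
#' bitstring is a valid codeword the corresponding class is returned;
#' otherwise the valid codeword at minimum Hamming distance is used, ties
#' broken toward the smallest code integer. This makes decoding a total
#' function on `(0,1)^6`.
#'
#' @param raw Numeric vector of 6 network outputs, or a matrix with 6 columns
#'   (one row per sample).
#' @return A data frame with one row per sample and columns `codeword`,
#'   `pollutant`, `group`, `level_uM`, plus the six raw outputs as
#'   `raw_1` .. `raw_6`.
#' @export
decode_output <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  if (ncol(raw) != 6) stop("raw output must have exactly 6 components")
  cb <- codebook()
  bits <- (raw >= 0.5) * 1L
  ints <- as.integer(bits %*% 2L^(5:0))
  idx <- match(ints, cb$code)
  # invalid bitstrings -> nearest valid codeword by Hamming distance
  bad <- which(is.na(idx))
  if (length(bad)) {
    code_bits <- t(vapply(cb$code, function(k) rev(as.integer(intToBits(k)[1:6])),
                          integer(6)))
    for (i in bad) {
      d <- rowSums(abs(sweep(code_bits, 2, bits[i, ])))
      # which.min returns the first minimum; cb is sorted by code integer,
      # so ties break toward the smallest code
      idx[i] <- which.min(d)
    }
  }
  out <- cb[idx, c("codeword", "pollutant", "group", "level_uM")]
  rownames(out) <- NULL
  rawdf <- as.data.frame(raw)
  names(rawdf) <- paste0("raw_", 1:6)
  cbind(out, rawdf)
}

#' Quantize a concentration to the calibration grid
#'
#' Rounds a concentration to the nearest member of the five-level grid
#' \{0.1, 1, 10, 100, 1000\} uM in log10 distance. A concentration exactly at
#' the geometric midpoint between two levels (sqrt(10) times the lower level)
#' is assigned to the lower level.
#'
#' @param concentration_uM Positive numeric vector of concentrations in uM.
#' @return Numeric vector of grid levels, same length as the input.
#' @examples
#' quantize_concentration(c(0.66, 1.45, 83))  # 1 1 100
#' @export
quantize_concentration <- function(concentration_uM) {
  if (any(!is.finite(concentration_uM)) || any(concentration_uM <= 0))
    stop("concentration must be strictly positive")
  lv <- concentration_levels()
  lg <- log10(concentration_uM)
  vapply(lg, function(x) {
    d <- abs(x - log10(lv))
    # ties (geometric midpoints) go to the lower level: which.min picks the
    # first minimum and lv is ascending
    lv[which.min(d)]
  }, numeric(1))
}
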