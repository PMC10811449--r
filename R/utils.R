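# Shared small helpers.

#' Round half away from zero
#'
#' Decimal rounding in which ties go up (`0.005` at 2 decimals becomes
#' `0.01`), unlike [base::round()] which rounds half to even. All linkage
#' rates reported by the package use this convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3
#' round_half_up(84.15, 1) # 84.2
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by one ulp so values stored just below .5 (e.g. 94.955 as
  # 94.95499...) still round the way their printed form suggests
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Parse a DICOM DA value (YYYYMMDD) or an ISO date; unparseable -> NA.
parse_dicom_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  out <- rep(as.Date(NA), length(x))
  da <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[da] <- as.Date(x[da], format = "%Y%m%d")
  iso <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[iso] <- as.Date(x[iso])
  out
}

# Collapse repeated whitespace and trim.
squish <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a "|"-separated multi-value cell into a character vector.
split_multi <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}

join_multi <- function(x) paste(x, collapse = "|")

# Stable data.frame constructor used throughout (no factors, no row names).
df <- function(...) data.frame(..., stringsAsFactors = FALSE, check.names = FALSE)

# Write a table as CSV (always) and optionally Parquet via arrow.
write_table_out <- function(x, path_stem, formats = "csv") {
  paths <- character(0)
  if ("csv" %in% formats) {
    p <- paste0(path_stem, ".csv")
    utils::write.csv(x, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  if ("parquet" %in% formats) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the 'arrow' package", call. = FALSE)
    }
    p <- paste0(path_stem, ".parquet")
    arrow::write_parquet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
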