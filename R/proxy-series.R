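#' Stratigraphic proxy series
#'
#' The universal container for one dated variable: an ordered set of samples
#' with age (kyr BP, larger = older), a value, and an optional 1-sigma
#' replicate uncertainty. Rows are stored sorted by increasing age
#' (youngest first); duplicate ages are rejected because every downstream
#' step (interpolation, constrained clustering) assumes a strict order.
#'
#' @param age_kyr numeric vector of ages in kyr BP.
#' @param value numeric vector of measured values, same length as `age_kyr`.
#' @param sigma optional numeric vector of 1-sigma uncertainties (same units
#'   as `value`); recycled if length 1.
#' @param name single string naming the variable (used in logs and aligned
#'   matrix columns).
#' @return A `data.frame` of class `proxy_series` with columns `age_kyr`,
#'   `value` and (if supplied) `sigma`, sorted by increasing age.
#' @examples
#' ps <- proxy_series(c(2, 1, 3), c(10, 5, 20), name = "demo")
#' ps$age_kyr  # sorted ascending
#' @export
proxy_series <- function(age_kyr, value, sigma = NULL, name = "series") {
  if (!is.numeric(age_kyr) || !is.numeric(value)) {
    stop("`age_kyr` and `value` must be numeric", call. = FALSE)
  }
  if (length(age_kyr) != length(value)) {
    stop("`age_kyr` and `value` must have the same length", call. = FALSE)
  }
  if (anyNA(age_kyr) || any(!is.finite(age_kyr))) {
    stop("ages must be finite and non-missing", call. = FALSE)
  }
  if (any(age_kyr < 0)) stop("ages in kyr BP must be >= 0", call. = FALSE)
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single string", call. = FALSE)
  }
  ord <- order(age_kyr)
  age_kyr <- age_kyr[ord]
  value <- value[ord]
  if (anyDuplicated(age_kyr)) {
    dup <- which(duplicated(age_kyr))[1L]
    stop(sprintf("duplicated age %.6g kyr (sorted row %d)", age_kyr[dup], dup),
         call. = FALSE)
  }
  out <- data.frame(age_kyr = age_kyr, value = value)
  if (!is.null(sigma)) {
    if (length(sigma) == 1L) sigma <- rep(sigma, length(value))
    sigma <- sigma[ord]
    if (any(sigma < 0, na.rm = TRUE)) stop("`sigma` must be >= 0", call. = FALSE)
    out$sigma <- sigma
  }
  attr(out, "name") <- name
  class(out) <- c("proxy_series", "data.frame")
  out
}

#' @export
print.proxy_series <- function(x, ...) {
  cat(sprintf("<proxy_series> %s: %d samples, %.3g-%.3g kyr BP\n",
              attr(x, "name"), nrow(x), min(x$age_kyr), max(x$age_kyr)))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
`[.proxy_series` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "name") <- attr(x, "name")
    class(out) <- c("proxy_series", "data.frame")
  }
  out
}

series_name <- function(x) attr(x, "name") %||% "series"

`%||%` <- function(a, b) if (is.null(a)) b else a

check_numeric_column <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) v <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                 path, col, bad[1L]), call. = FALSE)
  }
  if (anyNA(v)) {
    stop(sprintf("%s: missing value in column '%s' at data row %d",
                 path, col, which(is.na(v))[1L]), call. = FALSE)
  }
  v
}

#' Read a generic proxy CSV
#'
#' Expects a header with at least `age_kyr` and a value column; an optional
#' `sigma` column is carried along. Ages are validated (numeric, finite,
#' no duplicates) with row-numbered error messages.
#'
#' @param path path to a CSV file (UTF-8, '.' decimal separator).
#' @param value_col name of the value column (default `"value"`).
#' @param name variable name for the returned series; defaults to
#'   `value_col`.
#' @return A [proxy_series()].
#' @export
read_proxy_csv <- function(path, value_col = "value", name = value_col) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_kyr", value_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  age <- check_numeric_column(df, "age_kyr", path)
  val <- check_numeric_column(df, value_col, path)
  sig <- if ("sigma" %in% names(df)) check_numeric_column(df, "sigma", path) else NULL
  proxy_series(age, val, sigma = sig, name = name)
}

#' Read a diatom silicon-isotope CSV
#'
#' Column contract: `depth_mcd`, `age_kyr`, `d30si_permil`, `sigma_permil`
#' (header required). d30Si is in permil vs NBS28; sigma is the replicate
#' 1-sigma.
#'
#' @param path path to the CSV file.
#' @return A [proxy_series()] named `"d30si"` with an extra `depth_mcd`
#'   column.
#' @export
read_isotope_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("depth_mcd", "age_kyr", "d30si_permil", "sigma_permil")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  age <- check_numeric_column(df, "age_kyr", path)
  d30 <- check_numeric_column(df, "d30si_permil", path)
  sig <- check_numeric_column(df, "sigma_permil", path)
  dep <- check_numeric_column(df, "depth_mcd", path)
  out <- proxy_series(age, d30, sigma = sig, name = "d30si")
  out$depth_mcd <- dep[order(age)]
  out
}

#' Write a proxy series to CSV
#'
#' @param x a [proxy_series()] (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proxy_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
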