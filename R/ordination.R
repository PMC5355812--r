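#' DCA gradient-length screen
#'
#' Runs detrended correspondence analysis (detrending by segments, rare
#' columns down-weighted) on the aligned variables and reports the first
#' axis gradient length in standard-deviation units. Lengths below the
#' threshold (1.5 by default) indicate approximately linear responses, the
#' justification for following up with PCA rather than unimodal methods.
#'
#' Correspondence analysis needs non-negative entries, so each column is
#' first shifted by its minimum (shifts are logged in the result); constant
#' columns are dropped with a warning. If the shifted matrix contains
#' all-zero rows, a small offset (1\% of the column range) is added to
#' every entry, also logged. A matrix of identical rows carries no
#' gradient: length 0, verdict linear, without calling the CA machinery.
#'
#' @param x an `aligned_matrix`, or a data.frame/matrix of variables
#'   (an `age_kyr` column, if present, is not ordinated).
#' @param threshold verdict threshold in SD units (default 1.5).
#' @return list of class `dca_screen`: `gradient_length_sd`, `verdict`
#'   (`"linear"` or `"unimodal"`), `threshold`, `shifts`, `offset`,
#'   `dropped`.
#' @export
dca_gradient_length <- function(x, threshold = 1.5) {
  m <- as_ordination_matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 rows for the DCA screen", call. = FALSE)
  keep <- apply(m, 2L, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(m)[!keep], collapse = ", ")), call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) == 0L || all(apply(m, 2L, function(v) stats::sd(v) == 0))) {
    return(structure(list(gradient_length_sd = 0, verdict = "linear",
                          threshold = threshold, shifts = numeric(0),
                          offset = 0, dropped = colnames(x)),
                     class = "dca_screen"))
  }
  shifts <- apply(m, 2L, min)
  m2 <- sweep(m, 2L, shifts)
  offset <- 0
  if (any(rowSums(m2) <= 0)) {
    offset <- 0.01 * mean(apply(m2, 2L, max))
    m2 <- m2 + offset
  }
  if (max(m2) == 0 || isTRUE(all.equal(stats::sd(rowSums(m2)), 0)) &&
      all(apply(m2, 2L, stats::sd) < 1e-12)) {
    len <- 0
  } else {
    ord <- vegan::decorana(m2, iweigh = 1)
    sc <- vegan::scores(ord, display = "sites", choices = 1)
    len <- diff(range(sc))
  }
  structure(list(gradient_length_sd = len,
                 verdict = if (len < threshold) "linear" else "unimodal",
                 threshold = threshold, shifts = shifts, offset = offset,
                 dropped = colnames(m)[!keep]),
            class = "dca_screen")
}

#' @export
print.dca_screen <- function(x, ...) {
  cat(sprintf("<dca_screen> axis-1 gradient length %.3f SD (threshold %.2f): %s response\n",
              x$gradient_length_sd, x$threshold, x$verdict))
  invisible(x)
}

#' PCA with scaling for all variables
#'
#' Principal components analysis of the aligned variables after centering
#' and scaling each to unit variance (i.e. an eigen-analysis of the
#' correlation structure), so eigenvalues sum to the number of variables.
#' Axis signs follow a deterministic convention: within each axis the
#' largest-magnitude loading is made positive.
#'
#' @param x an `aligned_matrix`, or a data.frame/matrix of variables.
#' @return list of class `pca_ordination`: `eigenvalues`,
#'   `variance_fractions`, `loadings` (variables x axes), `scores`
#'   (samples x axes), `center`, `scale`.
#' @export
pca_scaled <- function(x) {
  m <- as_ordination_matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 rows for PCA", call. = FALSE)
  keep <- apply(m, 2L, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(m)[!keep], collapse = ", ")), call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need at least 2 non-constant variables", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, variance_fractions = ev / sum(ev),
                 loadings = load, scores = scores,
                 center = pc$center, scale = pc$scale),
            class = "pca_ordination")
}

#' @export
print.pca_ordination <- function(x, ...) {
  cat("<pca_ordination> eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat("variance explained (%):",
      paste(sprintf("%.1f", 100 * x$variance_fractions), collapse = ", "), "\n")
  invisible(x)
}

as_ordination_matrix <- function(x) {
  if (inherits(x, "aligned_matrix")) x <- x$data
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "age_kyr"), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("ordination input must be numeric", call. = FALSE)
  if (anyNA(x)) {
    drop <- apply(x, 1L, anyNA)
    warning(sprintf("dropping %d row(s) with missing values", sum(drop)),
            call. = FALSE)
    x <- x[!drop, , drop = FALSE]
  }
  x
}

#' OLS regression with adjusted R-squared
#'
#' Ordinary least squares of `y` on `x` with the two-sided slope test and
#' the one-predictor adjusted R-squared,
#' `1 - (1 - R^2) (n - 1) / (n - 2)`.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list: `slope`, `intercept`, `r_squared`, `adj_r_squared`,
#'   `p_value`, `n`.
#' @export
regress_adjusted_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       adj_r_squared = sm$adj.r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = n)
}

#' Long-term trend test of a proxy series
#'
#' OLS of value on age (kyr BP) with the two-sided slope test. Because
#' larger ages are older, a *decline toward the present* is a positive
#' slope on age. A constant series returns slope 0, p = 1 with a warning.
#'
#' @param series a [proxy_series()] (or data.frame with `age_kyr`,
#'   `value`), >= 4 samples.
#' @return list: `slope_per_kyr`, `p_value`, `n`.
#' @export
trend_test <- function(series) {
  stopifnot(is.data.frame(series), all(c("age_kyr", "value") %in% names(series)))
  n <- nrow(series)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (stats::sd(series$value) == 0) {
    warning("constant series: slope 0, p = 1", call. = FALSE)
    return(list(slope_per_kyr = 0, p_value = 1, n = n))
  }
  fit <- stats::lm(value ~ age_kyr, data = series)
  sm <- summary(fit)
  list(slope_per_kyr = unname(stats::coef(fit)[2L]),
       p_value = sm$coefficients[2L, 4L],
       n = n)
}
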