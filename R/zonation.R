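#' Constrained incremental sum-of-squares (CONISS) zonation
#'
#' Agglomerative, stratigraphically constrained clustering: starting from
#' one block per sample, at each step the two *adjacent* blocks whose
#' merger least increases the pooled within-block sum of squares are
#' fused, until a single block remains. The increase at each step is the
#' incremental dispersion; cumulative dispersion plays the role of
#' dendrogram height. With a `sqrt` transform the values are square-root
#' transformed before the (euclidean) sums of squares are formed, the
#' convention used for proportion-like data such as utilization fractions.
#'
#' Ties between equal-increase mergers are broken in favour of the
#' stratigraphically oldest pair so results are deterministic.
#'
#' @param series a [proxy_series()] (its `value` column is clustered), or a
#'   numeric vector/matrix of values ordered stratigraphically.
#' @param transform `"sqrt"` (default; requires non-negative values) or
#'   `"none"`.
#' @param ages optional ages (taken from `series$age_kyr` when available);
#'   must be strictly increasing.
#' @return An object of class `coniss_zonation`: list with
#'   \describe{
#'     \item{merges}{data.frame (`step`, `left_start`, `boundary`,
#'       `right_end`, `increment`, `height`): at `step`, samples
#'       `left_start..boundary` fused with `boundary+1..right_end`.}
#'     \item{boundaries_at}{list; element `k` holds the sample indices
#'       (last sample of each zone but the deepest... see Details) when
#'       exactly `k` blocks remain.}
#'     \item{total_dispersion}{within-SS of the whole (transformed) series.}
#'     \item{ages, values, transform, n}{inputs echoed back.}
#'   }
#' @details `boundaries_at[[k]]` stores, for the k-zone partition, the
#'   indices i such that a zone boundary falls between samples i and i+1
#'   (samples ordered youngest to oldest when ages are ascending).
#' @export
coniss <- function(series, transform = c("sqrt", "none"), ages = NULL) {
  transform <- match.arg(transform)
  if (is.data.frame(series)) {
    if (is.null(ages) && "age_kyr" %in% names(series)) ages <- series$age_kyr
    x <- as.matrix(series[["value"]])
  } else {
    x <- as.matrix(series)
  }
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples to zone", call. = FALSE)
  if (is.null(ages)) ages <- seq_len(n)
  if (length(ages) != n || any(diff(ages) <= 0)) {
    stop("ages must be strictly increasing and match the series length",
         call. = FALSE)
  }
  if (transform == "sqrt") {
    if (any(x < 0)) {
      stop("sqrt transform requires non-negative values", call. = FALSE)
    }
    xt <- sqrt(x)
  } else {
    xt <- x
  }

  # block statistics: per-variable sums, total sum of squares, counts
  p <- ncol(xt)
  blk_sum <- matrix(xt, nrow = n, ncol = p)      # running per-block sums
  blk_ssq <- rowSums(xt^2)                        # running sum of x^2
  blk_n <- rep(1L, n)
  blk_start <- seq_len(n)                         # first sample of block
  within_ss <- function(s, q, m) q - sum(s^2) / m # SS about the block mean

  ss <- rep(0, n)                                 # each singleton: SS 0
  active <- seq_len(n)                            # ordered block ids
  merges <- data.frame(step = integer(n - 1L), left_start = integer(n - 1L),
                       boundary = integer(n - 1L), right_end = integer(n - 1L),
                       increment = numeric(n - 1L), height = numeric(n - 1L))
  boundaries_at <- vector("list", n)
  boundaries_at[[n]] <- seq_len(n - 1L)
  cumdisp <- 0

  for (step in seq_len(n - 1L)) {
    nb <- length(active)
    inc <- numeric(nb - 1L)
    for (j in seq_len(nb - 1L)) {
      a <- active[j]; b <- active[j + 1L]
      s <- blk_sum[a, ] + blk_sum[b, ]
      q <- blk_ssq[a] + blk_ssq[b]
      m <- blk_n[a] + blk_n[b]
      inc[j] <- within_ss(s, q, m) - ss[a] - ss[b]
    }
    cand <- which(inc == min(inc))
    j <- cand[length(cand)]  # ties: stratigraphically oldest pair (largest age)
    a <- active[j]; b <- active[j + 1L]
    boundary <- blk_start[b] - 1L
    right_end <- if (j + 1L < nb) blk_start[active[j + 2L]] - 1L else n
    blk_sum[a, ] <- blk_sum[a, ] + blk_sum[b, ]
    blk_ssq[a] <- blk_ssq[a] + blk_ssq[b]
    blk_n[a] <- blk_n[a] + blk_n[b]
    ss[a] <- within_ss(blk_sum[a, ], blk_ssq[a], blk_n[a])
    cumdisp <- cumdisp + inc[j]
    merges[step, ] <- list(step, blk_start[a], boundary, right_end,
                           inc[j], cumdisp)
    active <- active[-(j + 1L)]
    boundaries_at[[nb - 1L]] <- blk_start[active[-1L]] - 1L
  }

  total <- within_ss(colSums(xt), sum(xt^2), n)
  structure(list(merges = merges, boundaries_at = boundaries_at,
                 total_dispersion = total, ages = ages, values = x,
                 transform = transform, n = n),
            class = "coniss_zonation")
}

#' @export
print.coniss_zonation <- function(x, ...) {
  cat(sprintf("<coniss_zonation> %d samples, transform = %s, total dispersion %.4g\n",
              x$n, x$transform, x$total_dispersion))
  bs <- broken_stick_table(x)
  ns <- n_significant_zones(x)
  cat(sprintf("significant zones (successive broken-stick rule): %d\n", ns))
  print(utils::head(bs, 5L))
  invisible(x)
}

#' Broken-stick expected variance proportions
#'
#' Expected proportion of variance for the kth (ranked) piece when a stick
#' is broken at random into `n_zones` pieces:
#' `Pr(k) = (1/n) * sum(1/i, i = k..n)`. The sequence is decreasing and
#' sums to one.
#'
#' @param n_zones integer >= 1.
#' @return numeric vector of length `n_zones`.
#' @examples
#' broken_stick_expected(2)  # 0.75 0.25
#' @export
broken_stick_expected <- function(n_zones) {
  if (length(n_zones) != 1L || n_zones < 1 || n_zones != round(n_zones)) {
    stop("`n_zones` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n_zones)
  vapply(seq_len(n), function(k) sum(1 / (k:n)) / n, numeric(1))
}

#' Broken-stick table for a CONISS zonation
#'
#' For each zone count k the observed proportion of total dispersion
#' explained by the split that creates the kth zone (the merge undone when
#' going from k-1 to k zones), alongside two broken-stick references:
#' `expected_pr`, the kth piece of a stick broken into n pieces (n =
#' number of samples; this column sums to one, as does the observed column
#' with the k = 1 row fixed at zero), and `expected_successive`, the
#' smallest (kth) piece of a k-piece stick (`1/k^2`), which is the
#' yardstick the significance rule uses.
#'
#' @param zonation a [coniss()] result.
#' @param max_zones truncate the table (default: all n rows).
#' @return data.frame with columns `k`, `observed_proportion`,
#'   `expected_pr`, `expected_successive`, `significant`.
#' @export
broken_stick_table <- function(zonation, max_zones = NULL) {
  stopifnot(inherits(zonation, "coniss_zonation"))
  n <- zonation$n
  inc <- zonation$merges$increment
  total <- zonation$total_dispersion
  # split creating the kth zone (k >= 2) undoes merge number n - k + 1
  observed <- c(0, rev(inc) / total)
  expected <- broken_stick_expected(n)
  successive <- c(NA_real_, (2:n)^-2)
  signif <- c(TRUE, observed[-1L] > successive[-1L])
  out <- data.frame(k = seq_len(n), observed_proportion = observed,
                    expected_pr = expected,
                    expected_successive = successive,
                    significant = signif)
  if (!is.null(max_zones)) out <- out[out$k <= max_zones, ]
  out
}

#' Number of significant zones under the broken-stick model
#'
#' Zone counts are accepted while every split up to that count explains
#' more of the total dispersion than expected for the smallest piece of a
#' random broken stick with that many pieces (1/k^2 for the split creating
#' the kth zone; 0.25 for the first split). `n_significant` is the largest
#' zone count whose splits all pass; it is at least 1.
#'
#' @param zonation a [coniss()] result.
#' @return integer >= 1.
#' @export
n_significant_zones <- function(zonation) {
  tab <- broken_stick_table(zonation)
  pass <- tab$significant
  # largest k such that rows 2..k all pass
  k <- 1L
  for (i in seq_along(pass)[-1L]) {
    if (pass[i]) k <- i else break
  }
  k
}

#' Cut a CONISS zonation into k zones
#'
#' @param zonation a [coniss()] result.
#' @param k number of zones (default: [n_significant_zones()]).
#' @return data.frame with one row per zone: `zone` (labelled 1 =
#'   youngest, matching the convention that Zone 1 is the late interval),
#'   `age_min_kyr`, `age_max_kyr`, `first_index`, `last_index`, `n`.
#' @export
cut_zones <- function(zonation, k = n_significant_zones(zonation)) {
  stopifnot(inherits(zonation, "coniss_zonation"))
  if (k < 1 || k > zonation$n) stop("`k` out of range", call. = FALSE)
  b <- zonation$boundaries_at[[k]]
  starts <- c(1L, b + 1L)
  ends <- c(b, zonation$n)
  data.frame(zone = seq_len(k),
             age_min_kyr = zonation$ages[starts],
             age_max_kyr = zonation$ages[ends],
             first_index = starts, last_index = ends,
             n = ends - starts + 1L)
}

#' Per-zone summary statistics
#'
#' Median, mean, quartiles (type-7 linear interpolation between order
#' statistics) and sample count of a series within each zone.
#'
#' @param series a [proxy_series()] (or data.frame with `age_kyr`, `value`).
#' @param zones a data.frame as returned by [cut_zones()] (needs
#'   `zone`, `age_min_kyr`, `age_max_kyr`).
#' @return data.frame with one row per zone: `zone`, `n`, `mean`, `median`,
#'   `q25`, `q75`.
#' @export
zone_stats <- function(series, zones) {
  stopifnot(is.data.frame(series), all(c("age_kyr", "value") %in% names(series)),
            all(c("zone", "age_min_kyr", "age_max_kyr") %in% names(zones)))
  out <- lapply(seq_len(nrow(zones)), function(i) {
    v <- series$value[series$age_kyr >= zones$age_min_kyr[i] &
                        series$age_kyr <= zones$age_max_kyr[i]]
    if (!length(v)) stop(sprintf("zone %s is empty", zones$zone[i]), call. = FALSE)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(zone = zones$zone[i], n = length(v), mean = mean(v),
               median = q[2L], q25 = q[1L], q75 = q[3L])
  })
  do.call(rbind, out)
}

#' Rank-sum test for a difference between two zones
#'
#' Two-sided Mann-Whitney rank-sum comparison of the values in two zones:
#' exact enumeration when both groups have at most 10 samples and no ties,
#' the tie-corrected normal approximation otherwise. Chosen to match a
#' median/IQR style of reporting; identical samples give p = 1 with a
#' warning.
#'
#' @param values_a,values_b numeric vectors of the per-zone values.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
zone_difference_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both zones must be non-empty", call. = FALSE)
  }
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values identical; p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- length(values_a) <= 10L && length(values_b) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact rank-sum" else "normal approximation (tie-corrected)")
}
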