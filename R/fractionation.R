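#' Silicon isotope fractionation system
#'
#' Parameterizes every conversion between diatom d30Si and silicic-acid
#' utilization: the isotopic composition of the silicic acid supplied to the
#' photic zone (`delta_source`, permil vs NBS28), the enrichment factor
#' between diatom opal and dissolved Si(OH)4 (`epsilon`, permil; negative,
#' because the light isotope is preferentially biomineralized), and their
#' 1-sigma uncertainties. Defaults are the values constrained for the
#' Southern Ocean south of the ACC: +1.4 permil source, -1.2 +/- 0.1 permil
#' enrichment.
#'
#' @param delta_source d30Si of supplied Si(OH)4 in permil (default +1.4).
#' @param epsilon enrichment factor in permil, must be negative
#'   (default -1.2). Stored signed, never as a magnitude.
#' @param epsilon_sd 1-sigma on `epsilon` in permil (default 0.1).
#' @param delta_source_sd 1-sigma on `delta_source` in permil (default 0).
#' @return A list of class `fractionation_system`.
#' @examples
#' sys <- fractionation_system()
#' utilization_open_system(0.8, sys)
#' @export
fractionation_system <- function(delta_source = 1.4, epsilon = -1.2,
                                 epsilon_sd = 0.1, delta_source_sd = 0) {
  stopifnot(length(delta_source) == 1L, length(epsilon) == 1L,
            length(epsilon_sd) == 1L, length(delta_source_sd) == 1L)
  if (!is.finite(delta_source)) stop("`delta_source` must be finite", call. = FALSE)
  if (!is.finite(epsilon) || epsilon >= 0) {
    stop("`epsilon` must be finite and negative (signed convention)", call. = FALSE)
  }
  if (epsilon_sd < 0 || delta_source_sd < 0) {
    stop("uncertainties must be >= 0", call. = FALSE)
  }
  structure(list(delta_source = delta_source, epsilon = epsilon,
                 epsilon_sd = epsilon_sd, delta_source_sd = delta_source_sd),
            class = "fractionation_system")
}

#' @export
print.fractionation_system <- function(x, ...) {
  cat(sprintf(
    "<fractionation_system> delta_source = %+.2f permil (sd %.2f), epsilon = %+.2f permil (sd %.2f)\n",
    x$delta_source, x$delta_source_sd, x$epsilon, x$epsilon_sd))
  invisible(x)
}

#' Admissible d30Si band of the open-system model
#'
#' For a negative enrichment factor the diatom product can only lie between
#' `delta_source + epsilon` (zero utilization: the full fractionation is
#' expressed) and `delta_source` (complete utilization: mass balance forces
#' the product onto the source).
#'
#' @param system a [fractionation_system()].
#' @return Length-2 numeric `c(lower, upper)` in permil.
#' @export
admissible_band <- function(system) {
  stopifnot(inherits(system, "fractionation_system"))
  c(system$delta_source + system$epsilon, system$delta_source)
}

#' Invert d30Si to silicic-acid utilization (open system)
#'
#' Under the steady-state open-system model with continuous supply of
#' silicic acid to the photic zone, the diatom product varies linearly with
#' the fraction f of supplied Si(OH)4 left in the water:
#' `delta_diatom = delta_source + epsilon * f`. Utilization is `1 - f`.
#'
#' Values outside the admissible band are a hard error by default (never
#' silently clamped); with `clamp = TRUE` they are mapped to the band edge
#' (utilization 0 or 1) with a warning, which is the pragmatic choice when
#' replicate noise overshoots the band by a fraction of a sigma.
#'
#' @param delta_diatom numeric vector, d30Si of diatom opal in permil.
#' @param system a [fractionation_system()].
#' @param sigma_delta optional measurement 1-sigma (permil, vectorized) used
#'   to attach an analytic `utilization_sd` column.
#' @param clamp logical; clamp out-of-band values to the band edge instead
#'   of raising (default `FALSE`).
#' @return A data.frame of class `utilization_estimate` with columns
#'   `delta_diatom`, `f_remaining`, `utilization` (fraction in \[0, 1\]),
#'   optional `utilization_sd`, and `model = "open"`.
#' @examples
#' sys <- fractionation_system()
#' utilization_open_system(c(0.2, 0.8, 1.4), sys)$utilization  # 0, 0.5, 1
#' @export
utilization_open_system <- function(delta_diatom, system,
                                    sigma_delta = NULL, clamp = FALSE) {
  stopifnot(inherits(system, "fractionation_system"))
  if (!is.numeric(delta_diatom) || anyNA(delta_diatom)) {
    stop("`delta_diatom` must be numeric with no missing values", call. = FALSE)
  }
  band <- admissible_band(system)
  out_of_band <- delta_diatom < band[1L] | delta_diatom > band[2L]
  if (any(out_of_band)) {
    if (!clamp) {
      stop(sprintf(
        "d30Si value %+.4g permil outside the admissible band [%+.4g, %+.4g] permil; use clamp = TRUE to map onto the band edge",
        delta_diatom[which(out_of_band)[1L]], band[1L], band[2L]), call. = FALSE)
    }
    warning(sprintf("%d value(s) outside [%+.4g, %+.4g] permil clamped to the band edge",
                    sum(out_of_band), band[1L], band[2L]), call. = FALSE)
    delta_diatom <- pmin(pmax(delta_diatom, band[1L]), band[2L])
  }
  f <- (delta_diatom - system$delta_source) / system$epsilon
  out <- data.frame(delta_diatom = delta_diatom,
                    f_remaining = f,
                    utilization = 1 - f,
                    model = "open",
                    stringsAsFactors = FALSE)
  if (!is.null(sigma_delta)) {
    out$utilization_sd <- vapply(seq_along(delta_diatom), function(i) {
      propagate_uncertainty(delta_diatom[i],
                            if (length(sigma_delta) == 1L) sigma_delta else sigma_delta[i],
                            system, method = "analytic")
    }, numeric(1))
  }
  class(out) <- c("utilization_estimate", "data.frame")
  out
}

#' Forward open-system model: utilization to d30Si
#'
#' Exact inverse of [utilization_open_system()]; used by the synthetic
#' generator and in round-trip tests.
#'
#' @param utilization numeric vector of fractions in \[0, 1\].
#' @param system a [fractionation_system()].
#' @return d30Si in permil: `delta_source + epsilon * (1 - utilization)`.
#' @export
delta_from_utilization <- function(utilization, system) {
  stopifnot(inherits(system, "fractionation_system"))
  if (any(utilization < 0 | utilization > 1)) {
    stop("`utilization` must lie in [0, 1]", call. = FALSE)
  }
  system$delta_source + system$epsilon * (1 - utilization)
}

#' Closed-system (Rayleigh) accumulated-product d30Si
#'
#' The rejected baseline model: Rayleigh distillation without resupply.
#' The accumulated product (what integrates into the sediment) is
#' `delta_source - epsilon * f * log(f) / (1 - f)`. Included so the two
#' models can be compared; they coincide at zero utilization and diverge
#' monotonically as utilization grows.
#'
#' @param f_remaining numeric vector of fractions; must lie in (0, 1)
#'   unless `allow_limits = TRUE`, in which case 0 and 1 are evaluated by
#'   their analytic limits (`delta_source` and `delta_source + epsilon`).
#' @param system a [fractionation_system()].
#' @param allow_limits logical (default `FALSE`).
#' @return Accumulated-product d30Si in permil.
#' @export
rayleigh_closed_delta <- function(f_remaining, system, allow_limits = FALSE) {
  stopifnot(inherits(system, "fractionation_system"))
  lo <- if (allow_limits) 0 else .Machine$double.eps
  hi <- if (allow_limits) 1 else 1 - 1e-15
  if (any(f_remaining < lo - 1e-15 | f_remaining > hi + 1e-15)) {
    stop("`f_remaining` must lie in (0, 1); set allow_limits = TRUE for the endpoints",
         call. = FALSE)
  }
  out <- numeric(length(f_remaining))
  at0 <- f_remaining <= 0
  at1 <- f_remaining >= 1
  mid <- !at0 & !at1
  out[at0] <- system$delta_source                      # total consumption: mass balance
  out[at1] <- system$delta_source + system$epsilon     # no consumption
  f <- f_remaining[mid]
  out[mid] <- system$delta_source - system$epsilon * f * log(f) / (1 - f)
  out
}

#' Propagate uncertainty into the utilization estimate
#'
#' First-order (delta-method) or Monte-Carlo propagation of the measurement
#' sigma and the system parameter sigmas, all treated as independent
#' normals. With U = 1 - (delta - delta_source)/epsilon the partials are
#' dU/ddelta = -1/epsilon, dU/ddelta_source = 1/epsilon and
#' dU/depsilon = (delta - delta_source)/epsilon^2.
#'
#' @param delta_diatom single d30Si value in permil.
#' @param sigma_delta measurement 1-sigma in permil (>= 0).
#' @param system a [fractionation_system()].
#' @param method `"analytic"` (delta method) or `"monte_carlo"`.
#' @param n_draws Monte-Carlo sample size (default 1e5).
#' @param seed integer seed, required for `method = "monte_carlo"`.
#' @return 1-sigma on the utilization fraction.
#' @export
propagate_uncertainty <- function(delta_diatom, sigma_delta, system,
                                  method = c("analytic", "monte_carlo"),
                                  n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(system, "fractionation_system"),
            length(delta_diatom) == 1L, length(sigma_delta) == 1L)
  if (sigma_delta < 0) stop("`sigma_delta` must be >= 0", call. = FALSE)
  method <- match.arg(method)
  eps <- system$epsilon
  ds <- system$delta_source
  if (method == "analytic") {
    var_u <- (sigma_delta^2 + system$delta_source_sd^2) / eps^2 +
      ((delta_diatom - ds) / eps^2)^2 * system$epsilon_sd^2
    return(sqrt(var_u))
  }
  if (is.null(seed)) {
    stop("`seed` is required for Monte-Carlo propagation", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- stats::rnorm(n_draws, delta_diatom, sigma_delta)
  e <- stats::rnorm(n_draws, eps, system$epsilon_sd)
  s <- stats::rnorm(n_draws, ds, system$delta_source_sd)
  stats::sd(1 - (d - s) / e)
}

#' Convert an isotope series to a utilization series
#'
#' Applies [utilization_open_system()] sample-wise and returns the input
#' with the columns the rest of the pipeline consumes appended:
#' `f_remaining`, `utilization_pct`, `utilization_sd_pct`, `model`.
#' Internally everything is a fraction; the I/O columns are percent to
#' match how utilization records are reported.
#'
#' @param series a [proxy_series()] (values = d30Si permil; `sigma` column
#'   used for per-sample propagation when present).
#' @param system a [fractionation_system()].
#' @param clamp passed to [utilization_open_system()].
#' @return A [proxy_series()] named `"utilization"` whose `value` column is
#'   the utilization fraction, with the percent I/O columns attached.
#' @export
convert_utilization <- function(series, system = fractionation_system(),
                                clamp = FALSE) {
  stopifnot(is.data.frame(series), all(c("age_kyr", "value") %in% names(series)))
  sig <- if ("sigma" %in% names(series)) series$sigma else rep(0, nrow(series))
  est <- utilization_open_system(series$value, system, sigma_delta = sig,
                                 clamp = clamp)
  out <- proxy_series(series$age_kyr, est$utilization,
                      sigma = est$utilization_sd, name = "utilization")
  out$d30si_permil <- est$delta_diatom
  out$f_remaining <- est$f_remaining
  out$utilization_pct <- 100 * est$utilization
  out$utilization_sd_pct <- 100 * est$utilization_sd
  out$model <- est$model
  out
}
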