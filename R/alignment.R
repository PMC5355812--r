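#' Linear interpolation of a proxy series onto target ages
#'
#' Piecewise-linear interpolation in age with exact pass-through at
#' coincident ages. Targets outside the series span are never extrapolated:
#' they come back as `NA` and are reported in the `outside` attribute.
#'
#' @param series a [proxy_series()] (or data.frame with `age_kyr`, `value`).
#' @param target_ages numeric vector of ages (kyr BP).
#' @return numeric vector of interpolated values (NA outside the span),
#'   with attribute `outside` = indices of out-of-span targets.
#' @export
interpolate_to_ages <- function(series, target_ages) {
  stopifnot(is.data.frame(series), all(c("age_kyr", "value") %in% names(series)))
  if (!nrow(series)) stop("empty series", call. = FALSE)
  out <- stats::approx(series$age_kyr, series$value, xout = target_ages,
                       method = "linear", rule = 1)$y
  outside <- which(target_ages < min(series$age_kyr) |
                     target_ages > max(series$age_kyr))
  attr(out, "outside") <- outside
  out
}

#' Age-gap exclusion rule
#'
#' For each target age, the gap is the distance to the nearest original
#' observation of the series (`gap_rule = "nearest"`, the default) or the
#' larger of the distances to the two bracketing observations
#' (`gap_rule = "bracket"`). Targets whose gap exceeds the tolerance are
#' flagged for exclusion; gaps are reported in years (ages are kyr
#' internally, the tolerance is specified in years).
#'
#' @param series a [proxy_series()].
#' @param target_ages numeric vector (kyr BP).
#' @param tolerance_years maximum allowed gap in years (default 50);
#'   `Inf` keeps everything.
#' @param gap_rule `"nearest"` or `"bracket"`.
#' @return data.frame: `age_kyr`, `gap_years`, `keep`.
#' @export
age_gap_filter <- function(series, target_ages, tolerance_years = 50,
                           gap_rule = c("nearest", "bracket")) {
  stopifnot(is.data.frame(series), "age_kyr" %in% names(series))
  gap_rule <- match.arg(gap_rule)
  if (!nrow(series)) stop("empty series", call. = FALSE)
  if (tolerance_years <= 0) stop("`tolerance_years` must be > 0", call. = FALSE)
  obs <- series$age_kyr
  gap_kyr <- vapply(target_ages, function(a) {
    if (gap_rule == "nearest") {
      min(abs(obs - a))
    } else {
      lo <- obs[obs <= a]; hi <- obs[obs >= a]
      if (!length(lo) || !length(hi)) {
        min(abs(obs - a))  # outside the span: nearest end
      } else {
        max(a - max(lo), min(hi) - a)
      }
    }
  }, numeric(1))
  gap_years <- 1000 * gap_kyr
  data.frame(age_kyr = target_ages, gap_years = gap_years,
             keep = gap_years <= tolerance_years)
}

#' Align covariate records onto the isotope sample ages
#'
#' Builds the samples-by-variables matrix that feeds ordination: rows are
#' the isotope/utilization sample ages (the master grid; the isotope series
#' itself is never resampled), columns are the utilization values plus each
#' covariate linearly interpolated to those ages. A row is dropped when any
#' non-exempt covariate's age gap exceeds `tolerance_years` (the joint
#' rule; set `joint = FALSE` to only blank the offending covariate), or
#' when a target age falls outside a non-exempt covariate's span. Exempt
#' covariates (e.g. a coarse-resolution westerly-wind clay/silt series) are
#' interpolated without the gap rule but flagged in the exclusion log where
#' a span violation forces an `NA`.
#'
#' @param utilization a [proxy_series()] whose ages define the target grid.
#' @param covariates named list of [proxy_series()].
#' @param tolerance_years gap tolerance in years (default 50).
#' @param exempt character vector of covariate names exempt from the gap
#'   rule (default `character()`).
#' @param span optional `c(age_min, age_max)` restricting the target rows
#'   (used for per-zone matrices).
#' @param joint drop whole rows on any violation (default `TRUE`).
#' @param gap_rule passed to [age_gap_filter()].
#' @return An object of class `aligned_matrix`: list with `data` (data.frame
#'   `age_kyr`, `utilization`, one column per covariate), `exclusions`
#'   (data.frame `age_kyr`, `variable`, `gap_years`, `reason`), `exempt`,
#'   `tolerance_years`.
#' @export
align_covariates <- function(utilization, covariates, tolerance_years = 50,
                             exempt = character(), span = NULL, joint = TRUE,
                             gap_rule = c("nearest", "bracket")) {
  stopifnot(is.data.frame(utilization),
            all(c("age_kyr", "value") %in% names(utilization)))
  gap_rule <- match.arg(gap_rule)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates)))) {
    stop("`covariates` must be a named list", call. = FALSE)
  }
  targets <- utilization$age_kyr
  uvals <- utilization$value
  if (!is.null(span)) {
    keep <- targets >= min(span) & targets <= max(span)
    targets <- targets[keep]
    uvals <- uvals[keep]
  }
  data <- data.frame(age_kyr = targets, utilization = uvals)
  exclusions <- data.frame(age_kyr = numeric(0), variable = character(0),
                           gap_years = numeric(0), reason = character(0),
                           stringsAsFactors = FALSE)
  drop_row <- rep(FALSE, length(targets))
  for (nm in names(covariates)) {
    cov <- covariates[[nm]]
    vals <- interpolate_to_ages(cov, targets)
    outside <- attr(vals, "outside")
    attributes(vals) <- NULL
    is_exempt <- nm %in% exempt
    if (!is_exempt) {
      gf <- age_gap_filter(cov, targets, tolerance_years, gap_rule)
      over <- which(!gf$keep)
      for (i in over) {
        exclusions <- rbind(exclusions, data.frame(
          age_kyr = targets[i], variable = nm, gap_years = gf$gap_years[i],
          reason = "age gap exceeds tolerance", stringsAsFactors = FALSE))
      }
      bad <- union(over, outside)
      if (joint) {
        drop_row[bad] <- TRUE
      } else {
        vals[bad] <- NA_real_
      }
      for (i in setdiff(outside, over)) {
        exclusions <- rbind(exclusions, data.frame(
          age_kyr = targets[i], variable = nm, gap_years = NA_real_,
          reason = "outside covariate span", stringsAsFactors = FALSE))
      }
    } else {
      vals[outside] <- NA_real_
      for (i in outside) {
        exclusions <- rbind(exclusions, data.frame(
          age_kyr = targets[i], variable = nm, gap_years = NA_real_,
          reason = "outside exempt covariate span (value NA)",
          stringsAsFactors = FALSE))
      }
    }
    data[[nm]] <- vals
  }
  if (any(drop_row)) data <- data[!drop_row, , drop = FALSE]
  rownames(data) <- NULL
  if (nrow(data) < 3L) {
    warning(sprintf("aligned matrix has only %d retained row(s); ordination will refuse",
                    nrow(data)), call. = FALSE)
  }
  structure(list(data = data, exclusions = exclusions, exempt = exempt,
                 tolerance_years = tolerance_years),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d rows x %d variables, %d exclusion log entries (tolerance %g yr)\n",
              nrow(x$data), ncol(x$data) - 1L, nrow(x$exclusions),
              x$tolerance_years))
  print(utils::head(x$data, 5L))
  invisible(x)
}

#' Per-zone aligned matrices
#'
#' Applies [align_covariates()] within each zone span.
#'
#' @param utilization a [proxy_series()] on the master age grid.
#' @param covariates named list of [proxy_series()].
#' @param zones data.frame from [cut_zones()] (needs `zone`,
#'   `age_min_kyr`, `age_max_kyr`).
#' @param ... passed to [align_covariates()].
#' @return named list of `aligned_matrix`, one per zone.
#' @export
align_by_zone <- function(utilization, covariates, zones, ...) {
  stopifnot(all(c("zone", "age_min_kyr", "age_max_kyr") %in% names(zones)))
  out <- lapply(seq_len(nrow(zones)), function(i) {
    suppressWarnings(align_covariates(
      utilization, covariates,
      span = c(zones$age_min_kyr[i], zones$age_max_kyr[i]), ...))
  })
  names(out) <- paste0("zone", zones$zone)
  out
}
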