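#' Run the full utilization inference chain
#'
#' Chains the analysis stages on one record: (1) invert d30Si to
#' utilization under the open-system model; (2) CONISS zonation of the
#' utilization series with broken-stick significance; (3) per-zone summary
#' statistics, the between-zone rank-sum test and the long-term trend
#' test; (4) per-zone alignment of the covariates onto the isotope ages
#' with the age-gap exclusion rule; (5) DCA gradient-length screen and
#' scaled PCA per zone. The report also carries the exact fractionation
#' constants used, so it is self-describing.
#'
#' @param isotopes either a `proxy_record` from [generate_record()] or a
#'   data.frame with columns `age_kyr`, `d30si_permil`, `sigma_permil`
#'   (e.g. from [read_isotope_csv()]).
#' @param covariates named list of [proxy_series()]; defaults to the
#'   record's covariates when `isotopes` is a `proxy_record`.
#' @param system a [fractionation_system()].
#' @param transform CONISS transform, `"sqrt"` (default) or `"none"`.
#' @param cluster_on `"utilization"` (default) or `"d30si"`.
#' @param tolerance_years age-gap tolerance (default 50).
#' @param exempt covariates exempt from the gap rule (default: the
#'   record's `exempt` set, else none).
#' @param dca_threshold gradient-length verdict threshold (default 1.5).
#' @param clamp passed to the utilization inversion.
#' @param outdir optional directory: writes `report.json`, the utilization
#'   CSV, per-sample zone labels and exclusion logs there.
#' @return list of class `silutil_report`; see the elements in the
#'   examples/vignette. All percent-scale numbers are percent.
#' @export
run_pipeline <- function(isotopes, covariates = NULL,
                         system = fractionation_system(),
                         transform = c("sqrt", "none"),
                         cluster_on = c("utilization", "d30si"),
                         tolerance_years = 50, exempt = NULL,
                         dca_threshold = 1.5, clamp = FALSE, outdir = NULL) {
  transform <- match.arg(transform)
  cluster_on <- match.arg(cluster_on)
  if (inherits(isotopes, "proxy_record")) {
    if (is.null(covariates)) covariates <- isotopes$covariates
    if (is.null(exempt)) exempt <- isotopes$exempt
    isotopes <- isotopes$isotopes
  }
  if (is.null(exempt)) exempt <- character(0)
  stopifnot(is.data.frame(isotopes),
            all(c("age_kyr", "d30si_permil") %in% names(isotopes)))
  iso <- proxy_series(isotopes$age_kyr, isotopes$d30si_permil,
                      sigma = if ("sigma_permil" %in% names(isotopes))
                        isotopes$sigma_permil else NULL,
                      name = "d30si")

  util <- convert_utilization(iso, system, clamp = clamp)

  clus_series <- if (cluster_on == "utilization") util else iso
  clus_transform <- if (cluster_on == "d30si") "none" else transform
  zonation <- coniss(clus_series, transform = clus_transform)
  n_sig <- n_significant_zones(zonation)
  zones <- cut_zones(zonation, max(n_sig, 1L))
  # label zones the stratigrapher's way: Zone 1 = youngest
  stats_pct <- zone_stats(util, zones)
  stats_pct[c("mean", "median", "q25", "q75")] <-
    100 * stats_pct[c("mean", "median", "q25", "q75")]

  zdiff <- NULL
  if (nrow(zones) >= 2L) {
    va <- util$value[util$age_kyr >= zones$age_min_kyr[1L] &
                       util$age_kyr <= zones$age_max_kyr[1L]]
    vb <- util$value[util$age_kyr >= zones$age_min_kyr[2L] &
                       util$age_kyr <= zones$age_max_kyr[2L]]
    zdiff <- zone_difference_test(va, vb)
  }
  trend <- trend_test(util)

  alignment <- NULL
  ordination <- NULL
  if (length(covariates)) {
    alignment <- align_by_zone(util, covariates, zones,
                               tolerance_years = tolerance_years,
                               exempt = exempt)
    ordination <- lapply(alignment, function(am) {
      if (nrow(am$data) < 3L) {
        return(list(dca = NULL, pca = NULL,
                    note = "fewer than 3 retained rows; ordination refused"))
      }
      dca <- suppressWarnings(dca_gradient_length(am, threshold = dca_threshold))
      pca <- suppressWarnings(pca_scaled(am))
      list(dca = dca, pca = pca, note = NULL)
    })
  }

  report <- structure(list(
    system = system,
    n_samples = nrow(iso),
    utilization = util,
    zonation = zonation,
    broken_stick = broken_stick_table(zonation, max_zones = min(10L, zonation$n)),
    n_significant = n_sig,
    zones = zones,
    zone_stats_pct = stats_pct,
    zone_difference = zdiff,
    trend = trend,
    alignment = alignment,
    ordination = ordination
  ), class = "silutil_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.silutil_report <- function(x, ...) {
  cat(sprintf("<silutil_report> %d samples; %d significant zone(s)\n",
              x$n_samples, x$n_significant))
  cat(sprintf("system: delta_source %+.2f permil, epsilon %+.2f permil\n",
              x$system$delta_source, x$system$epsilon))
  print(x$zone_stats_pct, row.names = FALSE)
  if (!is.null(x$zone_difference)) {
    cat(sprintf("zone 1 vs zone 2 rank-sum p = %.3g (%s)\n",
                x$zone_difference$p_value, x$zone_difference$method))
  }
  cat(sprintf("trend: %+.4g utilization fraction per kyr, p = %.3g\n",
              x$trend$slope_per_kyr, x$trend$p_value))
  if (!is.null(x$ordination)) {
    for (nm in names(x$ordination)) {
      o <- x$ordination[[nm]]
      if (!is.null(o$note)) {
        cat(sprintf("%s: %s\n", nm, o$note))
      } else {
        cat(sprintf("%s: DCA length %.2f SD (%s); PCA axis-1 %.0f%% of variance\n",
                    nm, o$dca$gradient_length_sd, o$dca$verdict,
                    100 * o$pca$variance_fractions[1L]))
      }
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine-readable summary), `utilization.csv`
#' (sample table with `f_remaining`, `utilization_pct`,
#' `utilization_sd_pct`, `model`), `zones.csv` (per-sample zone labels)
#' and one exclusion log per zone.
#'
#' @param report a `silutil_report`.
#' @param outdir output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "silutil_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  util <- as.data.frame(report$utilization)
  utils::write.csv(util, file.path(outdir, "utilization.csv"),
                   row.names = FALSE, quote = FALSE)
  zl <- data.frame(age_kyr = report$utilization$age_kyr)
  zl$zone <- vapply(zl$age_kyr, function(a) {
    z <- report$zones
    z$zone[a >= z$age_min_kyr & a <= z$age_max_kyr][1L]
  }, numeric(1))
  utils::write.csv(zl, file.path(outdir, "zones.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(report$alignment)) {
    for (nm in names(report$alignment)) {
      ex <- report$alignment[[nm]]$exclusions
      utils::write.csv(ex, file.path(outdir, paste0("exclusions_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  js <- list(
    system = unclass(report$system),
    n_samples = report$n_samples,
    n_significant = report$n_significant,
    zones = report$zones,
    zone_stats_pct = report$zone_stats_pct,
    broken_stick = report$broken_stick,
    zone_difference_p = if (is.null(report$zone_difference)) NULL
      else report$zone_difference$p_value,
    trend = report$trend,
    ordination = if (is.null(report$ordination)) NULL else
      lapply(report$ordination, function(o) {
        if (!is.null(o$note)) return(list(note = o$note))
        list(dca_gradient_length_sd = o$dca$gradient_length_sd,
             dca_verdict = o$dca$verdict,
             eigenvalues = o$pca$eigenvalues,
             variance_fractions = o$pca$variance_fractions,
             loadings = as.data.frame(o$pca$loadings))
      })
  )
  jsonlite::write_json(js, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
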