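#' Scenario configuration for the synthetic record generator
#'
#' Describes a multiproxy stratigraphic scenario: irregular age sampling
#' over a span, a piecewise-constant (regime) mean structure in
#' silicic-acid utilization with AR(1) process noise around it, isotope
#' measurement error, covariates with regime-specific correlations to the
#' latent utilization on their own (possibly coarser) age grids, and a
#' small cryophilic fraction in the assemblage.
#'
#' Regimes are indexed youngest first: with boundaries `b1 < b2 < ...`,
#' regime 1 is `age < b1`, regime 2 is `b1 <= age < b2`, and so on.
#'
#' @param seed integer; one global seed drives per-stream child seeds (see
#'   Details) so adding a covariate never perturbs existing streams.
#' @param n_samples number of isotope samples (default 80).
#' @param age_span `c(young, old)` in kyr BP (default `c(0.2, 12.6)`).
#' @param regime_boundaries ordered ages inside the span (default 5.45).
#' @param regime_utilization_means utilization fractions, youngest regime
#'   first (default `c(0.342, 0.483)`); one more than boundaries.
#' @param ar1_coefficient AR(1) coefficient of the process noise,
#'   `|phi| < 1` (default 0.3).
#' @param process_sd stationary SD of the AR(1) process noise, as a
#'   utilization fraction (default 0.03).
#' @param measurement_sd_delta isotope measurement 1-sigma in permil
#'   (default 0.03, the replicate analytical reproducibility).
#' @param covariate_specs named list; each element a list with
#'   `correlations` (one per regime, youngest first), `interval_kyr`
#'   (sampling interval), `base`, `scale` (affine placement in native
#'   units), optional `exempt` (logical, exempt from the age-gap rule) and
#'   optional `on_isotope_grid` (sampled at the isotope ages, as for a
#'   variable measured on the same samples; `interval_kyr` then unused).
#' @param cryophilic_p mean cryophilic fraction of the assemblage
#'   (default 0.006).
#' @param system a [fractionation_system()].
#' @details Stream k uses seed `(seed * 1009 + k * 9973) mod (2^31 - 1)`;
#'   streams are: 1 ages, 2 process noise, 3 measurement noise, 10+i the
#'   i-th covariate, 50 the assemblage.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed, n_samples = 80, age_span = c(0.2, 12.6),
                            regime_boundaries = 5.45,
                            regime_utilization_means = c(0.342, 0.483),
                            ar1_coefficient = 0.3, process_sd = 0.03,
                            measurement_sd_delta = 0.03,
                            covariate_specs = list(),
                            cryophilic_p = 0.006,
                            system = fractionation_system()) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_samples < 3L) stop("`n_samples` must be >= 3", call. = FALSE)
  if (length(age_span) != 2L || age_span[1L] >= age_span[2L]) {
    stop("`age_span` must be c(young, old) with young < old", call. = FALSE)
  }
  if (length(regime_boundaries)) {
    if (is.unsorted(regime_boundaries, strictly = TRUE)) {
      stop("`regime_boundaries` must be strictly increasing", call. = FALSE)
    }
    if (any(regime_boundaries <= age_span[1L] | regime_boundaries >= age_span[2L])) {
      stop("`regime_boundaries` must lie inside the age span", call. = FALSE)
    }
  }
  if (length(regime_utilization_means) != length(regime_boundaries) + 1L) {
    stop("need one regime mean per regime (boundaries + 1)", call. = FALSE)
  }
  if (any(regime_utilization_means <= 0 | regime_utilization_means >= 1)) {
    stop("regime means must be utilization fractions in (0, 1)", call. = FALSE)
  }
  if (abs(ar1_coefficient) >= 1) stop("|ar1_coefficient| must be < 1", call. = FALSE)
  if (process_sd < 0 || measurement_sd_delta < 0) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  if (cryophilic_p < 0 || cryophilic_p > 0.05) {
    stop("`cryophilic_p` must lie in [0, 0.05]", call. = FALSE)
  }
  for (nm in names(covariate_specs)) {
    cs <- covariate_specs[[nm]]
    if (length(cs$correlations) != length(regime_utilization_means)) {
      stop(sprintf("covariate '%s': need one correlation per regime", nm),
           call. = FALSE)
    }
    if (any(abs(cs$correlations) > 1)) {
      stop(sprintf("covariate '%s': correlations must lie in [-1, 1]", nm),
           call. = FALSE)
    }
    if (!isTRUE(cs$on_isotope_grid) &&
        (is.null(cs$interval_kyr) || cs$interval_kyr <= 0)) {
      stop(sprintf("covariate '%s': positive `interval_kyr` required", nm),
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 age_span = age_span, regime_boundaries = regime_boundaries,
                 regime_utilization_means = regime_utilization_means,
                 ar1_coefficient = ar1_coefficient, process_sd = process_sd,
                 measurement_sd_delta = measurement_sd_delta,
                 covariate_specs = covariate_specs,
                 cryophilic_p = cryophilic_p, system = system),
            class = "scenario_config")
}

stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

regime_index <- function(age, boundaries) {
  findInterval(age, boundaries) + 1L
}

#' Holocene two-regime preset
#'
#' The default scenario mirroring the Palmer Deep style record: ~80
#' isotope samples over 12.6-0.2 kyr BP, a regime shift at 5.45 kyr
#' between utilization means 0.483 (older regime) and 0.342 (younger,
#' neoglacial regime), measurement sigma 0.03 permil, and four covariates
#' (sea-ice taxon %, d18O of diatom opal, a coarse clay/silt westerly-wind
#' proxy exempt from the gap rule, and a dense solar-irradiance series)
#' with regime-specific correlations to utilization.
#'
#' @param seed integer seed (default 1).
#' @return a [scenario_config()].
#' @export
holocene_preset <- function(seed = 1) {
  scenario_config(
    seed = seed,
    n_samples = 80,
    age_span = c(0.2, 12.6),
    regime_boundaries = 5.45,
    regime_utilization_means = c(0.342, 0.483),
    ar1_coefficient = 0.3,
    process_sd = 0.03,
    measurement_sd_delta = 0.03,
    covariate_specs = list(
      fcurta = list(correlations = c(0.3, 0.7), interval_kyr = 0.06,
                    base = 10, scale = 5),
      d18o = list(correlations = c(0.7, 0.0), on_isotope_grid = TRUE,
                  base = 38, scale = 0.8),
      sww = list(correlations = c(-0.3, -0.3), interval_kyr = 0.4,
                 base = 1.2, scale = 0.3, exempt = TRUE),
      tsi = list(correlations = c(0.0, -0.5), interval_kyr = 0.02,
                 base = 1361, scale = 0.5)
    ),
    cryophilic_p = 0.006
  )
}

#' Generate a synthetic multiproxy record
#'
#' Deterministic given the config seed. Stages: (1) irregular ages from a
#' jittered regular grid; (2) latent utilization = regime mean + AR(1)
#' noise, clipped to (0.01, 0.99) (clips counted in `n_clipped`);
#' (3) d30Si through the forward open-system model plus Gaussian
#' measurement noise; (4) covariates built conditionally on the latent
#' (noise-free) utilization interpolated to their own age grids, so the
#' configured regime-wise correlations are structural; (5) assemblage
#' abundances with the configured cryophilic fraction.
#'
#' @param config a [scenario_config()].
#' @return list of class `proxy_record`: `isotopes` (data.frame
#'   `depth_mcd`, `age_kyr`, `d30si_permil`, `sigma_permil`), `truth`
#'   (a [proxy_series()] of latent utilization), `covariates` (named list
#'   of [proxy_series()]), `exempt` (names of gap-rule-exempt covariates),
#'   `assemblage` (long data.frame), `config`, `n_clipped`.
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  span <- config$age_span
  n <- config$n_samples

  set.seed(stream_seed(config$seed, 1L))
  base_ages <- seq(span[1L], span[2L], length.out = n)
  spacing <- diff(base_ages[1:2])
  ages <- sort(base_ages + stats::runif(n, -0.3, 0.3) * spacing)
  ages <- pmin(pmax(ages, span[1L]), span[2L])
  while (anyDuplicated(ages)) ages[duplicated(ages)] <- ages[duplicated(ages)] + 1e-6

  set.seed(stream_seed(config$seed, 2L))
  phi <- config$ar1_coefficient
  innov_sd <- config$process_sd * sqrt(1 - phi^2)
  e <- numeric(n)
  if (config$process_sd > 0) {
    e[1L] <- stats::rnorm(1L, 0, config$process_sd)
    for (t in seq_len(n - 1L)) e[t + 1L] <- phi * e[t] + stats::rnorm(1L, 0, innov_sd)
  }
  means <- config$regime_utilization_means[regime_index(ages, config$regime_boundaries)]
  u_raw <- means + e
  u <- pmin(pmax(u_raw, 0.01), 0.99)
  n_clipped <- sum(u != u_raw)

  d30_true <- delta_from_utilization(u, config$system)
  set.seed(stream_seed(config$seed, 3L))
  d30_meas <- d30_true + stats::rnorm(n, 0, config$measurement_sd_delta)

  isotopes <- data.frame(depth_mcd = round(3.38 * ages, 4),
                         age_kyr = ages,
                         d30si_permil = d30_meas,
                         sigma_permil = config$measurement_sd_delta)
  truth <- proxy_series(ages, u, name = "utilization_truth")

  covariates <- list()
  exempt <- character(0)
  specs <- config$covariate_specs
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    cs <- specs[[i]]
    set.seed(stream_seed(config$seed, 10L + i))
    if (isTRUE(cs$on_isotope_grid)) {
      grid <- ages  # e.g. d18O measured on the very same samples
    } else {
      grid <- seq(span[1L] + cs$interval_kyr / 2, span[2L] - cs$interval_kyr / 2,
                  by = cs$interval_kyr)
      grid <- sort(grid + stats::runif(length(grid), -0.2, 0.2) * cs$interval_kyr)
      grid <- grid[grid >= span[1L] & grid <= span[2L]]
    }
    u_at <- stats::approx(ages, u, xout = grid, rule = 2)$y
    reg <- regime_index(grid, config$regime_boundaries)
    z <- if (config$process_sd > 0) {
      (u_at - config$regime_utilization_means[reg]) / config$process_sd
    } else rep(0, length(grid))
    rho <- cs$correlations[reg]
    raw <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(grid))
    base <- cs$base %||% 0
    scale <- cs$scale %||% 1
    covariates[[nm]] <- proxy_series(grid, base + scale * raw, name = nm)
    if (isTRUE(cs$exempt)) exempt <- c(exempt, nm)
  }

  set.seed(stream_seed(config$seed, 50L))
  cryo_taxa <- default_taxonomy()$taxon[default_taxonomy()$eco_class == "cryophilic"]
  assemblage <- do.call(rbind, lapply(ages, function(a) {
    p_cryo <- min(config$cryophilic_p * exp(stats::rnorm(1L, 0, 0.5)), 0.02)
    cryo_shares <- stats::runif(length(cryo_taxa))
    cryo_shares <- p_cryo * cryo_shares / sum(cryo_shares)
    fc <- 0.10 * exp(stats::rnorm(1L, 0, 0.3))
    fcy <- 0.03 * exp(stats::rnorm(1L, 0, 0.3))
    hc <- 0.60 * exp(stats::rnorm(1L, 0, 0.1))
    tot <- p_cryo + fc + fcy + hc
    if (tot > 0.98) {  # keep room for the 'other' remainder
      sc <- 0.98 / tot
      cryo_shares <- cryo_shares * sc; fc <- fc * sc; fcy <- fcy * sc; hc <- hc * sc
    }
    other <- 1 - sum(cryo_shares) - fc - fcy - hc
    data.frame(age_kyr = a,
               taxon = c(cryo_taxa, "Fragilariopsis curta",
                         "Fragilariopsis cylindrus", "Hyalochaete chaetoceros",
                         "Other diatoms"),
               rel_abundance_pct = 100 * c(cryo_shares, fc, fcy, hc, other),
               eco_class = c(rep("cryophilic", length(cryo_taxa)),
                             "sea_ice_associated", "sea_ice_associated",
                             "open_water", "open_water"),
               stringsAsFactors = FALSE)
  }))

  structure(list(isotopes = isotopes, truth = truth, covariates = covariates,
                 exempt = exempt, assemblage = assemblage, config = config,
                 n_clipped = n_clipped),
            class = "proxy_record")
}

#' @export
print.proxy_record <- function(x, ...) {
  cat(sprintf("<proxy_record> %d isotope samples over %.1f-%.1f kyr BP, %d covariate(s), seed %d\n",
              nrow(x$isotopes), min(x$isotopes$age_kyr), max(x$isotopes$age_kyr),
              length(x$covariates), x$config$seed))
  invisible(x)
}

#' Write a synthetic record as the CSV bundle the pipeline reads
#'
#' Emits `isotopes.csv` (isotope schema), one `<name>.csv` per covariate
#' (generic proxy schema), `assemblage.csv` and `utilization_truth.csv`
#' into `outdir`.
#'
#' @param record a [generate_record()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_record_csv <- function(record, outdir) {
  stopifnot(inherits(record, "proxy_record"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(isotopes = file.path(outdir, "isotopes.csv"))
  utils::write.csv(record$isotopes, paths[["isotopes"]], row.names = FALSE,
                   quote = FALSE)
  for (nm in names(record$covariates)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(record$covariates[[nm]]), p,
                     row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  paths["assemblage"] <- file.path(outdir, "assemblage.csv")
  utils::write.csv(record$assemblage, paths[["assemblage"]], row.names = FALSE,
                   quote = FALSE)
  paths["utilization_truth"] <- file.path(outdir, "utilization_truth.csv")
  utils::write.csv(as.data.frame(record$truth), paths[["utilization_truth"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
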