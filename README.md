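# silutil

Reconstruction of photic-zone silicic-acid utilization from diatom
silicon-isotope records, and the statistical characterisation of its
stratigraphic structure.

Diatoms preferentially incorporate light silicon into opal (enrichment
factor ε ≈ −1.2 ‰), so the δ³⁰Si of sedimentary diatom opal tracks how
completely the Si(OH)₄ supplied to the photic zone was consumed. For a
coastal Antarctic-style record, `silutil` provides the whole inference
chain from measured δ³⁰Si to utilization *regimes*:

1. **Fractionation inversion** — open-system steady state,
   δ₃₀Si_diatom = δ₃₀Si(OH)₄ + ε·f, utilization U = 1 − f
   (defaults δ_source = +1.4 ‰, ε = −1.2 ± 0.1 ‰), with a Rayleigh
   closed-system baseline, analytic and Monte-Carlo uncertainty
   propagation, and strict handling of the admissible band
   [δ_source + ε, δ_source].
2. **Cryophilic mass balance** — bounds the bias from isotopically heavy
   sea-ice brine diatoms via a two-end-member mixing inversion and a
   sensitivity sweep over their (unmeasured) end member.
3. **Zonation** — CONISS (constrained incremental sum-of-squares
   clustering, square-root transform by default) with a broken-stick
   significance rule (Pr(k) = (1/n)·Σᵢ₌ₖⁿ 1/i), per-zone medians/IQRs,
   a Mann–Whitney between-zone test and an OLS trend test.
4. **Alignment** — linear interpolation of covariate proxies (sea-ice
   taxon %, δ¹⁸O, clay/silt, solar irradiance) onto the isotope sample
   ages with a 50-year age-gap exclusion rule and a full exclusion log.
5. **Ordination** — per-zone DCA gradient-length screen (< 1.5 SD ⇒
   linear response) followed by PCA with scaling for all variables.
6. **Synthetic records** — a seeded generator of multiproxy bundles with
   regime-shift mean structure, AR(1) noise, measurement error and
   regime-wise covariate correlations, used for all calibration
   experiments.

## Worked example

```r
library(silutil)

## invert three measured d30Si values (permil vs NBS28)
sys <- fractionation_system()                 # +1.4 / -1.2 +/- 0.1 permil
est <- utilization_open_system(c(0.63, 0.78, 1.03), sys, sigma_delta = 0.03)
round(est$utilization * 100, 1)
#> [1] 35.8 48.3 69.2
round(est$utilization_sd * 100, 1)
#> [1] 5.9 5.0 3.6

## end-to-end on a synthetic Holocene-style record
rec    <- generate_record(holocene_preset(seed = 1))
report <- run_pipeline(rec)
report
#> <silutil_report> 80 samples; 2 significant zone(s)
#> system: delta_source +1.40 permil, epsilon -1.20 permil
#>  zone  n     mean   median      q25      q75
#>     1 34 34.62325 34.73598 32.09916 37.83618
#>     2 46 48.65187 48.56526 46.52035 51.37389
#> zone 1 vs zone 2 rank-sum p = 6.93e-14 (normal approximation (tie-corrected))
#> trend: +0.0166 utilization fraction per kyr, p = 1.99e-15
#> zone1: DCA length 1.44 SD (linear); PCA axis-1 35% of variance
#> zone2: DCA length 1.46 SD (linear); PCA axis-1 44% of variance
```

Reading the output: a δ³⁰Si of +0.78 ‰ corresponds to 48.3 % utilization
with a 1σ of 5 percentage points (measurement plus ε uncertainty). The
synthetic record — whose generating truth is a utilization regime shift
at 5.45 kyr BP from a mean of 48.3 % down to 34.2 % — is zoned into
exactly two significant zones by CONISS + broken stick; the recovered
per-zone medians (34.7 % and 48.6 %) sit within two percentage points of
the truth, the zones differ at p ≪ 0.001 on the rank-sum test, the
utilization trend toward the present is a decline, and within each zone
the aligned covariate matrix screens as linear (DCA gradient length
< 1.5 SD), justifying the PCA whose axis-1 eigenvalue share is printed.
Real records are read the same way; `read_isotope_csv()` and
`read_proxy_csv()` ingest the CSV schemas documented on those functions.

The methods vignette (`vignettes/silutil-methods.Rmd`) explains the
models, the broken-stick decision rule, the age-gap rule, every tunable
parameter with units and defaults, and what the synthetic generator does
and does not emulate.

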