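---
title: "From diatom silicon isotopes to silicic-acid utilization regimes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From diatom silicon isotopes to silicic-acid utilization regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silutil)
```

# The scientific problem

Diatoms discriminate against the heavy silicon isotopes when they
biomineralize dissolved silicic acid, Si(OH)~4~, into opal: the enrichment
factor $\varepsilon$ between frustule and dissolved phase is about
−1.2 ‰ in marine systems and is, to current knowledge, independent
of temperature and growth conditions. As a bloom draws down the Si(OH)~4~
pool, both the dissolved phase and the opal produced from it become
isotopically heavier. A downcore record of $\delta^{30}\mathrm{Si}$ in
diatom opal is therefore a proxy for the *fraction of supplied silicic acid
consumed in the photic zone* — the utilization — and its stratigraphic
structure records how nutrient drawdown was regulated through time (sea
ice, glacial discharge, winds, solar forcing).

`silutil` implements the full inference chain for such records: the
isotope-to-utilization inversion with uncertainty propagation; a mass
balance bounding the bias from cryophilic (sea-ice brine) diatoms;
stratigraphically constrained zonation with a broken-stick significance
rule; alignment of covariate proxy records onto the isotope sample ages;
and an ordination screen (DCA gradient length, then PCA on standardized
variables). A synthetic multiproxy generator with the same statistical
anatomy ties the chain together for calibration experiments.

# The fractionation models

## Open system (the working model)

With continuous resupply of Si(OH)~4~ to the photic zone and steady-state
drawdown, the opal leaving the system varies *linearly* with the fraction
$f$ of supplied silicic acid left in the water:

$$\delta^{30}\mathrm{Si}_{\mathrm{diatom}}
  = \delta^{30}\mathrm{Si(OH)_4} + \varepsilon\, f ,
  \qquad U = 1 - f,$$

where $\delta^{30}\mathrm{Si(OH)_4}$ is the source composition and $U$ the
utilization. The inversion is

$$f = \frac{\delta^{30}\mathrm{Si}_{\mathrm{diatom}} -
        \delta^{30}\mathrm{Si(OH)_4}}{\varepsilon}.$$

Defaults are the regional constraints for the Southern Ocean south of the
ACC: source +1.4 ‰, ε = −1.2 ± 0.1 ‰
(`fractionation_system()`). $\varepsilon$ is stored *signed*; every formula
is written for signed $\varepsilon$, which removes an entire class of sign
bugs. The admissible product band is
$[\delta_{\mathrm{source}} + \varepsilon,\; \delta_{\mathrm{source}}]$
([+0.2, +1.4] ‰ at the defaults): measurements outside it raise an
error naming the interval. Because replicate noise of 0.03 ‰ can
legitimately overshoot the band near its edges, an explicit `clamp = TRUE`
maps such values onto utilization 0 or 1 with a warning — never silently.

Internally everything is a fraction; CSV output columns
(`utilization_pct`, `utilization_sd_pct`) are percent, matching how such
records are plotted and tabulated.

## Closed system (the rejected baseline)

`rayleigh_closed_delta()` gives the Rayleigh accumulated product,
$\delta_{\mathrm{source}} - \varepsilon f \ln f / (1-f)$. It is included
only for comparison: closed-system behaviour is not appropriate for most
oceanic regions. One analytic subtlety worth recording: the *accumulated
product* coincides with the open-system curve at **both** utilization
extremes (at $U\!\to\!0$ both give
$\delta_{\mathrm{source}}+\varepsilon$; at $U\!\to\!1$ mass balance forces
both onto $\delta_{\mathrm{source}}$), with the maximal divergence
mid-range. Tests assert exactly this geometry rather than a global
monotone divergence, which only the instantaneous product would show.

## Uncertainty

The paper-level inputs are marginal sigmas (measurement 0.03 ‰;
ε ± 0.1 ‰), with no stated propagation rule, so
`propagate_uncertainty()` treats $\delta$, $\varepsilon$ and
$\delta_{\mathrm{source}}$ as independent normals and offers two routes
that must agree: a first-order delta method,

$$\sigma_U^2 = \frac{\sigma_\delta^2 + \sigma_{\delta s}^2}{\varepsilon^2}
 + \left(\frac{\delta-\delta_s}{\varepsilon^2}\right)^2 \sigma_\varepsilon^2,$$

and a seeded Monte Carlo (the seed is a required argument: no silent global
RNG use). With measurement error alone, $\sigma_U = 0.03/1.2 = 0.025$,
i.e. 2.5 percentage points of utilization.

# Cryophilic mass balance

Diatoms growing inside sea-ice brine channels fractionate in a semi-closed
system and are isotopically heavier, but they are thinly silicified and
rarely preserved; in the assemblages this record represents they average
about 0.6 % of counted valves (max ≈ 2 %). `mixing_correct_delta()` inverts
the two-end-member balance
$\delta_{\mathrm{meas}} = p\,\delta_{\mathrm{cryo}} +
(1-p)\,\delta_{\mathrm{open}}$. The cryophilic end member has never been
measured here, so `cryophilic_sensitivity()` brackets it with a
configurable offset grid (default 0–2 ‰ *above* the measurement, the
physically motivated direction) rather than fixing a value. At $p = 0.006$
the worst-case shift over that whole grid is
0.006 × 2 / 0.994 ≈ 0.012 ‰ — under half the
analytical sigma, which is the quantitative content of "negligible
impact". The packaged taxonomy classifies the named cryophilic,
sea-ice-associated and open-water taxa and is overridable from a user CSV.

# Zonation

## CONISS

`coniss()` is agglomerative constrained clustering: only stratigraphically
adjacent blocks may fuse, and at each step the merger with the least
increase in pooled within-block sum of squares wins (incremental sum of
squares). The series is square-root transformed by default before the
euclidean sums of squares are formed — the standard variance-stabilizing
choice for proportion-like data; `transform = "none"` is available, and
the series clustered is the utilization record (clustering the raw
$\delta^{30}$Si instead is exposed via `run_pipeline(cluster_on =
"d30si")`). Ties between equal-increase mergers go to the
stratigraphically oldest pair, for determinism. The implementation keeps
running block sums (so a merge step is O(blocks)), and the test suite pins
every merge choice to an exhaustive oracle that recomputes all pooled sums
of squares from scratch for series of up to eight samples, plus a
conservation identity (increments sum to the total dispersion).

## How many zones are real?

The broken-stick null says: if a stick of unit length is broken at random
into $n$ pieces, the expected size of the $k$th-largest piece is
$\Pr(k) = \frac{1}{n}\sum_{i=k}^{n} \frac{1}{i}$.
`broken_stick_expected()` implements exactly this (for $n=2$: 0.75, 0.25).

Two conventions circulate for *using* it on a constrained dendrogram, and
the choice matters. Comparing each split's share of total dispersion
against the fixed-$n$ stick (with $n$ = number of samples) is
anti-conservative: in a simulation of 200 white-noise series of length 50,
the first split beat $\Pr(2) = (H_{50}-1)/50 \approx 0.07$ about 40 % of
the time — pure noise would routinely be declared structured. `silutil`
therefore uses the *successive-stick* rule: the split that creates the
$k$th zone is significant when its dispersion share exceeds the smallest
expected piece of a $k$-piece stick, $1/k^2$ (0.25 for the first split,
$1/9$ for the second, ...). Under the same simulation this rule returns a
single zone in ≈ 98–100 % of white-noise replicates while recovering the
true structure of two-regime records essentially always — the behaviour a
zonation null is supposed to have. `broken_stick_table()` reports both
columns (the fixed-$n$ expectations sum to one, as does the observed
column with the $k=1$ entry zero by convention); `n_significant_zones()`
is the largest zone count all of whose splits pass.

Per-zone summaries use type-7 quantiles (linear interpolation between
order statistics, R's default); since central values reported as
"$x=$" in the literature are ambiguous between mean and median, both are
returned. The between-zone comparison is a two-sided Mann–Whitney
rank-sum test — chosen to match median/IQR reporting — exact by
enumeration when both zones have ≤ 10 samples and tie-free, the
tie-corrected normal approximation otherwise. The long-term trend test is
OLS of value on age with the two-sided slope test; with ages in kyr BP,
a decline *toward the present* is a positive slope on age.

# Alignment

Covariates keep their native sampling; the isotope ages are the master
grid and are never resampled. `interpolate_to_ages()` is piecewise-linear
with exact pass-through and **no extrapolation** — out-of-span targets are
excluded and logged, never invented. The age-gap rule drops a target when
its distance to the nearest original observation of a covariate exceeds
the tolerance (default 50 years; ages are kyr internally and the tolerance
is converted once, 50 yr = 0.05 kyr). "Distance to the nearest
observation" is the default because it is the simplest reading and makes
the exclusion count monotone in the tolerance; the harsher
bracketing-distance variant is selectable (`gap_rule = "bracket"`). A row
is dropped when *any* non-exempt covariate over-gaps (the joint rule;
`joint = FALSE` blanks only the offending cell). Coarse-resolution series
such as a clay/silt westerly-wind proxy can be declared `exempt`: they are
interpolated without the gap rule — their resolution would otherwise
exclude nearly everything — and flagged, so their inclusion changes only
their own column, never row membership.

# Ordination

Before assuming linear methods, each per-zone matrix is screened with
detrended correspondence analysis (detrending by segments, rare-column
down-weighting — the classical defaults, since only the technique, not its
parameters, is conventionally reported): a first-axis gradient length
under 1.5 SD units indicates approximately linear responses. CA needs
non-negative input, so environmental columns are shifted by their column
minima (shifts logged); constant columns are dropped with a warning, and
a matrix of identical rows short-circuits to length 0 / linear. The screen
is followed by `pca_scaled()`: PCA of centered, unit-variance variables,
so eigenvalues sum to the number of variables and loadings are
correlation-scaled. Axis signs are made deterministic by forcing the
largest-magnitude loading of each axis positive. No multiple-testing
correction is applied anywhere; all P values are reported raw, and that is
stated rather than hidden.

The utilization–solar-irradiance regression uses `regress_adjusted_r2()`
(OLS, adjusted $R^2 = 1-(1-R^2)(n-1)/(n-2)$).

## Manual recipe: the early-Holocene irradiance regression

The published $n=5$ subzone regression (adjusted $R^2 = 0.91$, $P<0.01$)
needs two external inputs that cannot ship with a package: the study's own
supplementary utilization table and the composite total-solar-irradiance
reconstruction. To reproduce it: read both as CSVs
(`read_isotope_csv()` / `read_proxy_csv()`), convert with
`convert_utilization()`, align with `align_covariates(...,
tolerance_years = 50)` restricted to the 8.9–5.6 kyr subzone span, and
pass the five aligned pairs to `regress_adjusted_r2()`. The OLS machinery
itself is pinned to closed forms in the test suite.

# The synthetic generator

`generate_record()` emulates the statistical anatomy of a
Palmer-Deep-style multiproxy record so that every stage is testable
without any download:

* **ages** — a jittered regular grid (irregular but ordered sampling);
* **latent utilization** — regime means plus an AR(1) process
  (coefficient 0.3, stationary SD 0.03 as a fraction), clipped to
  (0.01, 0.99) with clips counted (`n_clipped`) rather than resampled;
* **isotopes** — the forward open-system model plus Gaussian measurement
  noise of 0.03 ‰ (the replicate reproducibility), so the
  noise-free values are guaranteed inside the admissible band;
* **covariates** — built conditionally on the latent (noise-free)
  utilization interpolated to their own grids, with regime-specific target
  correlations; conditioning on the latent signal makes the configured
  correlations structural rather than attenuated by measurement noise;
* **assemblage** — abundances with a lognormally jittered cryophilic
  fraction (mean 0.6 %, capped at 2 %).

One global seed derives per-stream child seeds
(`(seed*1009 + k*9973) mod (2^31-1)`), so adding a covariate never
perturbs the isotope stream, and the whole record is bit-reproducible.

`holocene_preset()` fixes the study conditions: 80 samples over
12.6–0.2 kyr BP, a regime boundary at 5.45 kyr (the midpoint of the
5.6–5.3 kyr zone gap), regime utilization means 0.483 (older) and 0.342
(younger) — the published zone medians — and four covariates: a sea-ice
taxon abundance (60-yr sampling), a same-sample $\delta^{18}$O series, a
coarse 400-yr clay/silt series exempt from the gap rule, and a dense
irradiance-like forcing. With these noise levels the two-zone structure
is recovered (boundary within ±2 samples, zone medians within ±2
percentage points) in ≥ 95 % of seeds, which is the regime the calibration
experiments in the test suite and `scripts/acceptance.R` operate in.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: secular trends and centennial excursions
inside regimes (real within-zone IQRs are several times wider than the
AR(1) envelope here), age-model uncertainty, abrupt single-sample events,
preservation changes, and any physically based ocean/sea-ice coupling
between the covariates beyond their prescribed correlations with
utilization. Parameter-recovery rates quoted anywhere in this package are
statements about this generative model, not about the sediment record.

# Numerical and degenerate-input policy

* Round trips (inversion ∘ forward model; mixing correction ∘ forward
  mixing) are exact to 1e−12 and tested as such.
* Out-of-band isotope values: error by default, clamp only on request,
  always with a warning.
* Zonation needs ≥ 3 samples; sqrt transform refuses negative values;
  unsorted or duplicate ages are rejected at construction with
  row-numbered messages.
* Empty zones, zero-variance regressors and constant series are explicit
  errors or warned degenerate returns (slope 0, p 1), never NaNs.
* Identical samples in the rank-sum test give p = 1 with a warning.
* Ordination refuses fewer than 3 rows; alignment warns when a zone
  retains fewer than 3 rows so the refusal is anticipated upstream.

# Problem sizes used in the shipped experiments

The test suite and acceptance script size their simulations to be decisive
yet quick: 10^6 points for the round-trip identity, 200 replicates for the
white-noise zonation null and for the CONISS-oracle sweep (n ≤ 8), 100
seeds for two-regime recovery at n = 80, 500 replicates for the trend-test
null calibration, and 10^4 samples for the AR(1) coefficient check. These
choices keep each property's Monte-Carlo error an order of magnitude below
the margin it is tested against.

# Known limitations

* The source composition is a scalar: no glacial Si(OH)~4~ end member, no
  spatial or temporal variation in $\delta^{30}\mathrm{Si(OH)_4}$ or
  $\varepsilon$. Where source waters changed, utilization changes are
  confounded with source changes and this package will not see it.
* The open-system model is steady state; transient bloom dynamics are
  outside its scope.
* CONISS here is the agglomerative variant only; divisive or optimal
  partitioning can place boundaries slightly differently on flat
  dispersion profiles.
* The broken-stick decision is a null-model heuristic, not a formal test
  with controlled error rates; treat `n_significant_zones()` as a
  screening device.
* DCA on environmental (shift-scaled) variables is a pragmatic screen
  inherited from palaeoecological practice, not a principled model for
  signed data; its gradient length should only ever gate the
  linear-vs-unimodal choice.
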