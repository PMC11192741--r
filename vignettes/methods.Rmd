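---
title: "Methods: isotope-tracer quantification of methane oxidation and methanotroph growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-tracer quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomox)
```

`isomox` quantifies microbial methane turnover in stratified water columns
from three kinds of raw data: incubation time series of isotope-tracer
observables, concentration–depth profiles, and nanoSIMS region-of-interest
(ROI) ion counts. This vignette is the package's account of the underlying
models, the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## Bulk rate estimation

All bulk rates derive from the slope of an ordinary least-squares
regression of an observable against incubation time. The linearity
assumption holds early in an incubation; by default only the **first five
sampling days** (`n_points = 5`, typically days 0–8 of a 0, 1, 2, 5, 8, 12
design) enter the fit, because tracer-product accumulation turns
exponential once the labeled community has grown appreciably. The day-12
sample is retained in the data but never fitted by default.

Significance is a one-sided *t*-test of slope > 0 at p < 0.05.
Non-significant rates are reported with `significant = FALSE`, never
dropped: a slow process estimated without confidence is still information.
Lag phases (a community adapting to bottle conditions before producing
tracer) are handled by explicit opt-in, `omit_lag_until`, which drops all
earlier samples before selecting points. There is deliberately no automatic
changepoint detection: whether a lag is real is a judgement made by the
analyst looking at the series, and an automated rule would hide that
judgement. Both variants (lag included/omitted) can be reported side by
side.

### Methane oxidation

The observable is the $^{13}\mathrm{CO_2}/\Sigma\mathrm{CO_2}$ ratio of
dissolved inorganic carbon. With DIC effectively constant over an
incubation (the CO₂ produced is small against a hard-water DIC pool),

$$MO = \frac{d}{dt}\!\left(\frac{^{13}CO_2}{\Sigma CO_2}\right)
  \times \frac{DIC}{F_{CH_4}} \quad [\mu M\ d^{-1}],$$

where $F_{CH_4}$ is the $^{13}$C atom fraction of the methane pool
(default 0.98; near-pure label). Whether to divide by $F$ at all is a
genuine choice — with >98% labeling it changes rates by <2% — and both
conventions are supported (`label_fraction = 1` disables it). The default
divides, because it makes the estimator the exact inverse of the generative
model and is the correct limit for partial labeling. DIC is assumed
constant per bottle; if measured per time point, the series should be
converted before fitting.

### Denitrification

The observable is accumulated $^{30}\mathrm{N_2}$ in the headspace,
referenced to the water volume. Two corrections apply.

**Headspace dilution.** Each sampling event withdraws `subsample_ml` of
headspace gas and replaces it with helium, diluting the accumulated tracer
by $(V_h - v_s)/V_h$ (default 27/30). Each measured point is multiplied by
the cumulative inverse factor over all sampling events after time zero and
before that point. This multiplicative cumulative form is a first-order
correction: it treats all tracer present at a point as having experienced
every prior dilution, which slightly over-weights gas produced late between
events. The exact inverse would require reconstructing per-interval
increments (and amplifies noise by differencing); at the default geometry
(10% dilution per event) the difference is well below measurement noise.
The package uses the multiplicative form consistently in both the
estimator and the generator, so noise-free round trips are exact. Water–gas
re-equilibration between events is ignored, consistent with N₂'s low
solubility.

**Isotope pairing.** Under random pairing of N atoms drawn from a nitrate
pool with $^{15}$N atom fraction $F$, the probability that both atoms of an
N₂ molecule are labeled is $F^2$, so

$$D_N = 2 \times \frac{d[^{30}N_2]}{dt} \times \frac{1}{F^2}
  \quad [\mu M\ N\ d^{-1}],$$

the factor 2 converting mol N₂ to mol N. $^{29}\mathrm{N_2}$, though
measurable, is never converted to a rate: single-labeled N₂ can arise from
N-transforming processes other than denitrification (e.g. anammox), so a
$^{29}$N₂-based rate would not be interpretable as denitrification. N₂O
observables are likewise outside the rate machinery: when produced N₂O is
consumed downstream, its accumulation slope has no rate interpretation.

### Methane-carbon assimilation

The observable is the excess $^{13}$C atom fraction of bulk biomass on a
filter, quantified by the filter's particulate organic carbon:

$$A = \frac{dE}{dt} \times \frac{POC_{\mu g}/M_C}{V_{filt}}
  \times \frac{1}{F_{CH_4}} \quad [\mu M\ C\ d^{-1}],$$

with $M_C = 12.011$ g mol⁻¹. The molar mass of *carbon* (not of the
$^{13}$C isotope, 13.003) is used throughout, because excess atom fraction
times total carbon measures the carbon newly built from methane, expressed
as carbon equivalents; the same constant reproduces the package's per-cell
reference rates. POC is assumed constant per bottle at the default; a
per-time-point POC series can be accommodated by pre-scaling.

### Derived statistics

The **assimilated fraction** $f = A/(A + MO)$ takes total methane
consumption as the sum of the two measured fates of methane carbon (CO₂
and biomass). It is bounded in [0, 1] and obeys the complement symmetry
$f(A, MO) + f(MO, A) = 1$. The **stoichiometric feasibility check**
computes the nitrate reduction a measured oxidation rate would require if
fully coupled to denitrification (5 CH₄ : 8 NO₃⁻, i.e.
$required_N = 1.6 \times MO$) and compares it with the measured
denitrification rate. It is a consistency bound, not an attribution:
heterotrophs contribute to denitrification too.

## Fickian fluxes

Vertical methane fluxes follow Fick's first law per depth zone,
$F = D\,dC/dz$, with a turbulent diffusion coefficient (default
0.27 cm² s⁻¹ = 2.3328 m² d⁻¹) replacing the molecular one because
water-column transport is dominated by internal currents. Zones are
**user-supplied breakpoints**: in practice they are chosen from visible
slope changes in the profile, and encoding that manual choice explicitly
(rather than auto-detecting breakpoints) keeps runs reproducible and
auditable. Per-zone gradients are OLS slopes over all points in the zone,
boundaries inclusive. Depth is positive downward, so a concentration
increasing with depth yields a positive gradient and a positive flux,
read as upward transport. The unit chain
(cm² s⁻¹ → m² d⁻¹, µM m⁻¹ = mmol m⁻⁴) is exact and tested as an identity.

## Single-cell quantification

Per-ROI ion counts are summed over all pixels and planes *before* any
ratio is formed. This count-weighted aggregation is what makes Poisson
statistics applicable: the ratio of two Poisson totals has relative error
$\sqrt{1/N_{minor} + 1/N_{major}}$, whereas averaging per-pixel ratios
would weight noisy pixels equally with clean ones.

ROIs are excluded when the relative Poisson error of **either** the
$^{13}C/(^{12}C+^{13}C)$ or the $^{12}C^{15}N/(^{12}C^{14}N+^{12}C^{15}N)$
ratio exceeds 5%. ROIs with a zero minor-isotope count have undefined
error and are flagged and excluded. Excess enrichment subtracts the mean
ratio of ≥3 background ROIs from the same field of view; if a FOV lacks
them, the canonical natural-abundance constants (1.1% for $^{13}$C, 0.36%
for $^{15}$N) are used with a warning and a provenance flag
(`background_source = "constant"`).

Biovolumes use three geometric models: spheres for cocci
($\pi d^3/6$), cylinders with hemispherical caps for rods
($\pi (d/2)^2 (l-d) + \pi d^3/6$, requiring $l \ge d$; at $l = d$ the rod
degenerates exactly to a sphere), and plain cylinders for filaments.
Carbon content follows the bacterioplankton allometry
$C_{fg} = 197 \times V^{0.46}$ — derived for smaller cells than the large
rods and filaments quantified here, but the only available prokaryote
model; the alternative (eukaryote-based) allometry would be less
appropriate. The per-cell assimilation rate is then
$C_{fg} \times E / 12.011 / t$ in fmol ¹³C cell⁻¹ d⁻¹.

### Growth rates and the effective label fraction

Under exponential growth on a substrate with effective labeling atom
fraction $A$, biomass enrichment approaches $A$ and the observed excess
$E$ after time $t$ implies

$$\mu = \frac{1}{t}\ln\frac{A}{A - E}.$$

$A$ is *effective*: it is reduced below the nominal labeling whenever
cells assimilate unlabeled carbon alongside methane, and it is rarely
known a priori. The package therefore ships a calibration helper that fits
$A$ by least squares to reference $(E, \mu)$ pairs
(`calibrate_label_fraction()`); `run_pipeline()` performs this calibration
at run time and records the fitted value in the report, explicitly as a
calibration rather than a known constant. The default without calibration
is $A = 1$. A linear-addition variant
($\mu = (E/A)/(1-E/A)/t$) is provided; both models share the small-label
limit $\mu \to E/(At)$ and the exponential estimate is never above the
linear one. Enrichment at or above $A$ signals label exhaustion and is an
error, not a rate.

CARD-FISH processing can isotopically dilute cell contents; no correction
is applied (none is quantifiable), so cross-morphotype comparisons between
FISH-stained cells and unstained filaments carry that caveat.

## Population accounting

Filter-count scaling divides counted cells by the screened area fraction
and filtered volume; coccus clusters contribute the sum of their member
counts. The filter/field geometry is explicit configuration (defaults: a
25-mm filter with ~21 mm effective diameter), since it is
instrument-specific. Biomass shares combine densities with the allometric
carbon contents and form a probability vector. Growth curves are
log-linear OLS fits; with two points this reduces to
$\mu = \ln(n_2/n_1)/\Delta t$. Poisson counting intervals for densities
are available conceptually but not asserted against any reference, since
per-morphotype count uncertainties are generally not reported.

## The synthetic-data generator

The generator emulates exactly the statistical structure the estimators
assume, which is what makes round-trip testing meaningful:

* **Incubation series**: linear product accumulation after an optional
  hard-changepoint lag (zero slope, then constant slope — the simplest
  shape consistent with an observed ~2-day adaptation), converted to each
  observable's scale, plus additive Gaussian noise. The hard changepoint
  and additive noise are modelling choices: real lags are smooth and real
  ratio noise is approximately, not exactly, Gaussian.
* **Headspace series**: the accumulated tracer is attenuated by the
  cumulative dilution factor of prior sampling events — the same model the
  estimator inverts, so noise-free recovery is exact to machine precision.
* **ROI tables**: minor and major isotope counts drawn as independent
  Poisson variates at expected total `mean_counts`, with the minor
  fraction equal to natural abundance plus the true excess (backgrounds:
  natural abundance only).
* **Depth profiles**: piecewise-linear interpolation between knots on a
  1-m grid, optional Gaussian noise, clipped at zero.

Default study conditions: 220 ml water under ~30 ml headspace, 3-ml gas
subsamples, sampling days 0, 1, 2, 5, 8, 12, $F_{CH_4} = 0.98$,
$F_{NO_3} = 0.5$, DIC 2500 µM (a typical deep hard-water hypolimnion),
POC 50 µg C per 10-ml filter. Noise defaults are stated configuration, not
literature values: 2×10⁻⁵ on the CO₂ ratio (bounded above by the
requirement that anoxic oxidation rates of ~0.06 µM d⁻¹ remain detectable
from five points over eight days, as observed), 0.002 µM on ³⁰N₂, 2×10⁻⁴
on biomass atom fraction.

What passing recovery tests does **not** show about real data: the
generator contains no instrument drift or dead-time effects, no DIC or POC
time dependence, no water–headspace re-equilibration, no smooth lag onset,
no hydrodynamics behind the profiles, and no correlated noise. Agreement
between estimator and generator demonstrates internal consistency and
correct arithmetic, not robustness to violations of the model.

## Numerical choices

* A regression is treated as *perfect* (noise-free fixture, constant
  series) when the residual scale falls below 10⁻¹⁰ of the data scale; the
  slope's sign at that precision then decides the one-sided p-value (0,
  0.5 or 1) rather than an unstable 0/0 t-statistic.
* R² is reported as `NA` for constant series (zero total variance).
* `calibrate_label_fraction()` optimises on
  $(\max E + 10^{-9},\, 1]$ with `stats::optimize` at tolerance 10⁻¹⁰; the
  lower bound keeps the log argument positive.
* Zone fits require ≥2 points (2 points give the exact finite-difference
  slope); rate fits require ≥3 points after lag omission.
* Seeds: one integer seed per generator call; `run_pipeline()` derives
  per-bottle/per-FOV streams as `seed + 7919 k` so bottles are independent
  but jointly reproducible, and the JSON report is byte-identical across
  runs of the same config and seed.

## Problem sizes used in the tests

The shipped test-suite uses scales chosen for tight statistical bounds at
desk-scale runtimes: 200 replicate bottles per recovery scenario (mean
bias < 5% of truth, ~95% nominal CI coverage checked against a 90% floor),
500 ROIs for enrichment recovery, and 10⁵ Monte-Carlo draws per count
level for validating the analytic Poisson ratio error within 10%.

## Known limitations

* All rates are potential rates from bottle incubations; bottle effects
  (trace-oxygen contamination, substrate amendments) are properties of the
  data, not correctable here.
* The flux module assumes steady state and a depth-independent effective
  diffusivity within each zone.
* The assimilated-fraction denominator counts only the two measured fates
  of methane carbon; excreted intermediates (e.g. fermentation products
  taken up by other organisms) blur the attribution, though not the total.
* The allometric carbon model is extrapolated for cells larger than its
  calibration range.
* Per-cell rates from bulk rates divide by one population's density and
  therefore attribute the whole bulk process to that population — an upper
  bound when several populations contribute.
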