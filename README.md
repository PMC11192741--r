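# isomox

Quantification chain for stable-isotope tracer studies of microbial methane
oxidation in stratified water columns — from raw incubation observables,
concentration–depth profiles and nanoSIMS ion counts to the volumetric
rates, fluxes and single-cell activities a limnological survey reports.

Aerobic methane-oxidizing bacteria (MOB) consume most of the methane
diffusing up through lake water columns, and they remain active even in
anoxic hypolimnia. Measuring *how* active requires a series of conversions
that are individually simple but easy to get subtly wrong: regression
slopes must be turned into rates with the right pool sizes and labeling
corrections, headspace gas series must be un-diluted, ion-count ratios must
be filtered by counting statistics, and biovolumes must be turned into
carbon before a per-cell rate means anything. `isomox` implements that
chain once, tested end to end, with a seeded synthetic-data generator so
every estimator can be validated by parameter recovery without instrument
data.

## The quantities computed

**Bulk tracer rates** (from incubation time series, OLS on the first five
sampling days):

- Methane oxidation: `MO = slope(¹³CO₂/ΣCO₂) × DIC / F_CH₄` (µM d⁻¹).
- Denitrification: `D_N = 2 × slope(³⁰N₂) / F_NO₃²` (µM N d⁻¹), after
  multiplying each point by the cumulative headspace-dilution factor
  `Π V_h/(V_h − v_s)` of prior sampling events. The `F²` term is the
  isotope-pairing assumption: both N atoms of a ³⁰N₂ molecule come from the
  ¹⁵N-labeled nitrate pool.
- Methane-carbon assimilation: `A = slope(excess ¹³C at-fraction) ×
  (POC/M_C)/V_filt / F_CH₄` (µM C d⁻¹).
- Assimilated fraction `A/(A + MO)` and the 5:8 CH₄:NO₃⁻ stoichiometric
  feasibility check for nitrate-supported methane oxidation.

**Fickian fluxes**: `F = D × dC/dz` per analyst-defined depth zone, with
`D` in cm² s⁻¹ (default 0.27, turbulent) and zone gradients fitted by OLS;
output in mmol m⁻² d⁻¹.

**Single-cell rates** (nanoSIMS ROI tables): isotope ratios
`¹³C/(¹²C+¹³C)` and `¹²C¹⁵N/(¹²C¹⁴N+¹²C¹⁵N)`, relative Poisson error
`√(1/N_minor + 1/N_major)` with a 5% exclusion cut, excess enrichment
against per-FOV backgrounds, biovolume from morphotype geometry, carbon
from the allometric model `C_fg = 197 × V^0.46`, and
`rate = C_fg × E / 12.011 / t` (fmol ¹³C cell⁻¹ d⁻¹). Growth rates use the
exponential labeling model `µ = ln(A/(A − E))/t` with the effective label
fraction `A` calibrated by least squares.

**Population accounting**: CARD-FISH filter counts to cells ml⁻¹, biomass
(µg C L⁻¹) and morphotype biomass shares, plus log-linear growth curves.

## Worked example

```r
library(isomox)

# a 135-m anoxic bottle: true oxidation rate 0.18 uM/d, realistic noise
tr <- sim_truth(seed = 7, true_rate = 0.18, noise_sd = 2e-5,
                label_fraction = 0.98, dic_uM = 2500)
s  <- gen_incubation_series(tr, observable = "co2_ratio")
ch4_oxidation_rate(s)
#> rate estimate: 0.169 +/- 0.0111 uM CH4 d-1 (one-sided p = 0.000307, n = 5)

# can measured denitrification support that oxidation at 5:8 stoichiometry?
stoichiometry_check(0.18, 0.41)$required_N   # 0.288 uM N/d -> feasible
#> [1] 0.288

# per-cell assimilation of a 55.3-um3 filament at 29 at.% excess 13C
cell_assimilation_rate(carbon_content(55.3), 0.29)
#> [1] 30.1258

# three-zone methane fluxes from a synthetic concave profile
prof <- gen_depth_profile(c(120, 135, 160, 180), c(0.02, 0.35, 10, 41))
zone_fluxes(prof, c(120, 135, 160, 180))$flux_mmol_m2_d
#> [1] 0.0513216 0.9004608 3.6158400
```

The fitted 0.169 ± 0.011 µM d⁻¹ is one noisy realisation of the 0.18 µM d⁻¹
truth (the estimator is unbiased; see the recovery tests). The flux table
shows the characteristic pattern of an anoxic methane sink: most of the
upward flux is consumed in the deepest zone, and almost none reaches the
oxic–anoxic interface.

A full synthetic survey — six incubations across three depths and two
oxygen conditions, fluxes, single-cell tables, population accounting — runs
with one call and is byte-reproducible per seed:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
res$rates[, c("depth_m", "condition", "mo_rate", "assim_fraction")]
```

A thin command-line wrapper with subcommands `simulate`, `rates`, `flux`,
`cells`, `counts` and `report` lives at `inst/cli/isomox.R`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the estimation
models, their assumptions, every tunable constant with units and defaults,
what the synthetic generator does and does not emulate, and the numerical
edge cases.
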