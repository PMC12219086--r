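---
title: "ENSO-driven aerobic habitat change: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ENSO-driven aerobic habitat change: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The south-eastern Pacific hosts one of the ocean's largest oxygen minimum
zones (OMZ). For water-breathing animals, whether a water parcel is
habitable depends on the balance between environmental oxygen supply —
best expressed as oxygen partial pressure, pO2 — and the temperature-driven
metabolic oxygen demand of the organism. The El Niño–Southern Oscillation
(ENSO) perturbs both sides of this balance at once: its warm phase warms
the upper ocean (raising demand) while oxygenating the upper OMZ (raising
supply), and its cold phase does the reverse. On top of this interannual
see-saw, secular warming and deoxygenation move the baseline.

`ensohab` implements the full chain from ensemble ocean fields to
habitat-change statistics:

1. detect and classify ENSO events from sea-surface temperature (SST);
2. map each event flavour's subsurface oxygen/temperature fingerprint by
   regression;
3. convert dissolved oxygen to pO2 and apply a physiological threshold;
4. measure habitat volumes and their changes, with bootstrap uncertainty,
   phase integrals, frequency weighting and climate-change attribution.

Because multi-terabyte Earth-system-model archives cannot ship with a
package, every stage is validated against a *synthetic ocean-ensemble
generator with known ground truth* — the generator is a first-class,
tested component, not a fixture.

# Models and procedures

## ENSO indices and event classification

Monthly anomalies are formed by removing the pooled monthly climatology
and, by default, the ensemble mean at each time step
(`compute_anomalies(mode = "ensemble_mean")`): in externally forced
ensembles this strips the forced signal — including secular trends —
exactly, isolating internal variability. A per-member regression on month
intercepts plus a linear trend (`"linear_detrend"`) is offered for
single-member records.

The Niño-3.4 index is the cosine-latitude-weighted SST anomaly over
5°S–5°N, 170°W–120°W, averaged October–February (ONDJF) and labelled by
the year of the January. Events are seasons at or above +1.5 reference
standard deviations (warm) or at or below −0.5 s.d. (cold); these
thresholds are the field's standard selection for extreme El Niño and
La Niña in large ensembles.

Eastern-Pacific (EP) and Central-Pacific (CP) flavours are separated with
the E and C indices: from the first two EOFs of tropical-Pacific
(120°E–290°E, 10°N–10°S) SST anomalies, with principal components
standardised to unit variance,

$$E = \frac{PC1 + PC2}{\sqrt 2},\qquad C = \frac{PC1 - PC2}{\sqrt 2}.$$

This is an exact orthogonal rotation, so $PC1^2 + PC2^2 = E^2 + C^2$
month by month. Two sign conventions make the decomposition unique: EOF1
is oriented so PC1 co-varies positively with Niño-3.4, and EOF2 so that
the E combination (not C) loads maximally in the far-eastern Pacific.
A warm event is classed `EP_EN` when its peak-season E is at least its C
(ties to EP — a measure-zero, deterministic choice), else `CP_EN`.

The *phase window* of an event — used for phase-integrated habitat change
— is the contiguous run of months around the January peak with
|standardised monthly Niño-3.4| above 0.5 s.d. The 0.5-s.d. value is a
package choice: the developing-phase threshold is not pinned down by the
literature this analysis follows, so it mirrors the La Niña detection
threshold.

## Teleconnection model

At every ocean cell the ENSO fingerprint is the bilinear regression

$$\mathrm{anom}(t) = \alpha\,E(t) + \beta\,C(t) + \varepsilon(t),$$

fitted by least squares on monthly anomalies pooled across members (no
intercept: anomalies and indices are centred by construction). Since E
and C are orthogonal, α and β equal the univariate projections; the code
still solves the full 2×2 normal equations so mildly correlated sample
indices are handled exactly, and refuses near-collinear indices with a
condition-number error. `fit_teleconnection()` returns a classed model
with `coef()`, `predict()`, `residuals()`, `simulate()`, `print()` and
`summary()` methods. pO2 is regressed directly (not reconstructed from
regressed O2), because the habitat threshold acts on pO2.

An ENSO-state field is reconstructed from a neutral climatology — the
ONDJF mean over a period's seasons and members — as
`field_neutral + alpha*E + beta*C`. Reconstructed pO2 is floored at zero
and the number of clipped cells recorded.

## Physiology: metabolic index and P_crit

Habitat suitability uses the metabolic index,

$$\Phi = A_0\, p\mathrm{O}_2\, B^n
  \exp\!\left[\frac{E_0}{k_B}\left(\frac1T - \frac1{T_{\rm ref}}\right)\right],$$

with hypoxia tolerance $A_0$ (atm$^{-1}$), temperature sensitivity $E_0$
(eV), Boltzmann constant $k_B = 8.617\times10^{-5}$ eV/K, body mass and
allometry $B = n = 1$, and $T_{\rm ref} = 15\,^\circ$C. Setting
$\Phi = 1$ gives the critical threshold

$$P_{\rm crit}(T) = \frac{1}{A_0}
  \exp\!\left[-\frac{E_0}{k_B}\left(\frac1T - \frac1{T_{\rm ref}}\right)\right],$$

so a cell is suitable exactly when $p\mathrm{O}_2 > P_{\rm crit}(T)$; the
two formulations are interchangeable and the tests exercise their
equality cell-wise. Three archetype species span the measured trait
distribution: `HHT` ($A_0 = 67$), `MHT` ($A_0 = 23$) and `LHT`
($A_0 = 10$ atm$^{-1}$), i.e. $P_{\rm crit}(T_{\rm ref})$ of about 1.5,
4.4 and 10.1 kPa (conventionally quoted as 1, 4 and 10 kPa), all with the
median $E_0 = 0.34$ eV; sweeps cover the measured span
$E_0 \in [-0.1, 0.9]$ eV.

Oxygen conversion uses the Garcia–Gordon (1992) solubility fit (Benson–
Krause coefficients) with the Weiss–Price (1980) vapour-pressure
correction:
$p\mathrm{O}_2 = (\mathrm{O}_2 / \mathrm{O}_{2,\rm sat}(T,S)) \cdot
0.20946 \cdot (1013.25 - p_{\rm H_2O})$ mbar. The upstream literature
cites but does not reproduce its conversion formula; this community-
standard choice is isolated behind `partial_pressure()`, and the pipeline
only requires a monotone, physically consistent map. No hydrostatic
pressure correction is applied at depth. The µmol/kg-vs-µmol/L density
distinction is ignored; fields are used self-consistently.

## Habitat geometry

The aerobic habitat volume $V_{P\mathrm{O2,crit}}$ is the summed volume
of suitable cells within the analysis domain (0–600 m, 5–50°S,
70–110°W), with cell volumes $R^2\cos\varphi\,\Delta\varphi\,
\Delta\lambda\,\Delta z$, $R = 6371$ km. Cells are counted whole — no
partial volume at the crossing depth — because the volume definition is
cell-based and partial volumes would be an uncontrolled refinement; the
crossing depth itself, $Z_{\rm crit}$, is reported separately by linear
interpolation of $p\mathrm{O}_2 - P_{\rm crit}$ between bracketing
levels. Suitability uses a strict inequality, so a cell exactly at
threshold is unsuitable (deterministic, measure-zero choice). A
pO2-surplus-weighted integral is available as
`habitat_volume(weight = "surplus")` for the alternative reading of the
volume definition; it is not the default. Habitat change between two
states is the signed difference (Eq. of state 2 minus state 1), which is
antisymmetric by construction.

## Event statistics

Composites of habitat change align events on their January peak. The
default composite is the "volume of the composite state": at each lag the
state is reconstructed from the event-averaged (E, C) and differenced
against the neutral volume. The alternative, the average of per-event
volume changes, is `mode = "event_mean"`; the two coincide whenever
thresholding is locally linear. Uncertainty follows the standard
bootstrap for large-ensemble composites: 10,000 resamples of half the
events, drawn with replacement, and the standard deviation across the
resampled composite means; it is applied to the per-event trajectories
(the only quantity the resampling operates on) and reproduces the
$s/\sqrt{n/2}$ law for i.i.d. values.

Phase-integrated change is the sum of monthly volume changes over the
event's phase window (month-weighted km³, reported as km³). Decadal
frequency is events per member-decade; multiplying the mean phase
integral of each type by its frequency gives the frequency-weighted
cumulative impact, the quantity on which cold events — individually
weaker but roughly three times more frequent and longer-lasting — can
overtake extreme warm events.

Driver decomposition substitutes counterfactuals: the volume change is
recomputed with only the pO2 anomaly, only the temperature anomaly, and
both; fractions are reported relative to the full change together with
the non-additive residual (the thresholding interaction term). The E0
sweep repeats this across the trait range and reports the crossover E0
where temperature overtakes oxygen in magnitude, if any.

Climate-change-versus-El-Niño attribution classifies every cell whose
suitability differs among historical-neutral, future-neutral and
future-El-Niño states into six sign combinations (++, +−, −+, −−,
CC-only, EN-only), and reports each class's changed volume as a fraction
of the total changed volume, so the six fractions sum to one.

# The synthetic generator: what it emulates and what it does not

`synthetic_config()` defines a complete test ocean; `generate_ensemble()`
builds fields as

$$\text{field} = \text{mean state} + \text{trend}(t)
 + \alpha\,E(t) + \beta\,C(t) + \text{noise},$$

and returns a truth object carrying the realised PCs, the planted event
calendar, the true coefficient fields and the trend coefficients.

**Tropical SST modes.** Two area-weighted-orthogonal patterns: a broad
eastern-Pacific Gaussian and a central-Pacific zonal dipole, oriented so
the E combination loads the far east — the same convention the EOF stage
applies, making the planted modes exactly the quantities the analysis
estimates. With this orientation the dipole's central extremum is
negative over part of the Niño-3.4 box, so warm seasons lean CP-ward,
reproducing the observed excess of CP over EP warm events.

**PC process.** The EP component is an AR(1) with state-dependent
persistence (0.90 warm, 0.94 cold — cold states linger, as La Niña does)
passed through the quadratic transform $x + \gamma(x^2 - 1)$,
$\gamma = 0.35$, which skews amplitudes toward strong warm extremes; the
CP component is a plain AR(1) (persistence 0.85). The simulated PCs are
then orthogonalised (centred, pooled) and unit-standardised: the EOF
stage returns strictly uncorrelated unit-variance PCs, so this makes the
planted coefficients identifiable rather than confounded with sampling
correlation between the modes. The generator parameters are free knobs —
the upstream literature motivates the asymmetries but prescribes no
stochastic process — chosen once to give ENSO-like decorrelation
(roughly a year), positive E-skewness, and the event ordering
EP < CP < LN under the standard thresholds.

**Mean state.** An exponential thermocline (4–18 °C over 0–600 m) and an
oxycline/OMZ profile: surface-saturated oxygen decaying into a subsurface
minimum centred near 220 m, strongest in the northern coastal quadrant,
recovering below; floored at 5 µmol/kg. The vertical grid is stretched
(finer near the surface), as in z-level ocean models, so the habitat
boundaries of all three trait archetypes are resolved.

**Teleconnections.** Gaussian coefficient fields: warming is surface-
intensified and coastally confined for E (the planetary-wave coastal
signature of extreme El Niño), broader for C; oxygenation peaks at the
upper oxycline (130 m) where warm-phase oxygenation is observed, with
peak amplitudes a_T = 1.5 °C, a_O2 = 8 µmol/kg per unit E and half that
per unit C. Oxygen coefficients are attenuated by
$\mathrm{O}_2/(\mathrm{O}_2 + 15)$ toward the anoxic core so planted
anomalies respect O2 ≥ 0 by construction instead of being truncated. The
defaults place the system in the regime the analysis targets: the oxygen
term dominates the habitat response at the median E0, warm events gain
habitat, cold events lose it, and temperature takes over for
low-tolerance species only at higher E0 (the sweep's crossover).

**Trends.** Surface warming is linear-plus-quadratic in time with the two
coefficients solved exactly so the 2006–2050 and 2050–2100 period means
exceed the 1920–2005 mean by +0.6 and +1.7 °C (a single linear rate
cannot satisfy both); it decays with depth (150 m scale). Oxygen trends
combine basin-wide deoxygenation (−0.08 µmol/kg/yr, 300 m scale) with a
coastal reoxygenation band (+0.2 µmol/kg/yr, centred 150 m) confined to
the easternmost longitudes — the coastal-confinement contrast the
attribution analysis exploits.

**Noise and SNR.** White noise per field, defaults sized so the SST
pattern-to-noise ratio is 5 (2.0 °C vs 0.4 °C), and likewise the peak
subsurface coefficients against their field noise.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: ocean dynamics (waves, advection, eddies),
seasonality of the mean state and of ENSO phase-locking beyond the
calendar bookkeeping, realistic coastlines or bathymetry, salinity
structure (constant 35 PSU; salinity only enters the gas conversion),
nonlinear or lagged teleconnections, and model biases of any real Earth
system model. Recovery tests demonstrate the *estimators* are correct and
well-calibrated under the planted statistical structure; they cannot
certify the structure itself matches any particular ocean.

# Numerical and design choices

- **Default fixture scale.** 5 members × 50 years at 4° and 10 stretched
  depth levels: every stage runs in seconds and the full suite in well
  under a minute, while leaving enough events (~5 EP, ~13 CP, ~75 LN) for
  composite statistics. The century-scale checks (warming levels,
  attribution) use 4 members × 181 years with 6 depth levels. Full-scale
  configurations (34 members, 1°) are reachable through the same
  configuration object.
- **Anomaly baseline.** Ensemble-mean subtraction is the default because
  it removes the forced trend exactly and leaves regression recovery
  unbiased (indices and fields undergo the same linear transform). The
  choice is not pinned by the upstream literature; both modes are
  exposed.
- **EOFs pooled across members** over the analysis period (not
  per-member): maximises degrees of freedom and matches the projection
  framing of the teleconnection estimate; the regression is likewise
  pooled.
- **Ties and degeneracies.** E = C classifies as EP; pO2 = P_crit is
  unsuitable; a non-crossing Z_crit column is `NA`; an empty event set
  returns an empty result, not an error; rank-deficient SST covariance
  and near-collinear indices raise errors naming the condition.
- **Determinism.** All randomness flows from explicit seeds
  (`config$seed`, bootstrap `seed`); identical configuration reproduces
  bit-identical ensembles, event sets and composites, and the NetCDF
  fixtures are byte-identical across rewrites.
- **Units.** Pressure values carry explicit units (atm/kPa/mbar, exact
  conversions); traits are in atm⁻¹ internally; pO2 fields are mbar.
  Masks computed in mbar and atm agree exactly (tested).
- **Period conventions.** HIST 1920–2005, BEG_21C 2006–2050, END_21C
  2050–2100; ONDJF seasons are labelled by their January; decades are
  (years)/10 per member. Frequency arithmetic in the upstream tables is
  not exactly reconstructible from the stated counts, so no constant was
  tuned to match it.

# Known limitations

- Whole-cell volume counting quantises habitat changes at coarse
  resolution; on the 4° fixture a single cell is thousands of km³, which
  makes small responses (and per-step E0-sweep monotonicity for
  mid-tolerance species) jumpy even when the underlying response is
  smooth.
- The composite-state and event-mean composite definitions differ
  wherever thresholding is strongly nonlinear; both are exposed, only the
  default is exercised by the acceptance checks.
- The bootstrap quantifies event-sampling spread only; it does not model
  member-level dependence of events drawn from the same realisation.
- Real-data ingestion is deliberately thin: CF-style NetCDF with the
  package's dimension layout, Kelvin and 0–360° longitude normalisation,
  and missing-value masking. It is not a general CF reader.
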