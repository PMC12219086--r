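# ensohab

Quantifying how the El Niño–Southern Oscillation (ENSO) reshapes
metabolically suitable aerobic habitat in the south-eastern Pacific
oxygen minimum zone — and how that reshaping interacts with long-term
warming and deoxygenation.

## Who this is for

Ocean biogeochemists and marine ecophysiologists working with ensemble
model output (or any gridded monthly T/S/O₂ + SST fields) who want a
tested, reproducible pipeline from raw fields to habitat-change
statistics, and a synthetic ocean ensemble with known ground truth to
validate every stage against.

## The science in brief

Whether a water parcel can sustain a water-breathing animal depends on
the ratio of oxygen supply to temperature-driven oxygen demand — the
metabolic index

Φ = A₀ · pO₂ · Bⁿ · exp[(E₀/k_B)(1/T − 1/T_ref)],

with hypoxia tolerance A₀ (atm⁻¹) and temperature sensitivity E₀ (eV).
Φ = 1 defines the critical oxygen pressure

P_crit(T) = (1/A₀) · exp[−(E₀/k_B)(1/T − 1/T_ref)],

and the aerobic habitat volume V is the volume of water with
pO₂ > P_crit(T). ENSO perturbs both sides of the balance: its flavours
are separated with the E/C indices, E = (PC1+PC2)/√2,
C = (PC1−PC2)/√2, from the first two EOFs of tropical-Pacific SST
anomalies; events are ONDJF Niño-3.4 seasons beyond +1.5 s.d. (El Niño,
split Eastern/Central-Pacific by E vs C) or −0.5 s.d. (La Niña). Each
cell's ENSO fingerprint is the bilinear regression
anomaly = α·E + β·C, from which ENSO states are reconstructed on top of
neutral climatologies and differenced as habitat-volume changes ΔV, with
10,000-sample half-size bootstrap uncertainty, phase-integrated and
frequency-weighted impacts, oxygen-vs-temperature driver decomposition,
E₀ sweeps, and six-way attribution of change to climate change vs
El Niño.

Three archetype species span the measured trait distribution: HHT
(A₀ = 67 atm⁻¹), MHT (23) and LHT (10) — P_crit at T_ref ≈ 1.5, 4.4 and
10.1 kPa — all with the median E₀ = 0.34 eV.

## Worked example

The whole pipeline on the default desk-scale synthetic study (5 members
× 50 years, 4° grid, 10 stretched depth levels; runs in seconds):

```r
library(ensohab)
cfg <- synthetic_config()            # seed = 1: fully reproducible
res <- run_pipeline(cfg, traits = c("HHT", "MHT", "LHT"), n_boot = 2000)
print(res)
```

```
ensohab_analysis
  config df3aa3a8 (seed 1), anomaly mode ensemble_mean

EP_EN CP_EN    LN
    5    13    74
  events/decade:  EP_EN=0.20, CP_EN=0.52, LN=2.96
  HHT.EP_EN    peak dV =  9.822e+04 +/- 2.61e+04 km^3 (n=5)
  HHT.CP_EN    peak dV =  2.235e+04 +/- 1.57e+04 km^3 (n=13)
  HHT.LN       peak dV = -1.168e+04 +/- 7.19e+03 km^3 (n=74)
  MHT.EP_EN    peak dV =  8.624e+04 +/- 1.56e+04 km^3 (n=5)
  MHT.CP_EN    peak dV =  8.762e+04 +/- 1.9e+04 km^3 (n=13)
  MHT.LN       peak dV = -9.239e+04 +/- 6.94e+03 km^3 (n=74)
  LHT.EP_EN    peak dV =  3.238e+04 +/- 1.09e+04 km^3 (n=5)
  LHT.CP_EN    peak dV =  4.638e+04 +/- 9.45e+03 km^3 (n=13)
  LHT.LN       peak dV = -2.039e+04 +/- 2.29e+03 km^3 (n=74)
```

Reading the output: the detector found 5 extreme Eastern-Pacific El
Niño, 13 Central-Pacific El Niño and 74 La Niña events (cold events
~15× more frequent than extreme EP warm events, as the skewed ENSO
process implies). For every tolerance archetype, El Niño composites
*gain* suitable habitat at the event peak (positive ΔV: oxygenation of
the upper OMZ outweighs the extra metabolic demand from warming) while
La Niña composites *lose* habitat; the ± values are bootstrap standard
deviations across event resamples. Summed over the three archetypes the
peak EP El Niño response is about twice the La Niña response — the
amplitude asymmetry of ENSO propagated into habitat space.

The physiological threshold behind those masks:

```r
tr <- physio_traits("MHT")
print(tr)
#> physio_traits [MHT]: A0 = 23 /atm, E0 = 0.34 eV, T_ref = 288.15 K
#>   P_crit at T_ref: 4.405 kPa
convert_pressure(pcrit(tr, 25), "kPa")   # warmer water demands more O2
#> 6.973452 kPa
```

Lower-level entry points (`compute_anomalies()`, `eof_ec_indices()`,
`detect_events()`, `fit_teleconnection()`, `neutral_climatology()`,
`reconstruct_enso_state()`, `habitat_volume()`, `zcrit()`,
`composite_delta_volume()`, `driver_decomposition()`,
`cc_en_fractions()`, …) expose every stage separately;
`write_fixture()` / `read_ocean_netcdf()` round-trip CF-style NetCDF.
See the methods vignette (`vignettes/ensohab-methods.Rmd`) for the
models, parameter choices and design rationale.

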