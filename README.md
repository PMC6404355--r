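# hepaZone

Quantitative modelling of zonal hepatotoxicity in a 3D hepatic zonation
channel.

## The problem

Hepatocytes are not interchangeable: drug-metabolising cytochrome P450
enzymes (CYP1A2, CYP2E1, CYP3A4) concentrate in the perivenous zone 3 of
the liver lobule, so bioactivated hepatotoxicants such as acetaminophen
(APAP) and bromobenzene injure zone 3 selectively, while drugs like
tamoxifen are toxic across the lobule. Conventional in-vitro hepatic
models are spatially homogeneous and cannot see this difference.

A 3D hepatic zonation channel reproduces the zonal microenvironment in a
dish: HepaRG cells are embedded in a 1% agarose hydrogel inside a 9 cm x
5 mm channel, a Wnt/β-catenin agonist (CHIR99021, "CHIR") diffuses in
from one end (Inlet 2) against plain medium at the other (Inlet 1), and
the resulting CHIR gradient programs a perivenous-like CYP expression
gradient along the channel. Slicing the channel into sections after drug
exposure turns a single tube into a spatially resolved hepatotoxicity
screen.

`hepaZone` implements the quantitative core of that workflow for R, for
toxicologists and bioengineers who want to design such channels, decode
their readouts, and classify drugs as zonal or non-zonal — plus a fully
seeded synthetic-data generator so the entire pipeline is testable
without a wet lab.

## What is implemented

**Gradient design** (`solveProfile`, `linearityMetric`,
`optimalLinearTime`, `invertEffectiveD`, `estimateDiffusionCoefficient`)
— 1D Fickian diffusion with fixed reservoirs,

    C(x,t) = c1 + (c2-c1) [ x/L + (2/π) Σ_n ((-1)^n/n) sin(nπx/L) exp(-n²π²Dt/L²) ],

solved both analytically and by explicit finite differences; tracer
scaling D_CHIR = D_RhB (Mw_RhB / Mw_CHIR)^(1/3); a tangent-based
linearity score θ (midpoint slope over end-to-end slope, θ = 1 for a
perfect line) used to pick the diffusion time, and its inversion for an
effective channel diffusivity.

**Dose-response** (`fit4PL`, `compareIC50`, `inductionCurve`,
`inductionAt`, `normalizeCypActivity`) — four-parameter-logistic fits
V(d) = bottom + (top-bottom)/(1+(d/IC50)^hill) with
heteroscedasticity-robust IC50 confidence intervals, a log-scale z-test
for CHIR-induced IC50 shifts, and the CHIR-to-CYP fold-induction
calibration (20-fold CYP1A2, 5-fold CYP2E1/CYP3A4 at 9 µM CHIR).

**Expression statistics** (`ddctFoldChange`, `degFilter`) — 2^-ΔΔCt qPCR
quantification against an 18S reference, and the microarray-style
differential-expression filter (|FC| ≥ 2, Welch P < 0.01, no
multiplicity correction).

**Imaging** (`extractAxialProfile`, `normalizeToSaturation`,
`damageFractionBySection`) — ChemiDoc-style axial intensity profiles
from masked channel scans, saturation-anchored normalization, and
per-section EthD-1/CellTracker membrane-damage fractions.

**Zonal screening** (`sectionChannel`, `localIC50`,
`predictViabilitySurface`, `fitZonalScreen`, `zonalityIndex`) — 6-section
channel slicing, log-linear local-IC50 interpolation along the gradient,
predicted section-by-dose viability surfaces, joint shared-shape
refitting of sectioned screens, and the zonality classifier
(index = log10 of the extreme-section IC50 ratio; a drug is zonal when
the shift is significant and at least 2-fold over the calibration span).

**Synthetic data** (`genDoseResponse`, `genZonalScreen`,
`genChannelImages`, `genQpcrCt`, `genExpressionMatrix`, `getPreset`) —
seeded generators calibrated to the published ground truths (IC50 table,
fold inductions), deterministic in (preset, arguments, seed).

## Worked example

```r
library(hepaZone)

# 1. How long until the CHIR gradient is linear?
dEff <- invertEffectiveD(days = 7, thetaTarget = 0.95)   # 1.25e-05 cm^2/s
res  <- optimalLinearTime(D = dEff, days = 1:15)
res$tStar / 86400                                        # 7 days

# 2. Does CHIR pretreatment sensitise cells to bromobenzene?
untr <- fit4PL(genDoseResponse("table1_bromobenzene", "untreated", seed = 1))
chir <- fit4PL(genDoseResponse("table1_bromobenzene", "CHIR_9uM",  seed = 1))
ic50(untr); ic50(chir)            # 12.4 uM vs 0.80 uM
compareIC50(untr, chir)$p         # 1.5e-119 -> significant shift

# 3. Screen a drug across the sectioned channel and classify it
scr <- genZonalScreen("table1_apap", seed = 1)
fit <- fitZonalScreen(scr$screen, scr$sections, drug = "APAP")
zonalityIndex(fit)
#> $zonality_index  0.307   (log10 IC50 ratio, section 1 vs 6)
#> $span_ratio      2.36    (rescaled to the 0-9 uM calibration span)
#> $shift_p         9.2e-83
#> $verdict         "zonal"

# 4. Decode a qPCR experiment
ct <- genQpcrCt("cyp1a2_chir9", seed = 1)
ddctFoldChange(ct, "CYP1A2")$fold # 22.5-fold (truth: 20-fold at 9 uM CHIR)
```

Numbers above are what the code prints at the given seeds: the APAP
screen is classified zonal because cells near the CHIR source (zone-3
analogue) are ~2.4x more sensitive, while the same pipeline calls
tamoxifen non-zonal; the qPCR decode recovers the calibrated 20-fold
CYP1A2 induction to within the generator's noise band.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the CYP induction Ct tables with the given seed and recomputes
the CYP1A2 and CYP2E1 fold inductions at 9 µM CHIR by the 2^-ΔΔCt
procedure, writing them as JSON.

## Layout

- `R/` — implementation (S4 classes `ConcentrationProfile`, `FourPLFit`,
  `ChannelImage`, `ZonalViabilitySurface`, `SyntheticPreset`, plus the
  module functions above)
- `src/` — the explicit finite-difference diffusion stepper (Rcpp)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/zonal-channel-methods.Rmd` — models, assumptions, numerical
  choices, limitations
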