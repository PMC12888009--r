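---
title: "Quantitative venomics, antivenomics and antivenom potency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative venomics, antivenomics and antivenom potency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtools)
```

# The problem

Venoms of the *Bothrops neuwiedi* species complex are mixtures of a
dozen toxin families — metalloproteinases (PI- and PIII-SVMP), two
phospholipase A~2~ classes (catalytically active D49 and myotoxic K49
homologues), serine proteinases, disintegrins, L-amino acid oxidase,
C-type lectin-like proteins, CRISP, and an endogenous 444.4 Da
tripeptide SVMP inhibitor (SVMPi). Three quantitative questions about
these venoms and the polyvalent F(ab')~2~ antivenom raised against
*Bothrops* venoms drive this package:

1. **Composition.** What fraction of a venom, by mass and by molecule
   count, does each toxin family contribute, and how do the clade's
   venoms partition into compositional patterns?
2. **Immunorecognition.** How much venom can a fixed amount of
   immobilized antivenom physically bind, toxin fraction by toxin
   fraction (third-generation antivenomics, 3GA)?
3. **Neutralization.** How much venom does the antivenom actually
   neutralize in vivo (probit ED50 and the derived potency), and how
   many vials does an average bite require?

# Composition: from peak areas to molecules

A family's relative abundance is the summed area of its RP-HPLC peaks
over the total area of all venom protein peaks, times 100 — a mass
percentage (g toxin / 100 g venom) because detection at 214–215 nm
tracks peptide-bond concentration. `integrate_peaks()` performs the
baseline-subtracted trapezoidal integration for synthetic or re-exported
traces; instrument software normally does this upstream, and
`relative_abundance()` accepts any peak table regardless of its origin.
Fractions containing several proteins are split first across SDS-PAGE
bands by densitometry share and then, within a band, in proportion to
each protein's three most abundant peptide-ion intensities
(`allocate_band_abundance()`); the operation conserves the fraction's
total abundance by construction.

Mass percentages weight large toxins heavily. Dividing by the family's
representative molecular mass converts to a *molar* percentage,

$$\mathrm{mmoles\,\%} = \frac{1000 \times \mathrm{mass\,\%}}{M\ (\mathrm{Da})},$$

in millimoles per 100 g venom (`mass_to_molar()`). The unit convention
"per 100 g venom" reproduces every published molar cell of the clade
table at 3 decimals, which is why the package adopts it; "per 100 g
protein" does not. The conversion matters scientifically: the tripeptide
inhibitor is 12.8% of *B. mattogrossensis* venom by mass but, at 444.4
Da, it is 89.8% of all tabulated venom molecules
(`molecule_fraction()`), and its molar ratio to the SVMPs it inhibits is
20.4 : 1 (`molar_ratio()`).

## Compositional patterns

The clade venoms fall into three patterns: (I) K49-dominant
phospholipase arm with low PIII-SVMP, (II) K49 absent with D49 dominant,
and (III) comparable K49 and D49. The published description is
qualitative, so `classify_dichotomy()` uses explicit configurable
thresholds: K49 below 0.05 mmoles % counts as absent (pattern II); a
K49/D49 molar ratio at or above 1.5 is pattern I; below 0.67 is pattern
II. In the intermediate band a ratio alone cannot separate patterns I
and III — *B. pauloensis* (ratio 1.24) belongs to pattern I while
*B. mattogrossensis* (ratio 1.17) is pattern III — so the defining
second axis of pattern I, low PIII-SVMP, breaks the tie: below 0.3
mmoles % of PIII-SVMP the venom is pattern I, otherwise III. With these
defaults all seven clade venoms classify as published. The thresholds
live in `venomics_config()$dichotomy`, not in code.

# Third-generation antivenomics

Each toxin fraction of a venom dose incubated on a column carrying 7 mg
of immobilized F(ab')~2~ splits into retained and nonretained material,
quantified by rechromatography:

$$\%R_i = 100\,\frac{R_i}{R_i + NR_i}, \qquad
\mathrm{captured}_i = \frac{\%R_i}{100}\times\frac{\%Tx_i}{100}\times
\mu g\ \mathrm{venom\ incubated}.$$

Nonspecific retention measured on mock/naive-IgG columns is subtracted
with a floor at zero (`control_correct()`); because the original
protocol leaves the correction arithmetic unstated, an uncorrected mode
is available (`apply_control = FALSE`) and both are reported in tests.

Captured mass grows with dose and saturates. Following the original
workflow the saturation maximum is estimated by a least-squares
degree-2 polynomial in dose (`fit_saturation()`), taking the parabola's
vertex value as the per-toxin maximum. Two guards keep the
extrapolation honest: the vertex is accepted only inside
$(0,\,2\times\mathrm{max\ dose}]$ — beyond that the curve has no data
support — and an upward-opening parabola means no saturation is evident;
in both cases the largest observed captured mass is reported and the
fraction is flagged unsaturated. The fit is to captured mass versus
dose (the quantity summed into the capacity), not to $\%R_i$ versus
dose; the alternative parameterization would require an extra conversion
step and the original figures do not adjudicate between the two.

The antivenom's **maximal binding capacity** is the sum of per-toxin
maxima over the antivenom on the column,
$\mathrm{MaxBind} = \sum_i \max_i(\mu g) / 7\,\mathrm{mg}$, numerically
mg venom per g antivenom. With the antivenom containing 46.45 g
F(ab')~2~ per litre (0.4645 g per 10 mL vial — the product sheet's
"46.45 mg/L" is inconsistent with the per-vial gram figure and with the
published per-mL column, so the g/L reading is adopted),
`capacity_units()` converts to mg venom per mL and per vial.

# Probit bioassays and the dosing chain

Quantal assays (deaths per dose group) are fitted by maximum-likelihood
binomial regression with a probit link on log10 dose — Finney's
classical analysis, fitted with `stats::glm`. The median dose is
$10^{-\beta_0/\beta_1}$ and its 95% CI comes from the delta method on
the log10 scale. No natural-response (Abbott) correction is applied:
control animals are untreated. Completely separated tables (a step
response with fewer than two partially-responding groups) have an
unbounded likelihood; `probit_fit()` then reports the geometric mean of
the doses bracketing the 50% response with `converged = FALSE` rather
than a spurious estimate.

The neutralization assay challenges mice with $n = 5$ LD50s premixed
with antivenom dilutions. At the ED50 endpoint one LD50 remains
unneutralized (it kills half the animals), so the potency — venom fully
neutralized per unit antivenom — is

$$P = \mathrm{ED}_{50}\times\frac{n-1}{n},$$

applied elementwise to the CI bounds. The ratio
$100 \times P/\mathrm{MaxBind}$ estimates the percentage of toxin-binding
antibodies that contribute to neutralization; values above 100% are
expected when neutralizing a toxin subset suffices to abrogate
lethality. Finally
$\mathrm{vials} = \mathrm{yield} / (P \times 0.4645\,\mathrm{g})$
turns a species' average venom yield into a dose estimate.

Unit computations for the enzymatic and local-damage assays follow
their published definitions: azocoll collagenolysis (1 U = 0.003
absorbance units at 540 nm; U/min/mg), PLA~2~ on 4-NOBA (0.01
absorbance units at 425 nm = 25.8 nmol chromophore; nmol/min/mg), edema
as percentage increase of paw thickness over the contralateral control,
and the minimum hemorrhagic dose as the dose giving a 1 cm² spot,
obtained by inverting a least-squares line of area on log10 dose
(hemorrhagic area is conventionally linear in log dose; with two points
this is log-linear interpolation).

# The synthetic-data generator

The measured inputs behind the wet-lab numbers (chromatograms,
immunocapture areas, per-animal deaths) live in supporting archives
that are not part of this package, so every estimator is validated on
synthetic data whose ground truth is known (`generator_config()` and
the `gen_*()` functions). The generators emulate the study designs:

- **Compositions** are drawn around the published species templates
  with multiplicative lognormal noise (CV 0.15, renormalized to the
  template total) and a correlation of −0.7 between the K49-PLA~2~ and
  PIII-SVMP log-perturbations, emulating the inverse relationship
  between the two classes.
- **Chromatograms** place one Gaussian peak per family along the
  qualitative elution order of the *Bothrops* venom pattern (tripeptide
  inhibitors first, PIII-SVMP last; exact minutes are evenly spread
  conventions and asserted nowhere), with peak area equal to the
  family's mass percentage.
- **Immunocapture series** follow per-toxin Langmuir isotherms on the
  seven-dose 100–3600 μg design. Defaults: total Bmax ≈ 650 μg on the
  7 mg column (MaxBind ≈ 93 mg/g, the *B. mattogrossensis* scale) split
  across toxins in proportion to their proteome shares, and
  half-saturation at 600 μg venom so the dose range visibly saturates
  while captured mass can never exceed the toxin amount incubated at
  the lowest dose. Retained/nonretained areas are back-computed so the
  3GA equations reproduce the Langmuir curve exactly at zero noise.
- **Lethality tables** draw Binomial deaths from
  $\Phi\!\big(b(\log_{10} d - \log_{10} m)\big)$ with default median
  50 μg and slope 4 on the six-dose 23–230 μg grid.
- **Hemorrhage tables** use a line of slope 0.8 cm² per log10 μg with
  the true MHD placed near 3 μg (the observed scale), reporting the
  mean spot area over a group of five animals per dose, as the assay
  defines it.

What the generators deliberately do **not** model: chromatographic
physics (tailing, co-elution), binding kinetics beyond the Langmuir
equilibrium, between-animal body-weight variation, and any systematic
(non-random) assay bias. Passing recovery tests therefore shows the
estimators are correct for data satisfying the stated models at
realistic noise, not that real instruments are free of artefacts.

# Numerical choices and validation problem sizes

- Published-table comparisons round half away from zero at the printed
  precision (`round_half_up()`); internal computation is always full
  precision.
- The quadratic saturation estimator is biased low on truly Langmuir
  data (a parabola cannot reach an asymptote): on noiseless default
  series it recovers ≈ 87% of the true total Bmax. The validation
  criterion is therefore 20% relative error on total Bmax, met in all
  200 seeded replicates at 3% multiplicative noise.
- Probit CI coverage is checked over 100 seeded tables of 6 doses × 10
  subjects (nominal 95%, required ≥ 90 hits); MHD recovery over 100
  seeded tables (within 10% of truth, required ≥ 90). These sizes make
  the full suite run in well under a minute while keeping the binomial
  sampling noise of the pass thresholds negligible.
- Degenerate inputs fail loudly: zero total peak area, zero
  denominators, separated dose tables, flat dose–response lines and
  rank-deficient regression designs all raise errors naming the
  problem, except where a documented fallback exists (separation →
  bracketing geometric mean; unsaturated series → observed maximum).

# Design notes

- The package is a library, not a shell tool: the analysis chains are
  exposed as functions (`run_chain_composition()`,
  `run_chain_antivenom()`) plus CSV readers/writers and a JSON config
  loader, which is how R users script such pipelines.
- The correlation/regression layer (`pearson()`, `ols_adj_r2()`,
  `mean_sd()`) wraps the base-R estimators with the validation and
  reporting shape the rest of the package uses. The published
  correlation coefficients for the functional data depend on
  individual-specimen values not reproduced here, so those operations
  are validated on synthetic and hand-computed cases instead.
- The species factor in `ols_adj_r2()` uses reference-level dummy
  coding with the alphabetically first level as reference; an
  interaction with the predictors is available by flag, the additive
  model being the default.

# Known limitations

Family-level quantification only (no isoform resolution); the
quadratic saturation model is an empirical description, not a binding
mechanism, and systematically underestimates a true Langmuir asymptote;
the probit CIs are asymptotic (delta method) and can undercover for
very steep or sparse designs; the MHD line is only locally linear in
log dose and should not be extrapolated far outside the assayed range.
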