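---
title: "Individualized CT dosimetry and cancer risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized CT dosimetry and cancer risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose)
```

## The problem

The effective dose of a CT examination is routinely estimated as
$ED_{DLP} = DLP \cdot k$, the scanner-reported dose–length product times a
population-averaged conversion factor ($k_{body} = 0.015$ mSv/(mGy·cm) for
whole-body acquisitions). This ignores everything individual about the
patient: body habitus, organ positions, missing or enlarged organs, contrast
uptake. `voxdose` implements the individualized alternative: a per-voxel
dose distribution over a segmented patient volume is aggregated into organ
doses, weighted into a whole-body effective dose, and converted into
age- and sex-specific lifetime cancer-mortality risk. The package also
implements the conventional method and the cohort statistics needed to
compare the two.

## The dose chain

For a voxel phantom (Hounsfield volume plus organ label map) the chain is:

1. **Transport** (`simulate_dose`): Monte Carlo photon transport produces a
   per-voxel *relative* dose, normalized so that the free-in-air air kerma
   at the isocenter equals 1.
2. **Air-kerma scaling** (`scale_to_absorbed`): multiplying by the scanner's
   air kerma $K_{air}$ (18.3 mGy for the reference acquisition) gives
   absorbed dose $D_v$ in mGy per voxel.
3. **Organ averaging** (`organ_mean_dose`): the absorbed organ dose
   $D_T$ is the arithmetic mean of $D_v$ over the organ's labelled voxels.
   Hollow organs are labelled on wall voxels only.
4. **Equivalent dose**: $H_T = w_R \cdot D_T$ with $w_R = 1$ for photons.
5. **Effective organ dose**: $ED_T = w_T \cdot H_T$ with the ICRP 103
   tissue weighting factors.
6. **Whole-body effective dose**: $ED_{MC} = \sum_T ED_T$ over the organs
   present; each organ's relative contribution is
   $C_T = ED_T / ED_{MC}$, and $\sum_T C_T = 1$ by construction
   (checked to $10^{-9}$).

Two deliberate conventions follow the reference analysis rather than the
letter of ICRP 103: each of the 13 individually segmented remainder tissues
carries its own $w_T = 0.0092$ (instead of a collective remainder dose), and
the thymus is not part of the remainder set. With these conventions the
female organ table has 26 entries and the male one 25; the female weights
sum to 0.990 and the male ones to 0.870, so $ED_{MC}$ is a per-organ sum,
not a renormalized average. Missing organs (aplasia, resection, or a
deliberately omitted class) contribute nothing and are reported as missing —
they are never imputed, because the individual-anatomy effect is precisely
what the method is for.

## The transport model

The proprietary simulation software used clinically is a black box; the
package therefore ships its own *simplified, verifiable* transport model and
validates it against closed forms rather than against clinical output:

* **Physics**: photoelectric absorption and incoherent (Klein–Nishina)
  Compton scatter only; no coherent scatter, no bound-electron corrections.
  The kerma approximation deposits the energy transferred to electrons at
  the interaction site (no secondary-electron transport), which is accurate
  at CT energies where electron ranges are below the voxel size.
* **Cross sections**: water, air and cortical-bone mass attenuation
  coefficients on a 10–150 keV grid with log-log interpolation. A voxel's
  linear attenuation follows the CT number definition
  $\mu = \mu_w(E)(1 + HU/1000)$ up to 100 HU, then a steeper bone segment
  calibrated so HU = 1400 reproduces the cortical-bone/water ratio. The
  Compton component scales with electron density (i.e. with mass density);
  the entire bone excess is assigned to the photoelectric channel, which
  matches its physical origin (higher effective atomic number). Voxel mass
  uses a matching two-segment density ramp.
* **Beam model**: a point source on a helix (pitch from the scan
  parameters) with a rectangular field through the rotation axis;
  monoenergetic 64 keV by default, standing in for a 120 kVp spectrum. The
  monoenergetic default keeps the analytic oracles exact; a 3-bin spectrum
  is available. No bowtie filter, no heel effect, no overranging (a single
  spiral covering the full phantom makes the latter negligible).
* **Tracking and scoring**: Woodcock (delta) tracking through the voxel
  grid. The dose map uses the expected-value collision estimator: at every
  (virtual or real) collision the score $E\,\mu_{tr}/\mu_{maj}$ is added to
  the voxel, whose expectation is the track-length integral of the
  energy-transfer coefficient. The `score_boost` option inflates the
  majorant to add scoring points without changing the transported physics.
  An analog tally of physically deposited energy is kept alongside for
  energy bookkeeping (deposited ≤ emitted, always). Per-voxel relative
  standard errors come from 10 batches.
* **Normalization**: for this source model the expected free-in-air fluence
  on the axis is $1/(2 Z w)$ per emitted photon ($Z$ the scan length, $w$
  the fan half-width), independent of collimation; multiplying by
  $E\,(\mu_{tr}/\rho)_{air}$ gives the per-history air kerma that defines
  relative dose 1.
* **Reproducibility**: each history owns a counter-based RNG stream derived
  from the seed, so runs are bitwise reproducible and a primary-only run is
  an exact prefix of the corresponding scatter-on run (hence scatter can
  only add deposition, deterministically).

**Verification.** On a voxelized water cylinder (radius 100 mm) the
primary-only axis dose has the closed form
$e^{-\mu R}\,(\mu_{tr}/\rho)_w / (\mu_{tr}/\rho)_{air}$ — every incoming
direction crosses exactly one radius of water. The simulator agrees with
this oracle within 3 Monte Carlo standard errors at $10^5$ histories, the
empirical error scales as $1/\sqrt{n}$ across $10^4$–$10^6$ histories, and
the residual systematic difference (about 1–3%, dominated by the voxelized
cylinder boundary, which itself accounts for ~0.8%) is well below the
statistical resolution of those checks. Absorption-only runs on homogeneous
cylinders are depth-monotone, and a pure-air phantom deposits nothing.

## The synthetic cohort generator

No imaging data accompany the reference analysis, so the package generates
its own study material. The generator's defaults *are* the study
conditions; they were fixed once, from the reference cohort's reported
demographics, and are not tuned per experiment:

* **Demographics**: 22.7% female; age 57.3 ± 14.3 years truncated to
  18–85; sex-specific BMI (female 21.2 ± 2.5, male 27.4 ± 5.9 kg/m²);
  heights 163/175 ± 7 cm. Weight is derived so BMI is exact.
* **Phantom**: stylized geometric anatomy — an elliptical body whose
  cross-section scales as $\sqrt{BMI}$, head-to-mid-femur extent at 0.68 of
  body height, and all 27 organ classes as ellipsoids, shells and tubes at
  anatomically inspired positions, with per-phantom geometric jitter and
  ±10% HU jitter around nominal tissue values. Contrast-enhanced kidneys
  and thyroid carry elevated HU so their high equivalent doses are
  reproducible. Hollow organs are wall-labelled; the skin is the outer
  rind; cortical bone encloses red marrow.
* **Tube current modulation**: expected effective mAs
  $= a\,e^{b(BMI - 26)}$ with $a = 100.5$, $b = 0.0354$, calibrated so the
  reference anchors (86 mAs at BMI 21.6, 165 mAs at BMI 40.0) are
  bracketed, with 4% lognormal noise. CTDIvol is proportional to effective
  mAs (least-squares constant 0.0713 mGy/mAs fitted to the packaged cohort;
  the cohort's own CTDI/mAs ratio is not constant and the residual is
  ~1.3 mGy, an acknowledged approximation). Scan length is 0.68 × height;
  DLP = CTDIvol × length.
* **Beam output calibration**: one global constant (1.168) anchors the
  simplified transport at the study scale — the reference anatomy (male,
  BMI 26, age 57) at 18.3 mGy air kerma yields the reference mean
  $ED_{MC}$ of 11.6 mSv. It absorbs what the mono-energetic, bowtie-free
  stand-in underestimates relative to the clinical beam, was chosen once as
  part of the generator design, and enters only the synthetic pipeline.
  Per-patient air kerma scales with effective mAs.

What the generator does **not** emulate: real anatomy (organ shapes,
positions and inter-patient correlations are stylized), polychromatic beam
hardening, scanner-specific modulation schemes, and contrast-phase timing.
Passing the end-to-end checks therefore demonstrates that the *pipeline*
reproduces the structural findings (BMI–DLP coupling, the sign pattern of
the conventional method's bias, conservation identities) — not that it
predicts any individual patient's dose.

## Conventional dosimetry and risk

$ED_{DLP} = DLP \times k_{body}$ with $k_{body} = 0.015$ mSv/(mGy·cm); the
individual conversion factor is $k_{MC} = ED_{MC}/DLP$; method deviations
are reported as $100\,(alt - ED_{DLP})/ED_{DLP}$.

Lifetime attributable risk of cancer mortality interpolates the packaged
BEIR VII coefficients (deaths per 100,000 persons exposed to 100 mGy,
tabulated by sex and age-at-exposure anchors):

$$LAR = \Big(N_y - (N_y - N_o)\,\frac{A_p - A_y}{A_o - A_y}\Big)\,
\frac{ED}{100\ \mathrm{mGy}}$$

linearly in age between the younger ($N_y$) and older ($N_o$) anchor cohort
and linearly in dose. Doses are accepted in mSv, numerically equal to mGy
for photons ($w_R = 1$). Design choices that the source material left open:

* **Coefficient variant**: the whole-body default is the *all-solid-cancer*
  mortality table. The reference cohort's own unrounded pairwise risk
  values (41.3, 27.1, 22.8, 25.1 per 100,000) pin this choice down —
  all-solid reproduces every cohort LAR within ±1 per 100,000, while adding
  leukemia overshoots systematically. Leukemia is available as a separate
  site.
* **Whole-body dose input**: $ED_{MC}$ (the per-site formula's organ dose
  symbol generalizes to the effective dose for the whole-body estimate, as
  the cohort table implies). Per-site risks use the organ's *equivalent*
  dose by default — the scale the coefficients refer to — with the
  effective organ dose available as an option.
* **Anchors and clamping**: anchors at 0, 5, 10, 15 then decennially to 80;
  ages outside the span are clamped to the nearest anchor with a warning
  (or rejected on request). Organs without a tabulated mortality site —
  including the male gonads — yield no per-site estimate rather than a
  guessed one.

Excess relative risk divides LAR by the sex-specific baseline lifetime
solid-cancer mortality (female 17,500, male 22,100 per 100,000), reported
in percent.

## Statistics

Cohort summaries use the sample SD ($n-1$); Bland–Altman agreement reports
the mean paired difference and 1.96-SD limits; rank correlations are
tie-corrected Spearman coefficients (average ranks) with an informational
two-sided t-approximation p-value; matched pairs are user-specified by
patient id, as in the reference analysis, with per-metric percent changes.

## Numerical conventions

Reporting uses half-away-from-zero rounding (`round_half_up`), the
convention of printed dose tables: doses at 1 decimal, conversion factors
at 3, LAR as integers, ERR at 2-decimal percent. All comparisons against
printed tables are made at the printed precision; where a printed cell
cannot be reproduced exactly from its *printed* (already rounded) inputs,
the check uses the uncertainty band those inputs propagate — the tightest
bound the printed table supports. Contribution sums are asserted to
$10^{-9}$; dose-linearity and anchor-endpoint identities are exact.

The shipped checks use problem sizes chosen to exercise the methods at
meaningful statistical resolution while staying lightweight: 64³ voxel
benchmarks, $10^4$–$10^6$ histories for convergence studies, and an
end-to-end synthetic study of 20 phantoms at 64³ with $2\times10^5$
histories each.

## Known limitations

* Tissue weighting factors are sex- and age-averaged (ICRP convention), so
  per-patient effective dose individualizes geometry and exposure, not
  radiosensitivity.
* The transport stand-in is monoenergetic and bowtie-free; absolute organ
  doses from the synthetic pipeline inherit the single global calibration
  rather than a full beam model.
* BEIR VII risk coefficients follow the linear no-threshold model;
  uncertainty intervals on LAR are out of scope, as are cancer *incidence*
  coefficients and competing-risk life tables.
* The stylized phantoms support method validation, not patient-specific
  prediction; real DICOM ingestion and automatic segmentation are out of
  scope.
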