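# voxdose

Individualized radiation dosimetry and cancer-risk estimation for helical
whole-body CT, in R.

The conversion factor method used in clinical routine — effective dose
`ED_DLP = DLP × k_body` with the population constant
`k_body = 0.015 mSv/(mGy·cm)` — cannot see the patient: habitus, organ
anatomy, contrast uptake and missing organs are all averaged away.
`voxdose` implements the individualized alternative for medical physicists
and dose-monitoring researchers: per-voxel Monte Carlo dose distributions
over segmented voxel phantoms, aggregated into organ and effective doses,
and converted into per-patient cancer-mortality risk, alongside the
conventional method and the cohort statistics needed to compare them.

## The model

For each segmented organ *T* with mean absorbed dose *D_T* (mGy):

    H_T    = w_R · D_T            (equivalent dose; w_R = 1 for photons)
    ED_T   = w_T · H_T            (ICRP 103 tissue weighting)
    ED_MC  = Σ_T ED_T             (whole-body effective dose, mSv)
    C_T    = ED_T / ED_MC         (organ contribution, Σ C_T = 1)
    k_MC   = ED_MC / DLP          (individual conversion factor)

Absorbed doses come from a simplified helical-CT photon transport
(photoelectric + Klein–Nishina Compton, kerma approximation, Woodcock
tracking, expected-value collision estimator), normalized to free-in-air
air kerma at the isocenter and scaled by the scanner air kerma. Lifetime
attributable risk of cancer mortality interpolates BEIR VII coefficients
*N* (deaths per 100,000 per 100 mGy, by sex and age-at-exposure anchors):

    LAR = (N_y − (N_y − N_o) · (A_p − A_y)/(A_o − A_y)) · ED / 100 mGy
    ERR = LAR / baseline          (baseline lifetime solid-cancer mortality:
                                   17,500 ♀ / 22,100 ♂ per 100,000)

A synthetic-cohort module generates voxel phantoms, demographics and
scanner reports (tube-current modulation coupling effective mAs to BMI)
with the statistical structure of a 22-patient whole-body PET-CT reference
cohort, whose printed table ships as a package fixture.

## Worked example

```r
library(voxdose)

patient <- patient_record("P-example", age = 44, sex = "female",
                          height = 166, weight = 62)
phantom <- generate_phantom(patient, resolution = 64, seed = 20)
report  <- emulate_scanner_report(patient, seed = 20)   # eff mAs 93, DLP 749

map <- simulate_dose(phantom, scan_parameters(),
                     transport_config(n_histories = 2e5, rng_seed = 20))
map <- scale_to_absorbed(map, 18.3)                     # air kerma, mGy

organs <- organ_dose_table(map, phantom$labels, "female")
head(organs[order(-organs$effective_dose),
            c("organ", "absorbed_dose", "effective_dose", "contribution")], 5)
#>      organ absorbed_dose effective_dose contribution
#> 5   breast          16.7          2.000       0.1575
#> 3     lung          15.0          1.802       0.1419
#> 4  stomach          11.5          1.383       0.1089
#> 2    colon          10.9          1.312       0.1033
#> 10 thyroid          24.9          0.998       0.0786

ed_mc <- total_effective_dose(organs)
round_half_up(ed_mc, 1)                           #> 12.7   mSv (individual)
round_half_up(ed_dlp(report$dlp), 1)              #> 11.2   mSv (conventional)
round_half_up(k_mc(ed_mc, report$dlp), 3)         #> 0.017  mSv/(mGy·cm)

l <- lar(patient$age, patient$sex, ed_mc)
round_half_up(l)                                  #> 62     per 100,000
round_half_up(err(l, "female"), 2)                #> 0.36   %
```

The individualized estimate exceeds the conventional one for this
normal-weight woman (12.7 vs 11.2 mSv) — the conventional method
systematically underestimates dose in lean and female patients — and her
age and sex put the lifetime attributable risk of cancer mortality at 62
per 100,000 (0.36% of the female baseline).

Cohort-level comparisons work on any cohort table, including the packaged
reference fixture:

```r
tab <- load_cohort_table()
bland_altman(tab$ed_mc, tab$ed_dlp)$mean_difference  #> -1.65  (−1.7 mSv at 1 dp)
spearman_cor(tab$bmi, tab$ed_dlp)                    #> 0.951
k_within_band(k_mc(tab$ed_mc, tab$dlp))              #> 6 patients within ±10% of k_body
```

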