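#' Organ vocabulary for voxel phantoms
#'
#' The 27 radiosensitive organs and tissues tracked by the dosimetry chain,
#' with their integer label codes, sex restriction, hollow-organ flag (hollow
#' organs are segmented on wall voxels only) and nominal Hounsfield value used
#' by the synthetic phantom generator. Kidneys and thyroid carry elevated HU
#' to emulate contrast-medium uptake.
#'
#' @return A data.frame with columns `organ`, `label`, `sex`
#'   (`"both"`, `"female"`, `"male"`), `hollow`, `hu_nominal`, `tissue_group`.
#' @export
organ_vocabulary <- function() {
  vocab <- data.frame(
    organ = c(
      "red_bone_marrow", "colon", "lung", "stomach", "breast", "gonads",
      "bladder", "liver", "esophagus", "thyroid", "skin", "bone_surface",
      "salivary_glands", "brain", "spleen", "kidney", "heart", "pancreas",
      "oral_mucosa", "lymph_nodes", "muscle", "small_intestine",
      "gall_bladder", "adrenal_gland", "prostate", "uterus", "et_region"
    ),
    label = 1:27,
    sex = "both",
    hollow = FALSE,
    hu_nominal = c(
      80, 30, -750, 40, -20, 35,
      30, 90, 40, 300, 20, 1000,
      45, 35, 80, 180, 45, 45,
      40, 40, 50, 35,
      25, 30, 40, 45, 30
    ),
    stringsAsFactors = FALSE
  )
  vocab$sex[vocab$organ %in% c("breast", "uterus")] <- "female"
  vocab$sex[vocab$organ == "prostate"] <- "male"
  vocab$hollow[vocab$organ %in% c(
    "colon", "stomach", "bladder", "esophagus", "heart",
    "small_intestine", "gall_bladder", "et_region"
  )] <- TRUE
  vocab$tissue_group <- ifelse(vocab$label <= 14, "main", "remainder")
  vocab
}

#' ICRP 103 tissue weighting factors
#'
#' Per-organ tissue weighting factors W_T as used throughout the package:
#' 0.12 for red bone marrow, colon, lung, stomach and breast; 0.08 for the
#' gonads; 0.04 for bladder, liver, esophagus and thyroid; 0.01 for skin,
#' bone surface, salivary glands and brain; and a per-organ 0.0092 for each
#' of the 13 remainder tissues (the collective ICRP remainder weight spread
#' over the individually segmented remainder organs). Sex-conditional organs
#' are included only for the matching sex (26 entries for a female table,
#' 25 for a male one).
#'
#' @param sex `"female"` or `"male"`.
#' @return A list with elements `w_r` (radiation weighting factor for
#'   photons, always 1) and `w_t` (named numeric vector of tissue weights).
#' @export
icrp_weights <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  vocab <- organ_vocabulary()
  vocab <- vocab[vocab$sex %in% c("both", sex), ]
  wt <- numeric(nrow(vocab))
  wt[vocab$organ %in% c("red_bone_marrow", "colon", "lung", "stomach", "breast")] <- 0.12
  wt[vocab$organ == "gonads"] <- 0.08
  wt[vocab$organ %in% c("bladder", "liver", "esophagus", "thyroid")] <- 0.04
  wt[vocab$organ %in% c("skin", "bone_surface", "salivary_glands", "brain")] <- 0.01
  wt[vocab$tissue_group == "remainder"] <- 0.0092
  names(wt) <- vocab$organ
  list(w_r = 1, w_t = wt)
}

#' Baseline lifetime solid-cancer mortality
#'
#' United States baseline lifetime solid-cancer mortality per 100,000
#' persons, used as the denominator of the excess relative risk.
#'
#' @return Named numeric vector `c(female = 17500, male = 22100)`.
#' @export
baseline_mortality <- function() {
  c(female = 17500, male = 22100)
}

#' Reference per-organ dose table
#'
#' Packaged reference table of cohort-mean equivalent organ dose, tissue
#' weighting factor, effective organ dose by sex, relative contribution to
#' whole-body effective dose and site-specific lifetime attributable risk for
#' the 22-patient whole-body PET-CT reference cohort.
#'
#' @return A data.frame, one row per organ.
#' @export
organ_dose_reference <- function() {
  path <- system.file("extdata", "organ_dose_reference.csv", package = "voxdose")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' BEIR VII lifetime-attributable-risk coefficients
#'
#' Packaged grid of lifetime attributable risk of cancer mortality per
#' 100,000 persons exposed to 100 mGy, by sex, age at exposure and cancer
#' site, transcribed from the BEIR VII mortality tables. `"all_solid"` is the
#' whole-body default used for the study-level LAR.
#'
#' @param site Optional cancer site to filter on (e.g. `"all_solid"`,
#'   `"lung"`, `"breast"`, `"leukemia"`). `NULL` returns the full table.
#' @return A data.frame with columns `sex`, `age_anchor`, `site`,
#'   `n_per_100k_at_100mgy`, `source_label`.
#' @export
risk_coefficients <- function(site = NULL) {
  path <- system.file("extdata", "beir_vii_mortality.csv", package = "voxdose")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(site)) {
    if (!site %in% tab$site) {
      stop("unknown cancer site: ", site)
    }
    tab <- tab[tab$site == site, ]
  }
  tab
}

# Mapping from phantom organs to BEIR VII mortality sites. Organs without a
# site (and male gonads, for which BEIR VII tabulates no mortality site)
# yield no per-site estimate.
organ_site_map <- function(sex) {
  map <- c(
    colon = "colon", lung = "lung", stomach = "stomach", breast = "breast",
    bladder = "bladder", liver = "liver", prostate = "prostate",
    uterus = "uterus", red_bone_marrow = "leukemia"
  )
  if (identical(sex, "female")) {
    map <- c(map, gonads = "ovary")
  }
  map
}

#' Half-up decimal rounding for report output
#'
#' Rounds half away from zero, the convention of printed dose tables (R's
#' `round()` is half-even). Used at the reporting layer for doses (1
#' decimal), conversion factors (3 decimals), LAR (integer) and ERR (2
#' decimals).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
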