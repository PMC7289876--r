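#' Cohort distribution parameters for the synthetic patient generator
#'
#' Defaults emulate the demographics of the reference whole-body PET-CT
#' cohort: 22.7% female, age 57.3 +/- 14.3 years, sex-specific BMI
#' (female 21.2 +/- 2.5, male 27.4 +/- 5.9 kg/m^2), with truncation to
#' plausible adult ranges.
#'
#' @param female_fraction Probability that a generated patient is female.
#' @param age_mean,age_sd Mean and SD of age in years (truncated normal).
#' @param age_range Closed interval of admissible ages.
#' @param bmi_mean,bmi_sd Named vectors (`female`, `male`) of BMI moments.
#' @param bmi_range Closed interval of admissible BMI.
#' @param height_mean,height_sd Named vectors (`female`, `male`), cm.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(female_fraction = 5 / 22,
                        age_mean = 57.3, age_sd = 14.3,
                        age_range = c(18, 85),
                        bmi_mean = c(female = 21.2, male = 27.4),
                        bmi_sd = c(female = 2.5, male = 5.9),
                        bmi_range = c(16, 45),
                        height_mean = c(female = 163, male = 175),
                        height_sd = c(female = 7, male = 7)) {
  spec <- list(
    female_fraction = female_fraction,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
    height_mean = height_mean, height_sd = height_sd
  )
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must lie in [0, 1]")
  }
  if (age_sd <= 0 || any(c(bmi_sd, height_sd) <= 0)) {
    stop("distribution standard deviations must be positive")
  }
  if (diff(age_range) <= 0 || diff(bmi_range) <= 0 || age_range[1] <= 0) {
    stop("invalid (non-positive) parameter range")
  }
  class(spec) <- "cohort_spec"
  spec
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are deterministic without
# disturbing global state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rtrunc_norm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < range[1] | x > range[2])
  }
  x
}

#' Generate a synthetic patient record
#'
#' Draws sex, age, height and BMI from the cohort distribution and derives
#' weight so that BMI = weight / (height/100)^2 holds exactly.
#'
#' @param seed Integer seed; identical seeds yield identical records.
#' @param spec A [cohort_spec()].
#' @param id Patient identifier label.
#' @return A list of class `patient_record` with fields `id`, `age` (years),
#'   `sex`, `height` (cm), `weight` (kg), `bmi` (kg/m^2).
#' @export
generate_patient <- function(seed, spec = cohort_spec(), id = sprintf("S%04d", seed %% 10000L)) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    sex <- if (stats::runif(1) < spec$female_fraction) "female" else "male"
    age <- rtrunc_norm(1, spec$age_mean, spec$age_sd, spec$age_range)
    bmi <- rtrunc_norm(1, spec$bmi_mean[[sex]], spec$bmi_sd[[sex]], spec$bmi_range)
    height <- rtrunc_norm(1, spec$height_mean[[sex]], spec$height_sd[[sex]], c(145, 205))
    patient_record(
      id = id, age = round(age, 1), sex = sex,
      height = round(height, 1),
      weight = round(bmi * (height / 100)^2, 1)
    )
  })
}

#' Construct and validate a patient record
#'
#' @param id Label. @param age Years. @param sex `"female"`/`"male"`.
#' @param height cm. @param weight kg.
#' @param bmi kg/m^2; derived from height and weight when omitted.
#' @return A `patient_record` list.
#' @export
patient_record <- function(id, age, sex, height = NA_real_, weight = NA_real_,
                           bmi = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.finite(age) || age <= 0) stop("age must be positive")
  derived <- if (is.finite(height) && is.finite(weight)) weight / (height / 100)^2 else NA_real_
  if (is.null(bmi)) bmi <- derived
  if (is.finite(bmi) && is.finite(derived) && abs(bmi - derived) > 0.5) {
    stop("bmi inconsistent with height and weight (difference > 0.5 kg/m^2)")
  }
  structure(
    list(id = id, age = age, sex = sex, height = height, weight = weight,
         bmi = bmi),
    class = "patient_record"
  )
}

#' Helical scan acquisition parameters
#'
#' Defaults follow the reference acquisition: 120 kV tube voltage, reference
#' tube-current-time product 170 mAs with anatomic tube current modulation,
#' pitch 0.8, 0.5 s rotation time, 19.2 mm collimated beam width and a
#' free-in-air air kerma of 18.3 mGy at the isocenter.
#'
#' @param tube_voltage kV. @param reference_mas mAs. @param effective_mas mAs.
#' @param pitch Dimensionless table feed per rotation / beam width.
#' @param rotation_time s. @param collimation mm beam width at isocenter.
#' @param scan_length cm. @param air_kerma mGy free-in-air at isocenter.
#' @return A list of class `scan_parameters`.
#' @export
scan_parameters <- function(tube_voltage = 120, reference_mas = 170,
                            effective_mas = 100, pitch = 0.8,
                            rotation_time = 0.5, collimation = 19.2,
                            scan_length = 110, air_kerma = 18.3) {
  vals <- c(tube_voltage, reference_mas, effective_mas, pitch,
            rotation_time, collimation, scan_length, air_kerma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scan parameters must be positive")
  }
  structure(
    list(tube_voltage = tube_voltage, reference_mas = reference_mas,
         effective_mas = effective_mas, pitch = pitch,
         rotation_time = rotation_time, collimation = collimation,
         scan_length = scan_length, air_kerma = air_kerma),
    class = "scan_parameters"
  )
}

# Tube-current-modulation anchors: effective mAs grows exponentially with
# BMI, calibrated so BMI 21.6 -> ~86 mAs and BMI 40.0 -> ~165 mAs bracket the
# reference cohort. CTDIvol is proportional to effective mAs at 120 kV with a
# least-squares constant fitted to the packaged cohort table.
.tcm_a <- 100.5       # effective mAs at the BMI0 reference
.tcm_b <- 0.0354      # per kg/m^2 exponential slope
.tcm_bmi0 <- 26       # cohort-mean BMI reference point
.ctdi_per_mas <- 0.0713  # mGy per effective mAs at 120 kV (fixture LS fit)
.scan_length_frac <- 0.68  # head to mid-femur as a fraction of body height

#' Emulate the scanner dose report for a patient
#'
#' Models anatomic tube current modulation: expected effective mAs is a
#' monotone (exponential) function of BMI with multiplicative lognormal
#' noise; CTDIvol is proportional to effective mAs at fixed tube voltage; the
#' scan covers head to mid-femur so scan length derives from body height; and
#' DLP = CTDIvol x scan length.
#'
#' @param patient A `patient_record` (BMI must be present).
#' @param scan A [scan_parameters()] object.
#' @param seed Integer seed for the modulation noise.
#' @param noise_sd SD of log effective mAs (0 disables noise).
#' @return A list of class `scanner_report` with `ctdi_vol` (mGy), `dlp`
#'   (mGy cm), `effective_mas` (mAs) and `scan_length` (cm).
#' @export
emulate_scanner_report <- function(patient, scan = scan_parameters(), seed = 1L,
                                   noise_sd = 0.04) {
  stopifnot(inherits(patient, "patient_record"))
  if (!is.finite(patient$bmi)) stop("patient BMI is required")
  with_seed(seed, {
    mas <- .tcm_a * exp(.tcm_b * (patient$bmi - .tcm_bmi0))
    if (noise_sd > 0) mas <- mas * exp(stats::rnorm(1, 0, noise_sd))
    length_cm <- if (is.finite(patient$height)) {
      .scan_length_frac * patient$height
    } else {
      scan$scan_length
    }
    ctdi <- .ctdi_per_mas * mas * (scan$tube_voltage / 120)^2
    structure(
      list(
        ctdi_vol = round(ctdi, 2),
        dlp = round(ctdi * length_cm),
        effective_mas = round(mas),
        scan_length = round(length_cm, 1)
      ),
      class = "scanner_report"
    )
  })
}

#' Load a cohort table from CSV
#'
#' Reads a per-patient cohort table (one row per patient) with the documented
#' schema: `id`, `age`, `sex`, `weight`, `bmi`, `dlp`, `ctdi_vol`, `eff_mas`,
#' and optional dose columns `ed_dlp`, `ed_nci`, `ed_mc`, `dev_nci_vs_dlp`,
#' `dev_mc_vs_dlp`, `k_mc`, `lar`, `err`. Rows with non-positive DLP or
#' negative doses are rejected with their row index.
#'
#' @param path CSV file path; defaults to the packaged 22-patient reference
#'   cohort.
#' @return A data.frame (possibly with zero rows for an empty file).
#' @export
load_cohort_table <- function(path = system.file("extdata", "wholebody_cohort.csv",
                                                 package = "voxdose")) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame())
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(tab)
  required <- c("age", "sex", "dlp")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(tab$sex %in% c("female", "male"))) {
    bad <- which(!tab$sex %in% c("female", "male"))
    stop("row ", bad[1], ": sex must be 'female' or 'male'")
  }
  bad <- which(!is.finite(tab$dlp) | tab$dlp <= 0)
  if (length(bad)) stop("row ", bad[1], ": DLP must be positive")
  for (col in intersect(c("ed_dlp", "ed_nci", "ed_mc"), names(tab))) {
    bad <- which(!is.na(tab[[col]]) & tab[[col]] < 0)
    if (length(bad)) stop("row ", bad[1], ": negative dose in column ", col)
  }
  bad <- which(!is.finite(tab$age) | tab$age <= 0)
  if (length(bad)) stop("row ", bad[1], ": age must be positive")
  tab
}

#' Load a study configuration from JSON or YAML
#'
#' Reads a configuration file holding any of `cohort` (arguments to
#' [cohort_spec()]), `scan` (arguments to [scan_parameters()]) and `seed`,
#' and returns the constructed objects with defaults filled in.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `cohort` (a `cohort_spec`), `scan`
#'   (a `scan_parameters`) and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort_args <- raw$cohort %||% list()
  for (nm in c("bmi_mean", "bmi_sd", "height_mean", "height_sd")) {
    if (!is.null(cohort_args[[nm]])) cohort_args[[nm]] <- unlist(cohort_args[[nm]])
  }
  list(
    cohort = do.call(cohort_spec, cohort_args),
    scan = do.call(scan_parameters, raw$scan %||% list()),
    seed = as.integer(raw$seed %||% 1L)
  )
}

#' Generate a synthetic cohort of patient records and scanner reports
#'
#' @param n Number of patients.
#' @param spec A [cohort_spec()].
#' @param scan A [scan_parameters()] object.
#' @param seed Integer master seed; per-patient seeds are derived from it.
#' @return A data.frame with one row per patient (demographics plus scanner
#'   report quantities).
#' @export
generate_cohort <- function(n, spec = cohort_spec(), scan = scan_parameters(),
                            seed = 1L) {
  stopifnot(n >= 1)
  rows <- lapply(seq_len(n), function(i) {
    p <- generate_patient(seed * 100003L + i, spec, id = sprintf("S%03d", i))
    r <- emulate_scanner_report(p, scan, seed = seed * 200003L + i)
    data.frame(
      id = p$id, age = p$age, sex = p$sex, height = p$height,
      weight = p$weight, bmi = p$bmi, ctdi_vol = r$ctdi_vol, dlp = r$dlp,
      eff_mas = r$effective_mas, scan_length = r$scan_length,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
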