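#' Configuration for the Monte Carlo photon transport
#'
#' @param n_histories Number of photon histories (> 0).
#' @param photon_energy_model `"monoenergetic_effective"` (single 64 keV
#'   effective energy standing in for a 120 kVp spectrum; keeps the analytic
#'   oracles exact) or `"binned_spectrum"`.
#' @param energies_keV Photon energies (10-150 keV). One value for the
#'   monoenergetic model; several (with `energy_weights`) for the binned
#'   spectrum.
#' @param energy_weights Relative bin weights for the binned spectrum.
#' @param helix Optional list `(start_z, end_z, pitch, source_radius)` in mm;
#'   defaults cover the phantom z-extent with the scan pitch and a 600 mm
#'   source radius.
#' @param interactions List of flags: `photoelectric`, `compton` (enable the
#'   interaction channels) and `follow_scatter` (track Compton-scattered
#'   photons; when `FALSE` the simulation is primary-only but still deposits
#'   the Compton-transferred energy).
#' @param rng_seed Integer seed; identical configurations and seeds yield
#'   bit-identical dose maps.
#' @param n_batches Batches for the uncertainty estimate.
#' @param cutoff_keV Photons below this energy are absorbed locally.
#' @param score_boost Inflation factor of the Woodcock majorant; the extra
#'   virtual collisions act as additional scoring points for the
#'   expected-value dose estimator (lower variance, proportionally more CPU)
#'   without changing the transported physics.
#' @return A list of class `transport_config`.
#' @export
transport_config <- function(n_histories = 1e5,
                             photon_energy_model = c("monoenergetic_effective",
                                                     "binned_spectrum"),
                             energies_keV = NULL, energy_weights = NULL,
                             helix = NULL,
                             interactions = list(photoelectric = TRUE,
                                                 compton = TRUE,
                                                 follow_scatter = TRUE),
                             rng_seed = 1L, n_batches = 10L,
                             cutoff_keV = 5, score_boost = 2) {
  photon_energy_model <- match.arg(photon_energy_model)
  if (!is.finite(n_histories) || n_histories < 1) {
    stop("n_histories must be positive")
  }
  if (is.null(energies_keV)) {
    energies_keV <- if (photon_energy_model == "monoenergetic_effective") {
      64
    } else {
      c(45, 64, 90)
    }
  }
  if (is.null(energy_weights)) {
    energy_weights <- if (length(energies_keV) == 3) c(0.3, 0.5, 0.2) else
      rep(1, length(energies_keV))
  }
  if (any(energies_keV < 10) || any(energies_keV > 150)) {
    stop("photon energies must lie within 10-150 keV")
  }
  if (length(energy_weights) != length(energies_keV)) {
    stop("energy_weights must match energies_keV")
  }
  flags <- list(photoelectric = TRUE, compton = TRUE, follow_scatter = TRUE)
  flags[names(interactions)] <- interactions
  structure(
    list(n_histories = n_histories, photon_energy_model = photon_energy_model,
         energies_keV = energies_keV, energy_weights = energy_weights,
         helix = helix, interactions = flags, rng_seed = as.integer(rng_seed),
         n_batches = as.integer(n_batches), cutoff_keV = cutoff_keV,
         score_boost = score_boost),
    class = "transport_config"
  )
}

# per-history free-in-air air kerma on the rotation axis, keV/g.
# For a helical source emitting uniformly over a rectangle of half-width w
# (mm) through the axis, with source z uniform over a span Z (mm), the
# expected axis fluence per emitted photon is 1/(2 Z w) per mm^2
# (independent of collimation), hence kerma follows from the air mass
# energy-transfer coefficient.
axis_air_kerma_per_history <- function(energies, weights, z_span_mm, fan_half_width_mm) {
  w <- weights / sum(weights)
  fluence_cm2 <- 100 / (2 * z_span_mm * fan_half_width_mm)  # 1/mm^2 -> 1/cm^2
  sum(w * energies * mass_energy_transfer(energies, "air")) * fluence_cm2
}

#' Simulate the per-voxel dose distribution of a helical CT scan
#'
#' Runs the simplified photon transport (photoelectric + Klein-Nishina
#' Compton, kerma approximation, Woodcock tracking) for a point source on a
#' helix around the phantom and scores energy deposited per voxel. The
#' result is expressed as relative dose, normalized so that the free-in-air
#' air kerma at the isocenter equals 1; multiplying by the scanner air kerma
#' (see [scale_to_absorbed()]) yields absorbed dose in mGy.
#'
#' @param phantom A `voxel_phantom`.
#' @param scan A [scan_parameters()] object (pitch and collimation feed the
#'   helix; air kerma is not applied here).
#' @param cfg A [transport_config()].
#' @return A `dose_map`: list with `relative_dose`, `uncertainty` (per-voxel
#'   relative standard error from batch statistics), `absorbed_dose` (NULL
#'   until scaled), `emitted_keV`, `deposited_keV`, bookkeeping fields.
#' @export
simulate_dose <- function(phantom, scan = scan_parameters(), cfg = transport_config()) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(cfg, "transport_config"))
  dims <- dim(phantom$hu)
  if (length(dims) != 3 || any(dims < 1) || any(phantom$spacing <= 0)) {
    stop("degenerate phantom: zero extent")
  }
  z_ext <- dims[3] * phantom$spacing[3]
  helix <- cfg$helix %||% list(start_z = 0, end_z = z_ext, pitch = scan$pitch,
                               source_radius = 600)
  if (helix$start_z > 0 || helix$end_z < z_ext) {
    stop("helix must cover the phantom z-extent")
  }
  # fan wide enough to cover the grid diagonally from the source
  fan_half_width <- 0.75 * sqrt(sum((dims[1:2] * phantom$spacing[1:2])^2)) / 2

  res <- .transport_cpp(
    hu = as.numeric(phantom$hu), dims = as.integer(dims),
    spacing = as.numeric(phantom$spacing), origin = as.numeric(phantom$origin),
    src_radius = helix$source_radius, z_start = helix$start_z,
    z_end = helix$end_z, pitch = helix$pitch, collimation = scan$collimation,
    fan_half_width = fan_half_width, energies = cfg$energies_keV,
    energy_weights = cfg$energy_weights, n_histories = cfg$n_histories,
    n_batches = cfg$n_batches,
    photoelectric = isTRUE(cfg$interactions$photoelectric),
    compton = isTRUE(cfg$interactions$compton),
    follow_scatter = isTRUE(cfg$interactions$follow_scatter),
    cutoff_kev = cfg$cutoff_keV, score_boost = cfg$score_boost,
    rng_seed = cfg$rng_seed,
    atten_e = .atten_energies, atten_mu_water = .mu_rho_water,
    atten_cbone = vapply(.atten_energies, bone_ramp_slope, numeric(1))
  )

  vox_vol_cm3 <- prod(phantom$spacing) / 1000
  mass_g <- density_from_hu(phantom$hu) * vox_vol_cm3
  kerma_ref <- axis_air_kerma_per_history(cfg$energies_keV, cfg$energy_weights,
                                          helix$end_z - helix$start_z,
                                          fan_half_width)
  nb <- cfg$n_batches
  # batch estimates of relative dose per voxel
  batch_rel <- res$edep_batch * (nb / cfg$n_histories) / as.numeric(mass_g) / kerma_ref
  rel <- array(rowMeans(batch_rel), dim = dims)
  m2 <- rowMeans(batch_rel^2)
  batch_sd <- sqrt(pmax(0, m2 - rowMeans(batch_rel)^2) * nb / (nb - 1))
  se <- array(ifelse(rel > 0, (batch_sd / sqrt(nb)) / rel, 0), dim = dims)

  structure(
    list(relative_dose = rel, uncertainty = se, absorbed_dose = NULL,
         emitted_keV = res$emitted_kev, deposited_keV = res$deposited_kev,
         spacing = phantom$spacing, config = cfg,
         kerma_ref_per_history = kerma_ref),
    class = "dose_map"
  )
}

#' Scale a relative dose map to absorbed dose by air kerma
#'
#' Multiplies the relative dose grid (free-in-air isocenter kerma = 1) by the
#' scanner's air kerma, yielding absorbed dose per voxel in mGy. The relative
#' grid is left unchanged.
#'
#' @param map A `dose_map` from [simulate_dose()].
#' @param air_kerma Free-in-air air kerma at the isocenter, mGy (> 0).
#' @return The `dose_map` with `absorbed_dose` populated.
#' @export
scale_to_absorbed <- function(map, air_kerma) {
  stopifnot(inherits(map, "dose_map"))
  if (!is.finite(air_kerma) || air_kerma <= 0) {
    stop("air_kerma must be positive")
  }
  map$absorbed_dose <- map$relative_dose * air_kerma
  map$air_kerma <- air_kerma
  map
}

#' @export
print.dose_map <- function(x, ...) {
  cat("<dose_map> ", paste(dim(x$relative_dose), collapse = "x"),
      " voxels, ", format(x$config$n_histories, big.mark = ","),
      " histories\n", sep = "")
  cat("  mean relative dose (non-zero voxels): ",
      signif(mean(x$relative_dose[x$relative_dose > 0]), 4), "\n", sep = "")
  cat("  absorbed dose: ",
      if (is.null(x$absorbed_dose)) "not scaled" else
        paste0("scaled by air kerma ", x$air_kerma, " mGy"), "\n", sep = "")
  invisible(x)
}
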