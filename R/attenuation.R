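# Tabulated mass attenuation coefficients (cm^2/g) on a 10-150 keV grid,
# from the standard photon cross-section compilations (liquid water, dry air,
# cortical bone). Interpolation is log-log, which is accurate to <1% between
# nodes in this energy range.
.atten_energies <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)
.mu_rho_water <- c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                   0.1837, 0.1707, 0.1505)
.mu_rho_air <- c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875,
                 0.1662, 0.1541, 0.1356)
.mu_rho_bone <- c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148,
                  0.2229, 0.1855, 0.1480)
.rho_bone <- 1.92          # g/cm^3, cortical bone
.hu_bone_ref <- 1400       # HU assigned to cortical bone on the ramp
.ne_per_g_water <- 3.3428e23   # electrons per gram
.ne_per_g_air <- 3.0061e23

loglog_interp <- function(x, xg, yg) {
  exp(stats::approx(log(xg), log(yg), xout = log(x), rule = 1)$y)
}

check_energy <- function(energy) {
  if (any(!is.finite(energy)) || any(energy < 10) || any(energy > 150)) {
    stop("photon energy must lie within 10-150 keV")
  }
  energy
}

#' Linear attenuation coefficient of water
#' @param energy Photon energy in keV (10-150).
#' @return mu in 1/cm (density 1 g/cm^3).
#' @export
mu_water <- function(energy) {
  loglog_interp(check_energy(energy), .atten_energies, .mu_rho_water)
}

# slope of the bone segment of the HU->mu ramp (per 1000 HU), defined so that
# the ramp reaches the cortical-bone/water linear attenuation ratio at
# HU = 1400
bone_ramp_slope <- function(energy) {
  ratio <- .rho_bone * loglog_interp(check_energy(energy), .atten_energies, .mu_rho_bone) /
    loglog_interp(energy, .atten_energies, .mu_rho_water)
  (ratio - 1.1) * 1000 / (.hu_bone_ref - 100)
}

#' Convert Hounsfield units to a linear attenuation coefficient
#'
#' Below the soft-tissue threshold of 100 HU the CT definition is applied
#' directly, `mu = mu_water(E) * (1 + HU/1000)`, so that `mu(-1000) = 0`
#' (air) and `mu(0) = mu_water` exactly. Above 100 HU a steeper bone segment
#' is used, calibrated so that HU = 1400 reproduces the tabulated cortical
#' bone to water attenuation ratio at the given energy (bone attenuates more
#' per unit density because of its higher effective atomic number).
#'
#' @param hu Hounsfield units (>= -1000).
#' @param energy Photon energy in keV (10-150).
#' @return Linear attenuation coefficient in 1/cm.
#' @export
hu_to_attenuation <- function(hu, energy) {
  check_energy(energy)
  if (any(hu < -1000)) stop("HU below -1000 is not physical")
  f <- ifelse(hu <= 100, 1 + hu / 1000,
              1.1 + (hu - 100) / 1000 * bone_ramp_slope(energy))
  mu_water(energy) * f
}

#' Mass density from Hounsfield units
#'
#' Two-segment ramp used for voxel mass in dose scoring: `1 + HU/1000` g/cm^3
#' up to 100 HU (floored at the density of air), then a linear bone segment
#' reaching 1.92 g/cm^3 at HU 1400.
#'
#' @param hu Hounsfield units.
#' @return Density in g/cm^3.
#' @export
density_from_hu <- function(hu) {
  ifelse(hu <= 100, pmax(0.0012, 1 + hu / 1000),
         1.1 + (hu - 100) * (.rho_bone - 1.1) / (.hu_bone_ref - 100))
}

#' Klein-Nishina cross section per electron
#' @param energy Photon energy in keV.
#' @return Total incoherent scattering cross section in cm^2 per electron.
#' @export
kn_cross_section <- function(energy) {
  a <- energy / 510.99895
  re2_2pi <- 2 * pi * (2.8179403262e-13)^2
  re2_2pi * ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
               log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
}

#' Mean fraction of photon energy transferred to electrons in Compton scatter
#'
#' Computed by numerical integration of the Klein-Nishina differential cross
#' section weighted by the electron energy fraction `1 - E'/E`.
#'
#' @param energy Photon energy in keV.
#' @return Dimensionless fraction in (0, 1).
#' @export
kn_transfer_fraction <- function(energy) {
  vapply(energy, function(e) {
    a <- e / 510.99895
    ct <- seq(-1, 1, length.out = 2001)
    r <- 1 / (1 + a * (1 - ct))          # E'/E
    dcs <- r^2 * (r + 1 / r - (1 - ct^2))  # KN angular shape
    sum(dcs * (1 - r)) / sum(dcs)
  }, numeric(1))
}

#' Mass energy-transfer coefficient of the transport model
#'
#' The kerma-approximation energy-transfer coefficient implied by the
#' package's physics: full local deposition for photoelectric events (the
#' photoelectric component is the tabulated total minus the Klein-Nishina
#' part) plus the Klein-Nishina component weighted by the mean Compton
#' energy-transfer fraction. Used for the free-in-air kerma normalization and
#' for the analytic transport oracles.
#'
#' @param energy Photon energy in keV.
#' @param medium `"water"` or `"air"`.
#' @return Coefficient in cm^2/g.
#' @export
mass_energy_transfer <- function(energy, medium = c("water", "air")) {
  medium <- match.arg(medium)
  check_energy(energy)
  mu_rho <- if (medium == "water") {
    loglog_interp(energy, .atten_energies, .mu_rho_water)
  } else {
    loglog_interp(energy, .atten_energies, .mu_rho_air)
  }
  ne <- if (medium == "water") .ne_per_g_water else .ne_per_g_air
  kn <- kn_cross_section(energy) * ne
  tau <- pmax(0, mu_rho - kn)
  tau + kn * kn_transfer_fraction(energy)
}
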