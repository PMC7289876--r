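# shared helpers: analytic benchmark geometries and hand-built dose maps

# homogeneous cylinder phantom (HU hu_inside within radius_mm, air outside),
# axis along z, grid centered on the axis
make_cylinder_phantom <- function(n = 64, radius_mm = 100, hu_inside = 0,
                                  spacing_xy = 5, spacing_z = 10) {
  cx <- (seq_len(n) - (n + 1) / 2) * spacing_xy
  cz <- (seq_len(n) - 0.5) * spacing_z
  X <- array(rep(cx, times = n * n), c(n, n, n))
  Y <- array(rep(rep(cx, each = n), times = n), c(n, n, n))
  hu <- array(-1000, c(n, n, n))
  hu[X^2 + Y^2 <= radius_mm^2] <- hu_inside
  pat <- patient_record("BENCH", 50, "male", 170, 70)
  structure(
    list(hu = hu, labels = array(0L, c(n, n, n)),
         spacing = c(spacing_xy, spacing_xy, spacing_z),
         origin = c(cx[1], cx[1], cz[1]), patient = pat,
         omitted = character()),
    class = "voxel_phantom"
  )
}

# analytic primary-only relative dose on the cylinder axis: every incoming
# direction traverses exactly the cylinder radius of water, and the
# kerma-approximation dose-to-water / kerma-to-air ratio applies
cylinder_axis_oracle <- function(radius_mm, energy = 64) {
  exp(-hu_to_attenuation(0, energy) * radius_mm / 10) *
    mass_energy_transfer(energy, "water") / mass_energy_transfer(energy, "air")
}

# indices of a central block of voxels for axis scoring
cylinder_center_region <- function(n = 64) {
  list(xy = c(n / 2, n / 2 + 1), z = seq(round(0.44 * n), round(0.56 * n)))
}

# minimal dose_map around a given absorbed-dose array, for aggregation tests
fake_dose_map <- function(absorbed) {
  structure(
    list(relative_dose = absorbed, uncertainty = array(0, dim(absorbed)),
         absorbed_dose = absorbed, air_kerma = 1,
         emitted_keV = 0, deposited_keV = 0, spacing = c(1, 1, 1),
         config = NULL),
    class = "dose_map"
  )
}

# naive tie-aware Spearman: average ranks, Pearson on ranks
naive_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# precision bound for comparing a recomputed ratio/product against a printed
# cell whose inputs were themselves printed at limited precision
printed_cell_bound <- function(partials, input_steps, print_step) {
  sum(abs(partials) * input_steps / 2) + print_step / 2 + 1e-9
}
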