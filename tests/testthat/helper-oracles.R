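# Independent oracles used across the suite. They share no code with the
# transport engine: the ODE oracle integrates dE/dx = -rho*S(E) with a fixed
# fine step, the chord oracle walks the geometry in 0.01 um voxels, and the
# volume oracle uses rejection sampling.

# Brute-force Euler integration of the slowing-down ODE, step 0.1 um.
ode_exit_energy <- function(material, e0, depth_um, step_um = 0.1) {
  n <- ceiling(depth_um / step_um)
  h_cm <- depth_um / n * 1e-4
  E <- e0
  for (i in seq_len(n)) {
    if (E <= 0.0501) return(0)
    E <- E - material$density * h_cm * mass_stopping_power(material, E)
  }
  max(E, 0)
}

# Stepping containment oracle for the in-cell chords of a vertical ray at
# lateral distance r from the cell center.
chord_walk <- function(shape, r, dz_um = 0.01) {
  z <- seq(dz_um / 2, shape$c, by = dz_um)
  in_cell <- (r / shape$a)^2 + (z / shape$c)^2 <= 1
  in_nuc <- r < shape$an &
    (r / shape$an)^2 + ((z - shape$zn) / shape$cn)^2 <= 1
  c(cytoplasm = sum(in_cell & !in_nuc) * dz_um,
    nucleus = sum(in_nuc) * dz_um,
    height = sum(in_cell) * dz_um)
}

# Rejection-sampled volumes of the cell compartments, um^3.
mc_compartment_volumes <- function(shape, n = 1e6, seed = 7) {
  set.seed(seed)
  x <- runif(n, -shape$a, shape$a)
  y <- runif(n, -shape$a, shape$a)
  z <- runif(n, 0, shape$c)
  box <- (2 * shape$a)^2 * shape$c
  in_cell <- (x^2 + y^2) / shape$a^2 + z^2 / shape$c^2 <= 1
  in_nuc <- (x^2 + y^2) / shape$an^2 +
    (z - shape$zn)^2 / shape$cn^2 <= 1
  c(cytoplasm = mean(in_cell & !in_nuc) * box,
    nucleus = mean(in_nuc) * box)
}

water_col_segments <- function(depth_um, bin_um = 100) {
  n <- ceiling(depth_um / bin_um)
  tibble::tibble(
    material = "water",
    region = paste0("bin", seq_len(n)),
    length_um = bin_um
  )
}
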