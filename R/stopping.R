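# Bethe stopping number L(E). Below ~0.06 MeV the leading logarithm can turn
# negative for high-I materials; it is floored at a small positive value so
# that S stays positive on the whole grid. Energies that low lie below the
# transport cutoff and contribute negligibly (< 2 um) to any range.
.bethe_L_floor <- 0.05

.check_energy_window <- function(energy) {
  if (any(energy < .const$e_min | energy > .const$e_max)) {
    stop(sprintf(
      "proton energy outside the validity window [%g, %g] MeV",
      .const$e_min, .const$e_max
    ), call. = FALSE)
  }
}

.bethe_s <- function(za_eff, i_ev, energy) {
  gam <- 1 + energy / .const$mp
  b2 <- 1 - 1 / gam^2
  L <- log(2 * .const$me * 1e6 * b2 * gam^2 / i_ev) - b2
  .const$K * za_eff / b2 * pmax(L, .bethe_L_floor)
}

#' Electronic mass stopping power of protons
#'
#' Bethe formula for the electronic mass stopping power, with the material's
#' mean excitation energy combined from ICRU elemental values by Bragg
#' additivity (or a material-level override). Shell and Barkas corrections
#' are omitted; they are sub-percent effects above 1 MeV, and the transport
#' cutoff makes the region where they matter irrelevant to 10-35 MeV ranges.
#'
#' @param material A [material()].
#' @param energy Proton kinetic energy in MeV, within \[0.05, 50\].
#' @return Mass stopping power in MeV cm^2/g (vectorized over `energy`).
#' @export
#' @examples
#' mass_stopping_power(builtin_material("water"), 10) # ~45.7 MeV cm^2/g
mass_stopping_power <- function(material, energy) {
  stopifnot(inherits(material, "proton_material"))
  .check_energy_window(energy)
  .bethe_s(material$za_eff, material$i_ev, energy)
}

#' Cached stopping-power and range tables for one material
#'
#' Evaluates the Bethe stopping power on a log-spaced energy grid covering
#' 0.05-50 MeV and accumulates the CSDA range by trapezoidal quadrature of
#' 1/S(E) from the 0.05 MeV cutoff. The grid is the working representation
#' used by the transport engine; [csda_range()] and [residual_energy()]
#' interpolate it.
#'
#' @param material A [material()].
#' @param n_grid Number of grid points (log-spaced).
#' @return An object of class `stopping_model` with fields `energy_mev`,
#'   `s_mass` (MeV cm^2/g) and `range_g_cm2`.
#' @export
stopping_model <- function(material, n_grid = 800) {
  stopifnot(inherits(material, "proton_material"))
  e <- exp(seq(log(.const$e_min), log(.const$e_max), length.out = n_grid))
  s <- .bethe_s(material$za_eff, material$i_ev, e)
  inv <- 1 / s
  r <- c(0, cumsum(diff(e) * (inv[-1] + inv[-n_grid]) / 2))
  structure(
    list(material = material, energy_mev = e, s_mass = s, range_g_cm2 = r),
    class = "stopping_model"
  )
}

#' @export
print.stopping_model <- function(x, ...) {
  cat(sprintf(
    "<stopping_model> %s: %d points, %g-%g MeV, range(max) = %.4g g/cm^2\n",
    x$material$name, length(x$energy_mev), min(x$energy_mev),
    max(x$energy_mev), max(x$range_g_cm2)
  ))
  invisible(x)
}

.as_stopping_model <- function(x) {
  if (inherits(x, "stopping_model")) x else stopping_model(x)
}

.range_g <- function(model, energy) {
  stats::approx(log(model$energy_mev), model$range_g_cm2, log(energy),
                rule = 2)$y
}

.energy_at_range <- function(model, range_g) {
  out <- numeric(length(range_g))
  pos <- range_g > 0
  out[pos] <- stats::approx(model$range_g_cm2, model$energy_mev,
                            pmin(range_g[pos], max(model$range_g_cm2)),
                            rule = 2)$y
  out
}

#' CSDA range of protons
#'
#' Continuous-slowing-down-approximation range, the integral of 1/S(E) from
#' the 0.05 MeV cutoff up to `energy`, converted to length through the
#' material density when `units = "um"`.
#'
#' @inheritParams mass_stopping_power
#' @param units `"um"` (default) or `"g_cm2"`.
#' @param model Optional precomputed [stopping_model()] (avoids rebuilding
#'   the grid in loops).
#' @return Range (vectorized over `energy`).
#' @export
#' @examples
#' csda_range(builtin_material("water"), 15) # ~2500 um
csda_range <- function(material, energy, units = c("um", "g_cm2"),
                       model = NULL) {
  units <- match.arg(units)
  if (any(energy <= 0)) stop("energy must be positive", call. = FALSE)
  .check_energy_window(energy)
  m <- if (is.null(model)) .as_stopping_model(material) else model
  r <- .range_g(m, energy)
  if (units == "um") r / m$material$density * 1e4 else r
}

#' Residual proton energy after a slab
#'
#' Inverse-range solution: the energy E such that
#' range(`energy0`) - depth = range(E), i.e. the mean (CSDA) energy of a
#' proton after traversing `depth_um` of the material. Returns 0 when the
#' depth reaches or exceeds the range.
#'
#' @inheritParams csda_range
#' @param energy0 Incident energy, MeV.
#' @param depth_um Traversed thickness, micrometres (>= 0).
#' @return Residual energy in MeV (vectorized over `depth_um`).
#' @export
#' @examples
#' residual_energy(builtin_material("water"), 15, 2500) # ~0: end of range
residual_energy <- function(material, energy0, depth_um, model = NULL) {
  if (any(depth_um < 0)) stop("depth must be >= 0", call. = FALSE)
  .check_energy_window(energy0)
  m <- if (is.null(model)) .as_stopping_model(material) else model
  res <- .range_g(m, energy0) - depth_um * 1e-4 * m$material$density
  out <- .energy_at_range(m, pmax(res, 0))
  out[res <= 0] <- 0
  out
}

#' Energy-loss straggling width
#'
#' Standard deviation of the energy-loss distribution accumulated over a
#' traversed mass thickness. The default is the Bohr variance
#' sigma^2 = K m_e c^2 (Z/A) t, linear in the path and independent of energy
#' in the non-relativistic limit; `model = "vavilov"` applies the
#' relativistic (large-kappa Vavilov/Gaussian-limit) factor
#' (1 - beta^2/2)/(1 - beta^2). At the path lengths of this setup kappa is
#' large and the Vavilov distribution is near-Gaussian, so the same
#' interface covers both.
#'
#' @inheritParams residual_energy
#' @param path_g_cm2 Traversed mass thickness, g/cm^2 (>= 0; must be smaller
#'   than the residual mass range at `energy0`).
#' @param model `"bohr"` (default) or `"vavilov"`.
#' @param stopping Optional precomputed [stopping_model()].
#' @return Straggling standard deviation in MeV.
#' @export
#' @examples
#' straggling_sigma(builtin_material("water"), 15, 0.1)
straggling_sigma <- function(material, energy0, path_g_cm2,
                             model = c("bohr", "vavilov"), stopping = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(material, "proton_material"))
  if (any(path_g_cm2 < 0)) stop("path must be >= 0", call. = FALSE)
  .check_energy_window(energy0)
  m <- if (is.null(stopping)) .as_stopping_model(material) else stopping
  res <- .range_g(m, energy0)
  if (any(path_g_cm2 > res)) {
    stop("path exceeds the residual range at the given energy", call. = FALSE)
  }
  v <- .const$K * .const$me * material$za_eff * path_g_cm2
  if (model == "vavilov") {
    gam <- 1 + energy0 / .const$mp
    b2 <- 1 - 1 / gam^2
    v <- v * (1 - b2 / 2) / (1 - b2)
  }
  sqrt(v)
}

#' Stopping-power and range table
#'
#' Convenience table of stopping powers and CSDA ranges over an energy grid,
#' for documentation and CSV export.
#'
#' @param materials Named list of [material()]s (default: the built-ins).
#' @param energies Energy grid in MeV.
#' @return A tibble with columns `material`, `energy_mev`,
#'   `s_mass_mev_cm2_g`, `range_um`, `range_g_cm2`.
#' @export
stopping_table <- function(materials = default_materials(),
                           energies = c(5, 10, 15, 20, 25, 30, 35)) {
  purrr::map_dfr(materials, function(m) {
    sm <- stopping_model(m)
    tibble::tibble(
      material = m$name,
      energy_mev = energies,
      s_mass_mev_cm2_g = mass_stopping_power(m, energies),
      range_um = csda_range(m, energies, "um", model = sm),
      range_g_cm2 = csda_range(m, energies, "g_cm2", model = sm)
    )
  })
}

# Tables handed to the C++ engine: log-uniform energy grid with stopping
# powers and log-ranges, plus a log-uniform inverse (log-range -> log-energy)
# grid for the residual-energy step. Log-log interpolation keeps the
# range/energy relation (locally a power law) accurate enough that the
# range-difference step loss does not suffer cancellation; steps much
# shorter than the residual range use S(E)*dt directly in the engine.
.mat_tables <- function(material, n_grid = 800, n_inv = 2000) {
  sm <- stopping_model(material, n_grid)
  e <- sm$energy_mev
  r <- sm$range_g_cm2
  r_lo <- r[2]
  rg <- exp(seq(log(r_lo), log(r[n_grid]), length.out = n_inv))
  einv <- exp(stats::approx(log(r[-1]), log(e[-1]), log(rg), rule = 2)$y)
  list(
    density = material$density,
    za = material$za_eff,
    max_step_um = material$max_step_um,
    loge0 = log(e[1]),
    dloge = (log(e[n_grid]) - log(e[1])) / (n_grid - 1),
    s_mass = sm$s_mass,
    logrange = log(pmax(r, r_lo * 1e-3)),
    logr0 = log(r_lo),
    dlogr = (log(r[n_grid]) - log(r_lo)) / (n_inv - 1),
    logeinv = log(einv)
  )
}
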