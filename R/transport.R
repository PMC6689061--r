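#' Transport configuration
#'
#' Numerical controls of the condensed-history engine.
#'
#' Step lengths are capped at `min(max_step_um of the material,
#' step_fraction * residual range)` and floored at `min_step_um`; cell
#' compartments carry a 0.5 um material-level cap so the 5 um cells are
#' resolved. Below `cutoff_mev` the residual energy is deposited locally.
#' With `straggling = "bohr"` the per-step loss is drawn from a Gamma
#' distribution with the exact CSDA mean and the Bohr variance (strictly
#' non-negative, Gaussian in the thick-step limit — a clipped Gaussian
#' would bias thin-region doses upward); `"vavilov"` additionally applies
#' the relativistic large-kappa Vavilov factor to the variance.
#'
#' @param histories Number of transported histories per batch (>= 1).
#' @param seed Integer seed; every simulation derives per-task substreams
#'   from it (see [derive_seed()]), so subsets of a sweep reproduce the
#'   full-sweep results.
#' @param straggling `"bohr"` (default), `"vavilov"` or `"off"`.
#' @param cutoff_mev Low-energy cutoff, MeV.
#' @param step_fraction Residual-range fraction limiting the step.
#' @param min_step_um Step floor, um.
#' @return An object of class `proton_transport_config`.
#' @export
#' @examples
#' transport_config(histories = 1000, seed = 42)
transport_config <- function(histories = 10000, seed = 1L,
                             straggling = c("bohr", "vavilov", "off"),
                             cutoff_mev = 0.05, step_fraction = 0.02,
                             min_step_um = 0.5) {
  straggling <- match.arg(straggling)
  if (histories < 1) stop("histories must be >= 1", call. = FALSE)
  if (step_fraction <= 0 || min_step_um <= 0) {
    stop("step controls must be positive", call. = FALSE)
  }
  structure(
    list(
      histories = as.integer(histories), seed = as.integer(seed),
      straggling = straggling, cutoff_mev = cutoff_mev,
      step_fraction = step_fraction, min_step_um = min_step_um
    ),
    class = "proton_transport_config"
  )
}

.strag_code <- function(straggling) {
  match(straggling, c("off", "bohr", "vavilov")) - 1L
}

#' Transport one proton history through a ray (reference engine)
#'
#' Pure-R condensed-history stepping of a single proton through the ordered
#' segments of a ray, mirroring the compiled batch engine step for step. It
#' exists as an independently-readable reference implementation: tests
#' cross-check the compiled engine against it, and it is convenient for
#' inspecting individual histories.
#'
#' @param segments A segment tibble from [segment_ray_dish()] or
#'   [segment_ray_ioc()] (columns `material`, `region`, `length_um`).
#' @param energy0 Incident energy, MeV.
#' @param config A [transport_config()].
#' @param materials Named list of materials.
#' @return A list with `deposits_mev` (named by region, including `none`)
#'   and `exit_energy_mev`.
#' @export
#' @examples
#' seg <- segment_ray_dish(cell_array_geometry(100), 0, 0)
#' run_history(seg, 15, transport_config(straggling = "off"))
run_history <- function(segments, energy0, config = transport_config(),
                        materials = default_materials()) {
  stopifnot(inherits(config, "proton_transport_config"))
  .check_energy_window(energy0)
  regions <- unique(segments$region)
  dep <- stats::setNames(numeric(length(regions)), regions)
  models <- lapply(materials, stopping_model)
  E <- energy0
  strag <- config$straggling
  for (i in seq_len(nrow(segments))) {
    if (E <= 0) break
    m <- materials[[segments$material[i]]]
    sm <- models[[segments$material[i]]]
    reg <- segments$region[i]
    rem <- segments$length_um[i]
    while (rem > 1e-9 && E > 0) {
      if (E < config$cutoff_mev) {
        dep[reg] <- dep[reg] + E
        E <- 0
        break
      }
      res_g <- .range_g(sm, E)
      res_um <- res_g / m$density * 1e4
      step <- max(min(m$max_step_um, config$step_fraction * res_um),
                  config$min_step_um)
      step <- min(step, rem)
      t_g <- step * 1e-4 * m$density
      mu <- if (t_g >= res_g) {
        E
      } else if (t_g < 0.005 * res_g) {  # thin step: avoid cancellation
        min(E, .bethe_s(m$za_eff, m$i_ev, E) * t_g)
      } else {
        min(E, E - .energy_at_range(sm, res_g - t_g))
      }
      loss <- mu
      if (strag != "off" && mu > 0) {
        v <- .const$K * .const$me * m$za_eff * t_g
        if (strag == "vavilov") {
          gam <- 1 + E / .const$mp
          b2 <- 1 - 1 / gam^2
          v <- v * (1 - b2 / 2) / (1 - b2)
        }
        shape <- mu^2 / v
        loss <- if (shape > 100) {
          max(mu + sqrt(v) * stats::rnorm(1), 0)
        } else {
          stats::rgamma(1, shape = shape, scale = mu / shape)
        }
        loss <- min(loss, E)
      }
      dep[reg] <- dep[reg] + loss
      E <- E - loss
      rem <- rem - step
    }
  }
  list(deposits_mev = dep, exit_energy_mev = E)
}

# shared driver: segment matrices -> compiled engine
.cpp_run <- function(seg_len, seg_mat, seg_reg, energy0, materials,
                     n_regions, config) {
  tabs <- lapply(materials, .mat_tables)
  cpp_transport(
    seg_len, seg_mat, seg_reg, as.numeric(energy0), unname(tabs),
    as.integer(n_regions), config$cutoff_mev,
    .strag_code(config$straggling), .const$K * .const$me, .const$mp,
    config$min_step_um, config$step_fraction
  )
}

#' Run a batch of histories and tally per-region energy deposits
#'
#' Samples entry points on the uniform source disk, transports the
#' histories and accumulates per-region deposit sums and squared sums for
#' uncertainty estimation. Entry points are importance-sampled: only rays
#' whose vertical path can cross a scoring region are transported (the
#' footprint disk of each cell, or the chamber-width strip of the source
#' disk), and each tally carries the analytic area weight that restores the
#' per-emitted-source-particle normalization. With vertical rays this
#' reweighting is exact — rays outside those footprints cannot deposit in
#' any scoring region, yet still count in the normalization denominator.
#'
#' For the cell array, histories are split evenly over the nine cells and
#' each cell's cytoplasm and nucleus are tallied separately; for the
#' chamber the air cavity is tallied. Results are deterministic for a fixed
#' `config$seed`.
#'
#' @param geometry A [cell_array_geometry()] or [ioc_geometry()].
#' @param energy0 Incident proton energy, MeV.
#' @param config A [transport_config()].
#' @param materials Named list of materials.
#' @return A `proton_tally` tibble with columns `cell` (NA for the
#'   chamber), `group`, `region`, `sum_mev`, `sumsq_mev2`, `histories`,
#'   `weight` and `mass_g`, with the run parameters in attributes.
#' @export
#' @examples
#' tal <- run_batch(cell_array_geometry(100), 15,
#'                  transport_config(histories = 900, seed = 1))
#' dose_per_source_particle(tal)
run_batch <- function(geometry, energy0, config = transport_config(),
                      materials = default_materials()) {
  UseMethod("run_batch")
}

.finish_tally <- function(rows, energy0, geometry, config) {
  out <- dplyr::bind_rows(rows)
  attr(out, "energy_mev") <- energy0
  attr(out, "geometry") <- geometry
  attr(out, "config") <- config
  class(out) <- c("proton_tally", class(out))
  out
}

#' @export
run_batch.proton_cell_array <- function(geometry, energy0,
                                        config = transport_config(),
                                        materials = default_materials()) {
  stopifnot(inherits(config, "proton_transport_config"))
  .check_energy_window(energy0)
  if (config$histories < 9) {
    stop("need at least 9 histories (one per cell)", call. = FALSE)
  }
  s <- geometry$shape
  t <- geometry$medium_thickness_um
  n_cell <- ceiling(config$histories / 9)
  masses <- region_masses(geometry, materials)
  mat_idx <- c(air = 0L, water = 1L, cytoplasm = 2L, nucleus = 3L,
               glass = 4L)
  mats <- materials[c("air", "water", "cytoplasm", "nucleus", "glass")]
  weight <- (s$a / geometry$source_radius_um)^2  # footprint / source disk
  rows <- purrr::pmap(geometry$positions, function(cell, x_um, y_um, group) {
    set.seed(derive_seed(config$seed, energy0 * 1000, t, cell))
    r <- s$a * sqrt(stats::runif(n_cell))
    ch <- .cell_chords(s, r)
    seg_len <- cbind(
      geometry$air_gap_um,
      t + (s$c - ch$h_cell),
      ch$cyto_above, ch$nucleus, ch$cyto_below,
      geometry$substrate_thickness_um
    )
    seg_mat <- matrix(mat_idx[c("air", "water", "cytoplasm", "nucleus",
                                "cytoplasm", "glass")],
                      nrow = n_cell, ncol = 6, byrow = TRUE)
    seg_reg <- matrix(c(0L, 0L, 1L, 2L, 1L, 0L),
                      nrow = n_cell, ncol = 6, byrow = TRUE)
    res <- .cpp_run(seg_len, seg_mat, seg_reg, energy0, mats, 2L, config)
    d <- res$deposits
    tibble::tibble(
      cell = cell, group = group,
      region = c("cytoplasm", "nucleus"),
      sum_mev = c(sum(d[, 1]), sum(d[, 2])),
      sumsq_mev2 = c(sum(d[, 1]^2), sum(d[, 2]^2)),
      histories = n_cell,
      weight = weight,
      mass_g = masses$mass_g[match(region, masses$region)]
    )
  })
  .finish_tally(rows, energy0, geometry, config)
}

#' @export
run_batch.proton_ioc <- function(geometry, energy0,
                                 config = transport_config(),
                                 materials = default_materials()) {
  stopifnot(inherits(config, "proton_transport_config"))
  .check_energy_window(energy0)
  n <- config$histories
  ro <- geometry$outer_radius_mm
  rd <- geometry$source_radius_um / 1000  # mm
  set.seed(derive_seed(config$seed, energy0 * 1000, 0, 0))
  # offset marginal over the chamber-width strip of the source disk:
  # density proportional to the axial chord 2*sqrt(rd^2 - v^2)
  v <- numeric(0)
  while (length(v) < n) {
    prop <- stats::runif(n, -ro, ro)
    keep <- stats::runif(n) < sqrt(rd^2 - prop^2) / rd
    v <- c(v, prop[keep])
  }
  v <- v[seq_len(n)]
  ri <- geometry$cavity_radius_mm
  chord_out <- 2 * sqrt(pmax(ro^2 - v^2, 0))
  chord_in <- ifelse(abs(v) < ri, 2 * sqrt(pmax(ri^2 - v^2, 0)), 0)
  wall <- (chord_out - chord_in) / 2 * 1000
  seg_len <- cbind(geometry$air_gap_um, wall, chord_in * 1000, wall)
  seg_mat <- matrix(c(0L, 1L, 0L, 1L), nrow = n, ncol = 4, byrow = TRUE)
  seg_reg <- matrix(c(0L, 0L, 1L, 0L), nrow = n, ncol = 4, byrow = TRUE)
  mats <- materials[c("air", "pmma")]
  res <- .cpp_run(seg_len, seg_mat, seg_reg, energy0, mats, 1L, config)
  d <- res$deposits[, 1]
  strip_area <- 2 * (ro * sqrt(rd^2 - ro^2) + rd^2 * asin(ro / rd))
  masses <- region_masses(geometry, materials)
  rows <- tibble::tibble(
    cell = NA_integer_, group = "detector", region = "cavity",
    sum_mev = sum(d), sumsq_mev2 = sum(d^2), histories = n,
    weight = strip_area / (pi * rd^2),
    mass_g = masses$mass_g[1]
  )
  .finish_tally(list(rows), energy0, geometry, config)
}

#' Convert a tally to F6-style dose per emitted source particle
#'
#' Dose = weight * (deposit sum / histories) / region mass, in MeV/g per
#' emitted source particle (the importance weight restores the emitted-
#' particle denominator). The relative standard error comes from the
#' per-history second moments; it is `NA` (flagged) for zero-dose regions.
#'
#' @param tally A `proton_tally` from [run_batch()].
#' @return A tibble with columns `cell`, `group`, `region`,
#'   `dose_mev_g`, `rel_err`, `histories`.
#' @export
dose_per_source_particle <- function(tally) {
  stopifnot(inherits(tally, "proton_tally"))
  if (any(tally$mass_g <= 0)) stop("region mass must be > 0", call. = FALSE)
  if (any(tally$histories <= 0)) {
    stop("tally holds no histories", call. = FALSE)
  }
  mean_dep <- tally$sum_mev / tally$histories
  var_dep <- pmax(
    tally$sumsq_mev2 / tally$histories - mean_dep^2, 0
  ) / tally$histories
  out <- tibble::tibble(
    cell = tally$cell, group = tally$group, region = tally$region,
    dose_mev_g = tally$weight * mean_dep / tally$mass_g,
    rel_err = ifelse(mean_dep > 0, sqrt(var_dep) / mean_dep, NA_real_),
    histories = tally$histories
  )
  attr(out, "energy_mev") <- attr(tally, "energy_mev")
  out
}

#' Depth-dose curve in a homogeneous column
#'
#' Transports histories through a single-material column divided into equal
#' depth bins (each bin a scoring region) and returns the binned dose — the
#' Bragg curve. Doses are per history and per bin mass under unit beam
#' area.
#'
#' @param energy0 Incident energy, MeV.
#' @param depth_max_um Column depth, um.
#' @param bin_um Bin thickness, um.
#' @param config A [transport_config()].
#' @param material The column material (default water).
#' @return A tibble of class `proton_depth_dose` with columns
#'   `depth_um` (bin center), `dose_mev_g`.
#' @export
#' @examples
#' dd <- simulate_depth_dose(15, 3000, bin_um = 50,
#'                           config = transport_config(histories = 200))
#' dd$depth_um[which.max(dd$dose_mev_g)] # ~CSDA range of 15 MeV
simulate_depth_dose <- function(energy0, depth_max_um, bin_um = 20,
                                config = transport_config(),
                                material = builtin_material("water")) {
  .check_energy_window(energy0)
  n_bins <- ceiling(depth_max_um / bin_um)
  n <- config$histories
  set.seed(derive_seed(config$seed, energy0 * 1000, depth_max_um, 1))
  seg_len <- matrix(bin_um, nrow = n, ncol = n_bins)
  seg_mat <- matrix(0L, nrow = n, ncol = n_bins)
  seg_reg <- matrix(seq_len(n_bins), nrow = n, ncol = n_bins, byrow = TRUE)
  res <- .cpp_run(seg_len, seg_mat, seg_reg, energy0, list(material),
                  n_bins, config)
  mass_g <- bin_um * 1e-4 * material$density  # per cm^2 of beam
  out <- tibble::tibble(
    depth_um = (seq_len(n_bins) - 0.5) * bin_um,
    dose_mev_g = colMeans(res$deposits) / mass_g
  )
  class(out) <- c("proton_depth_dose", class(out))
  attr(out, "energy_mev") <- energy0
  attr(out, "material") <- material$name
  out
}
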