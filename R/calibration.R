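#' Calibration coefficient R = D_A / D_E
#'
#' Ratio of the dose absorbed in a cellular compartment to the dose
#' recorded by the external detector, with uncertainties combined in
#' quadrature from the two relative errors. Both doses must share the same
#' per-emitted-source-particle normalization, which makes R independent of
#' the number of source particles.
#'
#' @param dose_cell Compartment dose D_A, MeV/g per source particle (>= 0).
#' @param dose_detector Detector dose D_E, MeV/g per source particle (> 0).
#' @param rel_err_cell,rel_err_detector Relative standard errors.
#' @return A tibble with columns `R` and `rel_err` (vectorized).
#' @export
#' @examples
#' compute_R(2.0, 1.0, 0.01, 0.01)
compute_R <- function(dose_cell, dose_detector, rel_err_cell = 0,
                      rel_err_detector = 0) {
  if (any(dose_detector <= 0)) {
    stop("detector dose must be > 0", call. = FALSE)
  }
  r_a <- ifelse(is.na(rel_err_cell), 0, rel_err_cell)
  r_e <- ifelse(is.na(rel_err_detector), 0, rel_err_detector)
  tibble::tibble(
    R = dose_cell / dose_detector,
    rel_err = sqrt(r_a^2 + r_e^2)
  )
}

#' Group-average R records
#'
#' Collapses per-cell R values into the cell groups of the 3x3 lattice:
#' `central` (cell 1), `side` (mean of cells 2-5), `diagonal` (mean of
#' cells 6-9) and `all` (arithmetic mean of all nine cells). The group
#' uncertainty combines the standard error of the mean over member cells
#' with the mean tally error in quadrature.
#'
#' @param records Per-cell tibble with columns `energy_mev`,
#'   `thickness_um`, `compartment`, `cell`, `group`, `R`, `rel_err`
#'   (exactly 9 cells per energy/thickness/compartment).
#' @return A tibble with one row per group (including `all`) and the same
#'   identifying columns.
#' @export
group_average_R <- function(records) {
  need <- c("energy_mev", "thickness_um", "compartment", "cell", "group",
            "R", "rel_err")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- dplyr::count(
    records, .data$energy_mev, .data$thickness_um, .data$compartment
  )
  if (any(counts$n != 9)) {
    stop("need exactly 9 per-cell records per energy/thickness/compartment",
         call. = FALSE)
  }
  summarise_grp <- function(df) {
    n <- nrow(df)
    m <- mean(df$R)
    sem <- if (n > 1 && m > 0) stats::sd(df$R) / sqrt(n) / m else 0
    tal <- sqrt(mean(df$rel_err^2, na.rm = TRUE) / n)
    tibble::tibble(R = m, rel_err = sqrt(sem^2 + ifelse(is.nan(tal), 0,
                                                        tal)^2))
  }
  per_group <- records |>
    dplyr::group_by(.data$energy_mev, .data$thickness_um,
                    .data$compartment, .data$group) |>
    dplyr::group_modify(~summarise_grp(.x)) |>
    dplyr::ungroup()
  overall <- records |>
    dplyr::group_by(.data$energy_mev, .data$thickness_um,
                    .data$compartment) |>
    dplyr::group_modify(~summarise_grp(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(group = "all")
  dplyr::bind_rows(per_group, overall) |>
    dplyr::arrange(.data$energy_mev, .data$thickness_um, .data$compartment,
                   factor(.data$group,
                          c("central", "side", "diagonal", "all")))
}

#' Thickness of the maximum R on a curve
#'
#' Argmax of R over a thickness grid; ties are broken toward the smaller
#' thickness.
#'
#' @param curve Tibble with columns `thickness_um` and `R` (>= 2 rows).
#' @return The thickness (um) at the maximum.
#' @export
#' @examples
#' find_peak_thickness(tibble::tibble(thickness_um = c(100, 500, 1000),
#'                                    R = c(1, 3, 2)))
find_peak_thickness <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0) {
    stop("empty R-vs-thickness curve", call. = FALSE)
  }
  if (nrow(curve) < 2) {
    stop("need at least 2 grid points", call. = FALSE)
  }
  ord <- order(curve$thickness_um)
  t_sorted <- curve$thickness_um[ord]
  r_sorted <- curve$R[ord]
  t_sorted[which.max(r_sorted)]  # which.max takes the first (smallest t)
}

#' Default study grids
#'
#' The six incident energies and eleven medium-layer thicknesses of the
#' study design.
#'
#' @return Numeric vectors (MeV / um).
#' @export
default_energies <- function() c(10, 15, 20, 25, 30, 35)

#' @rdname default_energies
#' @export
default_thicknesses <- function() {
  c(100, 500, 1000, 1500, 2000, 2500, 3000, 3500, 4000, 4500, 5000)
}

#' Cell-compartment doses for one energy and medium thickness
#'
#' Runs the cell-array batch and returns per-cell cytoplasm and nucleus
#' doses (MeV/g per emitted source particle).
#'
#' @param energy0 Incident energy, MeV.
#' @param thickness_um Medium-layer thickness, um.
#' @param config A [transport_config()].
#' @param materials Named list of materials.
#' @param ... Passed to [cell_array_geometry()].
#' @return A tibble with columns `cell`, `group`, `region`, `dose_mev_g`,
#'   `rel_err`, `histories`.
#' @export
simulate_cell_doses <- function(energy0, thickness_um,
                                config = transport_config(),
                                materials = default_materials(), ...) {
  geom <- cell_array_geometry(thickness_um, ...)
  dose_per_source_particle(run_batch(geom, energy0, config, materials))
}

#' Energy x thickness sweep of the calibration coefficient R
#'
#' The central driver: for every incident energy the detector dose D_E is
#' simulated once; for every (energy, thickness) pair the nine-cell array
#' is simulated, per-cell R = D_A/D_E values are formed for cytoplasm and
#' nucleus, and group averages (central/side/diagonal/all) are attached.
#'
#' @param energies Incident energies, MeV.
#' @param thicknesses Medium-layer thicknesses, um.
#' @param config A [transport_config()] (`histories` applies per
#'   (energy, thickness) point; the detector runs use
#'   `max(histories, ioc_histories)`).
#' @param ioc_histories Histories for the detector runs.
#' @param materials Named list of materials.
#' @param geometry_args List of overrides passed to
#'   [cell_array_geometry()].
#' @param ioc_geometry An [ioc_geometry()].
#' @return A tibble of class `proton_rtable` with columns `energy_mev`,
#'   `thickness_um`, `compartment`, `group`, `R`, `rel_err`. The per-cell
#'   records and the detector doses are attached as attributes (see
#'   [per_cell_R()] and [detector_dose()]).
#' @export
#' @examples
#' sw <- sweep_R(15, c(100, 2500),
#'               config = transport_config(histories = 900, seed = 1))
#' subset(sw, group == "all" & compartment == "cytoplasm")
sweep_R <- function(energies = default_energies(),
                    thicknesses = default_thicknesses(),
                    config = transport_config(),
                    ioc_histories = 2e5,
                    materials = default_materials(),
                    geometry_args = list(),
                    ioc_geometry = protoncal::ioc_geometry()) {
  if (length(energies) == 0 || length(thicknesses) == 0) {
    stop("energies and thicknesses must be non-empty", call. = FALSE)
  }
  ioc_cfg <- transport_config(
    histories = max(config$histories, ioc_histories), seed = config$seed,
    straggling = config$straggling, cutoff_mev = config$cutoff_mev,
    step_fraction = config$step_fraction, min_step_um = config$min_step_um
  )
  det <- simulate_ioc_dose(energies, ioc_cfg, ioc_geometry, materials)
  per_cell <- purrr::map_dfr(energies, function(e) {
    de <- det$dose_mev_g[det$energy_mev == e]
    de_err <- det$rel_err[det$energy_mev == e]
    purrr::map_dfr(thicknesses, function(t) {
      doses <- do.call(
        simulate_cell_doses,
        c(list(energy0 = e, thickness_um = t, config = config,
               materials = materials), geometry_args)
      )
      r <- compute_R(doses$dose_mev_g, de, doses$rel_err, de_err)
      tibble::tibble(
        energy_mev = e, thickness_um = t,
        compartment = doses$region, cell = doses$cell,
        group = doses$group, R = r$R, rel_err = r$rel_err
      )
    })
  })
  out <- group_average_R(per_cell)
  attr(out, "per_cell") <- per_cell
  attr(out, "detector") <- det
  attr(out, "config") <- config
  class(out) <- c("proton_rtable", class(out))
  out
}

#' Access the per-cell records / detector doses of a sweep
#'
#' @param x A `proton_rtable` from [sweep_R()].
#' @return A tibble.
#' @export
per_cell_R <- function(x) {
  stopifnot(inherits(x, "proton_rtable"))
  attr(x, "per_cell")
}

#' @rdname per_cell_R
#' @export
detector_dose <- function(x) {
  stopifnot(inherits(x, "proton_rtable"))
  attr(x, "detector")
}

#' Fine thickness scan around the Bragg condition
#'
#' Evaluates R on a fine thickness grid spanning `window_um` around the
#' CSDA range in water for each energy, where the R-vs-thickness curve of a
#' low-energy beam peaks sharply.
#'
#' @inheritParams sweep_R
#' @param step_um Grid step, um.
#' @param window_um Half-width of the scan window around the CSDA range,
#'   um.
#' @return A `proton_rtable` (see [sweep_R()]).
#' @export
fine_peak_scan <- function(energies = c(10, 15, 20),
                           config = transport_config(),
                           step_um = 100, window_um = 500, ...) {
  water <- builtin_material("water")
  sm <- stopping_model(water)
  purrr::map(energies, function(e) {
    rng_um <- csda_range(water, e, "um", model = sm)
    grid <- seq(max(step_um, rng_um - window_um), rng_um + window_um,
                by = step_um)
    sweep_R(e, round(grid), config = config, ...)
  }) |>
    .bind_rtables()
}

.bind_rtables <- function(tables) {
  out <- dplyr::bind_rows(lapply(tables, function(x) {
    class(x) <- setdiff(class(x), "proton_rtable")
    x
  }))
  attr(out, "per_cell") <- dplyr::bind_rows(lapply(tables, per_cell_R))
  attr(out, "detector") <- dplyr::bind_rows(lapply(tables, detector_dose))
  attr(out, "config") <- attr(tables[[1]], "config")
  class(out) <- c("proton_rtable", class(out))
  out
}

#' @export
print.proton_rtable <- function(x, ...) {
  cat(sprintf(
    "<proton_rtable> %d records: %d energies x %d thicknesses\n",
    nrow(x), length(unique(x$energy_mev)), length(unique(x$thickness_um))
  ))
  NextMethod()
}

#' Tidy / summarize a calibration sweep
#'
#' `tidy()` returns the group-level records as a plain tibble; `glance()`
#' returns one row per energy and compartment with the peak thickness and
#' the maximum cell-averaged R over the swept grid.
#'
#' @param x A `proton_rtable`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.proton_rtable <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.proton_rtable
#' @export
glance.proton_rtable <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::filter(.data$group == "all") |>
    dplyr::group_by(.data$energy_mev, .data$compartment) |>
    dplyr::summarise(
      peak_thickness_um = {
        ord <- order(.data$thickness_um)
        .data$thickness_um[ord][which.max(.data$R[ord])]
      },
      max_R = max(.data$R),
      .groups = "drop"
    )
}
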