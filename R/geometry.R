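#' Adherent-cell shape: half-ellipsoid cell with ellipsoidal nucleus
#'
#' Cells are modeled as half ellipsoids sitting flat side down on the
#' substrate (lateral semi-axes 15 um, vertical semi-axis 5 um), each
#' containing a full ellipsoidal nucleus (lateral semi-axes 7 um, vertical
#' semi-axis 1.5 um) centered on the cell axis at a configurable height
#' above the substrate. The default nucleus height (2 um) keeps the nucleus
#' strictly inside the cytoplasm with margin.
#'
#' @param lateral_semi_axis_um,vertical_semi_axis_um Cell semi-axes, um.
#' @param nucleus_lateral_semi_axis_um,nucleus_vertical_semi_axis_um Nucleus
#'   semi-axes, um.
#' @param nucleus_center_height_um Height of the nucleus center above the
#'   substrate, um.
#' @return An object of class `proton_cell_shape`.
#' @export
#' @examples
#' cell_shape()
#' cell_volume_um3(cell_shape())
cell_shape <- function(lateral_semi_axis_um = 15, vertical_semi_axis_um = 5,
                       nucleus_lateral_semi_axis_um = 7,
                       nucleus_vertical_semi_axis_um = 1.5,
                       nucleus_center_height_um = 2.0) {
  s <- list(
    a = lateral_semi_axis_um, c = vertical_semi_axis_um,
    an = nucleus_lateral_semi_axis_um, cn = nucleus_vertical_semi_axis_um,
    zn = nucleus_center_height_um
  )
  if (s$an >= s$a || s$zn - s$cn < 0 || s$zn + s$cn > s$c) {
    stop("nucleus does not fit inside the half-ellipsoid cell", call. = FALSE)
  }
  # analytic containment: on the nucleus surface, max of r^2/a^2 + z^2/c^2
  th <- seq(0, pi, length.out = 721)
  r <- s$an * sin(th)
  z <- s$zn + s$cn * cos(th)
  if (any(r^2 / s$a^2 + z^2 / s$c^2 >= 1) || any(z <= 0)) {
    stop("nucleus surface touches or crosses the cell boundary",
         call. = FALSE)
  }
  structure(s, class = "proton_cell_shape")
}

#' @rdname cell_shape
#' @param shape A `proton_cell_shape`.
#' @export
cell_volume_um3 <- function(shape = cell_shape()) {
  2 / 3 * pi * shape$a^2 * shape$c
}

#' @rdname cell_shape
#' @export
nucleus_volume_um3 <- function(shape = cell_shape()) {
  4 / 3 * pi * shape$an^2 * shape$cn
}

#' Default 3x3 cell lattice
#'
#' Nine cells on a square lattice centered on the dish axis: one central
#' cell (1), four side cells (2-5) on the lattice axes and four diagonal
#' cells (6-9) on the lattice diagonals. The 40 um default pitch leaves a
#' 10 um gap between neighbouring 15 um cells and keeps the whole array
#' well inside the 550 um dish.
#'
#' @param pitch_um Lattice pitch, um.
#' @return A tibble with columns `cell`, `x_um`, `y_um`, `group`.
#' @export
#' @examples
#' default_cell_positions()
default_cell_positions <- function(pitch_um = 40) {
  p <- pitch_um
  tibble::tibble(
    cell = 1:9,
    x_um = c(0, p, -p, 0, 0, p, p, -p, -p),
    y_um = c(0, 0, 0, p, -p, p, -p, p, -p),
    group = c("central", rep("side", 4), rep("diagonal", 4))
  )
}

#' Cell-array irradiation geometry
#'
#' The cell-dish setup: a uniform disk source of vertical (downward) protons
#' above a 1 um air gap, a cylindrical water dish (radius 550 um) whose
#' water column of thickness `medium_thickness_um` covers the cell plane, a
#' 5 um cell plane holding the nine cells (water-filled around and above
#' the cells), and a 0.2 um glass substrate underneath.
#'
#' @param medium_thickness_um Water medium-layer thickness above the cell
#'   plane, um (>= 0).
#' @param dish_radius_um Dish radius, um.
#' @param substrate_thickness_um Glass substrate thickness, um.
#' @param air_gap_um Source-to-medium air gap, um.
#' @param source_radius_um Source-disk radius, um.
#' @param shape A [cell_shape()].
#' @param positions Cell positions as from [default_cell_positions()].
#' @return An object of class `proton_cell_array`.
#' @export
#' @examples
#' cell_array_geometry(1500)
cell_array_geometry <- function(medium_thickness_um,
                                dish_radius_um = 550,
                                substrate_thickness_um = 0.2,
                                air_gap_um = 1,
                                source_radius_um = 10000,
                                shape = cell_shape(),
                                positions = default_cell_positions()) {
  if (medium_thickness_um < 0) {
    stop("medium thickness must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(shape, "proton_cell_shape"))
  counts <- table(positions$group)
  if (nrow(positions) != 9 ||
      !identical(sort(names(counts)), c("central", "diagonal", "side")) ||
      counts[["central"]] != 1 || counts[["side"]] != 4 ||
      counts[["diagonal"]] != 4) {
    stop("positions must hold 9 cells: 1 central, 4 side, 4 diagonal",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(positions[, c("x_um", "y_um")]))
  if (any(d[upper.tri(d)] < 2 * shape$a)) {
    stop("cells overlap: minimum center distance is ", 2 * shape$a, " um",
         call. = FALSE)
  }
  if (any(sqrt(positions$x_um^2 + positions$y_um^2) + shape$a >
          dish_radius_um)) {
    stop("cells must lie inside the dish radius", call. = FALSE)
  }
  structure(
    list(
      medium_thickness_um = medium_thickness_um,
      dish_radius_um = dish_radius_um,
      substrate_thickness_um = substrate_thickness_um,
      air_gap_um = air_gap_um,
      source_radius_um = source_radius_um,
      shape = shape,
      positions = positions
    ),
    class = "proton_cell_array"
  )
}

#' @export
print.proton_cell_array <- function(x, ...) {
  cat(sprintf(
    paste0("<proton_cell_array> medium %g um, dish r = %g um, 9 cells ",
           "(pitch lattice), substrate %g um\n"),
    x$medium_thickness_um, x$dish_radius_um, x$substrate_thickness_um
  ))
  invisible(x)
}

#' Farmer-type ionization chamber geometry
#'
#' Cylindrical thimble chamber irradiated side-on (beam perpendicular to the
#' chamber axis at mid-length): a PMMA wall of thickness
#' `wall_thickness_mm` inside the 3.05 mm outer radius, enclosing an air
#' cavity of ~0.5 cm^3. The central electrode, stem and end caps are not
#' modeled.
#'
#' @param outer_radius_mm,length_mm,wall_thickness_mm Chamber dimensions, mm.
#' @param air_gap_um Source-to-wall air gap, um.
#' @param source_radius_um Source-disk radius, um (shared convention with
#'   the cell-array setup so that the per-emitted-particle normalization
#'   cancels in R).
#' @return An object of class `proton_ioc`.
#' @export
#' @examples
#' ioc_geometry()
ioc_geometry <- function(outer_radius_mm = 3.05, length_mm = 23.0,
                         wall_thickness_mm = 0.425, air_gap_um = 1,
                         source_radius_um = 10000) {
  cavity_radius_mm <- outer_radius_mm - wall_thickness_mm
  if (cavity_radius_mm <= 0) {
    stop("wall thickness must be smaller than the outer radius",
         call. = FALSE)
  }
  cavity_volume_cm3 <- pi * (cavity_radius_mm / 10)^2 * (length_mm / 10)
  if (abs(cavity_volume_cm3 - 0.5) / 0.5 > 0.2) {
    warning(sprintf(
      "cavity volume %.3f cm^3 deviates >20%% from the nominal ~0.5 cm^3",
      cavity_volume_cm3
    ), call. = FALSE)
  }
  structure(
    list(
      outer_radius_mm = outer_radius_mm,
      cavity_radius_mm = cavity_radius_mm,
      length_mm = length_mm,
      wall_thickness_mm = wall_thickness_mm,
      cavity_volume_cm3 = cavity_volume_cm3,
      air_gap_um = air_gap_um,
      source_radius_um = source_radius_um
    ),
    class = "proton_ioc"
  )
}

#' @export
print.proton_ioc <- function(x, ...) {
  cat(sprintf(
    paste0("<proton_ioc> outer r = %g mm, wall %g mm PMMA, length %g mm, ",
           "cavity %.3f cm^3 air\n"),
    x$outer_radius_mm, x$wall_thickness_mm, x$length_mm, x$cavity_volume_cm3
  ))
  invisible(x)
}

# chord bookkeeping for a vertical ray at lateral distance r from a cell
# center: cell height above substrate, nucleus half-chord, and the three
# in-cell pieces (cytoplasm above / nucleus / cytoplasm below).
.cell_chords <- function(shape, r) {
  hit <- r < shape$a
  h_cell <- ifelse(hit, shape$c * sqrt(pmax(1 - (r / shape$a)^2, 0)), 0)
  hn <- ifelse(r < shape$an,
               shape$cn * sqrt(pmax(1 - (r / shape$an)^2, 0)), 0)
  cy_above <- ifelse(hn > 0, h_cell - (shape$zn + hn), h_cell)
  cy_below <- ifelse(hn > 0, shape$zn - hn, 0)
  list(h_cell = h_cell, nucleus = 2 * hn,
       cyto_above = pmax(cy_above, 0), cyto_below = pmax(cy_below, 0))
}

#' Segment a vertical ray through the cell dish
#'
#' Decomposes the downward ray entering at `(x_um, y_um)` on the source disk
#' into contiguous material segments: air gap, water medium (plus the
#' water filler of the cell plane above/around the cells), the
#' cytoplasm/nucleus/cytoplasm chords if the ray crosses a cell (closed-form
#' ellipsoid intersections), and the glass substrate.
#'
#' @param geometry A [cell_array_geometry()].
#' @param x_um,y_um Entry point on the source disk, um.
#' @return A tibble with columns `material`, `region`, `length_um` and
#'   `cell` (NA outside cells).
#' @export
#' @examples
#' segment_ray_dish(cell_array_geometry(1000), 0, 0)
segment_ray_dish <- function(geometry, x_um, y_um) {
  stopifnot(inherits(geometry, "proton_cell_array"))
  if (x_um^2 + y_um^2 > geometry$source_radius_um^2) {
    stop("entry point lies outside the source disk", call. = FALSE)
  }
  s <- geometry$shape
  t <- geometry$medium_thickness_um
  if (x_um^2 + y_um^2 > geometry$dish_radius_um^2) {
    return(tibble::tibble(
      material = "air", region = "none",
      length_um = geometry$air_gap_um, cell = NA_integer_
    ))
  }
  pos <- geometry$positions
  rr <- sqrt((pos$x_um - x_um)^2 + (pos$y_um - y_um)^2)
  k <- which(rr < s$a)
  if (length(k) == 0) {
    seg <- tibble::tibble(
      material = c("air", "water", "glass"),
      region = "none",
      length_um = c(geometry$air_gap_um, t + s$c,
                    geometry$substrate_thickness_um),
      cell = NA_integer_
    )
    return(seg)
  }
  k <- k[1]  # non-overlap guarantees at most one hit
  ch <- .cell_chords(s, rr[k])
  seg <- tibble::tibble(
    material = c("air", "water", "cytoplasm", "nucleus", "cytoplasm",
                 "glass"),
    region = c("none", "none", "cytoplasm", "nucleus", "cytoplasm", "none"),
    length_um = c(geometry$air_gap_um, t + (s$c - ch$h_cell),
                  ch$cyto_above, ch$nucleus, ch$cyto_below,
                  geometry$substrate_thickness_um),
    cell = c(NA_integer_, NA_integer_, pos$cell[k], pos$cell[k],
             pos$cell[k], NA_integer_)
  )
  seg[seg$length_um > 0 | seg$material == "air", ]
}

#' Segment a horizontal-impact ray through the ionization chamber
#'
#' Beam perpendicular to the chamber axis: air gap, entrance PMMA wall
#' chord, air-cavity chord and exit wall chord from the analytic
#' circle-chord formula 2*sqrt(r^2 - d^2).
#'
#' @param geometry An [ioc_geometry()].
#' @param impact_offset_mm Signed lateral distance of the ray from the
#'   chamber axis, mm; must satisfy |offset| <= outer radius.
#' @return A tibble with columns `material`, `region`, `length_um`.
#' @export
#' @examples
#' segment_ray_ioc(ioc_geometry(), 0)
segment_ray_ioc <- function(geometry, impact_offset_mm) {
  stopifnot(inherits(geometry, "proton_ioc"))
  v <- abs(impact_offset_mm)
  ro <- geometry$outer_radius_mm
  ri <- geometry$cavity_radius_mm
  if (v > ro) {
    stop("impact offset beyond the chamber outer radius", call. = FALSE)
  }
  chord_out <- 2 * sqrt(pmax(ro^2 - v^2, 0))
  chord_in <- if (v < ri) 2 * sqrt(ri^2 - v^2) else 0
  wall <- (chord_out - chord_in) / 2
  seg <- tibble::tibble(
    material = c("air", "pmma", "air", "pmma"),
    region = c("none", "none", "cavity", "none"),
    length_um = c(geometry$air_gap_um, wall * 1000, chord_in * 1000,
                  wall * 1000)
  )
  seg[seg$length_um > 0 | seg$material == "air", ]
}

#' Masses of the scoring regions
#'
#' Closed-form masses used to convert tallied energy deposits into F6-style
#' doses (MeV/g): cytoplasm = (half-ellipsoid minus nucleus) volume times
#' density, nucleus = ellipsoid volume times density, chamber cavity =
#' cavity volume times air density.
#'
#' @param geometry A [cell_array_geometry()] or [ioc_geometry()].
#' @param materials Named list of materials (densities are taken from it).
#' @return A tibble with columns `region` and `mass_g`.
#' @export
#' @examples
#' region_masses(cell_array_geometry(1000))
#' region_masses(ioc_geometry())
region_masses <- function(geometry, materials = default_materials()) {
  UseMethod("region_masses")
}

#' @export
region_masses.proton_cell_array <- function(geometry,
                                            materials = default_materials()) {
  s <- geometry$shape
  v_cell <- cell_volume_um3(s)
  v_nuc <- nucleus_volume_um3(s)
  tibble::tibble(
    region = c("cytoplasm", "nucleus"),
    volume_um3 = c(v_cell - v_nuc, v_nuc),
    mass_g = c(
      (v_cell - v_nuc) * 1e-12 * materials$cytoplasm$density,
      v_nuc * 1e-12 * materials$nucleus$density
    )
  )
}

#' @export
region_masses.proton_ioc <- function(geometry,
                                     materials = default_materials()) {
  tibble::tibble(
    region = "cavity",
    volume_um3 = geometry$cavity_volume_cm3 * 1e12,
    mass_g = geometry$cavity_volume_cm3 * materials$air$density
  )
}
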