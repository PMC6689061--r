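# Physical constants in MeV / cm / g units.
.const <- list(
  K = 0.307075,      # 4*pi*N_A*r_e^2*m_e*c^2, MeV cm^2 mol^-1
  me = 0.51099895,   # electron rest energy, MeV
  mp = 938.27209,    # proton rest energy, MeV
  e_min = 0.05,      # low-energy validity cutoff, MeV
  e_max = 50         # high-energy validity cutoff, MeV
)

#' Elemental data used for stopping-power calculations
#'
#' Atomic number, standard atomic weight and ICRU-recommended mean excitation
#' energy for the elements occurring in the built-in materials.
#'
#' @return A tibble with columns `symbol`, `z`, `a` (g/mol) and `i_ev` (eV).
#' @export
#' @examples
#' element_data()
element_data <- function() {
  tibble::tibble(
    symbol = c("H", "C", "N", "O", "P", "Si", "Ar"),
    z      = c(1, 6, 7, 8, 15, 14, 18),
    a      = c(1.008, 12.011, 14.007, 15.999, 30.973762, 28.085, 39.948),
    i_ev   = c(19.2, 78, 82, 95, 173, 173, 188)
  )
}

.element_lookup <- function(symbols) {
  el <- element_data()
  idx <- match(symbols, el$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "),
         "; supported: ", paste(el$symbol, collapse = ", "), call. = FALSE)
  }
  el[idx, ]
}

#' Convert atom fractions to mass fractions (and back)
#'
#' @param fractions Named numeric vector of element fractions summing to 1.
#' @return Named numeric vector of fractions in the other convention.
#' @export
#' @examples
#' atom_to_mass_fractions(c(H = 2 / 3, O = 1 / 3)) # water
atom_to_mass_fractions <- function(fractions) {
  el <- .element_lookup(names(fractions))
  m <- fractions * el$a
  m / sum(m)
}

#' @rdname atom_to_mass_fractions
#' @export
mass_to_atom_fractions <- function(fractions) {
  el <- .element_lookup(names(fractions))
  n <- fractions / el$a
  n / sum(n)
}

#' Define a material for proton transport
#'
#' A material is an elemental mixture with a bulk density, an effective
#' electron density ratio Z/A (mass-fraction weighted) and a mean excitation
#' energy. The mean excitation energy is combined from ICRU elemental values
#' by Bragg additivity unless overridden (`i_ev`), which is standard practice
#' for materials such as liquid water (75 eV) or dry air (85.7 eV) whose
#' condensed-phase I-values differ from the additivity estimate.
#'
#' @param name Material identifier.
#' @param fractions Named numeric vector of element fractions (must sum to 1
#'   within 1e-6, all non-negative).
#' @param convention Either `"mass"` or `"atom"`: how `fractions` are read.
#' @param density Bulk density in g/cm^3 (> 0).
#' @param i_ev Optional mean excitation energy override, eV.
#' @param max_step_um Condensed-history step-length ceiling inside this
#'   material, micrometres. Thin scoring regions (cell compartments) use a
#'   sub-micrometre ceiling so that a 5 um cell is resolved.
#' @return An object of class `proton_material`.
#' @export
#' @examples
#' material("water", c(H = 0.111894, O = 0.888106), "mass", 1.0, i_ev = 75)
material <- function(name, fractions, convention = c("mass", "atom"),
                     density, i_ev = NULL, max_step_um = 20) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(fractions), length(fractions) >= 1)
  if (any(fractions < 0)) {
    stop("element fractions must be non-negative", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("element fractions of '", name, "' sum to ", sum(fractions),
         ", not 1 (tolerance 1e-6)", call. = FALSE)
  }
  if (!is.numeric(density) || density <= 0) {
    stop("density must be > 0 (g/cm^3)", call. = FALSE)
  }
  mass_frac <- if (convention == "atom") {
    atom_to_mass_fractions(fractions)
  } else {
    fractions / sum(fractions)
  }
  el <- .element_lookup(names(mass_frac))
  zoa <- mass_frac * el$z / el$a
  za_eff <- sum(zoa)
  i_additive <- exp(sum(zoa * log(el$i_ev)) / za_eff)
  structure(
    list(
      name = name,
      composition = tibble::tibble(
        element = names(fractions),
        fraction = unname(fractions),
        convention = convention
      ),
      mass_fractions = mass_frac,
      density = density,
      za_eff = za_eff,
      i_ev = if (is.null(i_ev)) i_additive else i_ev,
      i_additive_ev = i_additive,
      max_step_um = max_step_um
    ),
    class = "proton_material"
  )
}

#' @export
print.proton_material <- function(x, ...) {
  cat(sprintf(
    "<proton_material> %s: rho = %g g/cm^3, Z/A = %.4f, I = %.1f eV\n",
    x$name, x$density, x$za_eff, x$i_ev
  ))
  comp <- paste0(x$composition$element, " ",
                 signif(x$composition$fraction, 4), collapse = ", ")
  cat("  ", x$composition$convention[1], " fractions: ", comp, "\n", sep = "")
  invisible(x)
}

#' Built-in materials
#'
#' The six materials of the irradiation setups: the water medium and dish,
#' cellular cytoplasm and nucleus, the PMMA chamber wall, the glass (SiO2)
#' substrate and dry air. Cytoplasm and PMMA compositions are read as atom
#' fractions and the nucleus composition as mass fractions; each material
#' records its convention and can be overridden through the run
#' configuration. Densities not fixed by the setup take standard values
#' (tissue compartments 1.00, glass 2.20, dry air 1.205e-3 g/cm^3).
#'
#' @return `default_materials()` returns a named list of
#'   [material()] objects; `builtin_material()` returns one of them.
#' @export
#' @examples
#' names(default_materials())
#' builtin_material("water")
default_materials <- function() {
  list(
    water = material("water", c(H = 0.111894, O = 0.888106), "mass",
                     density = 1.0, i_ev = 75),
    cytoplasm = material("cytoplasm",
                         c(H = 0.596, O = 0.2424, C = 0.1111,
                           N = 0.0404, P = 0.0101),
                         "atom", density = 1.0, max_step_um = 0.5),
    nucleus = material("nucleus",
                       c(H = 0.1064, O = 0.745, C = 0.0904,
                         N = 0.0321, P = 0.0261),
                       "mass", density = 1.0, max_step_um = 0.5),
    pmma = material("pmma", c(C = 0.333, O = 0.133, H = 0.534), "atom",
                    density = 1.18, i_ev = 74),
    glass = material("glass", c(Si = 1 / 3, O = 2 / 3), "atom",
                     density = 2.20, i_ev = 139.2),
    air = material("air",
                   c(C = 0.000124, N = 0.755268, O = 0.231781, Ar = 0.012827),
                   "mass", density = 1.205e-3, i_ev = 85.7,
                   max_step_um = 1000)
  )
}

#' @rdname default_materials
#' @param name One of `"water"`, `"cytoplasm"`, `"nucleus"`, `"pmma"`,
#'   `"glass"`, `"air"`.
#' @export
builtin_material <- function(name) {
  mats <- default_materials()
  if (!name %in% names(mats)) {
    stop("no built-in material '", name, "'; available: ",
         paste(names(mats), collapse = ", "), call. = FALSE)
  }
  mats[[name]]
}

#' Serialize a material to/from a plain list
#'
#' Round-trippable representation used by the run configuration (YAML).
#'
#' @param x A `proton_material` (or, for `material_from_list()`, a list as
#'   produced by `material_to_list()`).
#' @return A plain list / a `proton_material`.
#' @export
material_to_list <- function(x) {
  stopifnot(inherits(x, "proton_material"))
  out <- list(
    name = x$name,
    convention = x$composition$convention[1],
    density = x$density,
    max_step_um = x$max_step_um,
    composition = as.list(stats::setNames(
      x$composition$fraction, x$composition$element
    ))
  )
  if (abs(x$i_ev - x$i_additive_ev) > 1e-9) out$i_ev <- x$i_ev
  out
}

#' @rdname material_to_list
#' @export
material_from_list <- function(x) {
  material(
    name = x$name,
    fractions = unlist(x$composition),
    convention = x$convention,
    density = x$density,
    i_ev = x$i_ev,
    max_step_um = if (is.null(x$max_step_um)) 20 else x$max_step_um
  )
}
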