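#' Derive a reproducible sub-seed
#'
#' Expands a single global seed into independent per-task substreams by
#' integer hashing, so that re-running any subset of a sweep (one energy,
#' one thickness) reproduces exactly the numbers of the full sweep.
#'
#' @param seed Integer global seed.
#' @param ... Numeric task keys (e.g. energy, thickness, cell index).
#' @return An integer in \[1, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(1, 15000, 2500, 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  for (k in c(...)) {
    h <- (h * 69069 + round(as.numeric(k)) %% m + 1) %% m
    h <- (h * 3877 + 29573) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Run configuration
#'
#' Bundles the study grids, transport controls and geometry overrides.
#' Defaults reproduce the study design: energies 10-35 MeV in 5 MeV steps
#' and the eleven medium thicknesses 100-5000 um.
#'
#' @param energies Incident energies, MeV.
#' @param thicknesses Medium thicknesses, um.
#' @param histories Histories per (energy, thickness) point.
#' @param ioc_histories Histories for detector runs.
#' @param seed Global seed.
#' @param straggling `"bohr"`, `"vavilov"` or `"off"`.
#' @param geometry Named list of [cell_array_geometry()] overrides.
#' @param materials Optional list of material definitions (as from
#'   [material_to_list()]) replacing built-ins of the same name.
#' @param output_dir Directory for CSV outputs.
#' @return An object of class `proton_run_config`.
#' @export
#' @examples
#' run_config(energies = 15, histories = 1000)
run_config <- function(energies = default_energies(),
                       thicknesses = default_thicknesses(),
                       histories = 1e5, ioc_histories = 2e5, seed = 1L,
                       straggling = "bohr", geometry = list(),
                       materials = list(), output_dir = "protoncal-out") {
  if (any(thicknesses < 0)) {
    stop("validation error for key 'thicknesses': must be >= 0",
         call. = FALSE)
  }
  if (any(energies <= 0)) {
    stop("validation error for key 'energies': must be > 0", call. = FALSE)
  }
  if (histories < 1 || ioc_histories < 1) {
    stop("validation error for key 'histories': must be >= 1",
         call. = FALSE)
  }
  if (!straggling %in% c("bohr", "vavilov", "off")) {
    stop("validation error for key 'straggling': must be one of ",
         "bohr/vavilov/off", call. = FALSE)
  }
  structure(
    list(
      energies = as.numeric(energies), thicknesses = as.numeric(thicknesses),
      histories = as.numeric(histories),
      ioc_histories = as.numeric(ioc_histories),
      seed = as.integer(seed), straggling = straggling,
      geometry = geometry, materials = materials, output_dir = output_dir
    ),
    class = "proton_run_config"
  )
}

#' @export
print.proton_run_config <- function(x, ...) {
  cat(sprintf(
    paste0("<proton_run_config> %d energies x %d thicknesses, %g histories",
           "/point, seed %d, straggling %s\n"),
    length(x$energies), length(x$thicknesses), x$histories, x$seed,
    x$straggling
  ))
  invisible(x)
}

#' Load / save a run configuration (YAML)
#'
#' An empty file yields the all-defaults configuration (the study grids).
#' Unknown keys are rejected by name; values are validated on load.
#' `save_run_config()` and `load_run_config()` round-trip.
#'
#' @param path File path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' @rdname load_run_config
#' @param config A [run_config()].
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "proton_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Configuration hash and run manifest
#'
#' `config_hash()` returns a stable hash of a run configuration;
#' `write_manifest()` records seed, hash and versions next to the outputs
#' so a run can be reproduced exactly.
#'
#' @param config A [run_config()].
#' @return A hash string / the manifest path, invisibly.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "proton_run_config"))
  x <- unclass(config)
  x$output_dir <- NULL  # where results land does not affect what they are
  rlang::hash(x)
}

#' @rdname config_hash
#' @param dir Output directory.
#' @export
write_manifest <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(
    list(
      seed = config$seed,
      config_hash = config_hash(config),
      package = "protoncal",
      version = as.character(utils::packageVersion("protoncal")),
      r_version = as.character(getRversion())
    ),
    path
  )
  invisible(path)
}

#' Write a CSV output stamped with the configuration hash
#'
#' The first line is a `# config_hash: <hash>` comment; read the file back
#' with `readr::read_csv(path, comment = "#")`.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param config A [run_config()].
#' @return `path`, invisibly.
#' @export
write_stamped_csv <- function(x, path, config) {
  readr::write_lines(paste0("# config_hash: ", config_hash(config)), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

# materials list after applying config overrides
.config_materials <- function(config) {
  mats <- default_materials()
  for (m in config$materials) {
    mm <- material_from_list(m)
    mats[[mm$name]] <- mm
  }
  mats
}

.config_transport <- function(config, histories = config$histories) {
  transport_config(
    histories = histories, seed = config$seed,
    straggling = config$straggling
  )
}

#' Frozen low-statistics reference fixtures
#'
#' Writes a small set of deterministic regression fixtures: the six-energy
#' water range table, a low-history detector-dose table and a two-point
#' 15 MeV R curve. Regeneration with the same seed is bit-identical.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run_config(histories = 1800, ioc_histories = 4000, seed = seed)
  water <- builtin_material("water")
  sm <- stopping_model(water)
  ranges <- tibble::tibble(
    energy_mev = default_energies(),
    range_um = csda_range(water, default_energies(), "um", model = sm)
  )
  tcfg <- .config_transport(cfg, histories = cfg$histories)
  det <- simulate_ioc_dose(
    default_energies(), .config_transport(cfg, cfg$ioc_histories)
  )
  sw <- sweep_R(15, c(100, 2500), config = tcfg,
                ioc_histories = cfg$ioc_histories)
  paths <- c(
    range_table = file.path(dir, "range_table.csv"),
    ioc_dose = file.path(dir, "ioc_dose.csv"),
    r_curve_15mev = file.path(dir, "r_curve_15mev.csv")
  )
  write_stamped_csv(ranges, paths["range_table"], cfg)
  write_stamped_csv(det, paths["ioc_dose"], cfg)
  write_stamped_csv(tibble::as_tibble(sw), paths["r_curve_15mev"], cfg)
  write_manifest(cfg, dir)
  invisible(paths)
}
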