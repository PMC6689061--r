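#' Detector dose D_E in the ionization chamber
#'
#' Transports protons of each incident energy through the Farmer-type
#' chamber (side-on: air gap, PMMA wall chord, air-cavity chord, exit wall)
#' and scores the F6-style cavity dose per emitted source particle. This is
#' the denominator of the calibration coefficient R = D_A/D_E; the same
#' source-disk normalization convention is used as for the cell dish so the
#' geometric factor is consistent.
#'
#' @param energies Incident proton energies, MeV. A warning is issued
#'   outside the 10-35 MeV study window.
#' @param config A [transport_config()].
#' @param geometry An [ioc_geometry()].
#' @param materials Named list of materials.
#' @return A tibble of class `proton_ioc_dose` with columns `energy_mev`,
#'   `dose_mev_g`, `rel_err`, `histories`.
#' @export
#' @examples
#' simulate_ioc_dose(c(15, 25), transport_config(histories = 2000))
simulate_ioc_dose <- function(energies, config = transport_config(),
                              geometry = ioc_geometry(),
                              materials = default_materials()) {
  stopifnot(inherits(geometry, "proton_ioc"))
  if (any(energies < 10 | energies > 35)) {
    warning("energy outside the 10-35 MeV study window", call. = FALSE)
  }
  out <- purrr::map_dfr(energies, function(e) {
    tal <- run_batch(geometry, e, config, materials)
    d <- dose_per_source_particle(tal)
    tibble::tibble(
      energy_mev = e, dose_mev_g = d$dose_mev_g, rel_err = d$rel_err,
      histories = d$histories
    )
  })
  class(out) <- c("proton_ioc_dose", class(out))
  out
}
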