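test_that("R is the detector-normalized dose ratio with quadrature errors", {
  expect_equal(compute_R(2, 2)$R, 1)
  expect_equal(compute_R(0, 5)$R, 0)
  r <- compute_R(3, 2, 0.03, 0.04)
  expect_equal(r$R, 1.5)
  expect_equal(r$rel_err, 0.05)
  expect_error(compute_R(1, 0), "> 0")
  expect_error(compute_R(1, -2), "> 0")
  # vectorized
  rr <- compute_R(c(1, 2), c(2, 2))
  expect_equal(rr$R, c(0.5, 1))
})

.fake_records <- function(r_values) {
  pos <- default_cell_positions()
  tibble::tibble(
    energy_mev = 15, thickness_um = 1000, compartment = "cytoplasm",
    cell = pos$cell, group = pos$group, R = r_values, rel_err = 0.01
  )
}

test_that("group averages reproduce direct arithmetic means", {
  rec <- .fake_records(c(2, 1.1, 1.2, 1.3, 1.4, 0.5, 0.6, 0.7, 0.8))
  g <- group_average_R(rec)
  expect_equal(g$R[g$group == "central"], 2)
  expect_equal(g$R[g$group == "side"], mean(c(1.1, 1.2, 1.3, 1.4)))
  expect_equal(g$R[g$group == "diagonal"], mean(c(0.5, 0.6, 0.7, 0.8)))
  expect_equal(g$R[g$group == "all"],
               mean(c(2, 1.1, 1.2, 1.3, 1.4, 0.5, 0.6, 0.7, 0.8)))
  # all cells equal: every group mean equals that value
  g1 <- group_average_R(.fake_records(rep(1.7, 9)))
  expect_true(all(abs(g1$R - 1.7) < 1e-12))
  expect_error(group_average_R(.fake_records(1:9)[-1, ]), "exactly 9")
})

test_that("peak finding returns the argmax with small-thickness tie-breaks", {
  curve <- tibble::tibble(thickness_um = c(100, 500, 1000, 1500),
                          R = c(1, 3, 2, 0))
  expect_equal(find_peak_thickness(curve), 500)
  mono <- tibble::tibble(thickness_um = c(100, 500, 1000),
                         R = c(1, 2, 3))
  expect_equal(find_peak_thickness(mono), 1000)
  tie <- tibble::tibble(thickness_um = c(2000, 500, 1000),
                        R = c(2, 1, 2))
  expect_equal(find_peak_thickness(tie), 1000)
  expect_error(find_peak_thickness(tie[0, ]), "empty")
  expect_error(find_peak_thickness(tie[1, ]), "2 grid points")
})

test_that("sweeps produce the full record structure and round-trip D_A", {
  sw <- sweep_R(15, c(100, 2500),
                config = transport_config(histories = 2700, seed = 1),
                ioc_histories = 5000)
  expect_s3_class(sw, "proton_rtable")
  # 1 energy x 2 thicknesses x 2 compartments x 4 groups
  expect_equal(nrow(sw), 16)
  expect_setequal(unique(sw$group), c("central", "side", "diagonal", "all"))
  pc <- per_cell_R(sw)
  expect_equal(nrow(pc), 2 * 2 * 9)
  det <- detector_dose(sw)
  expect_equal(nrow(det), 1)
  # round-trip: R times D_E reconstructs the cell dose exactly
  doses <- simulate_cell_doses(15, 2500,
                               transport_config(histories = 2700, seed = 1))
  cy <- pc[pc$thickness_um == 2500 & pc$compartment == "cytoplasm", ]
  rebuilt <- cy$R[match(1:9, cy$cell)] * det$dose_mev_g
  expect_equal(rebuilt,
               doses$dose_mev_g[doses$region == "cytoplasm"][match(
                 1:9, doses$cell[doses$region == "cytoplasm"]
               )],
               tolerance = 1e-12)
  # glance reports peak thickness and maximum R per compartment
  gl <- glance(sw)
  expect_equal(nrow(gl), 2)
  expect_true(all(gl$peak_thickness_um == 2500))
  expect_s3_class(tidy(sw), "tbl_df")
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})

test_that("R is invariant under rescaling of the source-particle count", {
  # the emitted-particle normalization cancels in the ratio: simulating
  # more histories changes only the statistical error, not the estimate
  cfg_a <- transport_config(histories = 3600, seed = 4)
  cfg_b <- transport_config(histories = 9000, seed = 5)
  sa <- sweep_R(15, 2000, config = cfg_a, ioc_histories = 12000)
  sb <- sweep_R(15, 2000, config = cfg_b, ioc_histories = 12000)
  ra <- sa$R[sa$group == "all" & sa$compartment == "cytoplasm"]
  rb <- sb$R[sb$group == "all" & sb$compartment == "cytoplasm"]
  ea <- sa$rel_err[sa$group == "all" & sa$compartment == "cytoplasm"]
  eb <- sb$rel_err[sb$group == "all" & sb$compartment == "cytoplasm"]
  expect_lt(abs(ra - rb), 3.5 * sqrt((ra * ea)^2 + (rb * eb)^2))
})

test_that("per-cell R values at fixed conditions agree within statistics", {
  sw <- sweep_R(15, 2000, config = transport_config(histories = 18000,
                                                    seed = 6),
                ioc_histories = 20000)
  pc <- per_cell_R(sw)
  cy <- pc[pc$compartment == "cytoplasm", ]
  m <- mean(cy$R)
  expect_true(all(abs(cy$R - m) / m < 4 * cy$rel_err + 1e-3))
})
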