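shape <- cell_shape()

test_that("closed-form compartment volumes agree with rejection sampling", {
  expect_equal(cell_volume_um3(shape), 2356.19, tolerance = 1e-5)
  expect_equal(nucleus_volume_um3(shape), 307.88, tolerance = 1e-4)
  mc <- mc_compartment_volumes(shape, n = 1e6)
  expect_equal(unname(mc["cytoplasm"]),
               cell_volume_um3(shape) - nucleus_volume_um3(shape),
               tolerance = 0.01)
  expect_equal(unname(mc["nucleus"]), nucleus_volume_um3(shape),
               tolerance = 0.01)
})

test_that("nucleus containment is enforced by the shape constructor", {
  expect_error(cell_shape(nucleus_vertical_semi_axis_um = 3.5), "fit")
  expect_error(cell_shape(nucleus_center_height_um = 4), "fit|touches")
  expect_error(cell_shape(nucleus_lateral_semi_axis_um = 16), "fit")
})

test_that("the 3x3 lattice is centered, contained and non-overlapping", {
  pos <- default_cell_positions(40)
  expect_equal(nrow(pos), 9)
  expect_equal(as.integer(table(pos$group)[c("central", "side", "diagonal")]),
               c(1L, 4L, 4L))
  expect_equal(pos$x_um[pos$group == "central"], 0)
  expect_equal(pos$y_um[pos$group == "central"], 0)
  expect_true(all(sqrt(pos$x_um^2 + pos$y_um^2) <= 550 - 15))
  d <- as.matrix(dist(pos[, c("x_um", "y_um")]))
  gap <- min(d[upper.tri(d)]) - 2 * shape$a
  expect_equal(gap, 40 - 30)  # nearest-neighbour gap at 40 um pitch
  expect_error(cell_array_geometry(100,
                                   positions = default_cell_positions(25)),
               "overlap")
})

test_that("dish ray segmentation matches closed-form and voxel-walk chords", {
  geom <- cell_array_geometry(1000)
  on_axis <- segment_ray_dish(geom, 0, 0)
  expect_equal(sum(on_axis$length_um[on_axis$region == "nucleus"]), 3)
  expect_equal(sum(on_axis$length_um[on_axis$region == "cytoplasm"]), 2)
  # miss ray: more than 15 um from every center, inside the dish
  miss <- segment_ray_dish(geom, 100, 100)
  expect_true(all(miss$region == "none"))
  # total traversal = air gap + medium + cell-plane height + substrate
  for (pt in list(c(0, 0), c(40, 0), c(3, 4), c(100, 100), c(43, -38))) {
    seg <- segment_ray_dish(geom, pt[1], pt[2])
    expect_equal(sum(seg$length_um), 1 + 1000 + 5 + 0.2, tolerance = 1e-9)
  }
  # voxel-walk containment oracle at off-center offsets
  for (r_off in c(0, 2.5, 5, 10, 14)) {
    seg <- segment_ray_dish(geom, r_off, 0)
    walk <- chord_walk(shape, r_off)
    expect_equal(sum(seg$length_um[seg$region == "cytoplasm"]),
                 unname(walk["cytoplasm"]), tolerance = 0.02)
    expect_equal(sum(seg$length_um[seg$region == "nucleus"]),
                 unname(walk["nucleus"]), tolerance = 0.02)
  }
  expect_error(segment_ray_dish(geom, 11000, 0), "source disk")
})

test_that("ray segmentation is symmetric under lattice rotations", {
  geom <- cell_array_geometry(500)
  probe <- function(x, y) {
    seg <- segment_ray_dish(geom, x, y)
    sum(seg$length_um[seg$region != "none"])
  }
  # 90-degree rotations map side cells onto side cells
  expect_equal(probe(40 + 3, 2), probe(-2, 40 + 3))
  expect_equal(probe(40 + 3, 2), probe(-(40 + 3), -2))
  # and diagonal cells onto diagonal cells
  expect_equal(probe(40 + 1, 40 - 2), probe(-(40 - 2), 40 + 1))
})

test_that("chamber ray segmentation follows the circle-chord formula", {
  geom <- ioc_geometry()
  mid <- segment_ray_ioc(geom, 0)
  expect_equal(mid$length_um[mid$material == "pmma"], c(425, 425))
  expect_equal(mid$length_um[mid$region == "cavity"], 5250)
  graze <- segment_ray_ioc(geom, 3.05)
  expect_equal(sum(graze$length_um[graze$region == "cavity"]), 0)
  off <- segment_ray_ioc(geom, 2.0)
  chord_out <- 2 * sqrt(3.05^2 - 2^2) * 1000
  chord_in <- 2 * sqrt(2.625^2 - 2^2) * 1000
  expect_equal(sum(off$length_um[off$material == "pmma"]),
               chord_out - chord_in, tolerance = 1e-9)
  expect_equal(off$length_um[off$region == "cavity"], chord_in,
               tolerance = 1e-9)
  expect_error(segment_ray_ioc(geom, 3.2), "beyond")
})

test_that("region masses follow the closed-form volumes", {
  m <- region_masses(cell_array_geometry(1000))
  expect_equal(m$mass_g[m$region == "nucleus"], 3.0788e-10,
               tolerance = 1e-4)
  expect_equal(m$mass_g[m$region == "cytoplasm"],
               (2356.19 - 307.88) * 1e-12, tolerance = 1e-5)
  mi <- region_masses(ioc_geometry())
  expect_equal(mi$mass_g, 0.5 * 1.205e-3, tolerance = 0.2)
  expect_equal(ioc_geometry()$cavity_volume_cm3, 0.5, tolerance = 0.2)
  expect_warning(ioc_geometry(wall_thickness_mm = 1.5), "cavity volume")
})
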