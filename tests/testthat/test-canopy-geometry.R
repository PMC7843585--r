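test_that("plant spacing is the reciprocal of row spacing times density", {
  expect_equal(plant_spacing(6, 0.6), 1 / (0.6 * 6))
  expect_equal(plant_spacing(1 / 0.6, 0.6), 1)
  # printed field spacings at 0.6 m rows (the reference-density report
  # rounds differently in the field notes and is not asserted)
  expect_equal(plant_spacing_reported(c(6, 7.5, 9, 15)),
               c(0.28, 0.22, 0.19, 0.11))
  expect_error(plant_spacing(0, 0.6), class = "maizecanopy_domain_error")
  # exact invariant before rounding
  for (d in c(4.5, 6, 7.5, 9, 15)) {
    expect_equal(plant_spacing(d) * 0.6 * d, 1)
  }
})

test_that("leaf insertion heights accumulate internode lengths", {
  base <- flat_profile(c(LL = 80, LW = 10, SL = 18, SW = 3, IL = 10, ID = 2))
  lih <- leaf_insertion_heights(base)
  expect_equal(unname(lih[c("6", "18")]), c(10, 130))
  expect_true(all(diff(lih) >= 0))
  expect_equal(unname(leaf_insertion_heights(base, basal_offset = 20)["6"]), 30)
  # linearity: doubling every internode doubles every height
  twice <- flat_profile(c(LL = 80, LW = 10, SL = 18, SW = 3, IL = 20, ID = 2))
  expect_equal(leaf_insertion_heights(twice), 2 * lih)
})

test_that("leaf area is shape factor times the bounding rectangle", {
  expect_equal(leaf_area(80, 10, 0.75), 600)
  expect_equal(leaf_area(0, 10), 0)
  expect_equal(leaf_area(80, 10, 1), 800)
  expect_error(leaf_area(80, 10, 1.2), class = "maizecanopy_domain_error")
  expect_error(leaf_area(80, 10, 0), class = "maizecanopy_domain_error")
})

test_that("default leaf angles honor the ear-adjacent anchors and stay clamped", {
  a <- default_leaf_angles()
  expect_equal(unname(a[c("11", "12", "13")]), c(18, 22, 10))
  expect_true(all(a >= 5 & a <= 40))
  expect_length(a, length(modeled_ranks()))
  over <- default_leaf_angles(overrides = c(`11` = 12))
  expect_equal(unname(over["11"]), 12)
})

test_that("build_plant realizes one leaf per modeled rank, reproducibly", {
  base <- generate_base_profile()
  plant <- build_plant(base, azimuth_seed = 7)
  expect_equal(nrow(plant$organs), 13)
  expect_equal(plant$total_leaf_number, 18L)
  expect_equal(unname(plant$organs$angle_deg[plant$organs$rank == 12]), 22)
  expect_true(all(diff(plant$organs$base_height_cm) > 0))
  expect_equal(plant$organs$lih_cm,
               unname(leaf_insertion_heights(base)))
  # bit-identical under the same seed, different under another
  again <- build_plant(base, azimuth_seed = 7)
  expect_identical(plant, again)
  other <- build_plant(base, azimuth_seed = 8)
  expect_false(identical(plant$organs$azimuth_deg, other$organs$azimuth_deg))
  # height is seed-invariant
  expect_equal(plant$height_cm, other$height_cm)
})

test_that("a droopless vertical leaf is a straight midrib of lamina length", {
  base <- flat_profile()
  angles <- stats::setNames(rep(0, 13), 6:18)
  plant <- build_plant(base, angles = angles, droop = 0)
  m <- plant$midribs[["10"]]
  expect_equal(max(abs(m[, "x"])), 0, tolerance = 1e-12)
  expect_equal(max(abs(m[, "y"])), 0, tolerance = 1e-12)
  expect_equal(unname(m[nrow(m), "z"] - m[1, "z"]), 80)  # LL of the flat profile
})

test_that("canopy grids honor plot geometry and the spacing invariant", {
  base <- flat_profile()
  scene <- build_canopy(base, 15, plot_length = 9, plot_width = 0.6)
  expect_equal(nrow(scene$positions), 81)  # floor(9 / 0.1111)
  expect_equal(scene$plant_spacing * scene$row_spacing * scene$density, 1)
  expect_true(all(scene$positions$x_m < 9))

  expect_warning(tiny <- build_canopy(base, 0.05, plot_length = 1, plot_width = 0.6),
                 "too small")
  expect_equal(length(tiny$plants), 0)

  # determinism of the whole scene
  s1 <- build_canopy(base, 4.5, plot_length = 1, plot_width = 0.6, seed = 3)
  s2 <- build_canopy(base, 4.5, plot_length = 1, plot_width = 0.6, seed = 3)
  expect_identical(s1, s2)
})

test_that("OBJ export round-trips structure and bounding box", {
  base <- generate_base_profile()
  scene <- build_canopy(base, 4.5, plot_length = 0.4, plot_width = 0.6, seed = 1)
  expect_equal(length(scene$plants), 1)
  path <- withr::local_tempfile(fileext = ".obj")
  export_mesh(scene, path)
  info <- read_obj_summary(path)
  expect_gte(sum(grepl("_leaf_r", info$groups)), 13)
  expect_true("reference_bar_100cm" %in% info$groups)
  expect_gt(info$n_faces, 0)
  # re-export is byte-identical (vertex count and bbox trivially preserved)
  path2 <- withr::local_tempfile(fileext = ".obj")
  export_mesh(scene, path2)
  info2 <- read_obj_summary(path2)
  expect_identical(info$n_vertices, info2$n_vertices)
  expect_equal(info$bbox, info2$bbox, tolerance = 1e-6)
  # bar top defines a 100 cm landmark; plant tops respect stored height
  expect_gte(info$bbox["max", "z"], 100)
  expect_error(export_mesh(structure(list(plants = list()), class = "canopy_scene"),
                           tempfile()),
               class = "maizecanopy_domain_error")
})
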