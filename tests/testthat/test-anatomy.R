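test_that("circular annulus reproduces its diameter in all four metrics", {
  mesh <- build_root(root_params("TAV", annulus_dmax = 25, annulus_dmin = 25))
  m <- annulus_metrics(mesh)
  expect_equal(unname(m["perimeter_diam"]), 25, tolerance = 0.01)
  for (k in names(m)) expect_equal(unname(m[k]), 25, tolerance = 0.01)

  mesh20 <- build_root(root_params("TAV", annulus_dmax = 20,
                                   annulus_dmin = 20))
  m20 <- annulus_metrics(mesh20)
  for (k in names(m20)) expect_equal(unname(m20[k]), 20, tolerance = 0.01)
})

test_that("elliptical annulus matches closed-form ellipse metrics", {
  ## semi-axes 14.35 / 11.15: area-derived diameter = 2*sqrt(a*b)
  mesh <- build_root(root_params("BAV0", annulus_dmax = 28.7,
                                 annulus_dmin = 22.3))
  m <- annulus_metrics(mesh)
  expect_equal(unname(m["area_diam"]), 2 * sqrt(14.35 * 11.15),
               tolerance = 0.005)
  expect_equal(unname(m["area_diam"]), 25.30, tolerance = 0.005)
  expect_equal(unname(m["dmax"]), 28.7, tolerance = 0.005)
  expect_equal(unname(m["dmin"]), 22.3, tolerance = 0.005)

  ## semi-axes 12 / 8: area-derived = 2*sqrt(96) ~ 19.60
  mesh2 <- build_root(root_params("TAV", annulus_dmax = 24,
                                  annulus_dmin = 16))
  expect_equal(unname(annulus_metrics(mesh2)["area_diam"]), 2 * sqrt(96),
               tolerance = 0.005)
})

test_that("perimeter-derived diameter dominates area-derived (isoperimetric)", {
  for (dm in list(c(26, 26), c(28, 22), c(30, 19), c(24, 23))) {
    m <- annulus_metrics(build_root(root_params("TAV", annulus_dmax = dm[1],
                                                annulus_dmin = dm[2])))
    expect_gte(m["perimeter_diam"], m["area_diam"] - 1e-9)
  }
})

test_that("morphologies have the expected interleaflet-triangle patches", {
  expect_identical(region_patch_count(build_root(root_params("TAV"))), 3L)
  expect_identical(region_patch_count(build_root(root_params("BAV0"))), 2L)
  expect_identical(region_patch_count(build_root(root_params("BAV1"))), 2L)
})

test_that("region labels partition the mesh area exactly", {
  for (mo in c("TAV", "BAV0", "BAV1")) {
    mesh <- build_root(root_params(mo))
    areas <- triangle_areas(mesh)
    by_region <- tapply(areas, mesh$region, sum)
    expect_setequal(names(by_region),
                    c("LVOT", "LEAFLET", "INTERLEAFLET_TRIANGLE",
                      "ASCENDING_AORTA"))
    expect_true(all(by_region > 0))
    expect_equal(sum(by_region), sum(areas))
    expect_true(all(areas > 0))
  }
})

test_that("invalid root parameters are rejected with clear messages", {
  expect_error(root_params("BAV0", raphe_present = TRUE), "raphe")
  expect_error(root_params("BAV1", raphe_present = FALSE), "raphe")
  expect_error(root_params("TAV", annulus_dmax = 20, annulus_dmin = 25),
               "annulus_dmin")
  expect_error(root_params("TAV", mesh_resolution = c(20, 60)),
               "circumferential")
  expect_error(root_params("TAV", mesh_resolution = c(96, 8)), "axial")
  expect_error(root_params("TAV", commissure_height = 25, stj_height = 22),
               "stj")
})

test_that("calcium placement conserves the requested volume", {
  base <- root_params("TAV")
  mesh <- build_root(base)
  ## empty deposit list: unchanged
  expect_identical(place_calcium(mesh, list()), mesh)
  ## one deposit of 500 mm^3 on a leaflet belly
  layout <- attr(mesh, "layout")
  nadir <- layout$commissures[1] + pi / 3
  dep <- calcium_deposit(center_angle = nadir, center_height = 9,
                         extent_angle = 1.1, extent_height = 10,
                         volume = 500, protrusion = 5)
  out <- place_calcium(mesh, list(dep))
  assigned <- attr(out, "calcium_assigned")
  expect_gte(assigned, 450)
  expect_lte(assigned, 550)
  expect_true(any(out$material == "CALCIUM"))
  ## protrusion 0: material relabeled, geometry untouched
  dep0 <- calcium_deposit(nadir, 9, 1.1, 10, volume = 500, protrusion = 0)
  out0 <- place_calcium(mesh, list(dep0))
  expect_identical(out0$vertices, mesh$vertices)
  expect_true(any(out0$material == "CALCIUM"))
  ## off-leaflet footprint rejected (deep in the LVOT)
  bad <- calcium_deposit(nadir, -8, 0.5, 4, volume = 100, protrusion = 2)
  expect_error(place_calcium(mesh, list(bad)), "off the leaflet")
})

test_that("cohort sampling is reproducible and respects its specification", {
  spec <- cohort_spec(n_tav = 17, n_bav0 = 11, n_bav1 = 15, seed = 7)
  co1 <- sample_cohort(spec)
  co2 <- sample_cohort(spec)
  expect_identical(co1$table, co2$table)          # byte-identical
  expect_identical(nrow(co1$table), 43L)
  expect_identical(sum(co1$table$morphology == "TAV"), 17L)
  expect_identical(sum(co1$table$morphology == "BAV0"), 11L)
  expect_identical(sum(co1$table$morphology == "BAV1"), 15L)
  ## covariates within configured bounds
  cv <- default_covariates()
  for (m in c("TAV", "BAV0", "BAV1")) {
    sub <- co1$table[co1$table$morphology == m, ]
    expect_true(all(sub$calcium_volume >= cv[[m]]$calcium_volume[3] &
                      sub$calcium_volume <= cv[[m]]$calcium_volume[4]))
    expect_true(all(sub$depth >= 0 & sub$depth <= 14))
    expect_true(all(sub$annulus_dmin <= sub$annulus_dmax))
  }
  expect_true(all(co1$table$device_size %in% c(23, 26, 29, 32)))
  ## sizing-index arithmetic: size / perimeter-derived diameter
  expect_equal(co1$table$sizing_index,
               co1$table$device_size / co1$table$perimeter_diam)
  expect_equal(26 / 24.7, 1.053, tolerance = 5e-4)
  ## a different seed changes the draw
  expect_false(identical(co1$table,
                         sample_cohort(cohort_spec(seed = 8))$table))
})
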