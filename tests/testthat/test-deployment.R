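test_that("tissue stiffness follows the thin-shell closed form", {
  wall <- tissue_material(2, 2)
  leaflet <- tissue_material(0.6, 1.5)
  expect_equal(tissue_stiffness(wall, 12.5), 2 * 2 / 156.25)
  expect_equal(tissue_stiffness(wall, 12.5), 0.0256)
  expect_equal(tissue_stiffness(leaflet, 12.5), 0.6 * 1.5 / 156.25)
  expect_lt(tissue_stiffness(leaflet, 12.5), tissue_stiffness(wall, 12.5))
  expect_error(tissue_stiffness(wall, 0), "local_radius")
  expect_error(tissue_material(-1, 2), "elastic_modulus")
  expect_error(tissue_material(2, 2, yield_stress = 0), "yield")
})

test_that("perfect plasticity caps the contact pressure at the yield stress", {
  ## stiff tissue pressed beyond its elastic range (k_t * delta > yield):
  ## the node equilibrates on the plastic plateau, pressure == yield exactly
  sol <- tavrseal:::solve_node(r_nom = 13, r_a = 5, k_t = 2,
                               yield = 0.6, thickness = 8,
                               scale = 5, contact = contact_params())
  expect_equal(sol$pressure, 0.6, tolerance = 1e-9)
  expect_lte(sol$residual, contact_params()$residual_tol)
  ## same configuration without the cap stops in the elastic branch
  sol_el <- tavrseal:::solve_node(r_nom = 13, r_a = 5, k_t = 2,
                                  yield = NULL, thickness = 8,
                                  scale = 5, contact = contact_params())
  expect_gt(sol_el$pressure, 0.6)
  expect_lt(sol_el$r, sol$r)
})

test_that("free expansion recovers the nominal geometry", {
  fr <- crimp(build_frame(frame_params(26)), 8)
  anatomy <- cylinder_mesh(15, z0 = -15, z1 = 60)   # lumen 30 > nominal 26
  st <- deploy(fr, anatomy, depth = 6)
  nominal <- matrix(rep(st$frame$reference_radii, 32), 40, 32)
  expect_lt(max(abs(st$frame$radii - nominal)), 0.01)
  ## gaps >= lumen - nominal radius, up to the 48-gon chord shortfall
  expect_true(all(st$contact_record$gap >= 15 * cos(pi / 48) - 13 - 1e-9,
                  na.rm = TRUE))
  expect_lte(st$convergence$final_residual, contact_params()$residual_tol)
})

test_that("a rigid wall confines the frame to the lumen", {
  fr <- crimp(build_frame(frame_params(26)), 8)
  anatomy <- cylinder_mesh(10, z0 = -15, z1 = 60)   # lumen 20 < nominal
  st <- deploy(fr, anatomy, depth = 6,
               materials = list(WALL = tissue_material(2000, 2)))
  d <- 2 * st$frame$radii
  ## lumen wall is a 48-gon: its chords sit at the apothem of the 20 mm bore
  expect_true(all(d >= 2 * 10 * cos(pi / 48) - 1e-6))
  expect_true(all(d <= 20.5))
  expect_lte(max(st$contact_record$penetration), 0.05)
})

test_that("stiffer tissue never increases the deployed radius", {
  fr <- crimp(build_frame(frame_params(26)), 8)
  anatomy <- cylinder_mesh(11, z0 = -15, z1 = 60, region = "LEAFLET",
                           material = "LEAFLET_TISSUE")
  radius_with <- function(E, yield = NULL) {
    st <- deploy(fr, anatomy, depth = 6,
                 materials = list(LEAFLET_TISSUE =
                                    tissue_material(E, 1.5, yield)))
    mean(st$frame$radii[st$contact_record$penetration > 0])
  }
  soft <- radius_with(0.6)
  medium <- radius_with(2)
  stiff <- radius_with(10)
  expect_gte(soft, medium)
  expect_gte(medium, stiff)
  ## calcified (stiff elastic + plastic cap) vs soft native leaflet
  calcified <- radius_with(4, yield = 0.6)
  expect_lte(calcified, soft)
})

test_that("deployment is deterministic and respects the requested depth", {
  fr <- crimp(build_frame(frame_params(26)), 8)
  anatomy <- cylinder_mesh(12, z0 = -15, z1 = 60)
  s1 <- deploy(fr, anatomy, depth = 6)
  s2 <- deploy(fr, anatomy, depth = 6)
  expect_identical(s1$frame$radii, s2$frame$radii)
  expect_identical(s1$contact_record, s2$contact_record)
  ## match_depth: straight tube, no axial migration
  for (target in c(6, 0, 6.1)) {
    st <- match_depth(fr, anatomy, target)
    expect_lte(abs(-min(st$frame$z) - target), 0.1)
  }
  ## frame that cannot fit: crimped wider than the lumen
  tight <- cylinder_mesh(3, z0 = -15, z1 = 60)
  expect_error(deploy(fr, tight, depth = 6), "does not fit")
})

test_that("deployed radii never exceed nominal", {
  pr <- quick_patient(seed = 21, morphology = "BAV1")
  st <- pr$result$state
  nominal <- matrix(rep(st$frame$reference_radii,
                        ncol(st$frame$radii)),
                    nrow(st$frame$radii), ncol(st$frame$radii))
  expect_true(all(st$frame$radii <= nominal + 1e-9))
  expect_lte(abs(-min(st$frame$z) - pr$covariates$depth), 0.1)
})
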