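test_that("polygon measurements match regular-polygon closed forms", {
  n <- 96; r <- 10
  th <- 2 * pi * (seq_len(n) - 1) / n
  poly <- cbind(r * cos(th), r * sin(th))
  m <- measure_section(poly)
  expect_equal(unname(m["dmax"]), 2 * r, tolerance = 1e-12)
  expect_equal(unname(m["dmin"]), 2 * r * cos(pi / n), tolerance = 1e-9)
  expect_equal(unname(m["perimeter"]), 2 * n * r * sin(pi / n),
               tolerance = 1e-9)
  expect_equal(unname(m["area"]), 0.5 * n * r^2 * sin(2 * pi / n),
               tolerance = 1e-9)
  ## within 0.2% of the circle values at 96 vertices
  expect_equal(unname(m["perimeter"]), 2 * pi * r, tolerance = 0.002)
  expect_equal(unname(m["area"]), pi * r^2, tolerance = 0.002)
  expect_equal(unname(m["dmin"]), 2 * r, tolerance = 0.002)
})

test_that("square and ellipse sections measure correctly", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  m <- measure_section(sq)
  expect_equal(unname(m["dmax"]), sqrt(200), tolerance = 1e-12)
  expect_equal(unname(m["dmin"]), 10, tolerance = 1e-12)
  expect_equal(unname(m["perimeter"]), 40)
  expect_equal(unname(m["area"]), 100)
  ## ellipse semi-axes 12 / 8: area converges to pi*96
  th <- 2 * pi * (seq_len(256) - 1) / 256
  el <- cbind(12 * cos(th), 8 * sin(th))
  me <- measure_section(el)
  expect_equal(unname(me["area"]), pi * 96, tolerance = 0.001)
  expect_equal(unname(me["dmax"]), 24, tolerance = 1e-6)
  expect_equal(unname(me["dmin"]), 16, tolerance = 0.001)
  expect_error(measure_section(sq[1:2, ]), "degenerate")
})

test_that("cross-sections of a cylindrical frame are circular", {
  prof <- data.frame(height = c(0, 40), radius = c(13, 13))
  fr <- build_frame(frame_params(26, nominal_profile = prof,
                                 n_levels = 12, n_sectors = 16))
  poly <- cross_section(fr, 20)
  expect_identical(nrow(poly), 16L)           # one point per sector
  expect_true(all(abs(sqrt(rowSums(poly^2)) - 13) < 1e-9))
  ## ordered polygon is simple: its area equals the convex-hull area
  hull <- poly[grDevices::chull(poly), ]
  expect_equal(tavrseal:::polygon_area(poly),
               tavrseal:::polygon_area(hull), tolerance = 1e-9)
  expect_error(cross_section(fr, 100), "extent")
  ## measurement invariants on a deployed (non-circular) frame
  st <- cylinder_deployment(r_frame = 10, r_anat = 12)
  for (z in c(0, 5, 10)) {
    m <- measure_section(cross_section(st$frame, z))
    expect_lte(m["dmin"], m["dmax"])
    expect_gte(m["perimeter"]^2, 4 * pi * m["area"] - 1e-9)
  }
})

test_that("measure_frame_levels reports all four standard levels", {
  fr <- build_frame(frame_params(26))
  tab <- measure_frame_levels(fr)
  expect_identical(tab$level, c("ventricular_end", "nadir",
                                "central_coaptation", "commissures"))
  expect_true(all(tab$dmin <= tab$dmax))
  expect_true(all(diff(tab$z) > 0))
  expect_error(level_specs(c(ventricular_end = 0.5, nadir = 0.2,
                             central_coaptation = 0.6, commissures = 0.9)),
               "increasing")
})

test_that("compare_frames recovers known differences and correlations", {
  fr <- build_frame(frame_params(26))
  pred <- do.call(rbind, lapply(c(23, 26, 29), function(s)
    measure_frame_levels(build_frame(frame_params(s)))))
  ## identical: zero difference, perfect correlation
  cmp <- compare_frames(pred, pred)
  expect_true(all(cmp$mean_diff == 0))
  expect_true(all(cmp$r_squared == 1))
  ## constant offset: mean difference recovered, R^2 unchanged
  obs <- pred
  for (m in c("dmax", "dmin", "perimeter", "area")) obs[[m]] <- pred[[m]] + 0.5
  cmp2 <- compare_frames(pred, obs)
  expect_equal(cmp2$mean_diff, rep(0.5, 4))
  expect_equal(cmp2$sd_diff, rep(0, 4))
  expect_true(all(abs(cmp2$r_squared - 1) < 1e-12))
  expect_error(compare_frames(pred, obs[1:3, ]), "paired")
  expect_error(compare_frames(pred[1:2, ], obs[1:2, ]), "at least 3")
})

test_that("R^2 equals the squared constructed correlation", {
  pairs <- make_correlated_pairs(10, 0.95)
  expect_equal(r_squared(pairs$y, pairs$x), 0.9025, tolerance = 0.001)
  ## affine shifts of either list leave R^2 unchanged
  expect_equal(r_squared(3 * pairs$y - 7, pairs$x),
               r_squared(pairs$y, pairs$x), tolerance = 1e-12)
  expect_equal(r_squared(pairs$y, -2 * pairs$x + 1),
               r_squared(pairs$y, pairs$x), tolerance = 1e-12)
})
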