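test_that("apposition threshold is strict at exactly 1 mm", {
  rec <- data.frame(distance = c(0.99, 1.00, 0, 2.5))
  out <- classify_apposition(rec, 1)
  expect_identical(out$apposed, c(TRUE, FALSE, TRUE, FALSE))
  ## threshold 0: nothing can be apposed (distances are non-negative)
  out0 <- classify_apposition(rec, 0)
  expect_false(any(out0$apposed))
})

test_that("summary conserves areas and percentages", {
  rec <- data.frame(element_id = 1:60,
                    x = cos(seq_len(60)), y = sin(seq_len(60)), z = 5,
                    area = rep(2, 60),
                    region = rep(c("LVOT", "INTERLEAFLET_TRIANGLE",
                                   "LEAFLET"), each = 20),
                    distance = rep(c(0.5, 1.5), 30),
                    fallback = FALSE)
  rec <- classify_apposition(rec)
  s <- summarize_sealing(rec)
  expect_equal(s$total_skirt_area, 120)
  expect_equal(s$malapposition_total_pct, 50, tolerance = 0.5)
  expect_equal(sum(s$by_region$apposed_area) +
                 sum(s$by_region$malapposed_area), s$total_skirt_area)
  expect_equal(sum(s$by_region$malapposition_pct),
               s$malapposition_total_pct, tolerance = 0.1)
  expect_equal(sum(s$by_region$apposition_contribution_pct), 100,
               tolerance = 0.1)
  expect_equal(s$malapposition_total_pct + s$apposition_total_pct, 100)
  ## all apposed: zero malapposition
  s0 <- summarize_sealing(classify_apposition(transform(rec, distance = 0.2)))
  expect_equal(s0$malapposition_total_pct, 0)
  expect_error(summarize_sealing(rec[0, ]), "empty")
})

test_that("ascending aorta is excluded and UNRESOLVED elements are absorbed", {
  rec <- data.frame(element_id = 1:4,
                    x = c(1, 0, -1, 0.99), y = c(0, 1, 0, 0.05), z = 0,
                    area = c(10, 10, 10, 10),
                    region = c("LEAFLET", "ASCENDING_AORTA", "LVOT",
                               "UNRESOLVED"),
                    distance = c(0.5, 3, 0.2, 2),
                    fallback = c(FALSE, FALSE, FALSE, TRUE))
  s <- summarize_sealing(classify_apposition(rec))
  ## ascending aorta excluded from totals, reported separately
  expect_equal(s$total_skirt_area, 30)
  expect_equal(unname(s$ascending_aorta["malapposed_area"]), 10)
  ## the UNRESOLVED element joins its angular neighbour (LEAFLET at x ~ 1)
  expect_equal(s$by_region$malapposed_area[s$by_region$region == "LEAFLET"],
               10)
  expect_identical(s$n_unresolved, 1L)
})

test_that("Table-3-style arithmetic: per-region sums reproduce the total", {
  ## construct elements whose per-region areas equal the published TAV
  ## column; total malapposition must come out at 174.3/1118.3 = 15.6%
  areas <- list(LVOT = c(app = 157.4, mal = 52.0),
                INTERLEAFLET_TRIANGLE = c(app = 175.1, mal = 65.5),
                LEAFLET = c(app = 611.5, mal = 56.8))
  rows <- list()
  for (reg in names(areas)) {
    rows[[paste0(reg, "a")]] <- data.frame(
      element_id = NA, x = 1, y = 0, z = 0, area = areas[[reg]]["app"],
      region = reg, distance = 0.3, fallback = FALSE)
    rows[[paste0(reg, "m")]] <- data.frame(
      element_id = NA, x = 1, y = 0, z = 0, area = areas[[reg]]["mal"],
      region = reg, distance = 2.0, fallback = FALSE)
  }
  rec <- classify_apposition(do.call(rbind, rows))
  s <- summarize_sealing(rec)
  expect_equal(s$malapposition_total_pct, 174.3 / 1118.3 * 100,
               tolerance = 1e-9)
  expect_equal(round(s$malapposition_total_pct, 1), 15.6)
})

test_that("malapposition is monotone non-increasing in the threshold", {
  pr <- quick_patient(seed = 5, morphology = "BAV0")
  rec <- pr$result$records
  pct <- vapply(seq(0, 3, by = 0.25), function(th) {
    summarize_sealing(classify_apposition(rec, th))$malapposition_total_pct
  }, numeric(1))
  expect_true(all(diff(pct) <= 1e-9))
})

test_that("sealing records resolve every element on synthetic cases", {
  pr <- quick_patient(seed = 9, morphology = "TAV")
  rec <- pr$result$records
  expect_true(all(rec$area > 0))
  expect_true(all(rec$distance >= 0))
  expect_lt(mean(rec$region == "UNRESOLVED"), 0.05)
  expect_identical(rec$apposed, rec$distance < 1)
})

test_that("2D projection unrolls a cylindrical skirt to a rectangle", {
  st <- cylinder_deployment(r_frame = 10, r_anat = 12)
  rec <- sealing_records(st)
  map2d <- project_skirt_2d(st, rec)
  expect_identical(length(unique(map2d$element_id)),
                   nrow(st$frame$skirt_elements))
  expect_equal(diff(range(map2d$u)), 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
  skirt_h <- max(map2d$v) - min(map2d$v)
  expect_equal(skirt_h, st$frame$params$skirt_height,
               tolerance = 0.07 * st$frame$params$skirt_height)
  ## unrolled area within 5% of the 3D skirt area
  area2d <- sum(vapply(split(map2d, map2d$element_id), function(e)
    tavrseal:::polygon_area(cbind(e$u, e$v)), numeric(1)))
  area3d <- sum(rec$area)
  expect_lt(abs(area2d - area3d) / area3d, 0.05)
  ## uniform 2 mm gap: everything malapposed at the 1 mm threshold
  expect_true(all(!rec$apposed))
  ## quad centroids sit slightly inside the nominal circle (chord midpoints)
  expect_equal(median(rec$distance), 2, tolerance = 0.03)
})

test_that("surrogate PVL grading matches its anchor cases", {
  expect_identical(as.character(pvl_surrogate(4.4)), "none_or_trace")
  expect_identical(as.character(pvl_surrogate(20.9)), "mild")
  expect_identical(as.character(pvl_surrogate(40)), "moderate")
  expect_identical(as.character(pvl_surrogate(0)), "none_or_trace")
  expect_identical(as.character(pvl_surrogate(0, c(0.5, 3))),
                   "none_or_trace")
  expect_error(pvl_surrogate(10, c(25, 10)), "t1 < t2")
})
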