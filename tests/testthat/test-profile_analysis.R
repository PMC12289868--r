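test_that("vertical profile averages valid windows per Z level", {
  counts <- data.frame(
    n_micropore = c(4L, 6L, 5L, 5L), n_air = c(0L, 0L, 0L, 0L),
    n_solid = c(96L, 94L, 95L, 95L), n_mask = c(0L, 0L, 0L, 0L))
  m <- fake_map(counts, k = c(0L, 0L, 1L, 1L))
  vp <- extract_vertical_profile(m)
  expect_equal(nrow(vp), 2L)
  expect_equal(vp$mip_mean[1], 5)
  expect_equal(vp$mip_sem[1], sd(c(4, 6)) / sqrt(2))
  expect_equal(vp$mip_sem[1], 1)
  expect_equal(vp$n_windows, c(2L, 2L))
  ## fewer than 2 usable Z levels is an error
  expect_error(extract_vertical_profile(fake_map(counts[1:2, ],
                                                 k = c(0L, 0L))),
               "fewer than 2")
})

test_that("coordinate normalization reproduces the closed form", {
  prof <- data.frame(z = 0:9)
  out <- normalize_coordinates(prof, reference_range = c(0, 9))
  expect_equal(out$z_norm, (0:9) / 9)
  expect_equal(out$z_mm, (0:9) / 9 * 8 + 0.45)
  ## endpoints of the largest fragment map to 0.45 and 8.45 mm
  expect_equal(out$z_mm[1], 0.45)
  expect_equal(out$z_mm[10], 8.45)
  ## midpoint arithmetic
  mid <- normalize_coordinates(data.frame(z = c(0, 5, 10)),
                               reference_range = c(0, 10))
  expect_equal(mid$z_mm[2], 4.45)
  expect_error(normalize_coordinates(prof, reference_range = c(3, 3)),
               "zero Z range")
})

test_that("coordinate normalization commutes with affine re-indexing", {
  z <- c(0, 2, 5, 9)
  a <- normalize_coordinates(data.frame(z = z), reference_range = c(0, 9))
  b <- normalize_coordinates(data.frame(z = 3 * z + 2),
                             reference_range = 3 * c(0, 9) + 2)
  expect_equal(a$z_norm, b$z_norm)
  expect_equal(a$z_mm, b$z_mm)
})

test_that("variable transformation matches the delta / delta_max form", {
  tv <- transform_variable(c(5, 7, 10))
  expect_equal(tv$delta, c(0, 2, 5))
  expect_equal(tv$delta_max, 5)
  expect_equal(tv$v_norm, c(0, 0.4, 1))
  expect_error(transform_variable(c(3, 3, 3)), "zero range")
  ## min maps to 0, max to 1, and the transform is idempotent
  set.seed(2)
  v <- rnorm(25)
  tv2 <- transform_variable(v)
  expect_equal(min(tv2$v_norm), 0)
  expect_equal(max(tv2$v_norm), 1)
  expect_true(all(tv2$delta >= 0))
  expect_equal(transform_variable(tv2$v_norm)$v_norm, tv2$v_norm)
})

test_that("LOESS reproduces straight lines and localizes a noiseless bump", {
  x <- seq(0, 10, length.out = 30)
  line <- fit_loess(x, 2 * x + 1, span = 0.5)
  expect_lt(max(abs(line$fitted - (2 * line$grid + 1))), 1e-8)
  bump <- fit_loess(x, exp(-0.5 * ((x - 4) / 1)^2), span = 0.3)
  step <- diff(bump$grid[1:2])
  expect_lte(abs(bump$grid[which.max(bump$fitted)] - 4), step)
  expect_error(fit_loess(x, x, span = 1.5), "span")
  expect_error(fit_loess(1:4, 1:4), "too few points")
})

test_that("extremum localization handles ties and boundaries", {
  cv <- structure(list(grid = c(0.45, 4.45, 8.45), fitted = c(1, 5, 2),
                       span = 0.5, degree = 2, n = 3, variable = "mip"),
                  class = "loess_curve")
  ex <- locate_extremum(cv, "peak")
  expect_equal(ex$location_mm, 4.45)
  expect_equal(ex$value, 5)
  expect_false(ex$at_boundary)
  mono <- structure(list(grid = 1:5, fitted = 1:5, span = 0.5, degree = 2,
                         n = 5, variable = NULL), class = "loess_curve")
  em <- locate_extremum(mono, "peak")
  expect_true(em$at_boundary)
  expect_equal(em$location_mm, 5)
  tie <- structure(list(grid = 1:4, fitted = c(1, 5, 5, 1), span = 0.5,
                        degree = 2, n = 4, variable = NULL),
                   class = "loess_curve")
  expect_equal(locate_extremum(tie, "peak")$location_mm, 2)  # apical tie-break
  expect_equal(locate_extremum(tie, "valley")$location_mm, 1)
})

test_that("zone assignment partitions the profile around the green band", {
  z <- c(0.45, 1.45, 2.45, 3.45, 7.45)
  zones <- assign_zones(z, c(1.1, 2.9))
  expect_equal(as.character(zones),
               c("coral_tissue", "green_band", "green_band",
                 "skeleton", "skeleton"))
  expect_true(all(assign_zones(z, c(0.1, 9)) == "green_band"))
  expect_error(assign_zones(z, c(9.5, 9.9)), "outside the profile range")
  expect_error(assign_zones(z, c(2, 1)), "low < high")
})

test_that("phantom profiles peak where the oracle says and contrast by zone", {
  ph <- generate_phantom(synthetic_truth(seed = 17),
                         dims = c(100L, 100L, 280L))
  seg <- segment_tomogram(ph$tomogram)
  pm <- compute_porosity_map(seg)
  vp <- extract_vertical_profile(pm)
  tp <- truth_profile(ph)
  expect_equal(vp$z[which.max(vp$mip_mean)], tp$z[which.max(tp$mip)])
  ## windows inside the band carry a higher micropore excess than outside
  delta <- pm$mip[pm$valid] - min(pm$mip[pm$valid])
  zone <- assign_zones(pm$cz_mm[pm$valid], ph$truth$band_interval_mm)
  in_band <- zone == "green_band"
  tt <- stats::t.test(delta[in_band], delta[!in_band],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  ## pooled physical mm scale: recovered peak lies within one window of truth
  ex <- find_band_extrema(vp)
  expect_lt(abs(ex$location_mm[ex$variable == "mip"] -
                  ph$truth$band_center_mm), 0.9)
})

test_that("mm scale helper reproduces physical window centers", {
  counts <- data.frame(n_micropore = rep(5L, 4), n_air = rep(10L, 4),
                       n_solid = rep(85L, 4), n_mask = rep(0L, 4))
  m <- fake_map(counts, k = 0:3)
  vp <- extract_vertical_profile(m)
  sc <- mm_scale_from_reference(vp)
  out <- normalize_coordinates(vp, conversion_mm = sc$conversion_mm,
                               correction_mm = sc$correction_mm)
  expect_equal(out$z_mm, vp$z_mm_window)
})
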