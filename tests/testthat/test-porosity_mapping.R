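test_that("a single window converts phase counts into the four variables", {
  ## 100 voxels: 50 solid, 10 micropore, 40 air; window covers the volume
  lab <- array(c(rep(2L, 10), rep(3L, 50), rep(1L, 40)), c(5L, 5L, 4L))
  pv <- phase_volume(lab, 180, "one")     # 5 voxels = 0.9 mm
  pm <- compute_porosity_map(pv, 0.9)
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$mip, 10)
  expect_equal(pm$map, 40)
  expect_equal(pm$tp, 50)
  expect_equal(pm$svf, 50)
  expect_equal(pm$colony_fraction, 1)
})

test_that("conservation holds for every window of a segmented phantom", {
  ph <- small_phantom(seed = 12)
  seg <- segment_tomogram(ph$tomogram)
  pm <- compute_porosity_map(seg)
  ok <- pm$valid
  expect_true(all(abs(pm$mip[ok] + pm$map[ok] + pm$svf[ok] - 100) <= 1e-9))
  expect_identical(pm$tp, pm$mip + pm$map)
})

test_that("an all-solid phantom maps to SVF 100 and TP 0 everywhere", {
  truth <- synthetic_truth(noise_sd = 0, mip_baseline_pct = 0,
                           mip_amplitude_pct = 0, map_baseline_pct = 0,
                           map_dip_pct = 0, container = FALSE, seed = 1)
  ph <- generate_phantom(truth, dims = c(40L, 40L, 130L))
  ## fixed thresholds: a noiseless all-solid histogram is degenerate for
  ## any automatic criterion
  seg <- segment_tomogram(ph$tomogram,
                          run_config(segmentation_mode = "fixed",
                                     t_low = 50, t_high = 150,
                                     air_threshold = 50))
  pm <- compute_porosity_map(seg)
  ok <- pm$valid
  expect_true(all(pm$svf[ok] == 100))
  expect_true(all(pm$tp[ok] == 0))
  fm <- fragment_mean(pm)
  expect_equal(fm$mean[fm$variable == "svf"], 100)
  expect_equal(fm$mean[fm$variable == "tp"], 0)
})

test_that("halving the window and re-aggregating counts reproduces the coarse map", {
  ph <- small_phantom(seed = 13)
  lab <- ph$labels
  ## window sizes chosen to land on whole voxel counts (40 and 20 voxels)
  coarse <- compute_porosity_map(lab, window_size_mm = 0.972)
  w_c <- attr(coarse, "window_vox")
  fine <- compute_porosity_map(lab, window_size_mm = 0.486)
  expect_equal(attr(fine, "window_vox") * 2L, w_c)
  agg <- aggregate(
    cbind(n_solid, n_micropore, n_air, n_mask) ~
      floor(i / 2) + floor(j / 2) + floor(k / 2),
    data = as.data.frame(fine), FUN = sum)
  names(agg)[1:3] <- c("i", "j", "k")
  m <- merge(as.data.frame(coarse)[, c("i", "j", "k", "n_solid",
                                       "n_micropore", "n_air", "n_mask")],
             agg, by = c("i", "j", "k"), suffixes = c("_c", "_f"))
  expect_equal(nrow(m), nrow(coarse))
  expect_identical(m$n_solid_c, m$n_solid_f)
  expect_identical(m$n_micropore_c, m$n_micropore_f)
  expect_identical(m$n_air_c, m$n_air_f)
  expect_identical(m$n_mask_c, m$n_mask_f)
})

test_that("porosity map on ground-truth labels matches the oracle slab counts", {
  ph <- small_phantom(seed = 14)
  pm <- compute_porosity_map(ph$labels)
  tp <- truth_profile(ph)
  per_k <- aggregate(cbind(n_solid, n_micropore, n_air) ~ k,
                     data = as.data.frame(pm), FUN = sum)
  expect_equal(per_k$n_solid, tp$n_solid)
  expect_equal(per_k$n_micropore, tp$n_micropore)
  expect_equal(per_k$n_air, tp$n_air)
})

test_that("fragment means and standard errors follow the textbook formulas", {
  counts <- data.frame(
    n_micropore = c(5L, 7L, 9L), n_air = c(0L, 0L, 0L),
    n_solid = c(95L, 93L, 91L), n_mask = c(0L, 0L, 0L))
  m <- fake_map(counts)
  fm <- fragment_mean(m)
  expect_equal(fm$mean[fm$variable == "mip"], 7)
  expect_equal(fm$sem[fm$variable == "mip"], sd(c(5, 7, 9)) / sqrt(3))
  expect_equal(fm$sem[fm$variable == "mip"], 2 / sqrt(3))
  single <- fake_map(counts[1, ])
  fs <- fragment_mean(single)
  expect_equal(fs$sem, rep(0, 4))
  expect_equal(fs$n, rep(1L, 4))
})

test_that("degenerate windows are rejected", {
  lab <- array(3L, c(4L, 4L, 4L))
  pv <- phase_volume(lab, 100, "tiny")
  expect_error(compute_porosity_map(pv, window_size_mm = 0.00005),
               "smaller than one voxel")
  masked <- array(0L, c(4L, 4L, 4L))
  expect_error(compute_porosity_map(phase_volume(masked, 100, "m")),
               "no colony voxels")
})
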