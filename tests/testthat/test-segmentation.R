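test_that("masking filter matches a brute-force boundary flood on a cube phantom", {
  ## solid 10^3 cube centered in a 20^3 air field, with an enclosed 2^3 void
  I <- array(0, c(20, 20, 20))
  I[6:15, 6:15, 6:15] <- 200
  I[10:11, 10:11, 10:11] <- 0           # enclosed void
  tom <- tomogram(I, 100, "cube")
  colony <- apply_mask_filter(tom, air_threshold = 50,
                              container_policy = "none")
  ext_oracle <- brute_flood(I < 50, "boundary")
  expect_identical(unname(colony == FALSE), ext_oracle)
  ## enclosed void is colony (candidate macropore), exterior is mask
  expect_true(all(colony[10:11, 10:11, 10:11]))
  expect_false(colony[1, 1, 1])

  ## a channel from the void to the boundary turns it into mask
  I2 <- I
  I2[10, 10, 1:10] <- 0                 # channel to the z face
  colony2 <- apply_mask_filter(tomogram(I2, 100, "chan"),
                               air_threshold = 50,
                               container_policy = "none")
  expect_false(any(colony2[10:11, 10:11, 10:11] &
                     (I2[10:11, 10:11, 10:11] < 50)))
})

test_that("vectorized flood fill equals the reference on random volumes", {
  set.seed(42)
  for (r in 1:4) {
    open <- array(runif(7 * 8 * 9) < 0.6, c(7, 8, 9))
    expect_identical(coralpore:::flood_fill_3d(open, "boundary", 6L),
                     brute_flood(open, "boundary"))
    seed <- which(open)[1]
    expect_identical(coralpore:::flood_fill_3d(open, seed, 6L),
                     brute_flood(open, seed))
  }
})

test_that("an all-solid volume yields an empty mask; full masks error", {
  tom <- tomogram(array(200, c(8, 8, 8)), 100, "solid")
  colony <- apply_mask_filter(tom, air_threshold = 50)
  expect_true(all(colony))
  air <- tomogram(array(0, c(8, 8, 8)), 100, "air")
  expect_error(apply_mask_filter(air, air_threshold = 50), "no colony found")
})

test_that("automatic thresholds separate three noiseless levels exactly", {
  set.seed(5)
  I <- array(sample(c(0, 100, 200), 4000, TRUE, c(0.3, 0.2, 0.5)),
             c(20, 20, 10))
  tom <- tomogram(I, 100, "levels")
  thr <- select_thresholds(tom, "auto")
  expect_gt(thr[1], 0); expect_lt(thr[1], 100)
  expect_gt(thr[2], 100); expect_lt(thr[2], 200)
  colony <- array(TRUE, dim(I))
  seg <- segment_phases(tom, colony, thr[1], thr[2])
  truth <- array(ifelse(I == 0, 1L, ifelse(I == 100, 2L, 3L)), dim(I))
  expect_identical(seg$labels, truth)
})

test_that("fixed thresholds are returned unchanged and validated", {
  tom <- tomogram(array(runif(125, 0, 255), c(5, 5, 5)), 100, "f")
  expect_equal(unname(select_thresholds(tom, "fixed", t_low = 40,
                                        t_high = 160)), c(40, 160))
  expect_error(select_thresholds(tom, "fixed", t_low = 160, t_high = 40),
               "t_low < t_high")
  flat <- tomogram(array(rep(c(0, 1), 64), c(4, 4, 8)), 100, "flat")
  expect_error(select_thresholds(flat, "auto"), "degenerate histogram")
})

test_that("the two-threshold rule labels air, micropore and solid", {
  I <- array(c(10, 90, 180), c(3, 1, 1))
  tom <- tomogram(I, 100, "rule")
  seg <- segment_phases(tom, array(TRUE, dim(I)), 50, 150)
  expect_identical(as.vector(seg$labels),
                   unname(phase_codes()[c("air", "micropore", "solid")]))
  ## everything at maximum intensity is solid
  hi <- tomogram(array(255, c(3, 3, 3)), 100, "hi")
  seg2 <- segment_phases(hi, array(TRUE, c(3, 3, 3)), 50, 150)
  expect_true(all(seg2$labels == phase_codes()[["solid"]]))
})

test_that("phase labels partition the volume and respect threshold monotonicity", {
  set.seed(8)
  ph <- small_phantom(seed = 8)
  seg <- segment_tomogram(ph$tomogram)
  expect_identical(sum(tabulate(seg$labels + 1L, 4L)),
                   length(seg$labels))
  ## raising t_high never decreases the micropore+air count
  tom <- ph$tomogram
  colony <- apply_mask_filter(tom)
  below <- vapply(c(120, 150, 180), function(th) {
    s <- segment_phases(tom, colony, 50, th)
    sum(s$labels == 1L | s$labels == 2L)
  }, numeric(1))
  expect_true(all(diff(below) >= 0))
})

test_that("segmentation reproduces noiseless ground truth exactly", {
  ph <- generate_phantom(synthetic_truth(noise_sd = 0, seed = 21),
                         dims = c(60L, 60L, 160L))
  seg <- segment_tomogram(ph$tomogram)
  expect_identical(seg$labels, ph$labels$labels)
})

test_that("under 5%-gap noise the voxel disagreement stays far below 2%", {
  rates <- vapply(1:2, function(s) {
    ph <- small_phantom(seed = 30 + s)     # noise_sd = 10 = 5% of the gap
    seg <- segment_tomogram(ph$tomogram)
    mean(seg$labels != ph$labels$labels)
  }, numeric(1))
  expect_lt(max(rates), 0.02)
})
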