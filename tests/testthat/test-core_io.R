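test_that("tomogram NetCDF write/read round-trips intensities and voxel size", {
  set.seed(1)
  tom <- tomogram(array(rnorm(10 * 10 * 20), c(10, 10, 20)), 24.3, "rt")
  f <- tempfile(fileext = ".nc")
  on.exit(unlink(f))
  write_tomogram(tom, f)
  back <- read_tomogram(f)
  expect_identical(dim(back$intensities), dim(tom$intensities))
  expect_equal(back$intensities, tom$intensities, tolerance = 0)
  expect_identical(back$voxel_size_um, 24.3)
  expect_identical(back$fragment_id, "rt")
})

test_that("declared voxel size drives the physical Z extent", {
  tom <- tomogram(array(0, c(40, 40, 80)), 24.3, "ext")
  expect_equal(z_extent_mm(tom), 80 * 0.0243)
  expect_equal(z_extent_mm(tom), 1.944)
})

test_that("files without a 3D variable or voxel size fail descriptively", {
  f <- tempfile(fileext = ".nc")
  on.exit(unlink(f))
  d1 <- ncdf4::ncdim_def("x", "vox", 1:5)
  d2 <- ncdf4::ncdim_def("y", "vox", 1:5)
  v <- ncdf4::ncvar_def("slice", "au", list(d1, d2), prec = "double")
  nc <- ncdf4::nc_create(f, v)
  ncdf4::ncvar_put(nc, v, matrix(0, 5, 5))
  ncdf4::nc_close(nc)
  expect_error(read_tomogram(f), "no 3D volume found")
  expect_error(read_tomogram(tempfile(fileext = ".nc")), "file not found")

  ## 3D variable but no voxel-size attribute anywhere
  f2 <- tempfile(fileext = ".nc")
  on.exit(unlink(f2), add = TRUE)
  d3 <- ncdf4::ncdim_def("z", "vox", 1:4)
  v3 <- ncdf4::ncvar_def("vol", "au", list(d1, d2, d3), prec = "double")
  nc2 <- ncdf4::nc_create(f2, v3)
  ncdf4::ncvar_put(nc2, v3, array(0, c(5, 5, 4)))
  ncdf4::nc_close(nc2)
  expect_error(read_tomogram(f2), "voxel_size_um")
  expect_equal(read_tomogram(f2, voxel_size_um = 50)$voxel_size_um, 50)
})

test_that("flip_z reverses the vertical axis and is an involution", {
  arr <- array(seq_len(3 * 3 * 5), c(3, 3, 5))
  f <- tempfile(fileext = ".nc")
  on.exit(unlink(f))
  write_tomogram(tomogram(arr, 24.3, "fz"), f)
  flipped <- read_tomogram(f, flip_z = TRUE)$intensities
  expect_equal(flipped[, , 1], arr[, , 5])
  expect_equal(flipped[, , rev(1:5)], arr)
})

test_that("tomogram constructor enforces its invariants", {
  expect_error(tomogram(matrix(0, 2, 2), 24.3), "3D")
  expect_error(tomogram(array(NA_real_, c(2, 2, 2)), 24.3), "finite")
  expect_error(tomogram(array(0, c(2, 2, 2)), -1), "positive")
})

test_that("porosity map CSV round-trips all numeric content exactly", {
  ph <- small_phantom(seed = 11)
  pm <- compute_porosity_map(ph$labels)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_porosity_map(pm, f)
  back <- read_porosity_map(f)
  for (cc in c("mip", "map", "tp", "svf", "colony_fraction",
               "cx_mm", "cy_mm", "cz_mm"))
    expect_identical(back[[cc]], pm[[cc]], label = cc)
  for (cc in c("i", "j", "k", "n_solid", "n_micropore", "n_air", "n_mask"))
    expect_identical(back[[cc]], pm[[cc]], label = cc)
  expect_identical(attr(back, "window_vox"), attr(pm, "window_vox"))
  expect_identical(attr(back, "voxel_size_um"), attr(pm, "voxel_size_um"))
  ## a second write of the read object is byte-identical
  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(f2), add = TRUE)
  write_porosity_map(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("single-window map writes the expected microporosity column", {
  m <- fake_map(data.frame(n_solid = 50L, n_micropore = 10L, n_air = 40L,
                           n_mask = 0L))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_porosity_map(m, f)
  expect_equal(read_porosity_map(f)$mip, 10)
  expect_error(write_porosity_map(m[0, ], f), "empty")
})

test_that("fragment metadata loads, validates, and keeps annotations", {
  path <- system.file("extdata", "porites_fragments.yaml",
                      package = "coralpore")
  meta <- load_fragment_metadata(path)
  expect_equal(nrow(meta), 12L)
  r <- meta[meta$fragment_id == "15G", ]
  expect_equal(c(r$gb_low_mm, r$gb_high_mm), c(1.1, 2.2))
  expect_equal(r$depth_m, 12)
  expect_identical(r$species, "P. panamensis")
  expect_identical(r$location, "Pacific")
  ann <- attr(meta, "annotations")
  expect_equal(ann[["28G"]]$z_length_mm, 9)

  bad <- tempfile(fileext = ".yaml")
  on.exit(unlink(bad))
  writeLines(c("fragments:", "  - id: X1", "    species: P. lobata",
               "    location: Pacific", "    depth_m: 10",
               "    green_band_mm: [3, 2]"), bad)
  expect_error(load_fragment_metadata(bad), "invalid green-band interval")
  writeLines(c("fragments:", "  - id: X2", "    location: Pacific",
               "    depth_m: 10", "    green_band_mm: [1, 2]"), bad)
  expect_error(load_fragment_metadata(bad), "species")
})

test_that("run config validates ranges and loads from YAML", {
  expect_error(run_config(loess_span = 1.5), "span")
  expect_error(run_config(window_size_mm = 0), "window_size_mm")
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(c("loess_span: 0.5", "seed: 7"), f)
  cfg <- load_run_config(f)
  expect_equal(cfg$loess_span, 0.5)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$window_size_mm, 0.9)
  writeLines("not_a_key: 1", f)
  expect_error(load_run_config(f), "unknown config key")
})
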