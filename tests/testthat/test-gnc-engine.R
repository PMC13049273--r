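# b-maps, ADC fitting, correction and fractional bias maps.

odd_geom <- function(extent, spacing, center = c(0, 0, 0)) {
  # odd voxel counts so one voxel center lands exactly on `center`
  centered_geometry(extent, spacing, center)
}

test_that("b-map follows the integer 1e4 isocenter convention", {
  m <- default_coil_model()
  geom <- odd_geom(c(50, 50, 50), 10)   # 5^3 voxels, center voxel at origin
  bm <- make_bmap(m, geom)
  expect_equal(bm$data[3, 3, 3], 10000)
  expect_true(all(bm$data > 0))
  expect_true(all(bm$data == round(bm$data)))
  lin <- make_bmap(linear_coil_model(), centered_geometry(c(300, 100, 300), 25))
  expect_true(all(lin$data == 10000))
})

test_that("table offsets shift grids consistently into the magnet frame", {
  m <- default_coil_model()
  g1 <- centered_geometry(c(120, 60, 120), 15, center = c(10, -10, 140))
  g2 <- centered_geometry(c(120, 60, 120), 15, center = c(10, -10, 250))
  b1 <- make_bmap(m, g1, table_offset = 120)
  b2 <- make_bmap(m, g2, table_offset = 230)
  expect_identical(b1$data, b2$data)   # same magnet-frame region, different offsets
  geom_far <- centered_geometry(c(100, 100, 100), 25, center = c(0, 0, 0))
  expect_error(make_bmap(m, geom_far, table_offset = 500), "validity radius")
})

test_that("percent bias map applies 100 * (v/1e4 - 1)", {
  geom <- grid_geometry(c(3, 1, 1), c(1, 1, 1))
  bm <- image_volume(array(c(10000, 9000, 10840), c(3, 1, 1)), geom, "dimensionless")
  bp <- bias_percent(bm)
  expect_equal(as.vector(bp$data), c(0, -10, 8.4))
  expect_identical(bp$units, "percent")
})

test_that("two-point ADC fit inverts the mono-exponential signal model", {
  geom <- grid_geometry(c(3, 1, 1), c(2, 2, 2))
  s0v <- c(1000, 1000, 1000)
  sbv <- c(1000 * exp(-800 * 2.13e-3), 1000, 1200)
  s0 <- image_volume(array(s0v, c(3, 1, 1)), geom, "a.u.")
  sb <- image_volume(array(sbv, c(3, 1, 1)), geom, "a.u.")
  adc <- fit_adc(dwi_series(s0, sb, 800))
  expect_equal(adc$data[1, 1, 1], 2.13, tolerance = 1e-12)
  expect_equal(adc$data[2, 1, 1], 0)           # S_b = S0 -> floored at 0
  expect_equal(adc$data[3, 1, 1], 0)           # S_b > S0 -> floored at 0
  expect_false(attr(adc, "mask")[2, 1, 1])     # and flagged out of the mask
  expect_false(attr(adc, "mask")[3, 1, 1])
  expect_identical(adc$units, "micron2/ms")
})

test_that("noiseless phantom under a linear coil fits to a constant map", {
  ph <- generate_phantom(phantom_spec(spacing = 10), linear_coil_model())
  adc <- fit_adc(ph$dwi)
  vals <- adc$data[ph$mask]
  expect_lt(max(abs(vals / 2.13 - 1)), 1e-9)
})

test_that("GNC divides by the trace corrector and round-trips the phantom", {
  m <- default_coil_model()
  ph <- generate_phantom(phantom_spec(spacing = 8), m)
  adc <- fit_adc(ph$dwi)
  bmap <- make_bmap(m, adc$geom)
  gnc <- apply_gnc(adc, bmap)
  msk <- ph$mask & attr(adc, "mask")
  # integer-scaled b-map: recovery limited only by the 0.5/1e4 rounding quantum
  expect_lt(max(abs(gnc$data[msk] / 2.13 - 1)), 1e-4)
  # exact cbar (unrounded) recovers the truth to float precision
  pts <- grid_points(adc$geom)
  cb <- array(1e4 * gncadc:::cbar_at(m, pts), dim = adc$geom$dim)
  exact <- apply_gnc(adc, image_volume(cb, adc$geom, "dimensionless"))
  expect_lt(max(abs(exact$data[msk] / 2.13 - 1)), 1e-9)
  # single-voxel arithmetic: ADC 0.87 with v = 10670
  g1 <- grid_geometry(c(1, 1, 1), c(1, 1, 1))
  a1 <- image_volume(array(0.87, c(1, 1, 1)), g1, "micron2/ms")
  b1 <- image_volume(array(10670, c(1, 1, 1)), g1, "dimensionless")
  expect_equal(apply_gnc(a1, b1)$data[1, 1, 1], 0.87 / 1.067, tolerance = 1e-12)
  # unit corrector is the identity operation
  b_unit <- image_volume(array(10000, dim(adc$data)), adc$geom, "dimensionless")
  expect_identical(apply_gnc(adc, b_unit)$data, adc$data)
  # aligned-geometry and positivity contracts
  g_shift <- grid_geometry(adc$geom$dim, adc$geom$spacing, adc$geom$origin + 1)
  expect_error(apply_gnc(adc, image_volume(cb, g_shift, "dimensionless")),
               "do not match")
  cb_bad <- cb; cb_bad[1] <- 0
  expect_error(apply_gnc(adc, image_volume(cb_bad, adc$geom, "dimensionless")),
               "positive")
})

test_that("fractional ADC bias reproduces the model bias map on the phantom", {
  m <- default_coil_model()
  ph <- generate_phantom(phantom_spec(spacing = 8), m)
  adc <- fit_adc(ph$dwi)
  bmap <- make_bmap(m, adc$geom)
  gnc <- apply_gnc(adc, bmap)
  fb <- fractional_adc_bias(adc, gnc)
  bp <- bias_percent(bmap)
  msk <- attr(fb, "mask") & ph$mask
  expect_lt(max(abs(fb$data[msk] - bp$data[msk])), 1)   # < 1% voxelwise
  # trivial identities
  expect_equal(fractional_adc_bias(gnc, gnc)$data[msk],
               rep(0, sum(msk)))
  g1 <- grid_geometry(c(1, 1, 1), c(1, 1, 1))
  a <- image_volume(array(1.1, c(1, 1, 1)), g1, "micron2/ms")
  b <- image_volume(array(1.0, c(1, 1, 1)), g1, "micron2/ms")
  expect_equal(fractional_adc_bias(a, b)$data[1, 1, 1], 10)
})

test_that("correction commutes with cropping and shifts ADC against the bias sign", {
  m <- default_coil_model()
  ph <- generate_phantom(phantom_spec(spacing = 8), m)
  adc <- fit_adc(ph$dwi)
  bmap <- make_bmap(m, adc$geom)
  gnc <- apply_gnc(adc, bmap)
  i <- 3:10; j <- 1:1; k <- 5:30
  crop_then <- apply_gnc(crop_volume(adc, i, j, k), crop_volume(bmap, i, j, k))
  then_crop <- crop_volume(gnc, i, j, k)
  expect_equal(crop_then$data, then_crop$data, tolerance = 1e-15)
  # where bias > 0 the corrected ADC is lower, and vice versa
  msk <- ph$mask & attr(adc, "mask")
  bp <- bias_percent(bmap)
  pos <- msk & bp$data > 0
  neg <- msk & bp$data < 0
  expect_true(all(gnc$data[pos] < adc$data[pos]))
  expect_true(all(gnc$data[neg] > adc$data[neg]))
})

test_that("median smoothing matches a brute-force sliding window", {
  geom <- grid_geometry(c(7, 6, 2), c(1, 1, 1))
  set.seed(5)
  vol <- image_volume(array(stats::rnorm(84), c(7, 6, 2)), geom, "a.u.")
  sm <- median_smooth3(vol)
  # independent double-loop oracle
  for (k in 1:2) {
    for (i in 1:7) {
      for (j in 1:6) {
        ii <- max(1, i - 1):min(7, i + 1)
        jj <- max(1, j - 1):min(6, j + 1)
        expect_equal(sm$data[i, j, k],
                     stats::median(vol$data[ii, jj, k]))
      }
    }
  }
  cvol <- image_volume(array(2, c(7, 6, 2)), geom, "a.u.")
  expect_equal(median_smooth3(cvol)$data, cvol$data)
  imp <- cvol
  imp$data[4, 3, 1] <- 100
  expect_equal(median_smooth3(imp)$data, cvol$data)
})
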