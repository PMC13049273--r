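# ROI statistics, histograms, nonuniformity, heterogeneity and trend flags.

test_that("uniform ROI statistics are exact", {
  u <- uniform_labelled_volume(value = 0.5, n_voxels = 100, spacing = 2)
  st <- roi_statistics(u$vol, u$labels)
  expect_equal(nrow(st), 1)
  expect_equal(st$mean, 0.5)
  expect_equal(st$median, 0.5)
  expect_equal(st$sd, 0)
  expect_equal(st$volume_cm3, 100 * 8 / 1000)     # 0.8 cm^3
  expect_equal(st$range, 0)
})

test_that("the ADC threshold drops voxels without diffusion contrast", {
  u <- uniform_labelled_volume(n_voxels = 100)
  u$vol$data[1:50] <- 0.005
  st <- roi_statistics(u$vol, u$labels, threshold = 0.01)
  expect_equal(st$n, 50)
  # below-threshold everywhere -> absent entry, not zeros
  u$vol$data[] <- 0.005
  st0 <- roi_statistics(u$vol, u$labels, threshold = 0.01)
  expect_equal(nrow(st0), 0)
})

test_that("ROI statistics equal a brute-force enumeration", {
  set.seed(21)
  dims <- c(8, 7, 6)
  geom <- grid_geometry(dims, c(2, 3, 4))
  vol <- image_volume(array(stats::runif(prod(dims), 0, 2), dims), geom, "micron2/ms")
  lab_arr <- array(sample(c(0L, site_codes()[["RI"]], site_codes()[["L2"]]),
                          prod(dims), replace = TRUE), dims)
  labels <- image_volume(lab_arr, geom, "label")
  st <- roi_statistics(vol, labels, threshold = 0.1)
  for (s in st$site) {
    vals <- c()
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
      if (lab_arr[i, j, k] == site_codes()[[s]] && vol$data[i, j, k] > 0.1) {
        vals <- c(vals, vol$data[i, j, k])
      }
    }
    row <- st[st$site == s, ]
    expect_equal(row$n, length(vals))
    expect_equal(row$mean, mean(vals))
    expect_equal(row$median, stats::median(vals))
    expect_equal(row$sd, stats::sd(vals))
    expect_equal(row$min, min(vals))
    expect_equal(row$max, max(vals))
    expect_equal(row$volume_cm3, length(vals) * 24 / 1000)
  }
  bad_geom <- image_volume(lab_arr, grid_geometry(dims, c(1, 1, 1)), "label")
  expect_error(roi_statistics(vol, bad_geom), "do not match")
})

test_that("histograms use zero-anchored left-closed bins and conserve mass", {
  h <- build_histogram(c(0.02, 0.02, 0.07), 0.05)
  expect_equal(h$left, c(0, 0.05))
  expect_equal(h$mass, c(2 / 3, 1 / 3))
  h1 <- build_histogram(0.3, 0.05)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$mass, 1)
  set.seed(3)
  v <- stats::rnorm(500, 1, 0.5)
  h2 <- build_histogram(v, 0.05)
  expect_equal(sum(h2$mass), 1, tolerance = 1e-9)
  # brute-force binning oracle
  for (r in sample(nrow(h2), 5)) {
    expect_equal(h2$mass[r],
                 mean(v >= h2$left[r] & v < h2$right[r]))
  }
  # negative values land in negative-index bins, still anchored at 0
  hneg <- build_histogram(c(-0.01, 0.01), 0.05)
  expect_equal(hneg$left, c(-0.05, 0))
  expect_equal(nrow(build_histogram(numeric(0), 0.5)), 0)
  expect_error(build_histogram(1, 0), "positive")
})

test_that("intra-subject nonuniformity is the max-min spread", {
  expect_equal(intra_subject_nonuniformity(c(8.4, -10, 0)), 18.4)
  expect_equal(intra_subject_nonuniformity(c(2, 2, 2)), 0)
  set.seed(8)
  x <- stats::rnorm(10)
  expect_equal(intra_subject_nonuniformity(x),
               sort(x)[10] - sort(x)[1])                 # sort-based oracle
  expect_equal(intra_subject_nonuniformity(sample(x)),
               intra_subject_nonuniformity(x))           # permutation invariant
  expect_warning(r <- intra_subject_nonuniformity(5), "fewer than 2")
  expect_true(is.na(r))
})

test_that("heterogeneity CV is scale-invariant and matches the direct formula", {
  expect_equal(heterogeneity_cv(c(0.5, 0.5, 0.5)), 0)
  x <- c(0.78, 0.87, 0.81, 0.82)
  expect_equal(heterogeneity_cv(x), 100 * stats::sd(x) / mean(x))
  expect_equal(heterogeneity_cv(2 * x), heterogeneity_cv(x))
  expect_warning(r <- heterogeneity_cv(0.8), "fewer than 2")
  expect_true(is.na(r))
})

test_that("trend deviation flags follow strict inequalities with tie exclusion", {
  ref <- c(T = 0.52, I = 0.63, MV = 0.58, EV = 0.59)
  expect_equal(unname(trend_deviation(ref)), c(FALSE, FALSE, FALSE))
  expect_true(trend_deviation(c(T = 0.7, I = 0.6, MV = 0.58, EV = 0.59))[
    "ilium_below_trochanter"])
  expect_true(trend_deviation(c(T = 0.5, I = 0.55, MV = 0.6, EV = 0.59))[
    "ilium_below_mid"])
  expect_true(trend_deviation(c(T = 0.5, I = 0.63, MV = 0.6, EV = 0.55))[
    "edge_below_mid"])
  ties <- trend_deviation(c(T = 0.6, I = 0.6, MV = 0.6, EV = 0.6))
  expect_equal(unname(ties), c(FALSE, FALSE, FALSE))
  missing_t <- trend_deviation(c(I = 0.6, MV = 0.58, EV = 0.59))
  expect_true(is.na(missing_t["ilium_below_trochanter"]))
  expect_false(is.na(missing_t["ilium_below_mid"]))
})

test_that("site groups are disjoint and cover the dictionary", {
  g <- site_groups()
  expect_equal(anyDuplicated(unlist(g)), 0)
  expect_setequal(unlist(g), names(site_codes()))
  expect_false("T11" %in% site_groups(include_t11 = FALSE)$EV)
})

test_that("ROI bias means match the analytic field average within discretization", {
  m <- default_coil_model()
  scan <- generate_subject(subject_spec(sigma = 0), m)
  st <- scan$stations$spine
  bias <- bias_percent(make_bmap(m, st$labels$geom,
                                 table_offset = st$dwi$table_offset))
  stats_tab <- roi_statistics(bias, st$labels)
  pts <- gncadc:::magnet_points(st$labels$geom, st$dwi$table_offset)
  for (s in stats_tab$site) {
    sel <- as.vector(st$labels$data) == site_codes()[[s]]
    analytic <- mean(100 * (gncadc:::cbar_at(m, pts[sel, , drop = FALSE]) - 1))
    expect_lt(abs(stats_tab$mean[stats_tab$site == s] - analytic), 0.2)
  }
})
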