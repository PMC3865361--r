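test_that("partitioning tiles the volume exactly", {
  v30 <- image_volume(array(0, c(30, 30, 30)))
  b <- partition_moving_image(v30, 15)
  expect_equal(nrow(b), 8)
  expect_true(all(b$hi_x - b$lo_x == 15))

  # truncated edge boxes: ceiling(40 / 15) = 3 per axis, extents 15, 15, 10
  v40 <- image_volume(array(0, c(40, 40, 40)))
  b40 <- partition_moving_image(v40, 15)
  expect_equal(nrow(b40), 27)
  expect_setequal(unique(b40$hi_x - b40$lo_x), c(15, 10))
  expect_equal(sort(unique(b40$lo_z)), c(0, 15, 30))
  # exhaustive voxel coverage: each voxel in exactly one box
  cover <- array(0L, c(40, 40, 40))
  for (i in seq_len(nrow(b40))) {
    cover[(b40$lo_x[i] + 1):b40$hi_x[i], (b40$lo_y[i] + 1):b40$hi_y[i],
          (b40$lo_z[i] + 1):b40$hi_z[i]] <-
      cover[(b40$lo_x[i] + 1):b40$hi_x[i], (b40$lo_y[i] + 1):b40$hi_y[i],
            (b40$lo_z[i] + 1):b40$hi_z[i]] + 1L
  }
  expect_true(all(cover == 1L))

  # single box covering everything
  b1 <- partition_moving_image(image_volume(array(0, c(15, 15, 15))), 15)
  expect_equal(nrow(b1), 1)
  expect_equal(c(b1$lo_x, b1$hi_x), c(0, 15))

  expect_error(partition_moving_image(image_volume(array(0, c(10, 10, 10))), 15),
               "exceeds")
})

test_that("search regions are centered with the floor convention and clipped", {
  fixed <- image_volume(array(0, c(60, 60, 60)))
  # center of [15, 30) is 22.5; low corner floor(22.5 - 15) = 7
  sr <- search_region_for(list(lo = rep(15, 3), hi = rep(30, 3)), fixed, 30)
  expect_equal(sr$lo, rep(7L, 3))
  expect_equal(sr$hi, rep(37L, 3))
  # corner box clips at zero
  sr0 <- search_region_for(list(lo = rep(0, 3), hi = rep(15, 3)), fixed, 30)
  expect_equal(sr0$lo, rep(0L, 3))
  expect_equal(sr0$hi, rep(30L, 3))
  # search = featurelet collapses to the footprint
  srf <- search_region_for(list(lo = rep(15, 3), hi = rep(30, 3)), fixed, 15)
  expect_equal(srf$lo, rep(15L, 3))
  expect_equal(srf$hi, rep(30L, 3))
})

test_that("a featurelet at its true location stays put", {
  arr <- smooth_noise(c(24, 24, 24), seed = 5)
  fixed <- image_volume(arr)
  cfg <- registration_config(featurelet_size = 8, search_size = 16)
  patch <- arr[9:16, 9:16, 9:16]
  sr <- search_region_for(list(lo = rep(8, 3), hi = rep(16, 3)), fixed, 16)
  r <- register_featurelet(patch, fixed, sr, cfg, box_lo = rep(8, 3))
  expect_lt(max(abs(r$displacement)), 0.1)
  expect_gt(r$merit$value, 0.99)
})

test_that("a known integer shift of random texture is recovered", {
  shift <- c(3, -2, 1)
  p <- shifted_pair(c(30, 30, 30), shift, seed = 7)
  fixed <- image_volume(p$fixed)
  cfg <- registration_config(featurelet_size = 10, search_size = 20)
  lo <- rep(10L, 3)
  patch <- p$moving[11:20, 11:20, 11:20]
  sr <- search_region_for(list(lo = lo, hi = lo + 10L), fixed, 20)
  r <- register_featurelet(patch, fixed, sr, cfg, box_lo = lo)
  expect_lt(max(abs(r$displacement - shift)), 0.5)
  # and the descent lands in the same integer cell as the exhaustive oracle
  oracle <- scan_oracle(patch, fixed, lo, sr, metric = "NC")
  expect_equal(oracle$displacement, shift)
  expect_gte(r$merit$value, oracle$merit - 1e-6)
})

test_that("descent matches the exhaustive-scan oracle on small cases", {
  for (seed in c(2, 4)) {
    for (metric in c("NC", "MI")) {
      shift <- c(-2, 1, 2)
      p <- shifted_pair(c(26, 26, 26), shift, seed = seed)
      fixed <- image_volume(p$fixed)
      cfg <- registration_config(featurelet_size = 9, search_size = 18,
                                 metric = metric, mi_bins = 16)
      lo <- rep(9L, 3)
      patch <- p$moving[10:18, 10:18, 10:18]
      sr <- search_region_for(list(lo = lo, hi = lo + 9L), fixed, 18)
      r <- register_featurelet(patch, fixed, sr, cfg, box_lo = lo)
      oracle <- scan_oracle(patch, fixed, lo, sr, metric = metric, bins = 16)
      if (r$converged) {
        expect_gte(r$merit$value, oracle$merit - 1e-6)
        expect_lt(max(abs(r$displacement - oracle$displacement)), 0.5 + 1e-9)
      }
    }
  }
})

test_that("flat featurelets are declared degenerate and unconverged", {
  fixed <- image_volume(smooth_noise(c(20, 20, 20), seed = 1))
  cfg <- registration_config(featurelet_size = 6, search_size = 12)
  sr <- list(lo = rep(4L, 3), hi = rep(16L, 3))
  r <- register_featurelet(array(3, c(6, 6, 6)), fixed, sr, cfg,
                           box_lo = rep(7L, 3))
  expect_false(r$converged)
  expect_true(r$merit$degenerate)
  expect_equal(r$displacement, c(0, 0, 0))
})

test_that("the compiled metric agrees with the R metrics at integer offsets", {
  set.seed(12)
  fixed_arr <- smooth_noise(c(20, 20, 20), seed = 12)
  fixed <- image_volume(fixed_arr)
  patch <- fixed_arr[5:10, 3:8, 7:12]
  lo <- c(4L, 2L, 6L)
  for (tau in list(c(0, 0, 0), c(2, -1, 1), c(-3, 3, 0))) {
    o <- lo + tau
    sub <- fixed_arr[(o[1] + 1):(o[1] + 6), (o[2] + 1):(o[2] + 6),
                     (o[3] + 1):(o[3] + 6)]
    expect_equal(
      featurelet:::fl_metric_cpp(as.numeric(fixed_arr), dim(fixed_arr),
                                 as.numeric(patch), dim(patch), lo,
                                 as.numeric(tau), 0L, 32L),
      normalized_correlation(patch, sub)$value, tolerance = 1e-12)
    expect_equal(
      featurelet:::fl_metric_cpp(as.numeric(fixed_arr), dim(fixed_arr),
                                 as.numeric(patch), dim(patch), lo,
                                 as.numeric(tau), 1L, 16L),
      mutual_information(patch, sub, 16)$value, tolerance = 1e-12)
  }
})

test_that("full runs are deterministic, bounded and complete", {
  p <- shifted_pair(c(30, 30, 30), c(2, 0, -1), seed = 3)
  moving <- image_volume(p$moving)
  fixed <- image_volume(p$fixed)
  cfg <- registration_config(featurelet_size = 10, search_size = 20)
  fl1 <- run_registration(moving, fixed, cfg)
  fl2 <- run_registration(moving, fixed, cfg)
  expect_identical(as.data.frame(fl1), as.data.frame(fl2))
  expect_equal(nrow(fl1), 27)   # 3 x 3 x 3 tiling
  # displacement bound: the translated patch stays inside the search region
  bound <- (20 - 10) / 2 + 1
  expect_true(all(abs(fl1[, c("dx", "dy", "dz")]) <= bound))
  # identity registration: everything non-degenerate lands near zero
  fl0 <- run_registration(moving, moving, cfg)
  nd <- !fl0$degenerate
  expect_true(all(abs(fl0$dx[nd]) < 0.1 & abs(fl0$dy[nd]) < 0.1 &
                    abs(fl0$dz[nd]) < 0.1))
  # 60^3 with 15^3 featurelets emits exactly 64
  v60 <- image_volume(smooth_noise(c(60, 60, 60), seed = 8))
  expect_equal(nrow(run_registration(v60, v60, registration_config())), 64)
  expect_error(run_registration(moving, image_volume(array(0, c(10, 10, 10)))),
               "geometry")
})

test_that("coarse pre-alignment recovers a global integer shift", {
  p <- shifted_pair(c(32, 32, 32), c(4, -2, 0), seed = 10)
  sh <- pre_align_translation(image_volume(p$moving), image_volume(p$fixed),
                              max_shift = 6, stride = 2)
  expect_equal(sh, c(4L, -2L, 0L))
})

test_that("configuration invariants are validated", {
  expect_error(registration_config(search_size = c(10, 10, 10)), "search_size")
  expect_error(registration_config(min_step = 0), "min_step")
  expect_error(registration_config(min_step = 0.1, max_step = 0.05), "min_step")
  expect_error(registration_config(max_iterations = 0), "max_iterations")
  expect_error(registration_config(relaxation = 1), "relaxation")
  expect_equal(registration_config(metric = "MI")$merit_threshold, 0.1)
  expect_equal(registration_config()$merit_threshold, 0.5)
})
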