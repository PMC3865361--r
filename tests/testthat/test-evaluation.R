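test_that("Dice matches exhaustive voxel counting and its identities", {
  m <- ball_mask(c(12, 12, 12), c(6, 6, 6), 3)
  expect_equal(dice_coefficient(m, m), 100)
  # disjoint masks
  a <- structure_mask(array(c(rep(1, 4), rep(0, 1724)), c(12, 12, 12)))
  b <- structure_mask(array(c(rep(0, 4), rep(1, 4), rep(0, 1720)), c(12, 12, 12)))
  expect_equal(dice_coefficient(a, b), 0)
  # two 2x2x2 cubes overlapping in a 2x2x1 slab: 2*4 / (8+8) * 100 = 50
  x <- array(0, c(4, 4, 4)); x[1:2, 1:2, 1:2] <- 1
  y <- array(0, c(4, 4, 4)); y[1:2, 1:2, 2:3] <- 1
  expect_equal(dice_coefficient(structure_mask(x), structure_mask(y)), 50)
  # symmetry
  expect_equal(dice_coefficient(structure_mask(x), structure_mask(y)),
               dice_coefficient(structure_mask(y), structure_mask(x)))
  # both empty is undefined
  e <- structure_mask(array(0, c(4, 4, 4)))
  expect_error(dice_coefficient(e, e), "empty")
  expect_error(dice_coefficient(m, ball_mask(c(10, 10, 10), c(5, 5, 5), 3)),
               "geometry")
})

test_that("Dice is 100 only for identical masks", {
  m <- ball_mask(c(10, 10, 10), c(5, 5, 5), 3)
  m2 <- m
  m2$data[2, 2, 2] <- 1 - m2$data[2, 2, 2]
  expect_lt(dice_coefficient(m2, m), 100)
})

test_that("Hausdorff distance matches closed forms and the O(n^2) oracle", {
  m <- ball_mask(c(12, 12, 12), c(6, 6, 6), 3.2)
  expect_equal(hausdorff_distance(m, m), 0)
  # single voxels at (0,0,0) and (3,4,0): a 3-4-5 triangle
  s1 <- array(0, c(6, 6, 3)); s1[1, 1, 1] <- 1
  s2 <- array(0, c(6, 6, 3)); s2[4, 5, 1] <- 1
  expect_equal(hausdorff_distance(structure_mask(s1), structure_mask(s2)), 5)
  # random small masks against the double-loop brute force
  for (seed in c(5, 6)) {
    a <- random_mask(c(8, 8, 8), 25, seed)
    b <- random_mask(c(8, 8, 8), 25, seed + 100)
    expect_equal(hausdorff_distance(a, b), hausdorff_bruteforce(a, b))
    expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
  }
  # dilation shrinks or preserves the directed distance to the dilated mask:
  # verified against the oracle rather than assumed
  base <- ball_mask(c(14, 14, 14), c(7, 7, 7), 3)
  dil <- ball_mask(c(14, 14, 14), c(7, 7, 7), 4)
  expect_equal(hausdorff_distance(base, dil), hausdorff_bruteforce(base, dil))
  expect_error(hausdorff_distance(base, structure_mask(array(0, c(14, 14, 14)))),
               "non-empty")
})

test_that("Hausdorff in mm honors anisotropic spacing", {
  s1 <- array(0, c(6, 6, 6)); s1[1, 1, 1] <- 1
  s2 <- array(0, c(6, 6, 6)); s2[1, 1, 3] <- 1
  a <- structure_mask(s1, spacing = c(1, 1, 4))
  b <- structure_mask(s2, spacing = c(1, 1, 4))
  expect_equal(hausdorff_distance(a, b, use_mm = FALSE), 2)
  expect_equal(hausdorff_distance(a, b, use_mm = TRUE), 8)
})

test_that("mask volume counts voxels and converts to cc", {
  cube <- array(0, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1
  v <- mask_volume(structure_mask(cube, spacing = c(1, 1, 1)))
  expect_equal(v$voxels, 1000L)
  expect_equal(v$cc, 1)
  expect_equal(mask_volume(structure_mask(array(0, c(4, 4, 4))))$voxels, 0L)
  # voxelized sphere of radius 10 voxels: within 2% of (4/3) pi 1000
  sph <- ball_mask(c(24, 24, 24), c(11.5, 11.5, 11.5), 10)
  expect_lt(abs(mask_volume(sph)$voxels - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)
})

test_that("center of mass uses physical coordinates", {
  s <- array(0, c(6, 6, 6)); s[3, 4, 5] <- 1   # 0-based index (2, 3, 4)
  expect_equal(center_of_mass(structure_mask(s, spacing = c(1, 1, 4))),
               c(2, 3, 16))
  # symmetric cube sits at its geometric center
  cube <- array(0, c(11, 11, 11)); cube[4:8, 4:8, 4:8] <- 1
  expect_equal(center_of_mass(structure_mask(cube)), c(5, 5, 5))
  # two equal disjoint blobs average to the midpoint of their centers
  two <- array(0, c(12, 6, 6)); two[1:2, 1:2, 1:2] <- 1; two[9:10, 1:2, 1:2] <- 1
  expect_equal(center_of_mass(structure_mask(two))[1],
               mean(c(0.5, 8.5)))
  expect_error(center_of_mass(structure_mask(array(0, c(3, 3, 3)))), "empty")
})

test_that("Wilcoxon comparison handles the analytic cases", {
  # identical lists: all differences zero -> NS with p = 1
  r <- wilcoxon_compare(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(r$label, "NS")
  expect_equal(r$p_value, 1)
  # n = 6 all-positive distinct differences: exact p = 2 / 2^6
  r6 <- wilcoxon_compare(c(10, 20, 30, 40, 50, 60), c(11, 22, 33, 44, 55, 66))
  expect_equal(r6$p_value, 0.03125)
  expect_equal(r6$label, "better")
  # same differences with higher_is_better = FALSE flips the verdict
  expect_equal(wilcoxon_compare(c(10, 20, 30, 40, 50, 60),
                                c(11, 22, 33, 44, 55, 66),
                                higher_is_better = FALSE)$label, "worse")
  # one positive and one negative difference of equal rank among zeros
  r0 <- wilcoxon_compare(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5 + 2, 6 - 2))
  expect_equal(r0$label, "NS")
  expect_error(wilcoxon_compare(1:4, 2:5), "at least 5")
  expect_error(wilcoxon_compare(1:6, 1:5), "equal length")
})

test_that("the exact branch equals full sign-assignment enumeration", {
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    vs <- vapply(0:(2^n - 1), function(mask) {
      signs <- as.integer(intToBits(mask))[1:n]
      sum(r[signs == 1])
    }, numeric(1))
    p_le <- mean(vs <= v_obs + 1e-9)
    p_ge <- mean(vs >= v_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(99)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)   # rounding forces occasional ties and zeros
    if (all(a == b)) b[1] <- b[1] + 1
    got <- wilcoxon_compare(a, b)$p_value
    expect_equal(got, enum_p(b - a), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
  # tie-free cases also agree with the distribution in stats::psignrank
  # via wilcox.test's exact branch
  set.seed(100)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(wilcoxon_compare(a, b)$p_value,
               stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("the large-sample branch matches wilcox.test's normal approximation", {
  set.seed(7)
  a <- rnorm(30)
  b <- a + rnorm(30, 0.3)
  got <- wilcoxon_compare(a, b)$p_value
  ref <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("reports carry all metrics and sensible comparison labels", {
  # six little structures so the paired test can run
  dims <- c(10, 10, 60)
  reference <- lapply(1:6, function(i)
    ball_mask(dims, c(5, 5, 10 * i - 5), 2.6, spacing = c(2, 2, 2)))
  names(reference) <- paste0("s", 1:6)
  identical_m <- reference
  degraded <- lapply(reference, function(m) {
    shifted <- array(0, dims)
    shifted[, , 3:dims[3]] <- m$data[, , 1:(dims[3] - 2)]
    structure_mask(shifted, m$spacing, m$origin)
  })
  report <- build_report(reference,
                         list(RR = identical_m, degraded = degraded))
  expect_s3_class(report$metrics, "tbl_df")
  expect_equal(nrow(report$metrics), 12)  # 6 structures x 2 methods
  rr <- report$metrics[report$metrics$method == "RR", ]
  expect_true(all(rr$dsc == 100))
  expect_true(all(rr$hausdorff_px == 0))
  expect_true(all(rr$com_shift_mm == 0))
  # the degraded method is significantly worse on DSC
  cmp <- report$comparisons
  dsc_row <- cmp[cmp$criterion == "dsc", ]
  expect_equal(dsc_row$label, "-")   # p = 0.03125 with n = 6: worse, not "--"
  expect_lt(dsc_row$p_value, 0.05)
  # with fewer than 5 structures no test is attempted
  small <- build_report(reference[1:3],
                        list(RR = identical_m[1:3], degraded = degraded[1:3]))
  expect_true(all(is.na(small$comparisons$p_value)))
  expect_true(all(small$comparisons$label == "NS"))
})

test_that("report export writes tables and structured output", {
  dir <- withr::local_tempdir()
  reference <- list(a = ball_mask(c(10, 10, 10), c(5, 5, 5), 3))
  report <- build_report(reference, list(RR = reference))
  paths <- write_report(report, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[["metrics"]])
  expect_equal(tab$dsc, 100)
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$metrics[[1]]$structure, "a")
})
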