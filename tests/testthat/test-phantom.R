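test_that("phantom structures hit their target volumes", {
  ph <- default_phantom()
  pv <- mask_volume(ph$masks$prostate)$cc
  expect_lt(abs(pv - 110) / 110, 0.10)
  bv <- mask_volume(ph$masks$bladder)$cc
  expect_lt(abs(bv - 300) / 300, 0.10)
  # a different bladder fill is honored too
  ph2 <- generate_phantom(phantom_spec(bladder_volume_cc = 380, noise_sd = 0))
  expect_lt(abs(mask_volume(ph2$masks$bladder)$cc - 380) / 380, 0.10)
})

test_that("phantom spec validation", {
  expect_error(phantom_spec(bladder_volume_cc = 150), "200")
  expect_error(phantom_spec(intensities = c(background = 0, bladder = 0,
                                            prostate = 1, rectum = 2, bone = 3)),
               "distinct")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  # structures that cannot fit are refused
  expect_error(generate_phantom(phantom_spec(grid_dims = c(24, 24, 16),
                                             spacing = c(4, 4, 4))),
               "fit|overlap|incompatible")
})

test_that("phantom generation is deterministic and masks are consistent", {
  spec <- phantom_spec(grid_dims = c(48, 48, 40), spacing = c(8, 8, 8),
                       bladder_volume_cc = 250, seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  # masks pairwise disjoint and non-empty
  tot <- Reduce(`+`, lapply(a$masks, function(m) m$data))
  expect_true(all(tot <= 1))
  expect_true(all(vapply(a$masks, function(m) sum(m$data), numeric(1)) > 0))
  # noiseless geometry gives exactly the five intensity levels
  c0 <- generate_phantom(phantom_spec(grid_dims = c(48, 48, 40),
                                      spacing = c(8, 8, 8), noise_sd = 0))
  expect_setequal(unique(as.numeric(c0$volume$data)), c(0, 60, 100, -80, 700))
})

test_that("deformation ground truth behaves as constructed", {
  spec <- phantom_spec(grid_dims = c(48, 48, 40), spacing = c(8, 8, 8),
                       bladder_volume_cc = 250, noise_sd = 0, seed = 5)
  base <- generate_phantom(spec)
  # zero-parameter deformation is the identity with an all-zero field
  still <- deform_phantom(base, ground_truth_deformation(
    bladder_inflation = 1, prostate_shift_mm = c(0, 0, 0)))
  expect_identical(still$volume$data, base$volume$data)
  expect_true(all(still$truth_field$vectors == 0))
  expect_identical(still$masks$bladder$data, base$masks$bladder$data)

  def <- deform_phantom(base, ground_truth_deformation(
    bladder_inflation = 1.25, prostate_shift_mm = c(16, 0, 0),
    smoothness_mm = 70))
  # inflation strictly increases the bladder volume
  expect_gt(mask_volume(def$masks$bladder)$voxels,
            mask_volume(base$masks$bladder)$voxels)
  # prostate center of mass moves by the commanded shift (within a voxel)
  shift <- center_of_mass(def$masks$prostate) - center_of_mass(base$masks$prostate)
  expect_lt(abs(shift[1] - 16), max(spec$spacing))
  expect_lt(max(abs(shift[2:3])), max(spec$spacing))
  # the rectum neither moves nor changes: reference DSC 100, Hausdorff 0
  expect_equal(dice_coefficient(def$masks$rectum, base$masks$rectum), 100)
  expect_equal(hausdorff_distance(def$masks$rectum, base$masks$rectum), 0)
  # mask/field consistency: warping baseline masks with the stored truth
  # reproduces the deformed masks exactly
  for (s in names(base$masks)) {
    expect_identical(warp_mask(base$masks[[s]], def$truth_field)$data,
                     def$masks[[s]]$data, label = s)
  }
  # the amplitude cap is enforced
  expect_error(deform_phantom(base, ground_truth_deformation(
    prostate_shift_mm = c(100, 0, 0), max_amplitude_vox = 7)), "cap")
})

test_that("CBCT appearance simulation preserves geometry and rank order", {
  spec <- phantom_spec(grid_dims = c(32, 32, 24), spacing = c(8, 8, 8),
                       bladder_volume_cc = 210, prostate_volume_cc = 60,
                       noise_sd = 0, seed = 2)
  vol <- generate_phantom(spec)$volume
  # identity transform returns the input exactly
  out0 <- simulate_cbct_appearance(vol, identity, shading_amplitude = 0,
                                   noise_sd = 0)
  expect_identical(out0$data, vol$data)
  # any monotone remap preserves voxelwise rank order at zero shading/noise
  outg <- simulate_cbct_appearance(vol, function(x) sign(x) * abs(x)^1.3,
                                   shading_amplitude = 0, noise_sd = 0)
  expect_equal(rank(as.numeric(outg$data), ties.method = "average"),
               rank(as.numeric(vol$data), ties.method = "average"))
  expect_equal(outg$spacing, vol$spacing)
  # non-monotone curves are rejected
  expect_error(simulate_cbct_appearance(vol, function(x) x^2), "monotone")
  # seeded: reproducible
  o1 <- simulate_cbct_appearance(vol, cbct_remap, 0.2, 4, seed = 3)
  o2 <- simulate_cbct_appearance(vol, cbct_remap, 0.2, 4, seed = 3)
  expect_identical(o1$data, o2$data)
})

test_that("gamma-like remaps leave MI intact while lowering NC", {
  # a few-level patch: the remapped copy shares the self-MI of the original's
  # binned version, while the correlation drops strictly below 1. (Three
  # levels are the minimum: on a two-valued patch every monotone map acts
  # affinely, leaving NC at exactly 1.)
  set.seed(6)
  lv <- array(sample(c(10, 100, 200), 216, replace = TRUE), c(6, 6, 6))
  remapped <- sign(lv) * abs(lv)^1.7
  expect_equal(mutual_information(lv, remapped, bins = 16)$value,
               mutual_information(lv, lv, bins = 16)$value, tolerance = 1e-12)
  expect_lt(normalized_correlation(lv, remapped)$value, 1)
})

test_that("benchmark pairs wire the scenes together correctly", {
  pair <- tiny_pair()
  expect_s3_class(pair, "benchmark_pair")
  # moving is the baseline, fixed carries the truth field
  expect_null(pair$moving$truth_field)
  expect_s3_class(pair$fixed$truth_field, "displacement_field")
  # intramodality: the two volumes share their intensity levels (+/- noise)
  expect_lt(abs(median(pair$fixed$volume$data) - median(pair$moving$volume$data)),
            5)
  # reproducibility under a fixed seed
  pair2 <- make_benchmark_pair(pair$moving$spec,
                               ground_truth_deformation(
                                 bladder_inflation = 1.25,
                                 prostate_shift_mm = c(16, 0, 0),
                                 smoothness_mm = 70))
  expect_identical(pair2$moving$volume$data, pair$moving$volume$data)
  expect_identical(pair2$fixed$volume$data, pair$fixed$volume$data)
})

test_that("intermodality pairs transform intensities but never masks", {
  spec <- phantom_spec(grid_dims = c(48, 48, 40), spacing = c(8, 8, 8),
                       bladder_volume_cc = 250, noise_sd = 0, seed = 9)
  def <- ground_truth_deformation(bladder_inflation = 1.2,
                                  prostate_shift_mm = c(8, 0, 0),
                                  smoothness_mm = 70)
  intra <- make_benchmark_pair(spec, def, intermodality = FALSE)
  inter <- make_benchmark_pair(spec, def, intermodality = TRUE)
  # histograms differ after the appearance transform (bone compresses)
  expect_gt(abs(mean(inter$fixed$volume$data) - mean(intra$fixed$volume$data)),
            1)
  # masks identical to the intramodality fixed scene's masks
  for (s in names(intra$fixed$masks))
    expect_identical(inter$fixed$masks[[s]]$data, intra$fixed$masks[[s]]$data)
})
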