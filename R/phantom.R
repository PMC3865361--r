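#' Digital deformable pelvis phantom specification
#'
#' Parameters of the synthetic analogue of a deformable pelvis phantom: a
#' water-filled box containing an inflatable bladder balloon (200-400 cc), a
#' rigid prostate-shaped object of approximately 110 cc glued below it, a
#' fixed rectum tube posterior to the prostate and lateral radio-opaque bone
#' blocks. The default grid (96 x 96 x 64 voxels at 4 mm isotropic spacing)
#' is a scaled-down analogue of the physical 400 x 400 x 290 mm box that
#' preserves the featurelet-to-search-region size ratio.
#'
#' @param grid_dims integer triple of voxel counts.
#' @param spacing mm per voxel.
#' @param intensities named numeric vector with five pairwise-distinct levels
#'   `background`, `bladder`, `prostate`, `rectum`, `bone` (HU-like).
#' @param bladder_volume_cc bladder fill volume, within \[200, 400\] cc.
#' @param prostate_volume_cc prostate volume, cc.
#' @param noise_sd additive Gaussian intensity noise (same units as
#'   `intensities`).
#' @param seed integer RNG seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dims = c(96L, 96L, 64L),
                         spacing = c(4, 4, 4),
                         intensities = c(background = 0, bladder = 60,
                                         prostate = 100, rectum = -80,
                                         bone = 700),
                         bladder_volume_cc = 300,
                         prostate_volume_cc = 110,
                         noise_sd = 10,
                         seed = 42L) {
  grid_dims <- rep_len(as.integer(grid_dims), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  need <- c("background", "bladder", "prostate", "rectum", "bone")
  if (!all(need %in% names(intensities)))
    stop("`intensities` must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(intensities[need]))
    stop("the five intensity levels must be pairwise distinct", call. = FALSE)
  if (bladder_volume_cc < 200 || bladder_volume_cc > 400)
    stop("bladder_volume_cc must lie within [200, 400] cc", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(grid_dims = grid_dims, spacing = spacing,
                 intensities = intensities[need],
                 bladder_volume_cc = bladder_volume_cc,
                 prostate_volume_cc = prostate_volume_cc,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical (mm) coordinate arrays of all voxel centers, origin 0
grid_mm <- function(dims, spacing) {
  list(x = array(rep(seq.int(0L, dims[1] - 1L), times = dims[2] * dims[3]), dims) * spacing[1],
       y = array(rep(rep(seq.int(0L, dims[2] - 1L), each = dims[1]), times = dims[3]), dims) * spacing[2],
       z = array(rep(seq.int(0L, dims[3] - 1L), each = dims[1] * dims[2]), dims) * spacing[3])
}

#' Generate the digital phantom
#'
#' Builds the phantom scene at the requested bladder and prostate volumes:
#' an ellipsoidal bladder, an ellipsoid-with-flattened-base prostate abutting
#' the bladder inferiorly, a tubular rectum posterior to the prostate, two
#' lateral bone blocks and water background, plus seeded Gaussian intensity
#' noise. Structure sizes are matched to the requested volumes by bisection
#' on the shape scale, so voxelized volumes land well within a few percent
#' of the target. Masks are derived from the noiseless geometry and are
#' pairwise disjoint.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_scene`: list with `volume` ([image_volume()]), `masks`
#'   (named [structure_mask()]s: bladder, prostate, rectum, bone),
#'   `truth_field` (`NULL` until [deform_phantom()]), `shapes` (analytic
#'   shape parameters) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_dims
  sp <- spec$spacing
  ext <- dims * sp
  g <- grid_mm(dims, sp)
  voxvol <- prod(sp)  # mm^3

  # lateral bone blocks (fractions of the field of view)
  bone <- (((g$x >= 0.08 * ext[1] & g$x < 0.19 * ext[1]) |
            (g$x >= 0.81 * ext[1] & g$x < 0.92 * ext[1])) &
           g$y >= 0.30 * ext[2] & g$y < 0.72 * ext[2] &
           g$z >= 0.12 * ext[3] & g$z < 0.88 * ext[3])

  # rectum: capped cylinder along z, posterior
  rect_c <- c(0.5 * ext[1], 0.64 * ext[2])
  rect_r <- 0.05 * ext[1]
  rect_z <- c(0.15, 0.85) * ext[3]
  rectum <- ((g$x - rect_c[1])^2 + (g$y - rect_c[2])^2 <= rect_r^2) &
    g$z >= rect_z[1] & g$z <= rect_z[2]

  # bladder: ellipsoid sized to the requested fill volume
  bl_center <- c(0.5 * ext[1], 0.40 * ext[2], 0.64 * ext[3])
  bl_ratio <- c(1.1, 1.0, 0.9)
  bl_target <- spec$bladder_volume_cc * 1000 / voxvol
  bl_count <- function(s) {
    ax <- s * bl_ratio
    sum(((g$x - bl_center[1]) / ax[1])^2 + ((g$y - bl_center[2]) / ax[2])^2 +
          ((g$z - bl_center[3]) / ax[3])^2 <= 1)
  }
  bl_s <- bisect_scale(bl_count, bl_target, c(5, 0.45 * min(ext)))
  bl_ax <- bl_s * bl_ratio
  bladder <- ((g$x - bl_center[1]) / bl_ax[1])^2 +
    ((g$y - bl_center[2]) / bl_ax[2])^2 +
    ((g$z - bl_center[3]) / bl_ax[3])^2 <= 1

  # prostate: ellipsoid with flattened base, top abutting the bladder bottom
  pr_ratio <- c(1.05, 0.95, 0.85)
  pr_target <- spec$prostate_volume_cc * 1000 / voxvol
  gap <- sp[3]  # one slice of clearance
  pr_center_xy <- c(0.5 * ext[1], 0.40 * ext[2])
  bl_bottom <- bl_center[3] - bl_ax[3]
  pr_region <- function(s) {
    ax <- s * pr_ratio
    cz <- bl_bottom - gap - ax[3]
    (((g$x - pr_center_xy[1]) / ax[1])^2 +
       ((g$y - pr_center_xy[2]) / ax[2])^2 +
       ((g$z - cz) / ax[3])^2 <= 1) &
      g$z >= cz - 0.55 * ax[3]  # flattened base
  }
  pr_s <- bisect_scale(function(s) sum(pr_region(s)), pr_target,
                       c(5, 0.4 * min(ext)))
  prostate <- pr_region(pr_s)
  pr_ax <- pr_s * pr_ratio
  pr_center <- c(pr_center_xy, bl_bottom - gap - pr_ax[3])

  masks_logical <- list(bladder = bladder, prostate = prostate,
                        rectum = rectum, bone = bone)
  overlap <- bladder + prostate + rectum + bone
  if (any(overlap > 1))
    stop("phantom structures overlap; volumes are incompatible with the grid",
         call. = FALSE)
  if (any(vapply(masks_logical, sum, numeric(1)) == 0))
    stop("a phantom structure is empty; volumes are incompatible with the grid",
         call. = FALSE)

  lv <- spec$intensities
  vol <- array(lv[["background"]], dims)
  vol[bladder] <- lv[["bladder"]]
  vol[prostate] <- lv[["prostate"]]
  vol[rectum] <- lv[["rectum"]]
  vol[bone] <- lv[["bone"]]
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed,
                           array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims))
  }

  masks <- lapply(masks_logical, structure_mask, spacing = sp, origin = c(0, 0, 0))
  structure(list(volume = image_volume(vol, sp, c(0, 0, 0)),
                 masks = masks, truth_field = NULL,
                 shapes = list(bladder = list(center = bl_center, axes = bl_ax),
                               prostate = list(center = pr_center, axes = pr_ax),
                               rectum = list(center_xy = rect_c, radius = rect_r,
                                             z_range = rect_z)),
                 spec = spec),
            class = "phantom_scene")
}

# smallest scale whose voxel count reaches the target (count is a step
# function of s; bisection to sub-voxel precision in s)
bisect_scale <- function(count_fn, target, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  if (count_fn(hi) < target)
    stop("structure volume does not fit inside the grid", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count_fn(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("<phantom_scene>\n")
  print(x$volume)
  for (nm in names(x$masks)) {
    v <- mask_volume(x$masks[[nm]])
    cat(sprintf("  %-9s %6d voxels, %7.1f cc\n", nm, v$voxels, v$cc))
  }
  if (!is.null(x$truth_field)) cat("  carries a ground-truth deformation field\n")
  invisible(x)
}

#' Ground-truth deformation parameters
#'
#' An analytic, smooth pull-back deformation composed of (i) a radial
#' bladder-inflation term with Gaussian falloff centered at the bladder
#' centroid, (ii) a rigid prostate translation blended smoothly to zero away
#' from the prostate, and (iii) an exact zero inside the rectum dilated by
#' one voxel (the physical rectum neither moves nor changes size), enforced
#' by a distance ramp off the rectum tube. The deformed scene is produced by
#' resampling the baseline with this field, so the field is the exact ground
#' truth for the registration pipeline.
#'
#' @param bladder_inflation radial pull-back strength as a scale factor;
#'   1 means no inflation, values > 1 inflate the bladder.
#' @param prostate_shift_mm rigid prostate translation (mm triple).
#' @param smoothness_mm Gaussian falloff scale of both terms (mm).
#' @param max_amplitude_vox cap on the field magnitude (voxels); exceeding it
#'   is an error, keeping displacements within the search-region reach.
#' @return A `ground_truth_deformation` list.
#' @export
ground_truth_deformation <- function(bladder_inflation = 1.3,
                                     prostate_shift_mm = c(12, 0, 0),
                                     smoothness_mm = 40,
                                     max_amplitude_vox = 7) {
  if (bladder_inflation < 1)
    stop("bladder_inflation must be >= 1", call. = FALSE)
  structure(list(bladder_inflation = bladder_inflation,
                 prostate_shift_mm = rep_len(as.numeric(prostate_shift_mm), 3L),
                 smoothness_mm = smoothness_mm,
                 max_amplitude_vox = max_amplitude_vox),
            class = "ground_truth_deformation")
}

#' Deform a phantom scene with an analytic ground-truth field
#'
#' Applies [ground_truth_deformation()] to a generated scene: the analytic
#' pull-back field is evaluated on the grid, the volume is warped with
#' trilinear interpolation, every mask with nearest-neighbor sampling, and
#' the field is stored as `truth_field` on the result. Warping the baseline
#' masks with `truth_field` therefore reproduces the deformed masks exactly.
#' A zero-parameter deformation returns an identical scene with an all-zero
#' field.
#'
#' @param scene a `phantom_scene` from [generate_phantom()].
#' @param deformation a [ground_truth_deformation()].
#' @return A new `phantom_scene` with `truth_field` set.
#' @export
deform_phantom <- function(scene, deformation = ground_truth_deformation()) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(deformation, "ground_truth_deformation"))
  if (is.null(scene$shapes))
    stop("deform_phantom needs the analytic shape parameters of a generated scene",
         call. = FALSE)
  dims <- vol_dims(scene$volume)
  sp <- scene$volume$spacing
  g <- grid_mm(dims, sp)
  sig <- deformation$smoothness_mm

  # (i) bladder inflation: pull-back points toward the bladder centroid
  bc <- center_of_mass(scene$masks$bladder)
  dx <- g$x - bc[1]; dy <- g$y - bc[2]; dz <- g$z - bc[3]
  r2 <- dx^2 + dy^2 + dz^2
  amp <- (deformation$bladder_inflation - 1) * exp(-r2 / (2 * sig^2))
  ux <- -amp * dx; uy <- -amp * dy; uz <- -amp * dz

  # (ii) prostate rigid shift, blended to zero outside the prostate
  pc <- scene$shapes$prostate$center
  r0 <- max(scene$shapes$prostate$axes) + max(sp)
  rp <- sqrt((g$x - pc[1])^2 + (g$y - pc[2])^2 + (g$z - pc[3])^2)
  w <- exp(-pmax(rp - r0, 0)^2 / (2 * (0.6 * sig)^2))
  sh <- deformation$prostate_shift_mm
  ux <- ux - sh[1] * w; uy <- uy - sh[2] * w; uz <- uz - sh[3] * w

  # (iii) exact zero on the rectum dilated by one voxel, with a smooth ramp
  rs <- scene$shapes$rectum
  dr <- pmax(sqrt((g$x - rs$center_xy[1])^2 + (g$y - rs$center_xy[2])^2) - rs$radius, 0)
  dzc <- pmax(rs$z_range[1] - g$z, g$z - rs$z_range[2], 0)
  dist <- sqrt(dr^2 + dzc^2)
  pad <- max(sp)          # one-voxel dilation
  ramp <- 2 * max(sp)
  gate <- pmin(pmax((dist - pad) / ramp, 0), 1)
  ux <- ux * gate; uy <- uy * gate; uz <- uz * gate

  vectors <- array(0, c(dims, 3L))
  vectors[, , , 1] <- ux / sp[1]
  vectors[, , , 2] <- uy / sp[2]
  vectors[, , , 3] <- uz / sp[3]
  maxamp <- sqrt(max(vectors[, , , 1]^2 + vectors[, , , 2]^2 + vectors[, , , 3]^2))
  if (maxamp > deformation$max_amplitude_vox)
    stop(sprintf("deformation amplitude %.2f voxels exceeds the cap of %s voxels",
                 maxamp, deformation$max_amplitude_vox), call. = FALSE)
  field <- displacement_field(vectors, sp, scene$volume$origin)

  out <- scene
  out$volume <- warp_image(scene$volume, field)
  out$masks <- lapply(scene$masks, warp_mask, field = field)
  out$truth_field <- field
  out
}

#' Give a volume a CBCT-like appearance
#'
#' Intermodality surrogate: intensities are passed through a strictly
#' monotone remapping curve, multiplied by a smooth low-frequency shading
#' field of relative amplitude `shading_amplitude` (one period across the
#' volume, seeded phases) and perturbed by Gaussian noise. Geometry is
#' unchanged, and with the identity remap and zero shading/noise the output
#' equals the input exactly.
#'
#' @param volume an [image_volume()].
#' @param remap strictly monotone function applied voxelwise; checked
#'   numerically over the volume's intensity range.
#' @param shading_amplitude relative amplitude of the multiplicative shading.
#' @param noise_sd additive Gaussian noise sd (post-remap units).
#' @param seed integer seed for the shading phases and noise.
#' @return An [image_volume()].
#' @export
simulate_cbct_appearance <- function(volume, remap = identity,
                                     shading_amplitude = 0.15,
                                     noise_sd = 5, seed = 1L) {
  stopifnot(inherits(volume, "image_volume"), is.function(remap))
  rng <- range(volume$data)
  span <- max(rng[2] - rng[1], 1e-9)
  probe <- seq(rng[1] - 0.05 * span, rng[2] + 0.05 * span, length.out = 257)
  vals <- remap(probe)
  if (length(vals) != length(probe) || any(!is.finite(vals)) ||
      !(all(diff(vals) > 0) || all(diff(vals) < 0)))
    stop("`remap` must be a vectorized, strictly monotone function over the intensity range",
         call. = FALSE)
  dims <- vol_dims(volume)
  out <- array(remap(as.numeric(volume$data)), dims)
  if (shading_amplitude != 0) {
    ph <- with_seed(seed, stats::runif(3, 0, 2 * pi))
    X <- array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
    shading <- 1 + shading_amplitude *
      sin(2 * pi * X / dims[1] + ph[1]) *
      sin(2 * pi * Y / dims[2] + ph[2]) *
      sin(2 * pi * Z / dims[3] + ph[3])
    out <- out * shading
  }
  if (noise_sd > 0)
    out <- out + with_seed(seed + 1L,
                           array(stats::rnorm(prod(dims), 0, noise_sd), dims))
  image_volume(out, volume$spacing, volume$origin)
}

#' Default CBCT-like intensity curve
#'
#' A mild saturating remap (`200 * tanh(x / 300)`) that compresses the
#' high-intensity (bone) range the way cone-beam reconstructions do while
#' staying strictly monotone.
#'
#' @param x intensity.
#' @export
cbct_remap <- function(x) 200 * tanh(x / 300)

#' Build a fixed/moving benchmark pair
#'
#' The moving scene is the baseline phantom; the fixed scene is the phantom
#' deformed by the ground-truth field (carrying `truth_field`), optionally
#' passed through [simulate_cbct_appearance()] for intermodality benchmarks.
#' Masks are never intensity-transformed.
#'
#' @param spec a [phantom_spec()].
#' @param deformation a [ground_truth_deformation()].
#' @param intermodality give the fixed volume a CBCT-like appearance.
#' @param seed overrides `spec$seed` (noise and CBCT transform seeds derive
#'   from it).
#' @param remap,shading_amplitude,cbct_noise_sd intermodality transform
#'   parameters (see [simulate_cbct_appearance()]).
#' @return list with `fixed` and `moving` `phantom_scene`s, class
#'   `benchmark_pair`.
#' @export
make_benchmark_pair <- function(spec = phantom_spec(),
                                deformation = ground_truth_deformation(),
                                intermodality = FALSE,
                                seed = spec$seed,
                                remap = cbct_remap,
                                shading_amplitude = 0.15,
                                cbct_noise_sd = 5) {
  spec$seed <- as.integer(seed)
  moving <- generate_phantom(spec)
  fixed <- deform_phantom(moving, deformation)
  if (intermodality) {
    fixed$volume <- simulate_cbct_appearance(fixed$volume, remap,
                                             shading_amplitude, cbct_noise_sd,
                                             seed = spec$seed + 1L)
  }
  structure(list(fixed = fixed, moving = moving,
                 intermodality = isTRUE(intermodality)),
            class = "benchmark_pair")
}

#' Constructed intermodality worst case for the NC metric
#'
#' A seeded benchmark pair engineered so that normalized correlation fails
#' while mutual information succeeds, isolating the mechanistic difference
#' between the metrics. The remap is a strictly monotone *decreasing*
#' nonlinear curve (`250 * exp(-x / 150)`): contrast inversion between the
#' modalities, the canonical situation in which a linear-correlation merit
#' breaks down. At the true alignment the Pearson correlation is strongly
#' negative, so every featurelet falls below the NC acceptance threshold and
#' NC-driven registration degenerates to the identity, while the mutual
#' information of the very same patches is unchanged by the inversion and
#' MI-driven registration recovers the deformation. The baseline phantom is
#' noiseless so flat background featurelets are excluded as degenerate under
#' either metric.
#'
#' @param seed integer seed.
#' @return A `benchmark_pair` (see [make_benchmark_pair()]).
#' @export
intermodality_worst_case <- function(seed = 7L) {
  spec <- phantom_spec(noise_sd = 0, seed = seed)
  remap <- function(x) 250 * exp(-x / 150)
  make_benchmark_pair(spec, ground_truth_deformation(),
                      intermodality = TRUE, seed = seed,
                      remap = remap, shading_amplitude = 0.15,
                      cbct_noise_sd = 8)
}

# evaluate code with a transient RNG state, restoring the caller's
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  code
}
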