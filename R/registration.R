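#' Registration configuration
#'
#' Parameters of the piecewise featurelet registration. Defaults follow the
#' optimized parameter set used for all cases in the underlying method:
#' featurelets of 15 x 15 x 15 voxels, a 30 x 30 x 30 voxel search region,
#' gradient-descent step lengths between 0.05 (maximum) and 0.001 (minimum)
#' voxels and a cap of 2000 iterations per featurelet.
#'
#' @param featurelet_size integer triple, featurelet extent in voxels.
#' @param search_size integer triple, search-region extent in voxels; must be
#'   >= `featurelet_size` component-wise.
#' @param metric `"NC"` (normalized correlation) or `"MI"` (mutual
#'   information).
#' @param mi_bins histogram bins per axis for MI.
#' @param max_step,min_step maximum / minimum gradient-descent step length in
#'   voxels; the step is multiplied by `relaxation` whenever the metric
#'   gradient reverses direction, and the descent stops once it falls below
#'   `min_step`.
#' @param max_iterations per-featurelet iteration cap.
#' @param merit_threshold acceptance threshold on the final merit value used
#'   by [filter_by_merit()]; `NULL` selects the per-metric default
#'   (NC >= 0.5, MI >= 0.1 nats).
#' @param relaxation step-length relaxation factor in (0, 1).
#' @param global_init if `TRUE` (default) each featurelet's descent is
#'   initialized at the best integer translation found by an exhaustive scan
#'   of the search region; the descent then refines to subvoxel precision.
#'   `FALSE` starts every descent at zero displacement.
#' @param probe_step finite-difference probe (voxels) for the metric
#'   gradient.
#' @param seed integer; recorded for provenance (the optimizer itself is
#'   deterministic).
#' @return A `registration_config` list.
#' @export
registration_config <- function(featurelet_size = c(15L, 15L, 15L),
                                search_size = c(30L, 30L, 30L),
                                metric = c("NC", "MI"),
                                mi_bins = 32L,
                                max_step = 0.05,
                                min_step = 0.001,
                                max_iterations = 2000L,
                                merit_threshold = NULL,
                                relaxation = 0.5,
                                global_init = TRUE,
                                probe_step = 0.5,
                                seed = 1L) {
  metric <- match.arg(metric)
  featurelet_size <- rep_len(as.integer(featurelet_size), 3L)
  search_size <- rep_len(as.integer(search_size), 3L)
  if (any(featurelet_size < 1L)) stop("featurelet_size must be >= 1", call. = FALSE)
  if (any(search_size < featurelet_size))
    stop("search_size must be >= featurelet_size component-wise", call. = FALSE)
  if (!(min_step > 0 && min_step <= max_step))
    stop("need 0 < min_step <= max_step", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (!(relaxation > 0 && relaxation < 1))
    stop("relaxation must lie in (0, 1)", call. = FALSE)
  if (is.null(merit_threshold))
    merit_threshold <- if (metric == "NC") 0.5 else 0.1
  structure(list(featurelet_size = featurelet_size,
                 search_size = search_size,
                 metric = metric,
                 mi_bins = as.integer(mi_bins),
                 max_step = max_step,
                 min_step = min_step,
                 max_iterations = as.integer(max_iterations),
                 merit_threshold = merit_threshold,
                 relaxation = relaxation,
                 global_init = isTRUE(global_init),
                 probe_step = probe_step,
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Partition the moving image into featurelets
#'
#' Non-overlapping boxes tile the full volume on a regular grid anchored at
#' the origin corner; the last box along each axis is truncated at the volume
#' boundary so that every voxel belongs to exactly one featurelet. Boxes are
#' half-open `[lo, hi)` in 0-based voxel indices.
#'
#' @param volume an [image_volume()] (or anything with the same dims).
#' @param featurelet_size integer triple <= the volume dimensions.
#' @return A tibble with one row per box: grid indices `ix, iy, iz`
#'   (0-based), corners `lo_*`/`hi_*` and voxel-center coordinates `cx, cy,
#'   cz` (the center of the covered voxel span, used as the control-lattice
#'   node).
#' @export
partition_moving_image <- function(volume, featurelet_size) {
  dims <- vol_dims(volume)
  featurelet_size <- rep_len(as.integer(featurelet_size), 3L)
  if (any(featurelet_size > dims))
    stop(sprintf("featurelet size %s exceeds volume dimensions %s",
                 paste(featurelet_size, collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  starts <- lapply(1:3, function(a) seq.int(0L, dims[a] - 1L, by = featurelet_size[a]))
  g <- expand.grid(ix = seq_along(starts[[1]]) - 1L,
                   iy = seq_along(starts[[2]]) - 1L,
                   iz = seq_along(starts[[3]]) - 1L)
  lo <- cbind(starts[[1]][g$ix + 1L], starts[[2]][g$iy + 1L], starts[[3]][g$iz + 1L])
  hi <- pmin(sweep(lo, 2, featurelet_size, "+"), matrix(dims, nrow(lo), 3, byrow = TRUE))
  tibble::tibble(
    ix = g$ix, iy = g$iy, iz = g$iz,
    lo_x = lo[, 1], lo_y = lo[, 2], lo_z = lo[, 3],
    hi_x = hi[, 1], hi_y = hi[, 2], hi_z = hi[, 3],
    cx = (lo[, 1] + hi[, 1] - 1) / 2,
    cy = (lo[, 2] + hi[, 2] - 1) / 2,
    cz = (lo[, 3] + hi[, 3] - 1) / 2)
}

#' Search region for a featurelet
#'
#' A box of extent `search_size` centered on the (half-open) center of the
#' moving-region box, with low corner `floor(center - search_size / 2)`,
#' clipped to the fixed-image bounds.
#'
#' @param moving_region list with integer triples `lo` and `hi` (half-open,
#'   0-based).
#' @param fixed the fixed [image_volume()].
#' @param search_size integer triple.
#' @return list with `lo` and `hi` (half-open, 0-based), clipped.
#' @export
search_region_for <- function(moving_region, fixed, search_size) {
  dims <- vol_dims(fixed)
  search_size <- rep_len(as.integer(search_size), 3L)
  center <- (moving_region$lo + moving_region$hi) / 2
  lo <- floor(center - search_size / 2)
  # clip by shifting the box inside the bounds, preserving its extent where
  # the volume allows it
  lo <- pmin(pmax(lo, 0), pmax(dims - search_size, 0))
  hi <- pmin(lo + search_size, dims)
  lo <- pmin(lo, moving_region$lo)  # always contain the footprint
  hi <- pmax(hi, moving_region$hi)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

patch_is_flat <- function(patch) {
  r <- range(patch)
  (r[2] - r[1]) <= 1e-12 * max(1, abs(r[2]), abs(r[1]))
}

#' Register one featurelet by translation
#'
#' Maximizes the configured metric between the moving patch and the fixed
#' image sampled (trilinear, clamp-to-edge) at translated positions, with
#' the translation constrained so the patch footprint stays inside the
#' search region. With `config$global_init` the metric is first scanned at
#' every feasible integer translation and the regular-step gradient descent
#' (central finite differences, normalized gradient, step halving on
#' direction reversal) refines from the scan argmax; local descent alone
#' cannot search a 30-voxel region from a cold start.
#'
#' The returned displacement is the moving-to-fixed translation: fixed
#' content at `box + displacement` matches the moving patch at `box`.
#'
#' @param moving_patch numeric 3D array (the featurelet contents).
#' @param fixed the fixed [image_volume()].
#' @param search_region list `lo`/`hi` as from [search_region_for()].
#' @param config a [registration_config()].
#' @param box_lo integer triple: the patch's 0-based low corner on the shared
#'   grid; defaults to centering the patch footprint in the search region.
#' @return list with `displacement` (real triple, voxels), `merit`
#'   (`metric_value`), `converged`, `iterations`.
#' @export
register_featurelet <- function(moving_patch, fixed, search_region, config,
                                box_lo = NULL) {
  moving_patch <- as_array3(moving_patch)
  pdim <- dim(moving_patch)
  if (is.null(box_lo))
    box_lo <- floor((search_region$lo + search_region$hi) / 2 - pdim / 2)
  box_lo <- as.integer(box_lo)
  if (patch_is_flat(moving_patch)) {
    return(list(displacement = c(0, 0, 0),
                merit = metric_value(0, config$metric, degenerate = TRUE),
                converged = FALSE, iterations = 0L))
  }
  tau_lo <- as.numeric(search_region$lo - box_lo)
  tau_hi <- as.numeric(search_region$hi - (box_lo + pdim))
  # per-axis displacement bound: half the search margin plus one voxel, so
  # edge featurelets with a shift-clipped region keep the same reach
  bound <- (config$search_size - pdim) / 2 + 1
  tau_lo <- pmax(tau_lo, -bound)
  tau_hi <- pmin(tau_hi, bound)
  if (any(tau_hi < tau_lo))
    stop("search region does not contain the featurelet footprint", call. = FALSE)
  res <- fl_register_cpp(as.numeric(fixed$data), as.integer(vol_dims(fixed)),
                         as.numeric(moving_patch), as.integer(pdim),
                         box_lo, tau_lo, tau_hi,
                         metric = if (config$metric == "NC") 0L else 1L,
                         bins = config$mi_bins,
                         max_step = config$max_step, min_step = config$min_step,
                         max_iter = config$max_iterations,
                         relax = config$relaxation, probe = config$probe_step,
                         global_init = config$global_init)
  list(displacement = as.numeric(res$displacement),
       merit = metric_value(res$merit, config$metric),
       converged = isTRUE(res$converged),
       iterations = as.integer(res$iterations))
}

#' Run featurelet registration over a volume pair
#'
#' Partitions the moving image into featurelets and registers each one by
#' translation into its search region on the fixed image. Inputs are assumed
#' rigidly pre-aligned on a shared grid (see [pre_align_translation()] for a
#' coarse global pre-alignment). The run is fully deterministic.
#'
#' @param moving,fixed pre-aligned [image_volume()]s with identical geometry.
#' @param config a [registration_config()].
#' @return A `featurelet_set`: tibble with one row per featurelet carrying
#'   grid indices, box corners, lattice center (`cx, cy, cz`), the
#'   moving-to-fixed displacement (`dx, dy, dz`, voxels), `merit`,
#'   `degenerate`, `converged`, `iterations` and an `accepted` flag (filled
#'   by [filter_by_merit()]). The configuration and geometry travel along as
#'   attributes.
#' @export
run_registration <- function(moving, fixed, config = registration_config()) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  stopifnot_same_geometry(moving, fixed, "moving and fixed images")
  boxes <- partition_moving_image(moving, config$featurelet_size)
  n <- nrow(boxes)
  disp <- matrix(0, n, 3)
  merit <- numeric(n)
  degenerate <- logical(n)
  converged <- logical(n)
  iterations <- integer(n)
  slo <- matrix(0L, n, 3); shi <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    lo <- c(boxes$lo_x[i], boxes$lo_y[i], boxes$lo_z[i])
    hi <- c(boxes$hi_x[i], boxes$hi_y[i], boxes$hi_z[i])
    sr <- search_region_for(list(lo = lo, hi = hi), fixed, config$search_size)
    slo[i, ] <- sr$lo; shi[i, ] <- sr$hi
    patch <- moving$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                         drop = FALSE]
    r <- register_featurelet(patch, fixed, sr, config, box_lo = lo)
    disp[i, ] <- r$displacement
    merit[i] <- r$merit$value
    degenerate[i] <- r$merit$degenerate
    converged[i] <- r$converged
    iterations[i] <- r$iterations
  }
  out <- tibble::tibble(
    id = seq_len(n),
    ix = boxes$ix, iy = boxes$iy, iz = boxes$iz,
    lo_x = boxes$lo_x, lo_y = boxes$lo_y, lo_z = boxes$lo_z,
    hi_x = boxes$hi_x, hi_y = boxes$hi_y, hi_z = boxes$hi_z,
    slo_x = slo[, 1], slo_y = slo[, 2], slo_z = slo[, 3],
    shi_x = shi[, 1], shi_y = shi[, 2], shi_z = shi[, 3],
    cx = boxes$cx, cy = boxes$cy, cz = boxes$cz,
    dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
    merit = merit, degenerate = degenerate,
    converged = converged, iterations = iterations,
    accepted = NA)
  attr(out, "config") <- config
  attr(out, "geometry") <- list(dims = vol_dims(fixed), spacing = fixed$spacing,
                                origin = fixed$origin)
  attr(out, "lattice_dims") <- c(max(boxes$ix) + 1L, max(boxes$iy) + 1L,
                                 max(boxes$iz) + 1L)
  class(out) <- c("featurelet_set", class(out))
  out
}

#' Coarse global translation pre-alignment
#'
#' Plumbing for inputs that are not yet rigidly aligned: exhaustive
#' normalized-correlation scan of integer translations at a coarsened
#' resolution. Returns the integer voxel shift (moving-to-fixed) at full
#' resolution; apply it by translating the moving image before
#' [run_registration()].
#'
#' @param moving,fixed [image_volume()]s of identical dimensions.
#' @param max_shift maximum absolute shift searched, in full-resolution
#'   voxels per axis.
#' @param stride coarsening factor (every `stride`-th voxel is used).
#' @return integer triple.
#' @export
pre_align_translation <- function(moving, fixed, max_shift = 10L, stride = 2L) {
  stopifnot_same_geometry(moving, fixed, "moving and fixed images")
  idx <- lapply(vol_dims(moving), function(n) seq.int(1L, n, by = stride))
  m <- moving$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  f <- fixed$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  r <- max(1L, as.integer(max_shift) %/% as.integer(stride))
  res <- fl_register_cpp(as.numeric(f), as.integer(dim(f)),
                         as.numeric(m), as.integer(dim(m)),
                         box_lo = c(0L, 0L, 0L),
                         tau_lo = rep(-r, 3), tau_hi = rep(r, 3),
                         metric = 0L, bins = 32L,
                         max_step = 0.5, min_step = 0.4, max_iter = 1L,
                         relax = 0.5, probe = 0.5, global_init = TRUE)
  as.integer(round(res$scan_displacement)) * as.integer(stride)
}

#' @export
print.registration_config <- function(x, ...) {
  cat(sprintf("<registration_config> metric %s, featurelet %s, search %s\n",
              x$metric, paste(x$featurelet_size, collapse = "x"),
              paste(x$search_size, collapse = "x")))
  cat(sprintf("  steps %.3g -> %.3g, max %d iterations, merit threshold %.3g\n",
              x$max_step, x$min_step, x$max_iterations, x$merit_threshold))
  invisible(x)
}
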