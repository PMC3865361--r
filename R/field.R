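#' Restrict featurelets by merit and build the control-point lattice
#'
#' A featurelet is accepted iff its descent converged, it is not degenerate
#' (flat), and its final merit value reaches the configured threshold
#' (defaults: NC >= 0.5, MI >= 0.1 nats). The restriction keeps
#' misregistered featurelets from misleading the interpolation of the dense
#' field. Accepted nodes carry the displacement in the resampling direction
#' (the negated moving-to-fixed translation), so that interpolating them
#' yields a field directly usable by [warp_image()] without inversion.
#'
#' @param featurelets a `featurelet_set` from [run_registration()].
#' @param config a [registration_config()]; defaults to the one stored on
#'   `featurelets`.
#' @return A `control_points` object: per-axis lattice node coordinates
#'   (voxel units), a displacement array, a validity array, the fixed-image
#'   geometry, and the featurelet table with its `accepted` column filled in.
#' @export
filter_by_merit <- function(featurelets, config = NULL) {
  stopifnot(inherits(featurelets, "featurelet_set") || is.data.frame(featurelets))
  if (nrow(featurelets) == 0L) stop("no featurelets supplied", call. = FALSE)
  if (is.null(config)) config <- attr(featurelets, "config")
  if (is.null(config)) stop("no registration_config available", call. = FALSE)
  geometry <- attr(featurelets, "geometry")
  accepted <- featurelets$converged & !featurelets$degenerate &
    featurelets$merit >= config$merit_threshold
  if (!any(accepted))
    stop(sprintf(paste0(
      "all %d featurelets were rejected at merit threshold %.3g (%s); ",
      "consider relaxing `merit_threshold`"),
      nrow(featurelets), config$merit_threshold, config$metric), call. = FALSE)
  featurelets$accepted <- accepted
  ldims <- attr(featurelets, "lattice_dims")
  if (is.null(ldims))
    ldims <- c(max(featurelets$ix) + 1L, max(featurelets$iy) + 1L,
               max(featurelets$iz) + 1L)
  coords <- list(
    x = axis_coords(featurelets$ix, featurelets$cx, ldims[1]),
    y = axis_coords(featurelets$iy, featurelets$cy, ldims[2]),
    z = axis_coords(featurelets$iz, featurelets$cz, ldims[3]))
  disp <- array(0, c(ldims, 3L))
  valid <- array(FALSE, ldims)
  node <- cbind(featurelets$ix + 1L, featurelets$iy + 1L, featurelets$iz + 1L)
  for (i in which(accepted)) {
    valid[node[i, 1], node[i, 2], node[i, 3]] <- TRUE
    # resampling convention: field = -(moving -> fixed translation)
    disp[node[i, 1], node[i, 2], node[i, 3], ] <-
      -c(featurelets$dx[i], featurelets$dy[i], featurelets$dz[i])
  }
  structure(list(coords = coords, disp = disp, valid = valid,
                 geometry = geometry, featurelets = featurelets),
            class = "control_points")
}

axis_coords <- function(idx, centers, n) {
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- centers[match(i - 1L, idx)]
  out
}

#' @export
print.control_points <- function(x, ...) {
  cat(sprintf("<control_points> %s lattice, %d / %d nodes valid\n",
              paste(dim(x$valid), collapse = " x "), sum(x$valid),
              length(x$valid)))
  invisible(x)
}

#' Interpolate control-point displacements to a dense field
#'
#' Each displacement component is separately trilinearly interpolated on the
#' (rectilinear) featurelet-center lattice; truncated edge featurelets keep
#' their true centers. Invalid (rejected) nodes are filled beforehand with
#' the displacement of the nearest valid node (Euclidean distance between
#' node centers in voxel units; ties broken by lowest node index); voxels
#' outside the lattice hull take the clamped edge value. At a valid node
#' whose center falls on a voxel the field reproduces the node displacement
#' exactly.
#'
#' @param controls a `control_points` object from [filter_by_merit()].
#' @param geometry optional list with `dims`, `spacing`, `origin`; defaults
#'   to the fixed-image geometry stored on `controls`.
#' @return A [displacement_field()] over the full grid.
#' @export
interpolate_field <- function(controls, geometry = NULL) {
  stopifnot(inherits(controls, "control_points"))
  if (is.null(geometry)) geometry <- controls$geometry
  if (is.null(geometry)) stop("no geometry available", call. = FALSE)
  if (!any(controls$valid)) stop("no valid control nodes", call. = FALSE)
  disp <- infill_invalid(controls)
  dims <- as.integer(geometry$dims)
  ax <- lapply(1:3, function(a)
    axis_interp(controls$coords[[a]], seq.int(0L, dims[a] - 1L)))
  n1 <- length(controls$coords$x); n2 <- length(controls$coords$y)
  vectors <- array(0, c(dims, 3L))
  # expand per-axis node indices/weights to the full grid
  I0 <- list(ax[[1]]$i0, ax[[2]]$i0, ax[[3]]$i0)
  I1 <- list(ax[[1]]$i1, ax[[2]]$i1, ax[[3]]$i1)
  W  <- list(ax[[1]]$w,  ax[[2]]$w,  ax[[3]]$w)
  gx0 <- array(rep(I0[[1]], times = dims[2] * dims[3]), dims)
  gx1 <- array(rep(I1[[1]], times = dims[2] * dims[3]), dims)
  gwx <- array(rep(W[[1]], times = dims[2] * dims[3]), dims)
  gy0 <- array(rep(rep(I0[[2]], each = dims[1]), times = dims[3]), dims)
  gy1 <- array(rep(rep(I1[[2]], each = dims[1]), times = dims[3]), dims)
  gwy <- array(rep(rep(W[[2]], each = dims[1]), times = dims[3]), dims)
  gz0 <- array(rep(I0[[3]], each = dims[1] * dims[2]), dims)
  gz1 <- array(rep(I1[[3]], each = dims[1] * dims[2]), dims)
  gwz <- array(rep(W[[3]], each = dims[1] * dims[2]), dims)
  for (comp in 1:3) {
    dcomp <- disp[, , , comp]
    nidx <- function(i, j, k) i + n1 * (j - 1L) + n1 * n2 * (k - 1L)
    c000 <- dcomp[nidx(gx0, gy0, gz0)]; c100 <- dcomp[nidx(gx1, gy0, gz0)]
    c010 <- dcomp[nidx(gx0, gy1, gz0)]; c110 <- dcomp[nidx(gx1, gy1, gz0)]
    c001 <- dcomp[nidx(gx0, gy0, gz1)]; c101 <- dcomp[nidx(gx1, gy0, gz1)]
    c011 <- dcomp[nidx(gx0, gy1, gz1)]; c111 <- dcomp[nidx(gx1, gy1, gz1)]
    vectors[, , , comp] <-
      ((c000 * (1 - gwx) + c100 * gwx) * (1 - gwy) +
       (c010 * (1 - gwx) + c110 * gwx) * gwy) * (1 - gwz) +
      ((c001 * (1 - gwx) + c101 * gwx) * (1 - gwy) +
       (c011 * (1 - gwx) + c111 * gwx) * gwy) * gwz
  }
  displacement_field(vectors, geometry$spacing, geometry$origin)
}

# bracketing node indices (1-based) and weights for every query coordinate,
# clamped to the lattice hull
axis_interp <- function(coords, xs) {
  m <- length(coords)
  if (m == 1L)
    return(list(i0 = rep(1L, length(xs)), i1 = rep(1L, length(xs)),
                w = rep(0, length(xs))))
  i0 <- findInterval(xs, coords, all.inside = TRUE)
  i1 <- i0 + 1L
  w <- (xs - coords[i0]) / (coords[i1] - coords[i0])
  w <- pmin(pmax(w, 0), 1)
  list(i0 = i0, i1 = i1, w = w)
}

infill_invalid <- function(controls) {
  disp <- controls$disp
  valid <- controls$valid
  if (all(valid)) return(disp)
  ld <- dim(valid)
  g <- expand.grid(i = seq_len(ld[1]), j = seq_len(ld[2]), k = seq_len(ld[3]))
  pos <- cbind(controls$coords$x[g$i], controls$coords$y[g$j],
               controls$coords$z[g$k])
  vidx <- which(as.logical(valid))
  iidx <- which(!as.logical(valid))
  vpos <- pos[vidx, , drop = FALSE]
  for (ii in iidx) {
    d2 <- (vpos[, 1] - pos[ii, 1])^2 + (vpos[, 2] - pos[ii, 2])^2 +
      (vpos[, 3] - pos[ii, 3])^2
    nearest <- vidx[which.min(d2)]  # which.min takes the first = lowest index
    ijk_i <- arrayInd(ii, ld); ijk_n <- arrayInd(nearest, ld)
    disp[ijk_i[1], ijk_i[2], ijk_i[3], ] <- disp[ijk_n[1], ijk_n[2], ijk_n[3], ]
  }
  disp
}

#' Warp an image with a displacement field
#'
#' Pull-back resampling: output voxel `v` takes the input sampled with
#' trilinear interpolation (clamp-to-edge) at `v + field(v)`, so warping the
#' moving image with the field produced by the registration pipeline
#' resamples it onto the fixed grid. A zero field is the identity.
#'
#' @param image an [image_volume()].
#' @param field a [displacement_field()] with matching geometry.
#' @return An [image_volume()] on the same grid.
#' @export
warp_image <- function(image, field) {
  stopifnot(inherits(image, "image_volume"), inherits(field, "displacement_field"))
  stopifnot_same_geometry(image, field, "image and field")
  pos <- warp_positions(field)
  out <- sample_trilinear_arr(image$data, pos$x, pos$y, pos$z)
  image_volume(out, image$spacing, image$origin)
}

#' Warp a structure mask with a displacement field
#'
#' As [warp_image()] but with nearest-neighbor sampling so the output stays
#' strictly binary (contour propagation).
#'
#' @param mask a [structure_mask()].
#' @inheritParams warp_image
#' @return A [structure_mask()].
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(mask, "structure_mask"), inherits(field, "displacement_field"))
  stopifnot_same_geometry(mask, field, "mask and field")
  pos <- warp_positions(field)
  out <- sample_nearest_arr(mask$data, pos$x, pos$y, pos$z)
  structure_mask(out, mask$spacing, mask$origin)
}

warp_positions <- function(field) {
  d <- vol_dims(field)
  X <- array(rep(seq.int(0L, d[1] - 1L), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq.int(0L, d[2] - 1L), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq.int(0L, d[3] - 1L), each = d[1] * d[2]), d)
  list(x = X + field$vectors[, , , 1],
       y = Y + field$vectors[, , , 2],
       z = Z + field$vectors[, , , 3])
}

sample_trilinear_arr <- function(data, px, py, pz) {
  d <- dim(data); nx <- d[1]; ny <- d[2]; nz <- d[3]
  px <- pmin(pmax(px, 0), nx - 1)
  py <- pmin(pmax(py, 0), ny - 1)
  pz <- pmin(pmax(pz, 0), nz - 1)
  x0 <- pmax(pmin(floor(px), nx - 2), 0); x1 <- pmin(x0 + 1, nx - 1)
  y0 <- pmax(pmin(floor(py), ny - 2), 0); y1 <- pmin(y0 + 1, ny - 1)
  z0 <- pmax(pmin(floor(pz), nz - 2), 0); z1 <- pmin(z0 + 1, nz - 1)
  wx <- pmin(pmax(px - x0, 0), 1)
  wy <- pmin(pmax(py - y0, 0), 1)
  wz <- pmin(pmax(pz - z0, 0), 1)
  idx <- function(ix, iy, iz) 1 + ix + nx * (iy + ny * iz)
  c000 <- data[idx(x0, y0, z0)]; c100 <- data[idx(x1, y0, z0)]
  c010 <- data[idx(x0, y1, z0)]; c110 <- data[idx(x1, y1, z0)]
  c001 <- data[idx(x0, y0, z1)]; c101 <- data[idx(x1, y0, z1)]
  c011 <- data[idx(x0, y1, z1)]; c111 <- data[idx(x1, y1, z1)]
  out <- ((c000 * (1 - wx) + c100 * wx) * (1 - wy) +
          (c010 * (1 - wx) + c110 * wx) * wy) * (1 - wz) +
         ((c001 * (1 - wx) + c101 * wx) * (1 - wy) +
          (c011 * (1 - wx) + c111 * wx) * wy) * wz
  array(out, d)
}

sample_nearest_arr <- function(data, px, py, pz) {
  d <- dim(data); nx <- d[1]; ny <- d[2]; nz <- d[3]
  xi <- pmin(pmax(round(px), 0), nx - 1)
  yi <- pmin(pmax(round(py), 0), ny - 1)
  zi <- pmin(pmax(round(pz), 0), nz - 1)
  array(data[1 + xi + nx * (yi + ny * zi)], d)
}
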