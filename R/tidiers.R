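#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a featurelet registration
#'
#' @param x a `featurelet_registration` from [register_pair()].
#' @param ... unused.
#' @return The per-featurelet tibble (grid index, box corners, displacement,
#'   merit, acceptance).
#' @export
tidy.featurelet_registration <- function(x, ...) {
  out <- x$featurelets
  class(out) <- setdiff(class(out), "featurelet_set")
  out
}

#' @rdname tidy.featurelet_registration
#' @export
tidy.featurelet_set <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "featurelet_set")
  out
}

#' One-row summary of a featurelet registration
#'
#' @inheritParams tidy.featurelet_registration
#' @return tibble with metric, featurelet counts, acceptance rate, merit
#'   summaries and the maximum accepted displacement magnitude (voxels).
#' @export
glance.featurelet_registration <- function(x, ...) {
  fl <- x$featurelets
  acc <- fl$accepted %in% TRUE
  mag <- sqrt(fl$dx^2 + fl$dy^2 + fl$dz^2)
  tibble::tibble(
    metric = x$config$metric,
    n_featurelets = nrow(fl),
    n_degenerate = sum(fl$degenerate),
    n_accepted = sum(acc),
    acceptance_rate = mean(acc),
    median_merit = stats::median(fl$merit[!fl$degenerate]),
    max_displacement_vox = if (any(acc)) max(mag[acc]) else NA_real_,
    succeeded = x$succeeded)
}

#' Plot an axial slice of a volume
#'
#' @param volume an [image_volume()] (or [structure_mask()]).
#' @param k 0-based slice index along the third axis; defaults to the middle
#'   slice.
#' @return a ggplot object.
#' @export
plot_slice <- function(volume, k = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  d <- vol_dims(volume)
  if (is.null(k)) k <- (d[3] - 1L) %/% 2L
  sl <- volume$data[, , k + 1L]
  df <- tibble::tibble(
    x = rep(seq_len(d[1]) - 1L, times = d[2]),
    y = rep(seq_len(d[2]) - 1L, each = d[1]),
    intensity = as.numeric(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = volume$spacing[2] / volume$spacing[1]) +
    ggplot2::labs(x = "voxel x", y = "voxel y",
                  title = sprintf("axial slice k = %d", k)) +
    ggplot2::theme_minimal()
}

#' Quiver plot of featurelet displacements on a lattice slice
#'
#' Draws accepted featurelet displacement vectors (moving-to-fixed, voxel
#' units) for one axial layer of the control lattice; rejected and
#' degenerate featurelets are shown as hollow points.
#'
#' @param object a `featurelet_registration` or `featurelet_set`.
#' @param iz 0-based lattice layer; defaults to the middle layer.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.featurelet_registration <- function(object, iz = NULL, ...) {
  fl <- object$featurelets
  autoplot_featurelets(fl, iz)
}

#' @rdname autoplot.featurelet_registration
#' @export
autoplot.featurelet_set <- function(object, iz = NULL, ...) {
  autoplot_featurelets(object, iz)
}

autoplot_featurelets <- function(fl, iz = NULL) {
  if (is.null(iz)) iz <- floor(max(fl$iz) / 2)
  sl <- fl[fl$iz == iz, ]
  sl$status <- ifelse(sl$degenerate, "degenerate",
                      ifelse(sl$accepted %in% TRUE, "accepted", "rejected"))
  ggplot2::ggplot(sl, ggplot2::aes(x = .data$cx, y = .data$cy)) +
    ggplot2::geom_segment(
      data = sl[sl$status == "accepted", ],
      ggplot2::aes(xend = .data$cx + .data$dx, yend = .data$cy + .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), size = 1.5) +
    ggplot2::scale_shape_manual(
      values = c(accepted = 16, rejected = 1, degenerate = 4)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "voxel x", y = "voxel y",
                  title = sprintf("featurelet displacements, lattice layer iz = %d", iz)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
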