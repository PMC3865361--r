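#' Full registration pipeline on a volume pair
#'
#' Convenience composition of [run_registration()], [filter_by_merit()] and
#' [interpolate_field()]: featurelet matching, merit restriction and
#' trilinear interpolation to a dense pull-back field. When every featurelet
#' is rejected by the merit restriction, `on_empty = "error"` propagates the
#' error while `on_empty = "identity"` returns an all-zero field flagged as
#' a failed registration (useful when a benchmark must grade a metric that
#' breaks down, e.g. NC on intermodality data).
#'
#' @param moving,fixed pre-aligned [image_volume()]s.
#' @param config a [registration_config()].
#' @param on_empty behaviour when no featurelet survives the restriction.
#' @return A `featurelet_registration` object: list with `field`
#'   ([displacement_field()]), `featurelets` (tibble), `controls`
#'   (`control_points` or `NULL`), `config` and `succeeded`.
#' @export
register_pair <- function(moving, fixed, config = registration_config(),
                          on_empty = c("error", "identity")) {
  on_empty <- match.arg(on_empty)
  featurelets <- run_registration(moving, fixed, config)
  controls <- tryCatch(filter_by_merit(featurelets, config),
                       error = function(e) e)
  if (inherits(controls, "error")) {
    if (on_empty == "error") stop(controls)
    featurelets$accepted <- FALSE
    field <- displacement_field(array(0, c(vol_dims(fixed), 3L)),
                                fixed$spacing, fixed$origin)
    return(structure(list(field = field, featurelets = featurelets,
                          controls = NULL, config = config,
                          succeeded = FALSE,
                          failure = conditionMessage(controls)),
                     class = "featurelet_registration"))
  }
  field <- interpolate_field(controls)
  structure(list(field = field, featurelets = controls$featurelets,
                 controls = controls, config = config, succeeded = TRUE,
                 failure = NULL),
            class = "featurelet_registration")
}

#' @export
print.featurelet_registration <- function(x, ...) {
  n <- nrow(x$featurelets)
  acc <- sum(x$featurelets$accepted, na.rm = TRUE)
  cat(sprintf("<featurelet_registration> %s metric, %d featurelets, %d accepted%s\n",
              x$config$metric, n, acc,
              if (!x$succeeded) " (FAILED: identity field returned)" else ""))
  invisible(x)
}

#' Mean absolute field error inside structures
#'
#' Mean Euclidean norm (voxels) of the difference between an estimated and a
#' ground-truth displacement field, averaged over the foreground voxels of
#' the supplied masks.
#'
#' @param field,truth [displacement_field()]s with matching geometry.
#' @param masks a [structure_mask()] or list of masks; their union defines
#'   the evaluation region.
#' @return numeric scalar (voxels).
#' @export
field_mae <- function(field, truth, masks) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(truth, "displacement_field"))
  stopifnot_same_geometry(field, truth, "fields")
  if (inherits(masks, "structure_mask")) masks <- list(masks)
  region <- Reduce(`|`, lapply(masks, function(m) m$data != 0))
  if (!any(region)) stop("evaluation region is empty", call. = FALSE)
  diff2 <- (field$vectors[, , , 1] - truth$vectors[, , , 1])^2 +
           (field$vectors[, , , 2] - truth$vectors[, , , 2])^2 +
           (field$vectors[, , , 3] - truth$vectors[, , , 3])^2
  mean(sqrt(diff2[region]))
}

#' Run and score a registration method on a benchmark pair
#'
#' Registers the moving scene to the fixed scene of a [make_benchmark_pair()]
#' result, propagates the moving structure masks through the estimated field
#' and scores them against the fixed scene's ground-truth masks. The
#' pre-registration ("RR") score is the unwarped moving mask against the
#' same reference.
#'
#' @param pair a `benchmark_pair`.
#' @param config a [registration_config()].
#' @param on_empty passed to [register_pair()].
#' @return list with `registration` (`featurelet_registration`), `scores`
#'   (tibble: structure, dsc_before, dsc_after, hausdorff_before_px,
#'   hausdorff_after_px) and `mae_vox` (mean absolute field error inside the
#'   structures, against `truth_field`).
#' @export
evaluate_benchmark <- function(pair, config = registration_config(),
                               on_empty = "identity") {
  stopifnot(inherits(pair, "benchmark_pair"))
  reg <- register_pair(pair$moving$volume, pair$fixed$volume, config,
                       on_empty = on_empty)
  structures <- names(pair$fixed$masks)
  rows <- lapply(structures, function(s) {
    ref <- pair$fixed$masks[[s]]
    before <- pair$moving$masks[[s]]
    after <- warp_mask(before, reg$field)
    tibble::tibble(
      structure = s,
      dsc_before = dice_coefficient(before, ref),
      dsc_after = dice_coefficient(after, ref),
      hausdorff_before_px = hausdorff_distance(before, ref),
      hausdorff_after_px = hausdorff_distance(after, ref))
  })
  mae <- if (!is.null(pair$fixed$truth_field))
    field_mae(reg$field, pair$fixed$truth_field, pair$fixed$masks)
  else NA_real_
  list(registration = reg, scores = do.call(rbind, rows), mae_vox = mae)
}
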