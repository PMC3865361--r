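#' Patch similarity metrics
#'
#' The two merit functions driving featurelet registration. Both are
#' maximized: normalized correlation (NC) is the Pearson correlation of the
#' flattened intensities, reported on \[-1, 1\] and invariant under positive
#' affine rescaling of either patch; mutual information (MI) is
#' `H(A) + H(B) - H(A,B)` in nats (>= 0) estimated from a joint histogram
#' with `bins x bins` equal-width bins spanning each patch's own intensity
#' range, hence invariant under any monotone remapping of one patch that
#' preserves bin assignment. This asymmetry -- MI tolerating non-affine
#' intensity relationships that destroy linear correlation -- is what makes
#' MI the metric of choice for intermodality (CT vs CBCT) registration.
#'
#' A flat (zero-variance) patch makes NC undefined; the returned value is 0
#' with `degenerate = TRUE` so callers can exclude the featurelet instead of
#' dividing by zero. MI of a flat patch is exactly 0.
#'
#' @param patch_a,patch_b numeric arrays of identical shape (>= 2 voxels).
#' @param bins number of histogram bins per axis for MI (>= 2), default 32.
#' @return A `metric_value`: list with `value`, `kind` ("NC" or "MI"),
#'   `higher_is_better = TRUE` and `degenerate`.
#' @examples
#' a <- array(1:8, c(2, 2, 2))
#' normalized_correlation(a, a)$value          # 1
#' mutual_information(a, a, bins = 8)$value    # log(8)
#' @export
normalized_correlation <- function(patch_a, patch_b) {
  a <- as.numeric(patch_a); b <- as.numeric(patch_b)
  check_patches(patch_a, patch_b)
  va <- a - mean(a); vb <- b - mean(b)
  da <- sum(va * va); db <- sum(vb * vb)
  if (da <= 0 || db <= 0) {
    return(metric_value(0, "NC", degenerate = TRUE))
  }
  metric_value(sum(va * vb) / sqrt(da * db), "NC")
}

#' @rdname normalized_correlation
#' @export
mutual_information <- function(patch_a, patch_b, bins = 32L) {
  a <- as.numeric(patch_a); b <- as.numeric(patch_b)
  check_patches(patch_a, patch_b)
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  n <- length(a)
  p <- joint[joint > 0] / n
  hab <- -sum(p * log(p))
  pa <- tabulate(ia, nbins = bins); pa <- pa[pa > 0] / n
  pb <- tabulate(ib, nbins = bins); pb <- pb[pb > 0] / n
  mi <- -sum(pa * log(pa)) - sum(pb * log(pb)) - hab
  metric_value(max(mi, 0), "MI", degenerate = FALSE)
}

# equal-width bins over the vector's own range; flat input -> all in bin 1
bin_index <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  i <- floor((x - lo) / (hi - lo) * bins) + 1L
  i[i > bins] <- bins
  as.integer(i)
}

metric_value <- function(value, kind, degenerate = FALSE) {
  structure(list(value = as.numeric(value), kind = kind,
                 higher_is_better = TRUE, degenerate = isTRUE(degenerate)),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("<metric_value> %s = %.6g%s\n", x$kind, x$value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

check_patches <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("patch shapes differ: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  if (length(a) < 2L) stop("patches must contain at least 2 voxels", call. = FALSE)
  invisible(TRUE)
}
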