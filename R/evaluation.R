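#' Dice similarity coefficient (0-100)
#'
#' Volume overlap index `2 |Vd ∩ Vm| / (|Vd| + |Vm|) x 100` between a
#' deformed and a reference structure mask. Symmetric; 100 for identical
#' non-empty masks, 0 for disjoint masks.
#'
#' @param deformed,reference [structure_mask()]s with matching geometry; at
#'   least one must be non-empty.
#' @return numeric in \[0, 100\].
#' @export
dice_coefficient <- function(deformed, reference) {
  stopifnot(inherits(deformed, "structure_mask"),
            inherits(reference, "structure_mask"))
  stopifnot_same_geometry(deformed, reference, "masks")
  nd <- sum(deformed$data)
  nm <- sum(reference$data)
  if (nd + nm == 0)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  ni <- sum(deformed$data * reference$data)
  2 * ni / (nd + nm) * 100
}

#' Surface Hausdorff distance
#'
#' `H(A,B) = max(h(A,B), h(B,A))` with `h(A,B) = max_{a in A} min_{b in B}
#' ||a - b||`, computed over the surface voxels of each mask (foreground
#' voxels with at least one face-adjacent background neighbor, the volume
#' boundary counting as background). Distances are Euclidean on voxel
#' indices ("pixels") by default; with `use_mm = TRUE` indices are scaled by
#' the spacing first, which matters for anisotropic slices.
#'
#' @param a,b non-empty [structure_mask()]s with matching geometry.
#' @param use_mm report millimetres instead of pixels.
#' @return numeric >= 0; 0 iff the surfaces coincide.
#' @export
hausdorff_distance <- function(a, b, use_mm = FALSE) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  stopifnot_same_geometry(a, b, "masks")
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  if (nrow(sa) == 0L || nrow(sb) == 0L)
    stop("Hausdorff distance requires two non-empty masks", call. = FALSE)
  if (use_mm) {
    sa <- sweep(sa, 2, a$spacing, "*")
    sb <- sweep(sb, 2, b$spacing, "*")
  }
  max(directed_hausdorff(sa, sb), directed_hausdorff(sb, sa))
}

# 0-based index coordinates of surface voxels (6-connectivity)
surface_voxels <- function(mask) {
  m <- mask$data != 0
  d <- dim(m)
  shifted <- function(axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    src <- seq_len(n) + by
    keep <- src >= 1L & src <= n
    dst <- seq_len(n)[keep]
    src <- src[keep]
    if (axis == 1) out[dst, , ] <- m[src, , ]
    if (axis == 2) out[, dst, ] <- m[, src, ]
    if (axis == 3) out[, , dst] <- m[, , src]
    out
  }
  interior <- m
  for (axis in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shifted(axis, by)
  surf <- m & !interior
  which(surf, arr.ind = TRUE) - 1L
}

# max over rows of `from` of the distance to the nearest row of `to`,
# chunked to bound memory
directed_hausdorff <- function(from, to, chunk = 512L) {
  worst <- 0
  n <- nrow(from)
  t1 <- to[, 1]; t2 <- to[, 2]; t3 <- to[, 3]
  for (start in seq.int(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(from[rows, 1], t1, "-")^2 +
          outer(from[rows, 2], t2, "-")^2 +
          outer(from[rows, 3], t3, "-")^2
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(worst)
}

#' Mask volume
#'
#' @param mask a [structure_mask()].
#' @return list with `voxels` (foreground count) and `cc` (count times voxel
#'   volume in mm^3, divided by 1000).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  n <- sum(mask$data != 0)
  list(voxels = as.integer(n), cc = n * prod(mask$spacing) / 1000)
}

#' Center of mass of a mask
#'
#' Mean physical position (mm) of the foreground voxel centers,
#' `origin + index * spacing`.
#'
#' @param mask a non-empty [structure_mask()].
#' @return numeric triple (mm).
#' @export
center_of_mass <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  idx <- which(mask$data != 0, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stop("center of mass of an empty mask is undefined",
                            call. = FALSE)
  unname(mask$origin + colMeans(idx) * mask$spacing)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired differences `scores_m2 - scores_m1`.
#' Zero differences are dropped. For n <= 25 retained pairs the p-value uses
#' the exact null distribution of the signed-rank sum, computed by a
#' generating-function convolution over the (mid)ranks so ties are handled
#' exactly; larger n uses the normal approximation with tie correction and
#' continuity correction. The label follows the reporting convention
#' NS / better / worse: NS when `p >= alpha`, otherwise the sign of the
#' median difference oriented by `higher_is_better`.
#'
#' @param scores_m1,scores_m2 paired numeric vectors of equal length >= 5.
#' @param alpha significance level.
#' @param higher_is_better whether larger scores mean better performance
#'   (TRUE for DSC, FALSE for Hausdorff distance).
#' @return A `comparison_label`: list with `label` ("NS", "better", "worse"),
#'   `p_value`, `alpha`, `n_effective`, `median_difference`.
#' @examples
#' wilcoxon_compare(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))  # p = 0.03125
#' @export
wilcoxon_compare <- function(scores_m1, scores_m2, alpha = 0.05,
                             higher_is_better = TRUE) {
  if (length(scores_m1) != length(scores_m2))
    stop("paired score vectors must have equal length", call. = FALSE)
  if (length(scores_m1) < 5L)
    stop("at least 5 paired observations are required", call. = FALSE)
  d <- as.numeric(scores_m2) - as.numeric(scores_m1)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(comparison_label("NS", 1, alpha, 0L, 0))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  p <- if (n <= 25L) signed_rank_exact_p(r, v) else signed_rank_normal_p(r, v, n)
  med <- stats::median(d)
  label <- if (p >= alpha || med == 0) "NS"
    else if ((med > 0) == isTRUE(higher_is_better)) "better" else "worse"
  comparison_label(label, p, alpha, n, med)
}

comparison_label <- function(label, p, alpha, n, med) {
  structure(list(label = label, p_value = min(p, 1), alpha = alpha,
                 n_effective = n, median_difference = med),
            class = "comparison_label")
}

#' @export
print.comparison_label <- function(x, ...) {
  cat(sprintf("<comparison_label> %s (p = %.4g, n = %d, median diff = %.4g)\n",
              x$label, x$p_value, x$n_effective, x$median_difference))
  invisible(x)
}

# exact two-sided p for the signed-rank sum given the (mid)ranks of |d|:
# distribution over all 2^n equiprobable sign assignments via convolution on
# doubled ranks (integers even with midranks)
signed_rank_exact_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2V = s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(ranks)
  v2 <- 2 * v
  eps <- 1e-9
  p_le <- sum(counts[seq_len(total + 1L)[(seq_len(total + 1L) - 1) <= v2 + eps]])
  p_ge <- sum(counts[seq_len(total + 1L)[(seq_len(total + 1L) - 1) >= v2 - eps]])
  min(1, 2 * min(p_le, p_ge))
}

signed_rank_normal_p <- function(ranks, v, n) {
  mu <- n * (n + 1) / 4
  tie_tab <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- v - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-structure evaluation report with paired comparisons
#'
#' Computes, for each structure and method, the Dice similarity coefficient
#' against the reference, the surface Hausdorff distance in pixels and mm,
#' the volume in voxels and cc, the center of mass and its shift from the
#' reference (mm), and the unsigned percent volume change. Method pairs are
#' compared with the paired Wilcoxon signed-rank test over per-structure DSC
#' and Hausdorff scores when at least 5 structures are available; with fewer
#' structures the comparison rows carry `p_value = NA` and label "NS" with a
#' note.
#'
#' Labels: "NS", "+" (significantly better), "++" (p < alpha/5), "-" / "--"
#' (significantly worse), method 2 judged against method 1.
#'
#' @param reference named list of reference [structure_mask()]s.
#' @param methods named list of methods; each element is a named list of
#'   masks covering the same structure names (typically including an `"RR"`
#'   entry holding the unregistered input masks).
#' @param alpha significance level for the comparisons.
#' @return An `evaluation_report`: list with tibbles `metrics` and
#'   `comparisons`.
#' @export
build_report <- function(reference, methods, alpha = 0.05) {
  stopifnot(is.list(reference), length(reference) > 0, !is.null(names(reference)))
  stopifnot(is.list(methods), length(methods) > 0, !is.null(names(methods)))
  structures <- names(reference)
  rows <- list()
  for (m in names(methods)) {
    masks <- methods[[m]]
    missing <- setdiff(structures, names(masks))
    if (length(missing))
      stop(sprintf("method '%s' lacks masks for: %s", m,
                   paste(missing, collapse = ", ")), call. = FALSE)
    for (s in structures) {
      ref <- reference[[s]]
      msk <- masks[[s]]
      stopifnot_same_geometry(msk, ref, sprintf("masks for '%s'", s))
      vol <- mask_volume(msk)
      vol_ref <- mask_volume(ref)
      com <- center_of_mass(msk)
      com_ref <- center_of_mass(ref)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        structure = s, method = m,
        dsc = dice_coefficient(msk, ref),
        hausdorff_px = hausdorff_distance(msk, ref, use_mm = FALSE),
        hausdorff_mm = hausdorff_distance(msk, ref, use_mm = TRUE),
        volume_voxels = vol$voxels,
        volume_cc = vol$cc,
        com_x_mm = com[1], com_y_mm = com[2], com_z_mm = com[3],
        com_shift_mm = sqrt(sum((com - com_ref)^2)),
        volume_change_pct =
          if (vol_ref$voxels > 0) abs(vol$voxels - vol_ref$voxels) /
            vol_ref$voxels * 100 else NA_real_)
    }
  }
  metrics <- do.call(rbind, rows)
  cmp_rows <- list()
  pairs <- if (length(methods) >= 2L)
    utils::combn(names(methods), 2, simplify = FALSE) else list()
  for (pr in pairs) {
    m1 <- metrics[metrics$method == pr[1], ]
    m2 <- metrics[metrics$method == pr[2], ]
    m1 <- m1[match(structures, m1$structure), ]
    m2 <- m2[match(structures, m2$structure), ]
    for (crit in c("dsc", "hausdorff_px")) {
      hib <- crit == "dsc"
      if (length(structures) >= 5L) {
        cl <- wilcoxon_compare(m1[[crit]], m2[[crit]], alpha = alpha,
                               higher_is_better = hib)
        label <- signed_label(cl)
        p <- cl$p_value
        note <- NA_character_
      } else {
        label <- "NS"; p <- NA_real_
        note <- "fewer than 5 paired structures; no test performed"
      }
      cmp_rows[[length(cmp_rows) + 1L]] <- tibble::tibble(
        method_1 = pr[1], method_2 = pr[2], criterion = crit,
        label = label, p_value = p, note = note)
    }
  }
  comparisons <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else
    tibble::tibble(method_1 = character(), method_2 = character(),
                   criterion = character(), label = character(),
                   p_value = numeric(), note = character())
  structure(list(metrics = metrics, comparisons = comparisons, alpha = alpha),
            class = "evaluation_report")
}

signed_label <- function(cl) {
  if (cl$label == "NS") return("NS")
  strong <- cl$p_value < cl$alpha / 5
  if (cl$label == "better") (if (strong) "++" else "+")
  else (if (strong) "--" else "-")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$metrics, n = Inf)
  cat("\nPairwise comparisons:\n")
  print(x$comparisons, n = Inf)
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes `metrics.tsv` and `comparisons.tsv` (tab-separated) plus
#' `report.json` (structured key/value form) into `dir`.
#'
#' @param report an `evaluation_report` from [build_report()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metrics = file.path(dir, "metrics.tsv"),
             comparisons = file.path(dir, "comparisons.tsv"),
             json = file.path(dir, "report.json"))
  utils::write.table(report$metrics, paths["metrics"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$comparisons, paths["comparisons"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(metrics = report$metrics,
                            comparisons = report$comparisons,
                            alpha = report$alpha),
                       paths["json"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}
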