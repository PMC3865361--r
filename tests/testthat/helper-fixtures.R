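# shared fixtures, generated in code

# smooth correlated random texture: white noise plus shifted copies of itself
# (enough spatial correlation for interpolation, enough contrast for NC)
smooth_noise <- function(dims, seed = 1) {
  set.seed(seed)
  a <- array(rnorm(prod(dims)), dims)
  n <- dims
  b <- a
  b[2:n[1], , ] <- b[2:n[1], , ] + a[1:(n[1] - 1), , ]
  b[, 2:n[2], ] <- b[, 2:n[2], ] + a[, 1:(n[2] - 1), ]
  b[, , 2:n[3]] <- b[, , 2:n[3]] + a[, , 1:(n[3] - 1)]
  b
}

# fixed/moving arrays where the fixed content is the moving content shifted:
# fixed(v) = source(v - shift), cropped from a common oversized texture so no
# padding artifacts enter; the expected featurelet displacement is `shift`
shifted_pair <- function(dims, shift, seed = 1, margin = 8L) {
  big <- smooth_noise(dims + 2L * margin, seed = seed)
  take <- function(off) {
    big[(margin + 1 + off[1]):(margin + dims[1] + off[1]),
        (margin + 1 + off[2]):(margin + dims[2] + off[2]),
        (margin + 1 + off[3]):(margin + dims[3] + off[3]), drop = FALSE]
  }
  list(moving = take(c(0L, 0L, 0L)), fixed = take(-as.integer(shift)))
}

# small ball mask as structure_mask
ball_mask <- function(dims, center, radius, spacing = c(1, 1, 1)) {
  g <- expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1), z = 0:(dims[3] - 1))
  inside <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <=
    radius^2
  structure_mask(array(as.numeric(inside), dims), spacing = spacing)
}

# random sparse mask with a bounded surface size
random_mask <- function(dims, n_seeds, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  arr <- array(0, dims)
  idx <- cbind(sample(dims[1], n_seeds, TRUE), sample(dims[2], n_seeds, TRUE),
               sample(dims[3], n_seeds, TRUE))
  arr[idx] <- 1
  structure_mask(arr, spacing = spacing)
}

# independent O(n^2) double-loop Hausdorff oracle over surface voxel lists
hausdorff_bruteforce <- function(a, b, spacing = NULL) {
  surf <- function(m) {
    arr <- m$data != 0
    d <- dim(arr)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!arr[i, j, k]) next
      nb <- c(i == 1 || !arr[i - 1, j, k], i == d[1] || !arr[i + 1, j, k],
              j == 1 || !arr[i, j - 1, k], j == d[2] || !arr[i, j + 1, k],
              k == 1 || !arr[i, j, k - 1], k == d[3] || !arr[i, j, k + 1])
      if (any(nb)) out <- rbind(out, c(i, j, k) - 1)
    }
    out
  }
  sa <- surf(a); sb <- surf(b)
  if (!is.null(spacing)) {
    sa <- sweep(sa, 2, spacing, "*"); sb <- sweep(sb, 2, spacing, "*")
  }
  h <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sum((p[i, ] - q[j, ])^2))
      worst <- max(worst, best)
    }
    sqrt(worst)
  }
  max(h(sa, sb), h(sb, sa))
}

# direct triple-entropy MI oracle with explicit joint-count loops
mi_bruteforce <- function(a, b, bins) {
  a <- as.numeric(a); b <- as.numeric(b)
  edge <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) return(rep(1L, length(x)))
    pmin(floor((x - lo) / (hi - lo) * bins) + 1, bins)
  }
  ia <- edge(a); ib <- edge(b)
  joint <- matrix(0, bins, bins)
  for (i in seq_along(a)) joint[ia[i], ib[i]] <- joint[ia[i], ib[i]] + 1
  pj <- joint / length(a)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(rowSums(pj)) + ent(colSums(pj)) - ent(pj)
}

# exhaustive integer-translation metric scan oracle, written against the
# R-level metric functions (independent of the compiled search path)
scan_oracle <- function(moving_patch, fixed, box_lo, search, metric = "NC",
                        bins = 32L) {
  pdim <- dim(moving_patch)
  lo <- search$lo - box_lo
  hi <- search$hi - (box_lo + pdim)
  best <- -Inf; best_t <- c(0, 0, 0)
  for (tz in lo[3]:hi[3]) for (ty in lo[2]:hi[2]) for (tx in lo[1]:hi[1]) {
    o <- box_lo + c(tx, ty, tz)
    sub <- fixed$data[(o[1] + 1):(o[1] + pdim[1]),
                      (o[2] + 1):(o[2] + pdim[2]),
                      (o[3] + 1):(o[3] + pdim[3]), drop = FALSE]
    m <- if (metric == "NC") normalized_correlation(moving_patch, sub)$value
    else mutual_information(moving_patch, sub, bins)$value
    if (m > best) { best <- m; best_t <- c(tx, ty, tz) }
  }
  list(merit = best, displacement = best_t)
}

# small, fast benchmark pair reused across pipeline tests
tiny_pair <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- phantom_spec(grid_dims = c(48, 48, 40), spacing = c(8, 8, 8),
                           bladder_volume_cc = 250, prostate_volume_cc = 110,
                           noise_sd = 8, seed = 11)
      memo <<- make_benchmark_pair(
        spec, ground_truth_deformation(bladder_inflation = 1.25,
                                       prostate_shift_mm = c(16, 0, 0),
                                       smoothness_mm = 70))
    }
    memo
  }
})

default_phantom <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- generate_phantom(phantom_spec())
    memo
  }
})
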