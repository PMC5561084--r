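#' Denoising configuration
#'
#' Parameters of the single-stage block-matching collaborative filter:
#' 4x4x4 cubes matched within an 11^3 search window, stacks of up to 16
#' mutually similar cubes, separable orthonormal Haar transforms (3-D per
#' cube, then 1-D across the group), hard thresholding at
#' `hard_threshold_factor * sigma`, and weighted overlap averaging with
#' weight one over the number of retained coefficients.
#'
#' @param cube_size cube side (>= 2; default 4, giving 2 dyadic Haar
#'   levels).
#' @param search_radius matching search radius in voxels (default 5).
#' @param max_group maximum stack size, a power of two (default 16).
#' @param match_threshold optional mean-squared-difference cutoff for
#'   candidates (default `Inf`: keep the `max_group` closest).
#' @param sigma noise standard deviation in intensity units, or `NULL`
#'   to estimate it from the volume ([estimate_sigma()]).
#' @param hard_threshold_factor multiplier on sigma (default 2.7).
#' @param step reference-lattice stride in voxels (default 3).
#' @return `denoise_config` object.
#' @export
denoise_config <- function(cube_size = 4L, search_radius = 5L,
                           max_group = 16L, match_threshold = Inf,
                           sigma = NULL, hard_threshold_factor = 2.7,
                           step = 3L) {
  cube_size <- as.integer(cube_size)
  if (cube_size < 2L) stop("cube_size must be >= 2")
  if (!is_pow2(max_group)) stop("max_group must be a power of two")
  if (!is.null(sigma) && sigma < 0) stop("sigma must be >= 0")
  if (search_radius < 0L) stop("search_radius must be >= 0")
  structure(list(cube_size = cube_size,
                 search_radius = as.integer(search_radius),
                 max_group = as.integer(max_group),
                 match_threshold = match_threshold, sigma = sigma,
                 hard_threshold_factor = hard_threshold_factor,
                 step = as.integer(step)),
            class = "denoise_config")
}

#' @export
print.denoise_config <- function(x, ...) {
  cat("<denoise_config> cube", x$cube_size, "^3, search radius",
      x$search_radius, ", max group", x$max_group, ", step", x$step,
      ", sigma", if (is.null(x$sigma)) "auto" else x$sigma, "\n")
  invisible(x)
}

#' Estimate the noise standard deviation of a volume
#'
#' Robust estimate from the finest-scale 3-D Haar detail coefficients
#' (the HHH subband over disjoint 2x2x2 blocks): `MAD(|c|) / 0.6745`.
#' For additive Gaussian noise these coefficients are Gaussian with the
#' noise sd, while smooth image content contributes little.
#'
#' @param v `pvs_volume` or 3-D array.
#' @return Estimated sigma (>= 0).
#' @export
estimate_sigma <- function(v) {
  arr <- if (is_volume(v)) v$data else v
  d <- dim(arr)
  e <- 2L * (d %/% 2L)
  a <- arr[1:e[1], 1:e[2], 1:e[3], drop = FALSE]
  dx <- a[seq(2, e[1], 2), , , drop = FALSE] - a[seq(1, e[1], 2), , , drop = FALSE]
  dy <- dx[, seq(2, e[2], 2), , drop = FALSE] - dx[, seq(1, e[2], 2), , drop = FALSE]
  dz <- dy[, , seq(2, e[3], 2), drop = FALSE] - dy[, , seq(1, e[3], 2), drop = FALSE]
  hhh <- as.vector(dz) / sqrt(8)
  stats::mad(hhh, center = 0)
}

#' Match similar cubes around a reference cube
#'
#' Exhaustively compares the reference cube against every cube whose
#' corner lies in the search window (clipped to the volume), using the
#' mean squared intensity difference, and keeps the `max_group` most
#' similar (the reference always first, distance 0). The retained count
#' is then truncated to the largest power of two it contains, as required
#' by the group Haar transform.
#'
#' @param v `pvs_volume` or 3-D array.
#' @param ref_corner 1-based corner of the reference cube.
#' @param cfg a [denoise_config()].
#' @return `matched_stack`: list with `cubes` (n^3 x G matrix), `corners`
#'   (G x 3), `distances` (ascending), `n` (cube side).
#' @export
match_cubes <- function(v, ref_corner, cfg = denoise_config()) {
  arr <- if (is_volume(v)) v$data else v
  d <- dim(arr)
  n <- cfg$cube_size
  ref_corner <- as.integer(ref_corner)
  if (any(ref_corner < 1L) || any(ref_corner + n - 1L > d))
    stop("reference cube not inside the volume")
  m <- cpp_match_cubes(as.vector(arr), as.integer(d), ref_corner,
                       n, cfg$search_radius, cfg$max_group)
  corners <- m$corners; dists <- m$distances
  if (is.finite(cfg$match_threshold)) {
    keep <- dists <= cfg$match_threshold
    keep[1] <- TRUE
    corners <- corners[keep, , drop = FALSE]
    dists <- dists[keep]
  }
  G <- 2^floor(log2(nrow(corners)))
  corners <- corners[seq_len(G), , drop = FALSE]
  dists <- dists[seq_len(G)]
  base <- cube_indices(c(1L, 1L, 1L), n, d)
  cubes <- matrix(0, n^3, G)
  for (j in seq_len(G)) {
    cj <- corners[j, ]
    cubes[, j] <- arr[base + (cj[1] - 1L) + (cj[2] - 1L) * d[1] +
                        (cj[3] - 1L) * d[1] * d[2]]
  }
  structure(list(cubes = cubes, corners = corners, distances = dists, n = n),
            class = "matched_stack")
}

#' @export
print.matched_stack <- function(x, ...) {
  cat("<matched_stack>", ncol(x$cubes), "cubes of side", x$n,
      ", max distance", signif(max(x$distances), 4), "\n")
  invisible(x)
}

# Separable 3-D Haar transform matrix for a cube of side n (n a power of
# two): the Kronecker cube of the order-n Haar matrix, acting on cubes
# flattened in Fortran order.
haar3_matrix <- function(n) {
  H <- haar_matrix(n)
  H %x% H %x% H
}

#' Collaborative filtering of a matched cube stack
#'
#' Applies the separable orthonormal 3-D Haar transform to each cube and
#' a 1-D Haar transform across the group dimension, hard-thresholds every
#' coefficient with magnitude at most `hard_threshold_factor * sigma`
#' (the DC-of-DC coefficient is exempt), inverts both transforms, and
#' reports the number of surviving nonzero coefficients (used downstream
#' as aggregation weight `1 / max(1, count)`).
#'
#' @param stack a `matched_stack` from [match_cubes()] (group size must
#'   be a power of two).
#' @param cfg a [denoise_config()] with `sigma` set.
#' @param sigma overrides `cfg$sigma` when given.
#' @return List with `cubes` (filtered, same shape) and `retained`
#'   (surviving coefficient count).
#' @export
collaborative_filter <- function(stack, cfg = denoise_config(), sigma = NULL) {
  G <- ncol(stack$cubes)
  if (!is_pow2(G)) stop("group size must be a power of two, got ", G)
  if (is.null(sigma)) sigma <- cfg$sigma
  if (is.null(sigma)) stop("sigma must be given (or set in cfg)")
  T3 <- haar3_matrix(stack$n)
  Hg <- haar_matrix(G)
  coef <- T3 %*% stack$cubes %*% t(Hg)
  thr <- cfg$hard_threshold_factor * sigma
  dc <- coef[1L, 1L]
  coef[abs(coef) <= thr] <- 0
  coef[1L, 1L] <- dc
  retained <- sum(coef != 0)
  out <- stack
  out$cubes <- t(T3) %*% coef %*% Hg
  list(cubes = out$cubes, retained = retained, stack = out)
}

#' Block-matching collaborative denoising of a volume
#'
#' Single-stage hard-threshold analogue of 4-D block-matching
#' collaborative filtering: reference cubes on a stride-`step` lattice,
#' groups of mutually similar cubes found by [match_cubes()], filtered by
#' [collaborative_filter()], and aggregated by weighted overlap averaging
#' (weight `1 / max(1, retained)` per group, so sparser — more confident
#' — groups weigh more). Deterministic given input and config. With
#' `sigma = 0` the filter passes every coefficient and the output equals
#' the input up to aggregation round-off.
#'
#' @param v `pvs_volume` or 3-D array, at least `cube_size` per axis.
#' @param cfg a [denoise_config()]; if `cfg$sigma` is NULL it is
#'   estimated by [estimate_sigma()].
#' @return Denoised volume, same type and dimensions as `v`.
#' @export
denoise_volume <- function(v, cfg = denoise_config()) {
  arr <- if (is_volume(v)) v$data else v
  d <- dim(arr)
  n <- cfg$cube_size
  if (any(d < n))
    stop("volume is smaller than one cube (side ", n, ")")
  sigma <- if (is.null(cfg$sigma)) estimate_sigma(arr) else cfg$sigma
  thr <- cfg$hard_threshold_factor * sigma
  T3 <- haar3_matrix(n)
  Hmats <- lapply(0:as.integer(log2(cfg$max_group)),
                  function(p) haar_matrix(2^p))
  corners_1d <- function(dd) unique(c(seq.int(1L, dd - n + 1L, by = cfg$step),
                                      dd - n + 1L))
  cx <- corners_1d(d[1]); cy <- corners_1d(d[2]); cz <- corners_1d(d[3])
  base <- cube_indices(c(1L, 1L, 1L), n, d)
  acc <- array(0, d)
  wgt <- array(0, d)
  varr <- as.vector(arr)
  for (z in cz) for (y in cy) for (x in cx) {
    m <- cpp_match_cubes(varr, d, c(x, y, z), n, cfg$search_radius,
                         cfg$max_group)
    corners <- m$corners
    if (is.finite(cfg$match_threshold)) {
      keep <- m$distances <= cfg$match_threshold
      keep[1] <- TRUE
      corners <- corners[keep, , drop = FALSE]
    }
    G <- 2^floor(log2(nrow(corners)))
    corners <- corners[seq_len(G), , drop = FALSE]
    offs <- (corners[, 1] - 1L) + (corners[, 2] - 1L) * d[1] +
      (corners[, 3] - 1L) * d[1] * d[2]
    cubes <- matrix(0, n^3, G)
    for (j in seq_len(G)) cubes[, j] <- varr[base + offs[j]]
    coef <- T3 %*% cubes %*% t(Hmats[[as.integer(log2(G)) + 1L]])
    dc <- coef[1L, 1L]
    coef[abs(coef) <= thr] <- 0
    coef[1L, 1L] <- dc
    retained <- sum(coef != 0)
    rec <- t(T3) %*% coef %*% Hmats[[as.integer(log2(G)) + 1L]]
    w <- 1 / max(1, retained)
    for (j in seq_len(G)) {
      idx <- base + offs[j]
      acc[idx] <- acc[idx] + w * rec[, j]
      wgt[idx] <- wgt[idx] + w
    }
  }
  covered <- wgt > 0
  out <- arr
  out[covered] <- acc[covered] / wgt[covered]
  if (is_volume(v)) volume(out, v$spacing, v$affine) else out
}
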