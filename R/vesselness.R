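#' Separable Gaussian smoothing of a 3-D array
#'
#' Convolution with a normalized, truncated Gaussian kernel (radius
#' `ceiling(3.5 * sigma)`) applied separably along each axis, with
#' edge-exclusive reflect padding at borders.
#'
#' @param arr 3-D numeric array (or `pvs_volume`).
#' @param sigma Gaussian standard deviation in voxels (> 0).
#' @return Smoothed object of the same type.
#' @export
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  v <- NULL
  if (is_volume(arr)) { v <- arr; arr <- arr$data }
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) arr <- conv_axis(arr, k, axis)
  if (!is.null(v)) volume(arr, v$spacing, v$affine) else arr
}

# 1-D convolution along `axis` with reflect padding; kernel length 2r+1.
conv_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  m <- c(0L, 0L, 0L); m[axis] <- r
  p <- pad_reflect(arr, m)
  d <- dim(arr)
  out <- array(0, d)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (t in seq_along(k)) {
    sh <- idx
    sh[[axis]] <- sh[[axis]] + (t - 1L)
    out <- out + k[t] * p[sh[[1]], sh[[2]], sh[[3]]]
  }
  out
}

# Central-difference first/second derivatives with reflect padding.
shift_arr <- function(p, d, axis, by) {
  idx <- list(seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L)
  idx[[axis]] <- idx[[axis]] + by
  p[idx[[1]], idx[[2]], idx[[3]]]
}

# The six Hessian components of a (smoothed) array by central differences.
hessian_components <- function(arr) {
  d <- dim(arr)
  p <- pad_reflect(arr, 1L)
  s <- function(ax, by) shift_arr(p, d, ax, by)
  s2 <- function(ax1, b1, ax2, b2) {
    idx <- list(seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L)
    idx[[ax1]] <- idx[[ax1]] + b1
    idx[[ax2]] <- idx[[ax2]] + b2
    p[idx[[1]], idx[[2]], idx[[3]]]
  }
  list(
    xx = s(1, 1) - 2 * arr + s(1, -1),
    yy = s(2, 1) - 2 * arr + s(2, -1),
    zz = s(3, 1) - 2 * arr + s(3, -1),
    xy = (s2(1, 1, 2, 1) - s2(1, 1, 2, -1) - s2(1, -1, 2, 1) + s2(1, -1, 2, -1)) / 4,
    xz = (s2(1, 1, 3, 1) - s2(1, 1, 3, -1) - s2(1, -1, 3, 1) + s2(1, -1, 3, -1)) / 4,
    yz = (s2(2, 1, 3, 1) - s2(2, 1, 3, -1) - s2(2, -1, 3, 1) + s2(2, -1, 3, -1)) / 4
  )
}

# Closed-form eigenvalues of a field of symmetric 3x3 matrices
# (trigonometric method), returned unordered as three arrays.
sym3_eigenvalues <- function(h) {
  p1 <- h$xy^2 + h$xz^2 + h$yz^2
  q <- (h$xx + h$yy + h$zz) / 3
  p2 <- (h$xx - q)^2 + (h$yy - q)^2 + (h$zz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (h$xx - q) / safe_p; byy <- (h$yy - q) / safe_p; bzz <- (h$zz - q) / safe_p
  bxy <- h$xy / safe_p; bxz <- h$xz / safe_p; byz <- h$yz / safe_p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  zero <- p2 == 0
  e1[zero] <- q[zero]; e2[zero] <- q[zero]; e3[zero] <- q[zero]
  list(e1, e2, e3)
}

#' Hessian eigenvalues of a smoothed volume
#'
#' Smooths the volume with a Gaussian of scale `s` (voxels), forms the
#' 3x3 symmetric Hessian per voxel from central differences, and returns
#' the three eigenvalue fields sorted by increasing absolute value
#' (`|lambda1| <= |lambda2| <= |lambda3|`). For a bright tube, `lambda1`
#' is near zero along the tube axis and `lambda2`, `lambda3` are large
#' and negative.
#'
#' @param v `pvs_volume` or 3-D array.
#' @param s Gaussian scale in voxels (> 0).
#' @param scale_normalize multiply the Hessian by `s^2`
#'   (gamma-normalization), which makes responses comparable across
#'   scales; default FALSE, so eigenvalues are raw second derivatives.
#' @return List with 3-D arrays `l1`, `l2`, `l3` (ordered by `|.|`).
#' @export
hessian_eigen <- function(v, s, scale_normalize = FALSE) {
  arr <- if (is_volume(v)) v$data else v
  sm <- gaussian_smooth(arr, s)
  h <- hessian_components(sm)
  if (scale_normalize) h <- lapply(h, function(x) s^2 * x)
  ev <- sym3_eigenvalues(h)
  d <- dim(arr)
  E <- cbind(as.vector(ev[[1]]), as.vector(ev[[2]]), as.vector(ev[[3]]))
  A <- abs(E)
  ord1 <- max.col(-A, ties.method = "first")
  ord3 <- max.col(A, ties.method = "last")
  # middle index = 6 - first - last (indices sum to 6)
  ord2 <- 6L - ord1 - ord3
  nr <- nrow(E)
  pick <- function(o) array(E[cbind(seq_len(nr), o)], d)
  list(l1 = pick(ord1), l2 = pick(ord2), l3 = pick(ord3))
}

#' Frangi vesselness from Hessian eigenvalues
#'
#' Standard bright-tube vesselness: zero wherever `lambda2 > 0` or
#' `lambda3 > 0`, otherwise
#' `(1 - exp(-Ra^2 / (2 alpha^2))) * exp(-Rb^2 / (2 beta^2)) *
#'  (1 - exp(-S^2 / (2 c^2)))`
#' with `Ra = |l2|/|l3|` (plate vs line), `Rb = |l1|/sqrt(|l2 l3|)`
#' (blob), and `S = sqrt(l1^2 + l2^2 + l3^2)` (second-order structure
#' norm).
#'
#' @param eigs eigenvalue fields from [hessian_eigen()].
#' @param alpha,beta Frangi discriminators (> 0, defaults 0.5).
#' @param c structure-norm scale; default half the maximum `S` over the
#'   volume.
#' @return 3-D array of vesselness values in `[0, 1]`.
#' @export
frangi_vesselness <- function(eigs, alpha = 0.5, beta = 0.5, c = NULL) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  l1 <- eigs$l1; l2 <- eigs$l2; l3 <- eigs$l3
  S <- sqrt(l1^2 + l2^2 + l3^2)
  if (is.null(c)) c <- max(S) / 2
  if (c <= 0) return(array(0, dim(l1)))
  a2 <- abs(l2); a3 <- abs(l3)
  safe3 <- ifelse(a3 > 0, a3, 1)
  Ra <- a2 / safe3
  Rb <- abs(l1) / sqrt(ifelse(a2 * a3 > 0, a2 * a3, 1))
  vf <- (1 - exp(-Ra^2 / (2 * alpha^2))) * exp(-Rb^2 / (2 * beta^2)) *
    (1 - exp(-S^2 / (2 * c^2)))
  vf[l2 > 0 | l3 > 0 | a3 == 0] <- 0
  vf
}

#' Multiscale Frangi vesselness map
#'
#' Computes the Frangi vesselness at each Gaussian scale (on the
#' gamma-normalized Hessian, `s^2 H`, so responses are comparable across
#' scales) and fuses by the voxel-wise maximum. The default scales 0.5
#' and 1.0 voxels target very thin and relatively thick PVS-like tubes
#' respectively.
#'
#' @param v `pvs_volume` or 3-D array.
#' @param scales Gaussian scales in voxels (default `c(0.5, 1)`).
#' @inheritParams frangi_vesselness
#' @return `vesselness_map`: list with `values` (3-D array in `[0,1]`)
#'   and `scales_used`.
#' @export
multiscale_vesselness <- function(v, scales = c(0.5, 1), alpha = 0.5,
                                  beta = 0.5, c = NULL) {
  if (length(scales) == 0) stop("at least one scale required")
  arr <- if (is_volume(v)) v$data else v
  best <- array(0, dim(arr))
  for (s in scales) {
    vf <- frangi_vesselness(hessian_eigen(arr, s, scale_normalize = TRUE),
                            alpha, beta, c)
    best <- pmax(best, vf)
  }
  structure(list(values = best, scales_used = scales),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat("<vesselness_map>", paste(dim(x$values), collapse = "x"),
      "voxels, scales", paste(x$scales_used, collapse = ", "),
      ", max", signif(max(x$values), 4), "\n")
  invisible(x)
}

#' Threshold a vesselness map into a segmentation mask
#'
#' Marks voxels with vesselness strictly greater than `tau`, optionally
#' intersected with a tissue mask (e.g. white matter).
#'
#' @param m a `vesselness_map` (or bare 3-D array of vesselness values).
#' @param tau threshold in `[0, 1]`.
#' @param mask optional logical/binary 3-D array restricting the
#'   segmentation.
#' @return Logical 3-D array.
#' @export
threshold_segment <- function(m, tau, mask = NULL) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  vals <- if (inherits(m, "vesselness_map")) m$values else m
  out <- vals > tau
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(out))) stop("mask dimensions do not match")
    out <- out & (mask > 0)
  }
  out
}

#' Best-threshold sweep against a truth mask
#'
#' Sweeps `tau` over a grid, computes Dice (plus sensitivity and PPV) of
#' [threshold_segment()] against `truth` at each value, and reports the
#' full curve and the argmax. Mirrors per-image best-threshold evaluation
#' of vesselness segmentation.
#'
#' @param m a `vesselness_map`.
#' @param truth logical/binary 3-D truth mask.
#' @param taus thresholds to try.
#' @param mask optional evaluation/tissue mask.
#' @return List with `curve` (data.frame tau/DSC/SN/PPV), `best_tau`,
#'   `best` (the score row at `best_tau`).
#' @export
sweep_threshold <- function(m, truth, taus = seq(0.02, 0.9, by = 0.02),
                            mask = NULL) {
  rows <- lapply(taus, function(tau) {
    pred <- threshold_segment(m, tau, mask)
    cc <- confusion(pred, truth, eval_mask = mask)
    sc <- tryCatch(seg_scores(cc),
                   error = function(e) list(DSC = 0, SN = 0, PPV = 0))
    data.frame(tau = tau, DSC = sc$DSC, SN = sc$SN, PPV = sc$PPV)
  })
  curve <- do.call(rbind, rows)
  i <- which.max(curve$DSC)
  list(curve = curve, best_tau = curve$tau[i], best = curve[i, ])
}
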