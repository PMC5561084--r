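#' Enhancement configuration
#'
#' All hyperparameters of the nonlocal Haar enhancement. Defaults follow
#' the method's reference setting for 7T T2-weighted-like data: 7x7x7
#' cubes, groups of K = 8 cubes taken from a 3x3x3 neighborhood, reference
#' cubes on a stride-7 lattice, coefficient thresholds T1 = 150, T2 = 110,
#' T3 = 50 and gains gamma1 = 24, gamma2 = 12. The thresholds live on the
#' raw intensity scale of the input; images on a different scale must be
#' rescaled or the thresholds re-tuned.
#'
#' @param cube_size cube side length in voxels (>= 2).
#' @param K group size, a power of two.
#' @param neighborhood neighborhood side in voxels (3 means 3x3x3);
#'   informational — the actual cubes taken are given by `offset_set`.
#' @param step reference-lattice stride in voxels (default `cube_size`, so
#'   reference cubes tile the volume without overlap).
#' @param T1,T2,T3 coefficient thresholds, `T1 > T2 > T3 >= 0`. `|c| > T1`
#'   passes through (strong edges), `T2 <= |c| <= T1` is amplified by
#'   `gamma1` (edges that are typically PVSs), `T3 < |c| < T2` by `gamma2`
#'   (very weak edges), `|c| <= T3` is zeroed (noise floor).
#' @param gamma1,gamma2 gains, `gamma1 >= gamma2 > 0`.
#' @param offset_set K x 3 integer matrix of cube offsets relative to the
#'   reference corner; default [offset_set()] (the binary cube \{0,1\}^3).
#' @param exempt_dc if TRUE the DC subband (subband 1) bypasses the
#'   coefficient mapping. Default FALSE: all coefficients are mapped.
#' @return `enhance_config` object (a validated list).
#' @export
enhance_config <- function(cube_size = 7L, K = 8L, neighborhood = 3L,
                           step = cube_size, T1 = 150, T2 = 110, T3 = 50,
                           gamma1 = 24, gamma2 = 12,
                           offset_set = NULL, exempt_dc = FALSE) {
  cube_size <- as.integer(cube_size); K <- as.integer(K)
  step <- as.integer(step)
  if (cube_size < 2L) stop("cube_size must be >= 2")
  if (!is_pow2(K)) stop("K must be a power of two")
  if (step < 1L) stop("step must be >= 1")
  if (!(T1 > T2 && T2 > T3 && T3 >= 0))
    stop("thresholds must satisfy T1 > T2 > T3 >= 0 (got ",
         T1, ", ", T2, ", ", T3, ")")
  if (!(gamma1 >= gamma2 && gamma2 > 0))
    stop("gains must satisfy gamma1 >= gamma2 > 0")
  if (is.null(offset_set)) offset_set <- pvshaar::offset_set(K)
  offset_set <- as.matrix(offset_set)
  storage.mode(offset_set) <- "integer"
  if (nrow(offset_set) != K || ncol(offset_set) != 3L)
    stop("offset_set must be a K x 3 integer matrix")
  structure(list(cube_size = cube_size, K = K, neighborhood = as.integer(neighborhood),
                 step = step, T1 = T1, T2 = T2, T3 = T3,
                 gamma1 = gamma1, gamma2 = gamma2,
                 offset_set = offset_set, exempt_dc = isTRUE(exempt_dc)),
            class = "enhance_config")
}

#' @export
print.enhance_config <- function(x, ...) {
  cat("<enhance_config> cube", x$cube_size, "^3, K =", x$K,
      ", step", x$step, "\n  T1/T2/T3 =", x$T1, "/", x$T2, "/", x$T3,
      ", gamma1/gamma2 =", x$gamma1, "/", x$gamma2,
      ", exempt_dc =", x$exempt_dc, "\n")
  invisible(x)
}

#' Piecewise coefficient mapping
#'
#' The four-branch nonlinear mapping applied to every group-Haar
#' coefficient: large coefficients (strong edges, `|c| > T1`) are
#' preserved, mid-range coefficients are amplified by `gamma1`
#' (`T2 <= |c| <= T1`) or `gamma2` (`T3 < |c| < T2`), and sub-threshold
#' coefficients (`|c| <= T3`, the noise floor) are zeroed. The boundary
#' `|c| = T3` is assigned to the zero branch (ties-to-suppression). The
#' mapping is sign-preserving and odd; no clipping is applied, so a mapped
#' coefficient may exceed T1.
#'
#' @param c numeric vector/array of coefficients.
#' @param cfg an [enhance_config()].
#' @return Mapped coefficients, same shape as `c`.
#' @export
map_coefficient <- function(c, cfg) {
  a <- abs(c)
  out <- c                                      # |c| > T1: identity
  out[a >= cfg$T2 & a <= cfg$T1] <- cfg$gamma1 * c[a >= cfg$T2 & a <= cfg$T1]
  out[a > cfg$T3 & a < cfg$T2] <- cfg$gamma2 * c[a > cfg$T3 & a < cfg$T2]
  out[a <= cfg$T3] <- 0
  out
}

#' Apply the coefficient mapping to a subband stack
#'
#' Element-wise [map_coefficient()] over every subband; when
#' `cfg$exempt_dc` is TRUE, subband 1 (the DC subband) passes through
#' unchanged.
#'
#' @param s a `subband_stack` from [forward_transform()].
#' @inheritParams map_coefficient
#' @return A `subband_stack` of mapped coefficients.
#' @export
map_subbands <- function(s, cfg) {
  dc <- s$cubes[, 1L]
  s$cubes <- map_coefficient(s$cubes, cfg)
  if (cfg$exempt_dc) s$cubes[, 1L] <- dc
  s
}

# Reference-cube corners tiling dims `d` for side n, stride `step`, with
# `lo`/`hi` voxel clearance for the negative/positive group offsets. The
# last corner is clamped so the final tile always abuts the far border.
ref_corners_1d <- function(d, n, step, lo, hi) {
  first <- 1L + lo
  last <- d - n + 1L - hi
  stopifnot(last >= first)
  unique(c(seq.int(first, last, by = step), last))
}

#' Enhance a volume by nonlocal group-Haar coefficient mapping
#'
#' The complete enhancement: reflect-pad, extract a cube group at every
#' reference corner (stride `cfg$step`), forward Haar transform across the
#' group, map coefficients ([map_coefficient()]), inverse transform, and
#' aggregate overlapping reconstructed cubes by averaging. Deterministic;
#' accumulation is in double precision.
#'
#' @param v `pvs_volume` or 3-D array, at least `cube_size` per axis.
#' @param cfg an [enhance_config()].
#' @param mapping `"piecewise"` (default) or `"identity"` (pass-through:
#'   no coefficient change, useful to verify perfect reconstruction).
#' @return Enhanced volume, same type and dimensions as `v`.
#' @export
enhance_volume <- function(v, cfg = enhance_config(),
                           mapping = c("piecewise", "identity")) {
  mapping <- match.arg(mapping)
  arr <- if (is_volume(v)) v$data else v
  d0 <- dim(arr)
  n <- cfg$cube_size
  if (any(d0 < n))
    stop("volume (", paste(d0, collapse = "x"),
         ") is smaller than one cube (side ", n, ")")
  off_lo <- pmax(0L, -apply(cfg$offset_set, 2, min))
  off_hi <- pmax(0L, apply(cfg$offset_set, 2, max))
  m <- n  # pad margin: one full cube side keeps all offsets interior
  p <- pad_reflect(arr, m)
  d <- dim(p)
  Psi <- haar_matrix(cfg$K)
  cx <- ref_corners_1d(d[1], n, cfg$step, off_lo[1], off_hi[1])
  cy <- ref_corners_1d(d[2], n, cfg$step, off_lo[2], off_hi[2])
  cz <- ref_corners_1d(d[3], n, cfg$step, off_lo[3], off_hi[3])
  acc <- array(0, d)
  cnt <- array(0, d)
  base <- cube_indices(c(1L, 1L, 1L), n, d)
  offs <- cfg$offset_set
  K <- cfg$K
  for (z in cz) for (y in cy) for (x in cx) {
    ref <- c(x, y, z)
    corners <- sweep(offs, 2, ref, "+")
    cubes <- matrix(0, n^3, K)
    for (j in seq_len(K)) {
      cj <- corners[j, ]
      cubes[, j] <- p[base + (cj[1] - 1L) + (cj[2] - 1L) * d[1] +
                        (cj[3] - 1L) * d[1] * d[2]]
    }
    coef <- cubes %*% t(Psi)
    if (mapping == "piecewise") {
      dc <- coef[, 1L]
      coef <- map_coefficient(coef, cfg)
      if (cfg$exempt_dc) coef[, 1L] <- dc
    }
    rec <- coef %*% Psi
    for (j in seq_len(K)) {
      cj <- corners[j, ]
      idx <- base + (cj[1] - 1L) + (cj[2] - 1L) * d[1] + (cj[3] - 1L) * d[1] * d[2]
      acc[idx] <- acc[idx] + rec[, j]
      cnt[idx] <- cnt[idx] + 1
    }
  }
  covered <- cnt > 0
  p[covered] <- acc[covered] / cnt[covered]
  out <- crop_margin(p, m)
  if (is_volume(v)) volume(out, v$spacing, v$affine) else out
}
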