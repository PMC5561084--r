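#' Orthonormal Haar transform matrix
#'
#' Builds the standard orthonormal Haar matrix of order K (K a power of
#' two) by the usual recursive construction: the first row is the scaled
#' group mean `1/sqrt(K)`, subsequent rows encode dyadic differences at
#' progressively finer scales. For K = 8 the entries are
#' rows of `1/sqrt(8)`, `1/sqrt(4)` and `1/sqrt(2)` with the familiar
#' sign pattern; the matrix satisfies `Psi %*% t(Psi) == I`.
#'
#' @param K group size; must be a power of two (2, 4, 8, 16, ...).
#' @return K x K orthonormal matrix.
#' @export
haar_matrix <- function(K) {
  K <- as.integer(K)
  if (K < 1L || bitwAnd(K, K - 1L) != 0L)
    stop("K must be a power of two, got ", K)
  H <- matrix(1, 1, 1)
  while (nrow(H) < K) {
    n <- nrow(H)
    H <- rbind(
      H %x% matrix(c(1, 1), 1, 2),
      diag(n) %x% matrix(c(1, -1), 1, 2)
    )
  }
  # normalize rows to unit length -> orthonormal
  H / sqrt(rowSums(H^2))
}

is_pow2 <- function(K) K >= 1L && bitwAnd(as.integer(K), as.integer(K) - 1L) == 0L

#' Nonlocal cube group
#'
#' An ordered stack of K congruent cubes of side `n` extracted from a
#' volume at corners `corners` (a K x 3 integer matrix, 1-based), the first
#' of which is the reference cube. Stored as an `n^3 x K` matrix `cubes`
#' (one column per cube, Fortran voxel order) so that the group-wise Haar
#' transform is a single matrix product.
#'
#' @param cubes n^3 x K numeric matrix, one column per cube.
#' @param corners K x 3 integer matrix of cube corners.
#' @param ref_corner length-3 integer, corner of the reference cube.
#' @param n cube side length in voxels.
#' @return `cube_group` object.
#' @export
cube_group <- function(cubes, corners, ref_corner, n) {
  stopifnot(is.matrix(cubes), nrow(cubes) == n^3,
            nrow(corners) == ncol(cubes))
  structure(list(cubes = cubes, corners = corners,
                 ref_corner = as.integer(ref_corner), n = as.integer(n)),
            class = "cube_group")
}

#' @export
print.cube_group <- function(x, ...) {
  cat("<cube_group> K =", ncol(x$cubes), "cubes of side", x$n,
      "at ref corner", paste(x$ref_corner, collapse = ","), "\n")
  invisible(x)
}

#' Default nonlocal offset set
#'
#' The K corner offsets (relative to the reference corner) from which the
#' neighboring cubes of a group are taken. The default for K = 8 is the
#' binary cube \{0,1\}^3: the reference cube plus its 7 forward-shifted
#' neighbors, keeping shifts minimal so cube contents stay highly
#' correlated. `"corners"` gives the \{-1,+1\}^3 neighborhood-corner
#' alternative.
#'
#' @param K group size (8 for the built-in sets).
#' @param kind `"forward"` (default, \{0,1\}^3) or `"corners"` (\{-1,1\}^3).
#' @return K x 3 integer matrix of offsets; row 1 is c(0,0,0) for
#'   `"forward"`.
#' @export
offset_set <- function(K = 8L, kind = c("forward", "corners")) {
  kind <- match.arg(kind)
  if (K != 8L)
    stop("built-in offset sets are defined for K = 8; supply offsets directly")
  vals <- if (kind == "forward") c(0L, 1L) else c(-1L, 1L)
  g <- as.matrix(expand.grid(x = vals, y = vals, z = vals))
  dimnames(g) <- NULL
  # reference offset (0,0,0) first when present
  if (kind == "forward") g <- g[order(rowSums(abs(g)) != 0, g[, 3], g[, 2], g[, 1]), ]
  storage.mode(g) <- "integer"
  g
}

# linear (1-based) indices of a cube of side n at corner `corner` in an
# array of dims d
cube_indices <- function(corner, n, d) {
  ix <- corner[1] + 0:(n - 1)
  iy <- corner[2] + 0:(n - 1)
  iz <- corner[3] + 0:(n - 1)
  as.vector(outer(outer(ix, (iy - 1) * d[1], "+"), (iz - 1) * d[1] * d[2], "+"))
}

#' Extract a nonlocal cube group
#'
#' Extracts the K cubes whose corners are `ref_corner` plus the rows of
#' `cfg$offset_set` from a (typically reflect-padded) volume. Values are
#' copied.
#'
#' @param v `pvs_volume` or 3-D array (padded so all cubes fit).
#' @param ref_corner length-3 1-based corner of the reference cube.
#' @param cfg an [enhance_config()].
#' @return A [cube_group()].
#' @export
extract_cube_group <- function(v, ref_corner, cfg) {
  arr <- if (is_volume(v)) v$data else v
  d <- dim(arr)
  n <- cfg$cube_size
  offs <- cfg$offset_set
  corners <- sweep(offs, 2, as.integer(ref_corner), "+")
  if (any(corners < 1L) || any(sweep(corners, 2, d - n + 1L, ">")))
    stop("cube group at corner ", paste(ref_corner, collapse = ","),
         " exceeds volume bounds; pad the volume first")
  base <- cube_indices(c(1L, 1L, 1L), n, d)
  cubes <- matrix(0, n^3, nrow(corners))
  for (j in seq_len(nrow(corners))) {
    cj <- corners[j, ]
    off <- (cj[1] - 1L) + (cj[2] - 1L) * d[1] + (cj[3] - 1L) * d[1] * d[2]
    cubes[, j] <- arr[base + off]
  }
  cube_group(cubes, corners, ref_corner, n)
}

#' Forward group-wise Haar transform
#'
#' Applies the Haar matrix across the cube dimension, voxel-wise:
#' subband i = sum_j Psi(i,j) * cube_j. Subband 1 is sqrt(K) times the
#' voxel-wise mean of the K cubes (the DC subband); subbands 2..K encode
#' inter-cube differences.
#'
#' @param g a [cube_group()].
#' @param Psi Haar matrix from [haar_matrix()]; defaults to order K.
#' @return A `subband_stack` (same shape as the group).
#' @export
forward_transform <- function(g, Psi = NULL) {
  K <- ncol(g$cubes)
  if (is.null(Psi)) Psi <- haar_matrix(K)
  if (ncol(Psi) != K)
    stop("transform order ", ncol(Psi), " does not match group size ", K)
  s <- g
  s$cubes <- g$cubes %*% t(Psi)
  class(s) <- "subband_stack"
  s
}

#' Inverse group-wise Haar transform
#'
#' @param s a `subband_stack`.
#' @inheritParams forward_transform
#' @return A [cube_group()].
#' @export
inverse_transform <- function(s, Psi = NULL) {
  K <- ncol(s$cubes)
  if (is.null(Psi)) Psi <- haar_matrix(K)
  if (ncol(Psi) != K)
    stop("transform order ", ncol(Psi), " does not match stack size ", K)
  g <- s
  # Psi is orthonormal: inverse = transpose
  g$cubes <- s$cubes %*% Psi
  class(g) <- "cube_group"
  g
}

#' @export
print.subband_stack <- function(x, ...) {
  cat("<subband_stack>", ncol(x$cubes), "subbands of side", x$n, "\n")
  invisible(x)
}

#' Aggregate reconstructed cube groups by overlap averaging
#'
#' Places every cube of every group back at its corner on a canvas of the
#' given shape and averages values where cubes overlap (each output voxel
#' is the mean of all cube values covering it). Voxels covered by no cube
#' retain the value of `background` (by default 0); under the default
#' tiling plus padding no such voxel exists.
#'
#' @param groups list of reconstructed [cube_group()]s.
#' @param shape output (padded canvas) dimensions.
#' @param background optional array of dim `shape` supplying values for
#'   uncovered voxels.
#' @return 3-D array of dim `shape`.
#' @export
aggregate_cubes <- function(groups, shape, background = NULL) {
  if (length(groups) == 0L) stop("no cube groups to aggregate")
  acc <- array(0, shape)
  cnt <- array(0, shape)
  for (g in groups) {
    n <- g$n
    base <- cube_indices(c(1L, 1L, 1L), n, shape)
    for (j in seq_len(ncol(g$cubes))) {
      cj <- g$corners[j, ]
      idx <- base + (cj[1] - 1L) + (cj[2] - 1L) * shape[1] +
        (cj[3] - 1L) * shape[1] * shape[2]
      acc[idx] <- acc[idx] + g$cubes[, j]
      cnt[idx] <- cnt[idx] + 1
    }
  }
  covered <- cnt > 0
  out <- if (is.null(background)) array(0, shape) else background
  out[covered] <- acc[covered] / cnt[covered]
  out
}
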