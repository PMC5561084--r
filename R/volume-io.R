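#' 3-D image volume
#'
#' A `pvs_volume` is a plain 3-D numeric array plus voxel spacing (mm) and a
#' 4x4 voxel-to-world affine. Axis order is the on-disk NIfTI array order
#' (x, y, z); all corner coordinates in this package are 1-based and cube
#' extents are half-open in the 0-based sense, i.e. a cube of side `n` at
#' corner `c` covers voxels `c, ..., c + n - 1`. The "corner" of a cube is
#' always its lexicographically minimal-coordinate corner.
#'
#' @param data 3-D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default diag(spacing, 1).
#' @return An object of class `pvs_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- drop_singletons(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be 3-D (got ", length(dim(data)), " dimensions)")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  structure(
    list(data = data, spacing = as.numeric(spacing), affine = affine),
    class = "pvs_volume"
  )
}

# Squeeze trailing singleton dimensions (e.g. 4-D NIfTI with one timepoint).
drop_singletons <- function(x) {
  if (is.null(dim(x))) stop("data must be an array")
  d <- dim(x)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  dim(x) <- d
  x
}

#' @export
print.pvs_volume <- function(x, ...) {
  cat("<pvs_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 6), ", ", signif(max(x$data), 6),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.pvs_volume <- function(x) dim(x$data)

#' @rdname volume
#' @param x object to coerce/test.
#' @export
as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "pvs_volume")) return(x)
  volume(x, spacing)
}

#' @rdname volume
#' @export
is_volume <- function(x) inherits(x, "pvs_volume")

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file (.nii or .nii.gz) into a [volume()]. 4-D images
#' with singleton trailing dimensions are squeezed to 3-D; genuinely 4-D
#' images are rejected. Volumes containing NaN/Inf voxels are rejected with
#' the affected voxel count.
#'
#' @param path path to an existing NIfTI file.
#' @return A `pvs_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L && any(d[-(1:3)] != 1L))
    stop("expected a 3-D image, got dimensions ", paste(d, collapse = " x "))
  dat <- drop_singletons(array(as.numeric(img), dim = d))
  if (length(dim(dat)) != 3L)
    stop("expected a 3-D image, got dimensions ", paste(d, collapse = " x "))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  aff <- tryCatch(matrix(as.numeric(RNifti::xform(img)), 4, 4),
                  error = function(e) NULL)
  volume(dat, spacing = sp, affine = aff)
}

#' Write a volume to NIfTI
#'
#' @param v a `pvs_volume`.
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @param datatype on-disk datatype, e.g. "double", "float", "int16".
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "double") {
  v <- as_volume(v)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  if (!is.null(v$affine))
    RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Reflect-pad a volume
#'
#' Pads each axis by `margin` voxels by mirror reflection about the edge
#' sample, without duplicating the edge sample itself: the 1-D analogue of
#' `c(1, 2, 3)` with margin 1 is `c(2, 1, 2, 3, 2)`. Used so every cube
#' extracted near a border is fully interior.
#'
#' @param v a `pvs_volume` or 3-D array.
#' @param margin non-negative integer, or length-3 vector, voxels per axis.
#' @return Padded object of the same type as `v`.
#' @export
pad_reflect <- function(v, margin) {
  arr <- if (is_volume(v)) v$data else v
  margin <- rep_len(as.integer(margin), 3L)
  if (any(margin < 0)) stop("margin must be >= 0")
  d <- dim(arr)
  if (any(margin >= d))
    stop("margin (", paste(margin, collapse = ","),
         ") must be smaller than each dimension (", paste(d, collapse = ","), ")")
  idx <- lapply(1:3, function(a) reflect_index(d[a], margin[a]))
  out <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (is_volume(v)) volume(out, v$spacing, v$affine) else out
}

# Index vector implementing edge-exclusive mirror reflection.
reflect_index <- function(n, m) {
  if (m == 0L) return(seq_len(n))
  c(rev(seq_len(m) + 1L), seq_len(n), n - seq_len(m))
}

#' Crop the reflect padding off a volume
#'
#' Inverse of [pad_reflect()] for a known margin.
#' @inheritParams pad_reflect
#' @export
crop_margin <- function(v, margin) {
  arr <- if (is_volume(v)) v$data else v
  margin <- rep_len(as.integer(margin), 3L)
  d <- dim(arr)
  out <- arr[(margin[1] + 1L):(d[1] - margin[1]),
             (margin[2] + 1L):(d[2] - margin[2]),
             (margin[3] + 1L):(d[3] - margin[3]), drop = FALSE]
  if (is_volume(v)) volume(out, v$spacing, v$affine) else out
}
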