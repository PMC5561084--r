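# Independent oracles used to freeze expected values, deliberately written
# without reference to the package implementation paths they check.

# scalar four-branch coefficient mapping, one branch test per value
oracle_map <- function(c, T1 = 150, T2 = 110, T3 = 50, g1 = 24, g2 = 12) {
  vapply(c, function(ci) {
    a <- abs(ci)
    if (a > T1) ci
    else if (a >= T2) g1 * ci
    else if (a > T3) g2 * ci
    else 0
  }, numeric(1))
}

# brute-force confusion counts by an explicit voxel loop
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i] && !truth[i]) fp <- fp + 1L
    else if (!pred[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# naive box-sum feature evaluation by direct summation over box voxels
oracle_box_features <- function(patch, feats) {
  vapply(feats, function(f) {
    box_mean <- function(b) {
      s <- 0; cnt <- 0
      for (k in 0:(b$size[3] - 1)) for (j in 0:(b$size[2] - 1))
        for (i in 0:(b$size[1] - 1)) {
          s <- s + patch[b$lo[1] + i, b$lo[2] + j, b$lo[3] + k]
          cnt <- cnt + 1
        }
      s / cnt
    }
    v <- box_mean(f$box1)
    if (f$two_box) v <- v - box_mean(f$box2)
    v
  }, numeric(1))
}

# exhaustive cube matching by plain R loops over the search window
oracle_match <- function(arr, ref, n, radius) {
  d <- dim(arr)
  refc <- arr[ref[1]:(ref[1] + n - 1), ref[2]:(ref[2] + n - 1),
              ref[3]:(ref[3] + n - 1)]
  out <- NULL
  for (z in max(1, ref[3] - radius):min(d[3] - n + 1, ref[3] + radius))
    for (y in max(1, ref[2] - radius):min(d[2] - n + 1, ref[2] + radius))
      for (x in max(1, ref[1] - radius):min(d[1] - n + 1, ref[1] + radius)) {
        cu <- arr[x:(x + n - 1), y:(y + n - 1), z:(z + n - 1)]
        out <- rbind(out, c(x, y, z, mean((cu - refc)^2)))
      }
  out[order(out[, 4]), , drop = FALSE]
}

# 90-degree volume rotation taking axis 3 onto axis 1 (for equivariance)
rot_z_to_x <- function(a) aperm(a, c(3, 2, 1))

# bright Gaussian-profile cylinder along the given axis
cylinder_volume <- function(d = 32L, radius = 1, amp = 100, axis = 3L) {
  v <- array(0, c(d, d, d))
  ctr <- (d + 1) / 2
  i1 <- slice.index(v, 1); i2 <- slice.index(v, 2); i3 <- slice.index(v, 3)
  perp <- switch(axis, `1` = list(i2, i3), `2` = list(i1, i3), list(i1, i2))
  r2 <- (perp[[1]] - ctr)^2 + (perp[[2]] - ctr)^2
  v + amp * exp(-r2 / (2 * radius^2))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Shared phantom-suite cache for the comparison experiments: built once,
# reused by every test that needs the processed arms.
.suite_env <- new.env(parent = emptyenv())

phantom_suite <- function(n = 10L) {
  key <- paste0("suite", n)
  if (is.null(.suite_env[[key]])) {
    phantoms <- lapply(seq_len(n), function(s)
      generate_phantom(phantom_spec(seed = s)))
    res <- compare_arms(phantoms, keep_volumes = TRUE)
    .suite_env[[key]] <- list(phantoms = phantoms, res = res)
  }
  .suite_env[[key]]
}
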