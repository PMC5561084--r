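#' Randomized 3-D Haar-like feature specification
#'
#' Draws `n_features` random axis-aligned box features inside a cubic
#' patch of radius `patch_radius` (side `2 * patch_radius + 1`). Each
#' feature is either the mean intensity of one box, or the difference of
#' the mean intensities of two boxes (weights +1 / -1). Features are
#' evaluated on patches that have been orientation-normalized (dominant
#' Hessian eigenvector aligned to the z axis by a nearest-90-degree
#' rotation) and intensity-normalized (patch z-score), so the same
#' feature responds consistently to tubes of any orientation and local
#' brightness.
#'
#' @param n_features number of features.
#' @param patch_radius patch radius in voxels (default 4, i.e. 9^3
#'   patches).
#' @param max_box_size largest box side (default 5).
#' @param p_two_box probability a feature is a two-box difference.
#' @param seed RNG seed; the spec is fully reproducible from it.
#' @return `haar_feature_spec`: list with `features` (per-feature box
#'   definitions), a dense weight matrix `W` (patch voxels x n_features)
#'   for fast extraction, and the generation parameters.
#' @export
haar_feature_spec <- function(n_features = 1000L, patch_radius = 4L,
                              max_box_size = 5L, p_two_box = 0.8,
                              seed = 42L) {
  set.seed(seed)
  side <- 2L * patch_radius + 1L
  rand_box <- function() {
    sz <- sample.int(max_box_size, 3L, replace = TRUE)
    lo <- vapply(sz, function(s) sample.int(side - s + 1L, 1L), integer(1))
    list(lo = lo, size = sz)
  }
  feats <- vector("list", n_features)
  W <- matrix(0, side^3, n_features)
  for (f in seq_len(n_features)) {
    two <- stats::runif(1) < p_two_box
    b1 <- rand_box()
    feats[[f]] <- list(box1 = b1, box2 = if (two) rand_box() else NULL,
                       two_box = two)
    W[box_patch_indices(b1, side), f] <-
      W[box_patch_indices(b1, side), f] + 1 / prod(b1$size)
    if (two) {
      b2 <- feats[[f]]$box2
      W[box_patch_indices(b2, side), f] <-
        W[box_patch_indices(b2, side), f] - 1 / prod(b2$size)
    }
  }
  structure(list(features = feats, W = W, n_features = as.integer(n_features),
                 patch_radius = as.integer(patch_radius), side = side,
                 seed = as.integer(seed)),
            class = "haar_feature_spec")
}

# linear indices (within a flattened side^3 patch) of a box
box_patch_indices <- function(b, side) {
  ix <- b$lo[1] + 0:(b$size[1] - 1L)
  iy <- b$lo[2] + 0:(b$size[2] - 1L)
  iz <- b$lo[3] + 0:(b$size[3] - 1L)
  as.vector(outer(outer(ix, (iy - 1L) * side, "+"), (iz - 1L) * side^2, "+"))
}

#' @export
print.haar_feature_spec <- function(x, ...) {
  cat("<haar_feature_spec>", x$n_features, "features in a", x$side, "^3 patch\n")
  invisible(x)
}

# Dominant Hessian eigenvector (largest |eigenvalue|) at given voxel
# coordinates, from precomputed Hessian component fields.
dominant_axes <- function(h, coords) {
  n <- nrow(coords)
  ax <- integer(n); sgn <- integer(n)
  d <- dim(h$xx)
  lin <- coords[, 1] + (coords[, 2] - 1L) * d[1] + (coords[, 3] - 1L) * d[1] * d[2]
  for (i in seq_len(n)) {
    M <- matrix(c(h$xx[lin[i]], h$xy[lin[i]], h$xz[lin[i]],
                  h$xy[lin[i]], h$yy[lin[i]], h$yz[lin[i]],
                  h$xz[lin[i]], h$yz[lin[i]], h$zz[lin[i]]), 3, 3)
    e <- eigen(M, symmetric = TRUE)
    v3 <- e$vectors[, which.max(abs(e$values))]
    a <- which.max(abs(v3))
    ax[i] <- a
    sgn[i] <- if (v3[a] >= 0) 1L else -1L
  }
  list(axis = ax, sign = sgn)
}

# Rotate a cubic patch so that `axis` (with `sign`) maps onto +z, using
# 90-degree permutations/reversals only (no interpolation).
rotate_patch <- function(patch, axis, sign) {
  if (axis == 1L) patch <- aperm(patch, c(3, 2, 1))
  else if (axis == 2L) patch <- aperm(patch, c(1, 3, 2))
  if (sign < 0) patch <- patch[, , dim(patch)[3]:1, drop = FALSE]
  patch
}

#' Extract randomized Haar features at voxel coordinates
#'
#' For every coordinate, takes the surrounding patch from the
#' reflect-padded volume, optionally orientation-normalizes it (the
#' dominant Hessian eigenvector at Gaussian scale `orient_scale` is
#' aligned to +z by the nearest 90-degree rotation) and z-scores it
#' (`(patch - mean) / (sd + 1e-6)`), then evaluates the feature spec's
#' box means. Deterministic given the spec.
#'
#' @param v `pvs_volume` or 3-D array.
#' @param coords m x 3 integer matrix of 1-based voxel coordinates.
#' @param spec a [haar_feature_spec()].
#' @param normalize apply orientation and intensity normalization
#'   (default TRUE).
#' @param orient_scale Gaussian scale for the orientation Hessian.
#' @return m x n_features numeric matrix.
#' @export
extract_features <- function(v, coords, spec, normalize = TRUE,
                             orient_scale = 1.0) {
  arr <- if (is_volume(v)) v$data else v
  coords <- matrix(as.integer(coords), ncol = 3)
  r <- spec$patch_radius
  side <- spec$side
  p <- pad_reflect(arr, r)
  dp <- dim(p)
  m <- nrow(coords)
  Pat <- matrix(0, m, side^3)
  orient <- if (normalize) {
    h <- hessian_components(gaussian_smooth(arr, orient_scale))
    dominant_axes(h, coords)
  } else NULL
  base <- cube_indices(c(1L, 1L, 1L), side, dp)
  for (i in seq_len(m)) {
    lo <- coords[i, ]        # padded corner = coords - r + r(pad) = coords
    off <- (lo[1] - 1L) + (lo[2] - 1L) * dp[1] + (lo[3] - 1L) * dp[1] * dp[2]
    patch <- array(p[base + off], c(side, side, side))
    if (normalize) {
      patch <- rotate_patch(patch, orient$axis[i], orient$sign[i])
      patch <- (patch - mean(patch)) / (stats::sd(patch) + 1e-6)
    }
    Pat[i, ] <- patch
  }
  Pat %*% spec$W
}

#' Region of interest from a vesselness map
#'
#' Voxels with vesselness strictly above `tau_roi`; candidate set within
#' which training voxels are sampled and predictions are made. Warns if
#' empty.
#'
#' @param m a `vesselness_map` (or 3-D array).
#' @param tau_roi threshold in `[0, 1]` (default 0.01, deliberately
#'   permissive so nearly all true tube voxels are inside).
#' @return Logical 3-D array.
#' @export
build_roi <- function(m, tau_roi = 0.01) {
  out <- threshold_segment(m, tau_roi)
  if (!any(out)) warning("ROI is empty at tau_roi = ", tau_roi)
  out
}

#' Random-forest chain configuration
#'
#' @param n_trees trees per forest (default 100).
#' @param min_node minimum node size (default 5).
#' @param n_samples PVS and non-PVS voxels sampled per class per training
#'   volume (default 2000).
#' @param tau_roi ROI vesselness threshold (default 0.01).
#' @param scales vesselness scales for the ROI map.
#' @param max_stages auto-context chain length cap (default 3).
#' @param dsc_tol minimum held-out DSC gain to add a stage (default
#'   0.005).
#' @param spec a [haar_feature_spec()]; default spec with 1000 features.
#' @param seed RNG seed controlling sampling and forest growth.
#' @return `rf_config` object.
#' @export
rf_config <- function(n_trees = 100L, min_node = 5L, n_samples = 2000L,
                      tau_roi = 0.01, scales = c(0.5, 1), max_stages = 3L,
                      dsc_tol = 0.005, spec = NULL, seed = 7L) {
  if (is.null(spec)) spec <- haar_feature_spec()
  structure(list(n_trees = as.integer(n_trees), min_node = as.integer(min_node),
                 n_samples = as.integer(n_samples), tau_roi = tau_roi,
                 scales = scales, max_stages = as.integer(max_stages),
                 dsc_tol = dsc_tol, spec = spec, seed = as.integer(seed)),
            class = "rf_config")
}

# 3^3 box-mean of a probability field (auto-context neighborhood feature)
prob_context <- function(prob) {
  k <- rep(1 / 3, 3)
  for (axis in 1:3) prob <- conv_axis(prob, k, axis)
  prob
}

# Per-volume cached state used during training/prediction.
stage_volume_state <- function(v, cfg) {
  vm <- multiscale_vesselness(v, scales = cfg$scales)
  roi <- build_roi(vm, cfg$tau_roi)
  list(v = v, vm = vm, roi = roi,
       coords_roi = which(roi, arr.ind = TRUE))
}

# Stage feature matrix for given coords: image Haar features, plus the
# previous stage's probability (voxel + 3^3 mean) when available.
stage_features <- function(state, coords, cfg, prev_prob = NULL) {
  X <- extract_features(state$v, coords, cfg$spec)
  if (!is.null(prev_prob)) {
    ctx <- prob_context(prev_prob)
    d <- dim(prev_prob)
    lin <- coords[, 1] + (coords[, 2] - 1L) * d[1] + (coords[, 3] - 1L) * d[1] * d[2]
    X <- cbind(X, prob = prev_prob[lin], prob_ctx = ctx[lin])
  }
  X
}

# Predict one stage's probability field over the ROI of a volume.
stage_prob_map <- function(forest, state, cfg, prev_prob = NULL) {
  d <- dim(state$v$data %||% state$v)
  prob <- array(0, d)
  if (nrow(state$coords_roi) == 0) return(prob)
  X <- stage_features(state, state$coords_roi, cfg, prev_prob)
  pr <- stats::predict(forest, data = as.data.frame(X))$predictions[, "1"]
  prob[state$roi] <- pr
  prob
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced sampling of PVS / non-PVS coords within the ROI.
sample_training_coords <- function(state, truth, n_per_class) {
  pos <- which(state$roi & truth, arr.ind = TRUE)
  neg <- which(state$roi & !truth, arr.ind = TRUE)
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("training ROI must contain both PVS and non-PVS voxels")
  take <- function(m, n) m[sample.int(nrow(m), min(n, nrow(m))), , drop = FALSE]
  pos <- take(pos, n_per_class)
  neg <- take(neg, n_per_class)
  list(coords = rbind(pos, neg),
       labels = factor(c(rep(1L, nrow(pos)), rep(0L, nrow(neg))),
                       levels = c(0L, 1L)))
}

#' Train an auto-context random-forest chain
#'
#' Trains stage 1 on randomized Haar image features sampled (class
#' balanced) from the vesselness ROI of each training volume; each later
#' stage additionally receives the previous stage's probability map
#' (voxel value and 3^3 neighborhood mean) as features. Chain growth
#' stops when the held-out DSC improves by less than `dsc_tol`, or at
#' `max_stages`. With two or more labeled volumes the last one is a pure
#' validation volume (used only for the stopping rule, never for
#' training); with a single volume the training volume itself is used.
#' Fully deterministic under `cfg$seed`.
#'
#' @param volumes list of `pvs_volume`s (or 3-D arrays).
#' @param truths list of logical truth masks, same order.
#' @param cfg an [rf_config()].
#' @return `rf_chain`: list with `stages` (ranger forests), `cfg`,
#'   `val_dsc` (held-out DSC per stage).
#' @export
train_chain <- function(volumes, truths, cfg = rf_config()) {
  stopifnot(length(volumes) >= 1, length(volumes) == length(truths))
  set.seed(cfg$seed)
  n_vol <- length(volumes)
  val_i <- if (n_vol >= 2L) n_vol else 1L
  train_i <- if (n_vol >= 2L) seq_len(n_vol - 1L) else 1L
  states <- lapply(volumes, stage_volume_state, cfg = cfg)
  samples <- lapply(train_i, function(i)
    sample_training_coords(states[[i]], truths[[i]], cfg$n_samples))
  if (length(unique(unlist(lapply(samples, function(s) levels(droplevels(s$labels)))))) < 2)
    stop("training set contains a single class")
  stages <- list()
  val_dsc <- numeric(0)
  prev_train <- vector("list", length(train_i))
  prev_val <- NULL
  for (k in seq_len(cfg$max_stages)) {
    Xs <- lapply(seq_along(train_i), function(j)
      stage_features(states[[train_i[j]]], samples[[j]]$coords, cfg,
                     prev_train[[j]]))
    X <- do.call(rbind, Xs)
    y <- factor(unlist(lapply(samples, function(s) as.character(s$labels))),
                levels = c("0", "1"))
    df <- as.data.frame(X)
    df$.class <- y
    forest <- ranger::ranger(
      dependent.variable.name = ".class", data = df,
      num.trees = cfg$n_trees, min.node.size = cfg$min_node,
      mtry = floor(sqrt(ncol(X))), probability = TRUE,
      seed = cfg$seed + k, num.threads = 1)
    stages[[k]] <- forest
    # held-out DSC for the stopping rule
    vprob <- stage_prob_map(forest, states[[val_i]], cfg, prev_val)
    pred <- vprob >= 0.5
    dsc <- tryCatch(seg_scores(confusion(pred, truths[[val_i]]))$DSC,
                    error = function(e) 0)
    val_dsc <- c(val_dsc, dsc)
    if (k > 1 && dsc < val_dsc[k - 1] + cfg$dsc_tol) {
      stages <- stages[seq_len(k - 1L)]
      val_dsc <- val_dsc[seq_len(k - 1L)]
      break
    }
    if (k == cfg$max_stages) break
    # probability maps feeding the next stage
    prev_train <- lapply(seq_along(train_i), function(j)
      stage_prob_map(forest, states[[train_i[j]]], cfg, prev_train[[j]]))
    prev_val <- vprob
  }
  structure(list(stages = stages, cfg = cfg, val_dsc = val_dsc),
            class = "rf_chain")
}

#' @export
print.rf_chain <- function(x, ...) {
  cat("<rf_chain>", length(x$stages), "stage(s), held-out DSC:",
      paste(signif(x$val_dsc, 3), collapse = " -> "), "\n")
  invisible(x)
}

#' Predict a PVS mask with a trained chain
#'
#' Runs each stage in sequence over the vesselness ROI of the volume,
#' feeding each stage's probability map to the next; the final label is
#' the argmax class (probability >= 0.5 for the PVS class). Voxels
#' outside the ROI are non-PVS.
#'
#' @param v `pvs_volume` or 3-D array.
#' @param chain an `rf_chain` from [train_chain()].
#' @param roi optional precomputed logical ROI; default from the chain's
#'   config.
#' @return List with `mask` (logical array) and `prob` (final-stage
#'   probability field).
#' @export
predict_chain <- function(v, chain, roi = NULL) {
  cfg <- chain$cfg
  state <- if (is.null(roi)) stage_volume_state(as_volume(v), cfg) else {
    list(v = as_volume(v), roi = roi, coords_roi = which(roi, arr.ind = TRUE))
  }
  prev <- NULL
  for (forest in chain$stages)
    prev <- stage_prob_map(forest, state, cfg, prev)
  if (is.null(prev)) stop("chain has no stages")
  list(mask = prev >= 0.5, prob = prev)
}
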