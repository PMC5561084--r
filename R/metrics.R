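#' Confusion counts between two segmentation masks
#'
#' Voxel-wise TP/FP/FN/TN between a predicted and a truth mask, optionally
#' restricted to an evaluation mask (e.g. one hemisphere or a tissue
#' mask). The four counts sum to the number of evaluated voxels.
#'
#' @param pred,truth logical/binary arrays of identical dimensions.
#' @param eval_mask optional logical/binary array; voxels outside it are
#'   ignored.
#' @return List with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth, eval_mask = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth dimensions differ")
  p <- as.logical(pred); t <- as.logical(truth)
  if (!is.null(eval_mask)) {
    if (!all(dim(eval_mask) == dim(pred)))
      stop("eval_mask dimensions differ")
    keep <- as.logical(eval_mask)
    p <- p[keep]; t <- t[keep]
  }
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Dice, sensitivity and positive predictive value
#'
#' `DSC = 2 TP / (2 TP + FP + FN)`, `SN = TP / (TP + FN)`,
#' `PPV = TP / (TP + FP)`. DSC is the harmonic mean of SN and PPV. When
#' both the prediction and the truth are empty every denominator
#' vanishes and the scores are undefined; this raises an error rather
#' than silently returning 0.
#'
#' @param c confusion counts from [confusion()].
#' @return List with `DSC`, `SN`, `PPV`, each in `[0, 1]`.
#' @export
seg_scores <- function(c) {
  if ((c$TP + c$FP) == 0 && (c$TP + c$FN) == 0)
    stop("scores undefined: prediction and truth are both empty")
  dsc <- 2 * c$TP / (2 * c$TP + c$FP + c$FN)
  sn <- if ((c$TP + c$FN) > 0) c$TP / (c$TP + c$FN) else 0
  ppv <- if ((c$TP + c$FP) > 0) c$TP / (c$TP + c$FP) else 0
  list(DSC = dsc, SN = sn, PPV = ppv)
}

#' Three-arm phantom comparison
#'
#' Runs best-threshold vesselness segmentation on each phantom under the
#' three processing arms — `original` (the noisy volume as-is),
#' `denoised` (block-matching denoising only) and `enhanced_denoised`
#' (nonlocal Haar enhancement followed by denoising) — and tabulates
#' per-phantom and mean DSC/SN/PPV per arm.
#'
#' @param phantoms list of `phantom_pair`s from [generate_phantom()].
#' @param enh_cfg an [enhance_config()].
#' @param den_cfg a [denoise_config()].
#' @param scales,taus vesselness scales and threshold sweep grid.
#' @param arms which arms to run.
#' @param verbose print per-phantom progress.
#' @param keep_volumes also return the processed volumes per phantom and
#'   arm (for downstream classifiers).
#' @return List with `per_phantom` (data.frame: phantom, arm, tau, DSC,
#'   SN, PPV), `means` (data.frame: arm, DSC, SN, PPV), and — with
#'   `keep_volumes` — `volumes` (list of per-phantom arm volume lists).
#' @export
compare_arms <- function(phantoms, enh_cfg = enhance_config(),
                         den_cfg = denoise_config(),
                         scales = c(0.5, 1),
                         taus = seq(0.02, 0.9, by = 0.02),
                         arms = c("original", "denoised", "enhanced_denoised"),
                         verbose = FALSE, keep_volumes = FALSE) {
  if (length(phantoms) == 0) stop("at least one phantom required")
  rows <- list()
  volumes <- if (keep_volumes) vector("list", length(phantoms)) else NULL
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    vols <- arm_volumes(ph$noisy, arms, enh_cfg, den_cfg)
    if (keep_volumes) volumes[[i]] <- vols
    for (arm in arms) {
      vm <- multiscale_vesselness(vols[[arm]], scales = scales)
      sw <- sweep_threshold(vm, ph$truth, taus = taus)
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = i, arm = arm, tau = sw$best_tau,
        DSC = sw$best$DSC, SN = sw$best$SN, PPV = sw$best$PPV)
      if (verbose)
        message(sprintf("phantom %d %-18s best tau %.2f DSC %.3f",
                        i, arm, sw$best_tau, sw$best$DSC))
    }
  }
  per <- do.call(rbind, rows)
  means <- stats::aggregate(per[c("DSC", "SN", "PPV")],
                            by = list(arm = per$arm), FUN = mean)
  means <- means[match(arms, means$arm), ]
  rownames(means) <- NULL
  out <- list(per_phantom = per, means = means)
  if (keep_volumes) out$volumes <- volumes
  out
}

# Produce the processed volume for each requested arm.
arm_volumes <- function(noisy, arms, enh_cfg, den_cfg) {
  out <- list()
  if ("original" %in% arms) out$original <- noisy
  if ("denoised" %in% arms) out$denoised <- denoise_volume(noisy, den_cfg)
  if ("enhanced_denoised" %in% arms) {
    enh <- enhance_volume(noisy, enh_cfg)
    out$enhanced_denoised <- denoise_volume(enh, den_cfg)
  }
  out
}
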