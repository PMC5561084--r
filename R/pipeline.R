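#' Pipeline configuration
#'
#' Bundles the stage configurations, the processing arm and the seed for
#' a full run (enhance -> denoise -> segment -> evaluate) on one input
#' volume.
#'
#' @param enhance an [enhance_config()].
#' @param denoise a [denoise_config()].
#' @param scales vesselness scales (voxels).
#' @param tau vesselness segmentation threshold, or `"sweep"` to pick the
#'   best threshold against a supplied truth mask.
#' @param arm one of `"original"`, `"denoised"`, `"enhanced_denoised"`.
#' @param seed integer seed recorded in output metadata.
#' @return `pipeline_config` object.
#' @export
pipeline_config <- function(enhance = enhance_config(),
                            denoise = denoise_config(),
                            scales = c(0.5, 1), tau = 0.2,
                            arm = c("enhanced_denoised", "denoised", "original"),
                            seed = 1L) {
  arm <- match.arg(arm)
  stopifnot(inherits(enhance, "enhance_config"),
            inherits(denoise, "denoise_config"))
  structure(list(enhance = enhance, denoise = denoise, scales = scales,
                 tau = tau, arm = arm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline on one volume
#'
#' Applies the configured arm's processing (`original`: none;
#' `denoised`: block-matching denoising; `enhanced_denoised`: nonlocal
#' Haar enhancement then denoising), computes the multiscale vesselness
#' map and the thresholded segmentation, and — when a truth mask is given
#' — the DSC/SN/PPV scores (with a threshold sweep if `tau = "sweep"`).
#' When `out_dir` is given, writes the processed volume, vesselness map
#' and mask as NIfTI plus a JSON sidecar recording the resolved
#' configuration and seed; existing outputs are only overwritten with
#' `force = TRUE`.
#'
#' @param v input `pvs_volume` (or path to a NIfTI file).
#' @param cfg a [pipeline_config()].
#' @param truth optional logical truth mask (enables scoring/sweep).
#' @param mask optional tissue mask applied at thresholding.
#' @param out_dir optional output directory.
#' @param force overwrite existing outputs.
#' @return List with `processed` (volume), `vesselness`, `mask`, `tau`,
#'   and `scores` (NULL without truth).
#' @export
run_pipeline <- function(v, cfg = pipeline_config(), truth = NULL,
                         mask = NULL, out_dir = NULL, force = FALSE) {
  if (is.character(v)) v <- read_volume(v)
  v <- as_volume(v)
  processed <- switch(cfg$arm,
    original = v,
    denoised = denoise_volume(v, cfg$denoise),
    enhanced_denoised = denoise_volume(enhance_volume(v, cfg$enhance),
                                       cfg$denoise))
  vm <- multiscale_vesselness(processed, scales = cfg$scales)
  if (identical(cfg$tau, "sweep")) {
    if (is.null(truth)) stop("tau = \"sweep\" requires a truth mask")
    sw <- sweep_threshold(vm, truth, mask = mask)
    tau <- sw$best_tau
  } else tau <- cfg$tau
  seg <- threshold_segment(vm, tau, mask)
  scores <- NULL
  if (!is.null(truth))
    scores <- seg_scores(confusion(seg, truth, eval_mask = mask))
  res <- list(processed = processed, vesselness = vm, mask = seg,
              tau = tau, scores = scores)
  if (!is.null(out_dir))
    write_pipeline_outputs(res, v, cfg, out_dir, force)
  res
}

write_pipeline_outputs <- function(res, input, cfg, out_dir, force) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("processed.nii.gz", "vesselness.nii.gz",
                                "mask.nii.gz", "run.json"))
  if (!force && any(file.exists(paths)))
    stop("outputs exist in ", out_dir, "; use force = TRUE to overwrite")
  write_volume(res$processed, paths[1])
  write_volume(volume(res$vesselness$values, input$spacing, input$affine),
               paths[2])
  write_volume(volume(array(as.numeric(res$mask), dim(res$mask)),
                      input$spacing, input$affine), paths[3], datatype = "uint8")
  sidecar <- list(
    package = "pvshaar",
    version = as.character(utils::packageVersion("pvshaar")),
    arm = cfg$arm, seed = cfg$seed, tau = res$tau,
    enhance = unclass(cfg$enhance)[c("cube_size", "K", "step", "T1", "T2",
                                     "T3", "gamma1", "gamma2", "exempt_dc")],
    denoise = unclass(cfg$denoise)[c("cube_size", "search_radius", "max_group",
                                     "hard_threshold_factor", "step")],
    scales = cfg$scales,
    config_hash = config_hash(cfg))
  writeLines(to_json(sidecar), paths[4])
  invisible(paths)
}

# small dependency-free JSON writer for sidecar metadata
to_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      paste0(pad, "  \"", nm, "\": ", to_json(x[[nm]], indent + 2)),
      character(1))
    paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}")
  } else if (is.character(x)) {
    paste0("\"", x, "\"")
  } else if (length(x) == 1) {
    format(x, digits = 15)
  } else {
    paste0("[", paste(format(x, digits = 15), collapse = ", "), "]")
  }
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "")
  # simple polynomial rolling hash over the serialized config string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
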