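# Pipeline configuration: one flat, serialisable object holding every
# operator parameter, so a batch run is fully described by (inputs, config,
# seed).

#' Pipeline configuration
#'
#' All operator parameters of the imaging and event-detection stages, with
#' the package defaults. Thresholds are in native intensity units of the
#' ingested images and are deliberately mandatory where the measurement
#' depends on them (`deposit_threshold`, `yfp_threshold`): the same fixed
#' threshold must be reused across all time points of a batch, so it is
#' configuration, never inferred per image. Use [calibrate_threshold()] once
#' on a designated reference image to freeze it.
#'
#' @param channels Named character vector mapping channel roles
#'   (`nuclei`, `marker`, `deposit`, `yfp`, `gfap`) to channel labels in the
#'   ingested stacks.
#' @param pixel_size_um Optional override of the stack's pixel size; when
#'   both exist the configured value wins (logged).
#' @param deposit_threshold,yfp_threshold Fixed thresholds for the deposit
#'   and biosensor channels (native units, applied to the
#'   background-subtracted plane).
#' @param marker_threshold Threshold for the cellular-marker ROI.
#' @param nucleus_threshold Threshold for DAPI segmentation.
#' @param gfap_threshold Threshold for the cytoskeletal channel in the
#'   branching chain, in 8-bit units (the chain converts to 8-bit first).
#' @param ball_radius_px Rolling-ball radius for background subtraction.
#' @param bg_presmooth_sigma_px Gaussian pre-smoothing applied to the copy
#'   of the plane on which the background is estimated (0 = none); reduces
#'   the noise-driven downward bias of the morphological estimate.
#' @param connectivity Particle connectivity, 4 or 8.
#' @param cutoffs [size_class_cutoffs()] for deposit classification.
#' @param closing_cycles Dilation-erosion cycles for ROI/mask refinement.
#' @param intden_on_subtracted Measure integrated density on the
#'   background-subtracted plane (`TRUE`, default) or the raw plane.
#' @param blur_sigma_px Gaussian blur sigma in the branching chain.
#' @param branch_mask_frac Fraction of the blurred edge image's maximum used
#'   to binarise it ("convert to mask").
#' @param edge_then_threshold Run edge detection before thresholding in the
#'   branching chain instead of the literal threshold-then-edge order.
#' @param spur_prune_px Minimum retained skeleton branch length; shorter
#'   terminal spurs are pruned before branch-point counting.
#' @param nucleus_min_area_px,nucleus_max_area_px Area gates for nucleus
#'   segmentation.
#' @param split_touching_nuclei Split fused nuclei by distance-transform
#'   watershed.
#' @param area_max_condensed_px,intensity_min_condensed Condensed-nucleus
#'   classification thresholds (defaults from [nucleus_defaults()]).
#' @param puncta_min_area_px,puncta_max_area_px Area gates for generic
#'   puncta counting.
#' @param criterion_threshold Template-fit detection criterion threshold.
#' @param amp_min_pa Minimum event amplitude in pA; events at or below this
#'   magnitude are discarded.
#' @param window_s Analysis window for event statistics, seconds.
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Output directory for batch runs (`NULL` = in-memory only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(channels = c(nuclei = "nuclei", marker = "marker",
                                         deposit = "deposit", yfp = "yfp",
                                         gfap = "gfap"),
                            pixel_size_um = NULL,
                            deposit_threshold = NULL,
                            yfp_threshold = NULL,
                            marker_threshold = 40,
                            nucleus_threshold = 60,
                            gfap_threshold = 40,
                            ball_radius_px = 50,
                            bg_presmooth_sigma_px = 1,
                            connectivity = 8,
                            cutoffs = size_class_cutoffs(),
                            closing_cycles = 3,
                            intden_on_subtracted = TRUE,
                            blur_sigma_px = 2,
                            branch_mask_frac = 0.25,
                            edge_then_threshold = FALSE,
                            spur_prune_px = 6,
                            nucleus_min_area_px = 20,
                            nucleus_max_area_px = 400,
                            split_touching_nuclei = FALSE,
                            area_max_condensed_px = nucleus_defaults()$area_max_condensed_px,
                            intensity_min_condensed = nucleus_defaults()$intensity_min_condensed,
                            puncta_min_area_px = 2,
                            puncta_max_area_px = 200,
                            criterion_threshold = 3,
                            amp_min_pa = 10,
                            window_s = 60,
                            seed = 1,
                            out_dir = NULL) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  check_scalar(ball_radius_px, "ball_radius_px", min = 1)
  check_scalar(closing_cycles, "closing_cycles", min = 0)
  check_scalar(amp_min_pa, "amp_min_pa", min = 0)
  check_scalar(window_s, "window_s", min = 0, strict = TRUE)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(unlist(v)), collapse = " ")))
  }
  invisible(x)
}

#' Write / read a pipeline configuration (YAML)
#'
#' Serialisation round-trips losslessly: `read_config(write_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$cutoffs <- unclass(x$cutoffs)
  x$channels <- as.list(x$channels)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$channels <- unlist(x$channels)
  x$cutoffs <- do.call(size_class_cutoffs, x$cutoffs)
  do.call(pipeline_config, x)
}

#' Calibrate a fixed threshold on a reference plane
#'
#' Chooses a threshold once, on a designated reference image, to be frozen
#' for the whole batch (the same threshold must be used for all time
#' points). Otsu's method on the background-subtracted plane.
#'
#' @param plane Numeric matrix (a background-subtracted reference plane).
#' @param levels Number of histogram levels for Otsu (default 256).
#' @return Threshold in native intensity units.
#' @export
calibrate_threshold <- function(plane, levels = 256) {
  rng <- range(plane)
  if (rng[1] == rng[2]) return(rng[1])
  s <- (plane - rng[1]) / (rng[2] - rng[1])
  t <- EBImage::otsu(EBImage::Image(s), range = c(0, 1), levels = levels)
  t * (rng[2] - rng[1]) + rng[1]
}
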