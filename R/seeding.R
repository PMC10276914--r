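# FRET-biosensor seeding readout: integrated density of the thresholded YFP
# signal per field, normalised to the cell-covered area (the nuclei channel
# cannot be used as the normaliser because DAPI excitation interferes with
# the CFP/YFP emission).

#' Quantify biosensor seeding signal in a field
#'
#' Max-projects the YFP channel across z, runs the inclusion macro chain
#' (background subtraction, fixed threshold, particle analysis) on the
#' projection, sums the particle integrated densities, and divides by the
#' cell-covered area in square micrometres.
#'
#' @param stack An [image_stack()] with a YFP channel (role resolved through
#'   `config$channels[["yfp"]]`).
#' @param cell_area_mask A [binary_mask()] of the area covered by cells
#'   (typically ingested from a manually drawn mask file; derive one from a
#'   marker channel with [build_roi()] as a fallback).
#' @param config A [pipeline_config()]; `yfp_threshold` is mandatory.
#' @return One-row tibble of class `seeding_result`: `yfp_int_den`,
#'   `cell_area_um2`, `normalized_int_den` (= `yfp_int_den / cell_area_um2`,
#'   `NA` and flagged when the mask is empty), `n_particles`, `n_z_used`.
#' @export
quantify_seeding <- function(stack, cell_area_mask, config) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(config$yfp_threshold))
    abort("`yfp_threshold` is mandatory configuration: calibrate it once on a reference image.")
  ch <- config$channels[["yfp"]]
  if (!(ch %in% channel_roles(stack)))
    abort(sprintf("stack lacks the configured 'yfp' channel ('%s').", ch))
  px_um <- config$pixel_size_um %||% pixel_size(stack)
  if (!all(dim(stack)[1:2] == dim(cell_area_mask)[1:2]))
    abort("`cell_area_mask` geometry does not match the stack.")

  res <- run_particle_chain(stack, ch, config$yfp_threshold, roi = NULL,
                            config = config,
                            min_area_px = config$cutoffs$small_min)
  particles <- particle_table(res$lab, res$measured, px_um)
  yfp_int_den <- sum(particles$int_den)
  cell_area_um2 <- measure_cell_area(cell_area_mask, px_um)
  defined <- cell_area_um2 > 0
  if (!defined)
    warn("empty cell-area mask: normalized seeding signal undefined.")
  out <- tibble::tibble(
    yfp_int_den = yfp_int_den,
    cell_area_um2 = cell_area_um2,
    normalized_int_den = if (defined) yfp_int_den / cell_area_um2 else NA_real_,
    n_particles = nrow(particles),
    n_z_used = dim(stack)[4],
    normalization_defined = defined)
  class(out) <- c("seeding_result", class(out))
  out
}
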