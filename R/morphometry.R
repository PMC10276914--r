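# Nucleus segmentation and live/condensed classification, condensed-nuclei
# accumulation scoring, and the skeletonization-based branching macro.

#' Segment nuclei from a DAPI plane
#'
#' Threshold, closing refinement and component labelling with nucleus-scale
#' area gates; optionally splits touching nuclei with a distance-transform
#' watershed.
#'
#' @param dapi_plane Numeric matrix (nuclei channel).
#' @param config A [pipeline_config()] (uses `nucleus_threshold`,
#'   `closing_cycles`, `nucleus_min_area_px`, `nucleus_max_area_px`,
#'   `split_touching_nuclei`).
#' @return Tibble of nucleus records: `label`, `centroid_row`,
#'   `centroid_col` (0-based), `area_px`, `mean_intensity` (on the raw
#'   plane), `state` (`NA` until classified).
#' @export
segment_nuclei <- function(dapi_plane, config = pipeline_config()) {
  mask <- apply_threshold(dapi_plane, config$nucleus_threshold)
  mask <- refine_mask(mask, config$closing_cycles)
  if (isTRUE(config$split_touching_nuclei) && any(mask)) {
    dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    ws <- EBImage::watershed(dm)
    lab <- matrix(as.integer(ws), nrow(ws), ncol(ws))
    # re-impose area gates on the watershed labels
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= config$nucleus_min_area_px &
                    areas <= config$nucleus_max_area_px)
    remap <- integer(length(areas)); remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
    lab <- structure(lab, n = length(keep), areas = areas[keep],
                     connectivity = 8L,
                     class = c("labeled_components", "matrix"))
  } else {
    lab <- label_particles(mask, config$connectivity,
                           config$nucleus_min_area_px,
                           config$nucleus_max_area_px)
  }
  tab <- particle_table(lab, dapi_plane, 1)
  tibble::tibble(label = tab$label,
                 centroid_row = tab$centroid_row,
                 centroid_col = tab$centroid_col,
                 area_px = tab$area_px,
                 mean_intensity = tab$mean_intensity,
                 state = NA_character_)
}

#' Classify nuclei as live or condensed
#'
#' A nucleus is condensed (pyknotic, marking a dead cell) when it is both
#' small and bright: `area_px <= area_max_condensed_px` and
#' `mean_intensity >= intensity_min_condensed` (both boundaries inclusive).
#' The defaults come from [nucleus_defaults()] and are consistent with the
#' synthetic generator's rendering factors; on real images both thresholds
#' require explicit calibration.
#'
#' @param records Nucleus tibble from [segment_nuclei()].
#' @param area_max_condensed_px Maximum condensed-nucleus area (px).
#' @param intensity_min_condensed Minimum condensed-nucleus mean intensity.
#' @return The records with `state` set to `"live"` or `"condensed"`.
#' @export
classify_nucleus_state <- function(records,
                                   area_max_condensed_px = nucleus_defaults()$area_max_condensed_px,
                                   intensity_min_condensed = nucleus_defaults()$intensity_min_condensed) {
  stopifnot(is.data.frame(records))
  dplyr::mutate(tibble::as_tibble(records),
    state = ifelse(.data$area_px <= area_max_condensed_px &
                     .data$mean_intensity >= intensity_min_condensed,
                   "condensed", "live"))
}

#' Score condensed-nuclei accumulation per astrocyte
#'
#' Each condensed nucleus is assigned to the astrocyte whose mask contains
#' its centroid; condensed nuclei outside every mask count in the field
#' total but in no per-cell bin. Bin fractions over astrocytes use the
#' engulfed-corpse scheme 0, 1-2, 3-4, 5+.
#'
#' @param nuclei Classified nucleus tibble ([classify_nucleus_state()]).
#' @param astro_labels Integer label matrix of astrocyte cell masks
#'   (0 = background), e.g. a `labeled_components` object.
#' @return A list of class `accumulation_summary`: `summary` (one-row
#'   tibble: `n_condensed_total`, `n_live_astrocytes`, `condensed_per_live`,
#'   bin fractions `bin_0`, `bin_1_2`, `bin_3_4`, `bin_5plus`) and
#'   `per_astrocyte` (tibble of per-cell condensed counts).
#' @export
score_accumulation <- function(nuclei, astro_labels) {
  stopifnot(is.data.frame(nuclei))
  lab <- astro_labels
  n_astro <- max(0L, max(lab))
  cond <- nuclei[!is.na(nuclei$state) & nuclei$state == "condensed", ]
  n_cond <- nrow(cond)
  counts <- integer(n_astro)
  if (n_cond > 0 && n_astro > 0) {
    rows <- pmin(pmax(round(cond$centroid_row) + 1L, 1L), nrow(lab))
    cols <- pmin(pmax(round(cond$centroid_col) + 1L, 1L), ncol(lab))
    host <- lab[cbind(rows, cols)]
    assigned <- host[host > 0]
    if (length(assigned))
      counts <- tabulate(assigned, nbins = n_astro)
  }
  if (n_astro == 0) {
    warn("no live astrocyte: condensed-per-live ratio undefined.")
    summary <- tibble::tibble(
      n_condensed_total = n_cond, n_live_astrocytes = 0L,
      condensed_per_live = NA_real_, bin_0 = NA_real_, bin_1_2 = NA_real_,
      bin_3_4 = NA_real_, bin_5plus = NA_real_)
    return(structure(list(summary = summary,
                          per_astrocyte = tibble::tibble(astrocyte = integer(0),
                                                         n_condensed = integer(0))),
                     class = "accumulation_summary"))
  }
  bins <- c(bin_0 = sum(counts == 0),
            bin_1_2 = sum(counts >= 1 & counts <= 2),
            bin_3_4 = sum(counts >= 3 & counts <= 4),
            bin_5plus = sum(counts >= 5)) / n_astro
  summary <- tibble::tibble(
    n_condensed_total = n_cond,
    n_live_astrocytes = n_astro,
    condensed_per_live = n_cond / n_astro,
    bin_0 = bins[["bin_0"]], bin_1_2 = bins[["bin_1_2"]],
    bin_3_4 = bins[["bin_3_4"]], bin_5plus = bins[["bin_5plus"]])
  structure(list(summary = summary,
                 per_astrocyte = tibble::tibble(astrocyte = seq_len(n_astro),
                                                n_condensed = counts)),
            class = "accumulation_summary")
}

#' @export
print.accumulation_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<accumulation_summary> %d condensed over %d astrocyte(s): %.3g per cell; bins 0/1-2/3-4/5+ = %.2f/%.2f/%.2f/%.2f\n",
              s$n_condensed_total, s$n_live_astrocytes, s$condensed_per_live,
              s$bin_0, s$bin_1_2, s$bin_3_4, s$bin_5plus))
  invisible(x)
}

#' Measure astrocyte branching morphometry
#'
#' Runs the branching chain on the cytoskeletal (GFAP) plane: convert to
#' 8-bit, threshold, edge detection, Gaussian blur, conversion to a mask,
#' refinement by dilation-erosion cycles, skeletonization, spur pruning and
#' branch-point counting (a skeleton pixel touching 3 or more skeleton
#' pixels, adjacent qualifying pixels merged into one junction). The cell
#' count is the number of live nuclei whose centroid falls inside the
#' refined mask (confluent cells merge into one component, so components
#' cannot be counted).
#'
#' @param gfap_plane Numeric matrix (cytoskeletal channel).
#' @param dapi_plane Numeric matrix (nuclei channel).
#' @param config A [pipeline_config()]; `edge_then_threshold = TRUE` swaps
#'   the first two steps.
#' @return A list of class `branching_result`: `summary` (one-row tibble:
#'   `n_cells`, `total_branch_points`, `branch_points_per_cell`,
#'   `mask_area_um2`, `mean_cell_area_um2`) and `per_cell` (tibble of
#'   junction counts per skeleton component matched to a nucleus).
#' @export
measure_branching <- function(gfap_plane, dapi_plane,
                              config = pipeline_config()) {
  px_um <- config$pixel_size_um %||% 1
  g8 <- convert_bits(gfap_plane, 8)
  if (isTRUE(config$edge_then_threshold)) {
    edges <- sobel_edges(g8)
    work <- gaussian_blur(edges, config$blur_sigma_px)
  } else {
    bin <- apply_threshold(g8, config$gfap_threshold)
    edges <- sobel_edges(matrix(as.numeric(bin), nrow(bin), ncol(bin)) * 255)
    work <- gaussian_blur(edges, config$blur_sigma_px)
  }
  mask <- apply_threshold(work, config$branch_mask_frac * max(work))
  mask <- refine_mask(mask, config$closing_cycles)
  skel <- skeletonize_mask(mask)
  skel <- prune_spurs(skel, config$spur_prune_px)
  bp <- count_branch_points(skel)

  nuclei <- segment_nuclei(dapi_plane, config)
  nuclei <- classify_nucleus_state(nuclei, config$area_max_condensed_px,
                                   config$intensity_min_condensed)
  live <- nuclei[nuclei$state == "live", ]
  inside <- logical(nrow(live))
  if (nrow(live)) {
    rows <- pmin(pmax(round(live$centroid_row) + 1L, 1L), nrow(mask))
    cols <- pmin(pmax(round(live$centroid_col) + 1L, 1L), ncol(mask))
    inside <- mask_values(mask)[cbind(rows, cols)]
  }
  n_cells <- sum(inside)

  # per-cell breakdown: junctions grouped by skeleton component, components
  # matched to the nearest in-mask live nucleus
  per_cell <- tibble::tibble(cell = integer(0), n_branch_points = integer(0))
  if (n_cells > 0) {
    comp <- .label_components_cpp(mask_values(skel), 8L)
    live_in <- live[inside, ]
    cell_of_comp <- rep(NA_integer_, attr(comp, "n"))
    if (attr(comp, "n") > 0) {
      idx <- which(comp > 0, arr.ind = TRUE)
      labs <- comp[idx]
      for (ci in seq_len(attr(comp, "n"))) {
        pix <- idx[labs == ci, , drop = FALSE]
        d2 <- outer(pix[, 1] - 1, live_in$centroid_row, "-")^2 +
          outer(pix[, 2] - 1, live_in$centroid_col, "-")^2
        cell_of_comp[ci] <- which.min(apply(d2, 2, min))
      }
    }
    jb <- integer(n_cells)
    if (bp$count > 0) {
      for (i in seq_len(nrow(bp$points))) {
        # junction centroid may fall off-skeleton after merging; use raw pixel
        raw1 <- bp$raw_pixels[which.min((bp$raw_pixels$row - bp$points$row[i])^2 +
                                          (bp$raw_pixels$col - bp$points$col[i])^2), ]
        ci <- comp[raw1$row + 1L, raw1$col + 1L]
        if (ci > 0 && !is.na(cell_of_comp[ci]))
          jb[cell_of_comp[ci]] <- jb[cell_of_comp[ci]] + 1L
      }
    }
    per_cell <- tibble::tibble(cell = seq_len(n_cells), n_branch_points = jb)
  } else {
    warn("no live cell inside the mask: branching metrics undefined.")
  }
  mask_area_um2 <- sum(mask) * px_um^2
  summary <- tibble::tibble(
    n_cells = n_cells,
    total_branch_points = bp$count,
    branch_points_per_cell = if (n_cells > 0) bp$count / n_cells else NA_real_,
    mask_area_um2 = mask_area_um2,
    mean_cell_area_um2 = if (n_cells > 0) mask_area_um2 / n_cells else NA_real_)
  structure(list(summary = summary, per_cell = per_cell,
                 skeleton = skel, mask = mask, branch_points = bp$points),
            class = "branching_result")
}

#' @export
print.branching_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<branching_result> %d cell(s), %d branch point(s) (%.3g per cell), mean cell area %.4g um^2\n",
              s$n_cells, s$total_branch_points, s$branch_points_per_cell,
              s$mean_cell_area_um2))
  invisible(x)
}

#' Measure cell area from a binary mask
#'
#' Foreground pixel count times the squared pixel size; hand-drawn cell
#' areas are ingested as mask files and measured with this.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param pixel_size_um Micrometres per pixel side.
#' @return Area in square micrometres.
#' @export
measure_cell_area <- function(mask, pixel_size_um) {
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  sum(mask_values(mask)) * pixel_size_um^2
}
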