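# Inclusion (deposit) quantification: the particle-analysis chain with
# integrated-density reporting, size classes and per-living-cell
# normalisation. Also serves generic puncta counting.

#' Deposit size-class cut-offs (pixel areas)
#'
#' Default classes: small 5-200 px, medium 201-2000 px, large 2001+ px.
#' Classes are contiguous, non-overlapping and exhaustive above the small
#' minimum; particles below `small_min` are below the detection floor and
#' are discarded (counted separately).
#'
#' @param small_min,small_max,medium_max Integer bounds; large is
#'   `medium_max + 1` to infinity.
#' @return A `size_class_cutoffs` list.
#' @export
#' @examples
#' size_class_cutoffs()
size_class_cutoffs <- function(small_min = 5, small_max = 200,
                               medium_max = 2000) {
  check_scalar(small_min, "small_min", min = 1)
  if (small_max < small_min || medium_max <= small_max)
    abort("cut-offs must satisfy small_min <= small_max < medium_max.")
  structure(list(small_min = as.integer(small_min),
                 small_max = as.integer(small_max),
                 medium_max = as.integer(medium_max)),
            class = "size_class_cutoffs")
}

#' Assign size classes to particle records
#'
#' Every particle with `area_px >= small_min` receives exactly one class;
#' smaller particles are dropped from the returned table and reported via
#' the `n_discarded` attribute.
#'
#' @param records Data frame with an `area_px` column.
#' @param cutoffs A [size_class_cutoffs()].
#' @return The retained records as a tibble with a `size_class` factor
#'   column (`small`, `medium`, `large`); attributes `n_discarded` and
#'   `class_counts` (named integer vector).
#' @export
classify_sizes <- function(records, cutoffs = size_class_cutoffs()) {
  stopifnot(is.data.frame(records), "area_px" %in% names(records))
  stopifnot(inherits(cutoffs, "size_class_cutoffs"))
  a <- records$area_px
  keep <- a >= cutoffs$small_min
  out <- tibble::as_tibble(records[keep, , drop = FALSE])
  out$size_class <- factor(
    ifelse(out$area_px <= cutoffs$small_max, "small",
           ifelse(out$area_px <= cutoffs$medium_max, "medium", "large")),
    levels = c("small", "medium", "large"))
  counts <- table(out$size_class)
  attr(out, "n_discarded") <- sum(!keep)
  attr(out, "class_counts") <- setNames(as.integer(counts), names(counts))
  out
}

#' Build the cellular-marker region of interest
#'
#' Thresholds the marker plane and refines the mask with closing cycles;
#' the ROI restricts particle measurement to intracellular signal.
#'
#' @param marker_plane Numeric matrix (cellular-marker channel).
#' @param config A [pipeline_config()] (uses `marker_threshold`,
#'   `closing_cycles`).
#' @return A [binary_mask()]; empty ROIs trigger a warning.
#' @export
build_roi <- function(marker_plane, config = pipeline_config()) {
  roi <- apply_threshold(marker_plane, config$marker_threshold)
  roi <- refine_mask(roi, config$closing_cycles)
  if (!any(roi)) warn("ROI is empty: field will be reported with zero metrics.")
  attr(roi, "provenance") <- list(threshold = config$marker_threshold,
                                  closing_cycles = config$closing_cycles,
                                  source = "marker")
  roi
}

# the shared macro chain: project, subtract background, threshold, clear
# outside the ROI, label. Returns the pieces downstream measures need.
run_particle_chain <- function(stack, channel, threshold, roi, config,
                               min_area_px, max_area_px = Inf) {
  plane <- max_project(stack, channel)
  sub <- subtract_background(plane, config$ball_radius_px,
                             presmooth_sigma_px = config$bg_presmooth_sigma_px)
  measured <- if (isTRUE(config$intden_on_subtracted)) sub else plane
  mask <- apply_threshold(sub, threshold)
  if (!is.null(roi)) mask <- clear_outside(mask, roi)
  lab <- label_particles(mask, config$connectivity, min_area_px, max_area_px)
  list(plane = plane, sub = sub, measured = measured, mask = mask, lab = lab)
}

particle_table <- function(lab, measured, pixel_size_um) {
  n <- attr(lab, "n")
  if (n == 0) {
    return(tibble::tibble(label = integer(0), area_px = integer(0),
                          area_um2 = numeric(0), mean_intensity = numeric(0),
                          int_den = numeric(0), centroid_row = numeric(0),
                          centroid_col = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[idx]
  vals <- measured[idx]
  areas <- attr(lab, "areas")
  int_den <- as.vector(tapply(vals, labs, sum))
  tibble::tibble(
    label = seq_len(n),
    area_px = areas,
    area_um2 = areas * pixel_size_um^2,
    mean_intensity = int_den / areas,
    int_den = int_den,
    centroid_row = as.vector(tapply(idx[, 1], labs, mean)) - 1,
    centroid_col = as.vector(tapply(idx[, 2], labs, mean)) - 1)
}

#' Quantify fluorescent inclusions in a field
#'
#' Runs the inclusion macro chain on the deposit channel: max projection,
#' background subtraction, fixed threshold, clearing outside the
#' marker-derived ROI, and particle analysis. Each particle's integrated
#' density (area x mean intensity, equivalently the sum of its pixel
#' intensities) is measured on the background-subtracted plane by default.
#' The per-field summary is normalised by the number of living cells
#' (live-classified DAPI nuclei).
#'
#' @param stack An [image_stack()] with deposit, marker and nuclei channels.
#' @param config A [pipeline_config()]; `deposit_threshold` is mandatory.
#' @param roi Optional externally supplied [binary_mask()] ROI (overrides
#'   the marker-derived one).
#' @param field_id Identifier copied into the output tables.
#' @return A list of class `inclusion_result`: `particles` (per-particle
#'   tibble with size classes) and `summary` (one-row tibble with raw and
#'   per-live-nucleus metrics; normalised metrics are `NA` with
#'   `normalization_defined = FALSE` when no live nucleus is present).
#' @export
quantify_inclusions <- function(stack, config, roi = NULL,
                                field_id = "field") {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(config$deposit_threshold))
    abort("`deposit_threshold` is mandatory configuration: calibrate it once on a reference image.")
  ch <- config$channels
  for (role in c("deposit", "marker", "nuclei")) {
    if (!(ch[[role]] %in% channel_roles(stack)))
      abort(sprintf("stack lacks the configured '%s' channel ('%s').",
                    role, ch[[role]]))
  }
  px_um <- config$pixel_size_um %||% pixel_size(stack)

  if (is.null(roi)) roi <- build_roi(max_project(stack, ch[["marker"]]), config)
  res <- run_particle_chain(stack, ch[["deposit"]], config$deposit_threshold,
                            roi, config,
                            min_area_px = config$cutoffs$small_min)
  particles <- particle_table(res$lab, res$measured, px_um)
  particles <- classify_sizes(particles, config$cutoffs)
  cc <- attr(particles, "class_counts")

  nuclei <- segment_nuclei(max_project(stack, ch[["nuclei"]]), config)
  nuclei <- classify_nucleus_state(nuclei, config$area_max_condensed_px,
                                   config$intensity_min_condensed)
  n_live <- sum(nuclei$state == "live")

  raw <- tibble::tibble(
    field_id = field_id,
    n_particles = nrow(particles),
    total_area_px = sum(particles$area_px),
    total_area_um2 = sum(particles$area_um2),
    sum_int_den = sum(particles$int_den),
    n_small = cc[["small"]], n_medium = cc[["medium"]], n_large = cc[["large"]],
    n_live_nuclei = n_live)
  norm <- function(x) if (n_live > 0) x / n_live else NA_real_
  summary <- dplyr::mutate(raw,
    particles_per_live = norm(.data$n_particles),
    area_px_per_live = norm(.data$total_area_px),
    int_den_per_live = norm(.data$sum_int_den),
    small_per_live = norm(.data$n_small),
    medium_per_live = norm(.data$n_medium),
    large_per_live = norm(.data$n_large),
    normalization_defined = n_live > 0)
  if (n_live == 0)
    warn(sprintf("field '%s': no live nucleus; normalized metrics undefined.",
                 field_id))
  particles <- dplyr::mutate(particles, field_id = field_id,
                             .before = 1)
  structure(list(particles = particles, summary = summary,
                 nuclei = nuclei, roi = roi),
            class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<inclusion_result> field '%s': %d particle(s) (S/M/L %d/%d/%d), sum IntDen %.4g, %d live nuclei\n",
              s$field_id, s$n_particles, s$n_small, s$n_medium, s$n_large,
              s$sum_int_den, s$n_live_nuclei))
  invisible(x)
}

#' Count puncta normalised to the total cell count
#'
#' The same macro chain with puncta-scale area gates; the result is the
#' puncta count divided by the total number of nuclei in the field
#' (live and condensed alike), as used for synaptophysin puncta and
#' TUNEL-positive nuclei.
#'
#' @param stack An [image_stack()].
#' @param channel_role Role of the channel to count (must resolve via
#'   `config$channels` or be a channel label present in the stack).
#' @param config A [pipeline_config()]; the fixed threshold used is
#'   `deposit_threshold`.
#' @param roi Optional ROI mask; default none (whole field).
#' @return One-row tibble: `n_puncta`, `n_nuclei`, `puncta_per_cell`
#'   (`NA` when the field holds no nuclei).
#' @export
count_puncta <- function(stack, channel_role, config, roi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(config$deposit_threshold))
    abort("`deposit_threshold` is mandatory configuration.")
  ch <- if (channel_role %in% names(config$channels))
    config$channels[[channel_role]] else channel_role
  res <- run_particle_chain(stack, ch, config$deposit_threshold, roi, config,
                            min_area_px = config$puncta_min_area_px,
                            max_area_px = config$puncta_max_area_px)
  nuclei <- segment_nuclei(max_project(stack, config$channels[["nuclei"]]),
                           config)
  n_nuc <- nrow(nuclei)
  tibble::tibble(
    n_puncta = attr(res$lab, "n"),
    n_nuclei = n_nuc,
    puncta_per_cell = if (n_nuc > 0) attr(res$lab, "n") / n_nuc else NA_real_)
}
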