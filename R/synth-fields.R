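# Synthetic microscopy fields with exact ground-truth ledgers. Every draw
# goes through R's RNG seeded from the spec, so identical specs give
# bit-identical fields and ledgers.

#' Acquisition geometry shared by all synthetic fields
#'
#' @param width_px,height_px Field size in pixels (>= 32).
#' @param pixel_size_um Micrometres per pixel side (default 0.3, a typical
#'   40x widefield scale; the scale is always explicit configuration).
#' @param n_z Number of z-slices (1 = single plane).
#' @param seed Integer seed controlling every random draw.
#' @param background_level Constant background added to every channel.
#' @param noise_sd Gaussian read-noise standard deviation (0 = noise-free).
#' @return A `field_spec` list.
#' @export
field_spec <- function(width_px = 256, height_px = 256, pixel_size_um = 0.3,
                       n_z = 1, seed = 1, background_level = 10,
                       noise_sd = 0) {
  check_scalar(width_px, "width_px", min = 32)
  check_scalar(height_px, "height_px", min = 32)
  check_scalar(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  check_scalar(n_z, "n_z", min = 1)
  check_scalar(background_level, "background_level", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 0)
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, n_z = as.integer(n_z),
    seed = as.integer(seed), background_level = background_level,
    noise_sd = noise_sd), class = "field_spec")
}

#' Specification of a synthetic inclusion field
#'
#' Describes a three-channel field (nuclei, cellular marker, deposit) holding
#' fluorescent deposits in three size classes inside a cellular-marker ROI,
#' plus live and condensed nuclei.
#'
#' @inheritParams field_spec
#' @param n_particles_per_class Integer triple: number of small, medium and
#'   large deposits.
#' @param intensity_range Two positive numbers; each deposit's uniform
#'   interior intensity is drawn from this interval.
#' @param min_separation_px Minimum gap between deposit supports (>= 2).
#' @param n_live_nuclei,n_condensed_nuclei Nucleus counts.
#' @param roi_fraction Fraction of the field covered by the cellular-marker
#'   ROI, in (0, 1].
#' @param n_particles_outside_roi Deposits deliberately placed outside the
#'   ROI (they must be excluded by ROI-restricted quantification).
#' @param cutoffs Size-class pixel bounds, see [size_class_cutoffs()].
#' @param antialias Add a 1-px rim at half intensity around each deposit
#'   (rim pixels are part of the ledger pixel set).
#' @return An `inclusion_field_spec`.
#' @export
inclusion_field_spec <- function(width_px = 256, height_px = 256,
                                 pixel_size_um = 0.3, n_z = 1, seed = 1,
                                 background_level = 10, noise_sd = 0,
                                 n_particles_per_class = c(3, 2, 1),
                                 intensity_range = c(300, 900),
                                 min_separation_px = 4,
                                 n_live_nuclei = 10, n_condensed_nuclei = 0,
                                 roi_fraction = 0.9,
                                 n_particles_outside_roi = 0,
                                 cutoffs = size_class_cutoffs(),
                                 antialias = FALSE) {
  base <- field_spec(width_px, height_px, pixel_size_um, n_z, seed,
                     background_level, noise_sd)
  if (length(n_particles_per_class) != 3 || any(n_particles_per_class < 0))
    abort("`n_particles_per_class` must be 3 non-negative counts.")
  if (length(intensity_range) != 2 || any(intensity_range <= 0) ||
      diff(intensity_range) < 0)
    abort("`intensity_range` must be an increasing positive interval.")
  check_scalar(min_separation_px, "min_separation_px", min = 2)
  check_scalar(n_live_nuclei, "n_live_nuclei", min = 0)
  check_scalar(n_condensed_nuclei, "n_condensed_nuclei", min = 0)
  if (!is_scalar_number(roi_fraction) || roi_fraction <= 0 || roi_fraction > 1)
    abort("`roi_fraction` must be in (0, 1].")
  out <- c(base, list(
    n_particles_per_class = as.integer(n_particles_per_class),
    intensity_range = intensity_range,
    min_separation_px = as.integer(min_separation_px),
    n_live_nuclei = as.integer(n_live_nuclei),
    n_condensed_nuclei = as.integer(n_condensed_nuclei),
    roi_fraction = roi_fraction,
    n_particles_outside_roi = as.integer(n_particles_outside_roi),
    cutoffs = cutoffs, antialias = isTRUE(antialias)))
  class(out) <- c("inclusion_field_spec", "field_spec")
  out
}

# pixel offsets of a rotated filled ellipse with approximately `area_target`
# pixels; returns NULL when the rendered pixel count misses [lo, hi]
ellipse_offsets <- function(area_target, ratio, theta, lo, hi) {
  a <- sqrt(area_target * ratio / pi)
  b <- a / ratio
  k <- ceiling(a) + 1L
  g <- expand.grid(dr = -k:k, dc = -k:k)
  u <- g$dc * cos(theta) + g$dr * sin(theta)
  v <- -g$dc * sin(theta) + g$dr * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  n <- sum(keep)
  if (n < lo || n > hi) return(NULL)
  list(dr = g$dr[keep], dc = g$dc[keep])
}

# rim: background-adjacent pixels 8-touching the core
rim_offsets <- function(core) {
  key <- paste(core$dr, core$dc)
  cand <- unique(do.call(rbind, lapply(seq_along(core$dr), function(i) {
    expand.grid(dr = core$dr[i] + (-1:1), dc = core$dc[i] + (-1:1))
  })))
  keep <- !(paste(cand$dr, cand$dc) %in% key)
  list(dr = cand$dr[keep], dc = cand$dc[keep])
}

place_center <- function(taken, radius, sep, rows, cols, max_attempts = 2000) {
  if (rows[1] > rows[2] || cols[1] > cols[2])
    abort("field too crowded: object does not fit inside the placement region.")
  for (i in seq_len(max_attempts)) {
    r <- runif(1, rows[1], rows[2])
    c <- runif(1, cols[1], cols[2])
    ok <- TRUE
    if (nrow(taken) > 0) {
      d <- sqrt((taken$r - r)^2 + (taken$c - c)^2)
      ok <- all(d >= taken$radius + radius + sep)
    }
    if (ok) return(c(r, c))
  }
  abort("field too crowded: could not place object without violating min_separation_px.")
}

#' Generate a synthetic inclusion field with ground truth
#'
#' Renders a three-channel (nuclei / marker / deposit) field per the spec.
#' Deposits are filled ellipses of uniform interior intensity; their true
#' pixel sets and intensity sums are recorded in the ledger before background
#' and noise are added. Condensed nuclei are rendered smaller and brighter
#' than live nuclei by the shared [nucleus_defaults()] factors. With
#' `n_z > 1`, each deposit lives on one z-slice while nuclei and marker are
#' present on every slice, so a max projection recovers the composite.
#'
#' @param spec An [inclusion_field_spec()].
#' @return A list with `stack` (an [image_stack()] with channels
#'   `nuclei`, `marker`, `deposit`) and `truth` (a `ground_truth` ledger with
#'   `$particles`, `$nuclei`, `$roi_mask`).
#' @export
generate_inclusion_field <- function(spec) {
  stopifnot(inherits(spec, "inclusion_field_spec"))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px; nz <- spec$n_z
  nd <- nucleus_defaults()
  cut <- spec$cutoffs

  # ROI: centred band covering roi_fraction of the field, full width
  roi <- matrix(FALSE, h, w)
  band <- max(1L, round(h * spec$roi_fraction))
  r0 <- max(1L, floor((h - band) / 2) + 1L)
  roi[r0:(r0 + band - 1L), ] <- TRUE
  roi_rows <- c(r0, r0 + band - 1L)

  nuclei_plane <- matrix(0, h, w)
  marker_plane <- matrix(0, h, w)
  marker_plane[roi] <- 80
  deposit_planes <- replicate(nz, matrix(0, h, w), simplify = FALSE)

  # nuclei and deposits live on different channels, so they only need
  # separation within their own channel
  taken_nuc <- tibble::tibble(r = numeric(0), c = numeric(0), radius = numeric(0))
  taken_dep <- tibble::tibble(r = numeric(0), c = numeric(0), radius = numeric(0))

  # nuclei -------------------------------------------------------------------
  n_nuc <- spec$n_live_nuclei + spec$n_condensed_nuclei
  states <- rep(c("live", "condensed"),
                c(spec$n_live_nuclei, spec$n_condensed_nuclei))
  nuc_rows <- list()
  for (i in seq_len(n_nuc)) {
    live <- states[i] == "live"
    radius <- if (live) nd$live_radius_px else
      nd$live_radius_px * sqrt(nd$condensed_area_factor)
    value <- if (live) nd$live_intensity else
      nd$live_intensity * nd$condensed_intensity_factor
    margin <- ceiling(radius) + 1
    ctr <- place_center(taken_nuc, radius, 2,
                        c(roi_rows[1] + margin, roi_rows[2] - margin),
                        c(1 + margin, w - margin))
    taken_nuc <- dplyr::bind_rows(taken_nuc,
      tibble::tibble(r = ctr[1], c = ctr[2], radius = radius))
    off <- disc_offsets(radius)
    rr <- round(ctr[1]) + off$dr; cc <- round(ctr[2]) + off$dc
    nuclei_plane[cbind(rr, cc)] <- value
    nuc_rows[[i]] <- tibble::tibble(
      id = i, row = round(ctr[1]) - 1, col = round(ctr[2]) - 1,
      state = states[i], area_px = length(off$dr), mean_intensity = value,
      host_cell = NA_integer_)
  }

  # deposits -----------------------------------------------------------------
  classes <- rep(c("small", "medium", "large"), spec$n_particles_per_class)
  n_in <- length(classes)
  classes <- c(classes, rep("small", spec$n_particles_outside_roi))
  part_rows <- list()
  for (i in seq_along(classes)) {
    bounds <- switch(classes[i],
      small = c(cut$small_min, cut$small_max),
      medium = c(cut$small_max + 1, cut$medium_max),
      large = c(cut$medium_max + 1, min(cut$medium_max * 1.5, 3000)))
    core <- NULL
    for (try in 1:200) {
      target <- runif(1, bounds[1], bounds[2])
      core <- ellipse_offsets(target, runif(1, 1, 2), runif(1, 0, pi),
                              bounds[1], bounds[2])
      if (!is.null(core)) break
    }
    if (is.null(core))
      abort("could not render a deposit inside its class bounds.")
    rim <- if (spec$antialias) rim_offsets(core) else NULL
    ext <- max(abs(c(core$dr, core$dc, rim$dr, rim$dc))) + 1
    inside <- i <= n_in
    if (inside) {
      rows_rng <- c(roi_rows[1] + ext + 1, roi_rows[2] - ext - 1)
      cols_rng <- c(1 + ext + 1, w - ext - 1)
    } else {
      # outside the ROI band: above or below it
      space_top <- roi_rows[1] - 1; space_bot <- h - roi_rows[2]
      if (max(space_top, space_bot) < 2 * ext + 4)
        abort("field too crowded: no room outside the ROI for the requested deposits.")
      if (space_top >= space_bot) {
        rows_rng <- c(1 + ext + 1, roi_rows[1] - ext - 1)
      } else {
        rows_rng <- c(roi_rows[2] + ext + 1, h - ext - 1)
      }
      cols_rng <- c(1 + ext + 1, w - ext - 1)
    }
    ctr <- place_center(taken_dep, ext, spec$min_separation_px, rows_rng,
                        cols_rng)
    taken_dep <- dplyr::bind_rows(taken_dep,
      tibble::tibble(r = ctr[1], c = ctr[2], radius = ext))
    value <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
    zi <- if (nz > 1) sample.int(nz, 1) else 1L
    rr <- round(ctr[1]) + core$dr; cc <- round(ctr[2]) + core$dc
    pix <- cbind(rr, cc)
    deposit_planes[[zi]][pix] <- value
    if (!is.null(rim)) {
      rimpix <- cbind(round(ctr[1]) + rim$dr, round(ctr[2]) + rim$dc)
      deposit_planes[[zi]][rimpix] <- value / 2
      pix <- rbind(pix, rimpix)
    }
    vals <- deposit_planes[[zi]][pix]
    part_rows[[i]] <- tibble::tibble(
      id = i, class = classes[i], area_px = length(core$dr),
      centroid_row = mean(pix[, 1]) - 1, centroid_col = mean(pix[, 2]) - 1,
      intensity = value, intensity_sum = sum(vals),
      pixels = list(pix[, 1] + (pix[, 2] - 1) * h), z = zi, in_roi = inside)
  }

  # assemble, add background + noise -----------------------------------------
  arr <- array(0, c(h, w, 3, nz))
  for (z in seq_len(nz)) {
    arr[, , 1, z] <- nuclei_plane
    arr[, , 2, z] <- marker_plane
    arr[, , 3, z] <- deposit_planes[[z]]
  }
  arr <- arr + spec$background_level
  if (spec$noise_sd > 0) {
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim(arr))
    arr[arr < 0] <- 0
  }
  stack <- image_stack(arr, spec$pixel_size_um,
                       channels = c("nuclei", "marker", "deposit"))
  truth <- structure(list(
    particles = if (length(part_rows)) dplyr::bind_rows(part_rows) else
      tibble::tibble(id = integer(0), class = character(0),
                     area_px = integer(0), centroid_row = numeric(0),
                     centroid_col = numeric(0), intensity = numeric(0),
                     intensity_sum = numeric(0), pixels = list(),
                     z = integer(0), in_roi = logical(0)),
    nuclei = if (length(nuc_rows)) dplyr::bind_rows(nuc_rows) else
      tibble::tibble(id = integer(0), row = numeric(0), col = numeric(0),
                     state = character(0), area_px = integer(0),
                     mean_intensity = numeric(0), host_cell = integer(0)),
    roi_mask = roi, spec = spec), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Specification of a synthetic branched-cell field
#'
#' @inheritParams field_spec
#' @param branch_points_per_cell Integer vector, one entry per cell: the true
#'   number of topological branch points of that cell's tree.
#' @param stroke_width_px Stroke width of the rendered processes (>= 1).
#' @param cell_area_um2 Optional numeric vector of per-cell target areas; the
#'   trunk length is scaled to approximate it. `NULL` uses default lengths.
#' @param gfap_intensity Foreground intensity of the cytoskeletal channel.
#' @return A `branch_field_spec`.
#' @export
branch_field_spec <- function(width_px = 256, height_px = 256,
                              pixel_size_um = 0.3, n_z = 1, seed = 1,
                              background_level = 10, noise_sd = 0,
                              branch_points_per_cell = c(2, 3),
                              stroke_width_px = 3, cell_area_um2 = NULL,
                              gfap_intensity = 150) {
  base <- field_spec(width_px, height_px, pixel_size_um, n_z, seed,
                     background_level, noise_sd)
  if (length(branch_points_per_cell) < 1 || any(branch_points_per_cell < 0))
    abort("`branch_points_per_cell` needs one non-negative count per cell.")
  check_scalar(stroke_width_px, "stroke_width_px", min = 1)
  if (!is.null(cell_area_um2) &&
      length(cell_area_um2) != length(branch_points_per_cell))
    abort("`cell_area_um2` must match `branch_points_per_cell` in length.")
  out <- c(base, list(
    n_cells = length(branch_points_per_cell),
    branch_points_per_cell = as.integer(branch_points_per_cell),
    stroke_width_px = as.integer(stroke_width_px),
    cell_area_um2 = cell_area_um2, gfap_intensity = gfap_intensity))
  class(out) <- c("branch_field_spec", "field_spec")
  out
}

# stamp a stroke of given width between two points into `plane`
draw_segment <- function(plane, p1, p2, width, value) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2L, ceiling(len * 4))
  ts <- seq(0, 1, length.out = n)
  rad <- width / 2
  off <- disc_offsets(max(rad - 0.01, 0.01))
  for (t in ts) {
    p <- round(p1 + t * (p2 - p1))
    rr <- p[1] + off$dr; cc <- p[2] + off$dc
    ok <- rr >= 1 & rr <= nrow(plane) & cc >= 1 & cc <= ncol(plane)
    plane[cbind(rr[ok], cc[ok])] <- value
  }
  plane
}

#' Generate a synthetic field of branched (tree-shaped) cells
#'
#' Each cell is drawn as a stroke tree: a trunk with `k` side branches
#' sprouting from well-separated interior points, so the tree's true
#' topological branch-point count is exactly `k`. Cells are laid out on a
#' non-overlapping grid; one live nucleus is rendered on each trunk.
#'
#' @param spec A [branch_field_spec()].
#' @return A list with `stack` (channels `nuclei`, `gfap`) and `truth`
#'   (ledger with `$cells`: id, n_branch_points, branch-point coordinates,
#'   rendered area, nucleus position).
#' @export
generate_branch_field <- function(spec) {
  stopifnot(inherits(spec, "branch_field_spec"))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  nd <- nucleus_defaults()
  ks <- spec$branch_points_per_cell
  width <- spec$stroke_width_px
  branch_len <- 18
  spacing <- 16

  trunk_len <- pmax(40, spacing * (ks + 1L))
  if (!is.null(spec$cell_area_um2)) {
    area_px <- spec$cell_area_um2 / spec$pixel_size_um^2
    trunk_len <- pmax(spacing * (ks + 1L),
                      round(area_px / max(width, 1) - branch_len * ks))
  }

  cell_w <- max(trunk_len) + 2 * branch_len + 8
  cell_h <- 2 * branch_len + 16
  per_row <- max(1L, floor(w / cell_w))
  n_rows <- ceiling(spec$n_cells / per_row)
  if (n_rows * cell_h > h || cell_w > w)
    abort("field too crowded: trees do not fit the requested field.")

  gfap <- matrix(0, h, w)
  nuclei <- matrix(0, h, w)
  cells <- list()
  for (i in seq_len(spec$n_cells)) {
    gi <- (i - 1L) %% per_row
    gj <- (i - 1L) %/% per_row
    ox <- gi * cell_w + branch_len + 4
    oy <- gj * cell_h + cell_h / 2
    k <- ks[i]
    tl <- trunk_len[i]
    p1 <- c(oy, ox); p2 <- c(oy, ox + tl)
    gfap <- draw_segment(gfap, p1, p2, width, spec$gfap_intensity)
    bps <- matrix(numeric(0), ncol = 2)
    if (k > 0) {
      xs <- ox + seq(spacing, by = spacing, length.out = k)
      for (j in seq_len(k)) {
        ang <- (if (j %% 2 == 0) 1 else -1) * (55 + runif(1, -8, 8)) * pi / 180
        bp <- c(oy, xs[j])
        tip <- bp + branch_len * c(sin(ang), cos(ang))
        gfap <- draw_segment(gfap, bp, tip, width, spec$gfap_intensity)
        bps <- rbind(bps, bp)
      }
    }
    nuc <- c(oy, ox + tl / 2)
    off <- disc_offsets(nd$live_radius_px)
    rr <- round(nuc[1]) + off$dr; cc <- round(nuc[2]) + off$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    nuclei[cbind(rr[ok], cc[ok])] <- nd$live_intensity
    cells[[i]] <- tibble::tibble(
      id = i, n_branch_points = k,
      branch_points = list(bps - 1),      # 0-based coordinates
      nucleus_row = round(nuc[1]) - 1, nucleus_col = round(nuc[2]) - 1,
      trunk_len_px = tl)
  }
  # rendered per-cell areas from the labelled stroke raster
  lab <- .label_components_cpp(gfap > 0, 8L)
  areas <- tabulate(lab[lab > 0], nbins = attr(lab, "n"))
  cells <- dplyr::bind_rows(cells)
  cells$area_px <- vapply(seq_len(nrow(cells)), function(i) {
    l <- lab[cells$nucleus_row[i] + 1L, cells$nucleus_col[i] + 1L]
    if (l > 0) areas[l] else NA_integer_
  }, integer(1))

  arr <- array(0, c(h, w, 2, spec$n_z))
  for (z in seq_len(spec$n_z)) {
    arr[, , 1, z] <- nuclei
    arr[, , 2, z] <- gfap
  }
  arr <- arr + spec$background_level
  if (spec$noise_sd > 0) {
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim(arr))
    arr[arr < 0] <- 0
  }
  stack <- image_stack(arr, spec$pixel_size_um, channels = c("nuclei", "gfap"))
  truth <- structure(list(cells = cells, spec = spec), class = "ground_truth")
  list(stack = stack, truth = truth)
}
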