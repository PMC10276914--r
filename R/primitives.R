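# Raster operators underlying the quantification macros. All operators take
# and return plain numeric matrices (row = image row) or binary_mask objects,
# and are deterministic.

#' Construct a binary mask
#'
#' @param m Logical (or 0/1 numeric) matrix.
#' @param provenance Optional list describing how the mask was produced
#'   (e.g. threshold value and source channel); kept for auditability.
#' @return A `binary_mask` (logical matrix with a provenance attribute).
#' @export
binary_mask <- function(m, provenance = list()) {
  if (!is.matrix(m)) abort("`m` must be a matrix.")
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  if (anyNA(m)) abort("mask values must be TRUE/FALSE (no NA).")
  structure(m, provenance = provenance, class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  prov <- attr(x, "provenance")
  if (length(prov))
    cat("  provenance:", paste(names(prov), unlist(lapply(prov, format)),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

mask_values <- function(mask) {
  matrix(as.logical(mask), nrow(mask), ncol(mask))
}

# reflective padding used by the convolution-based operators
pad_reflect <- function(m, k) {
  if (k < 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) abort("padding exceeds image size.")
  ri <- c(rev(seq_len(k) + 1L), seq_len(nr), nr - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(nc), nc - seq_len(k))
  m[ri, ci]
}

conv2_reflect <- function(m, kernel) {
  k <- (max(dim(kernel)) - 1L) %/% 2L
  p <- pad_reflect(m, k)
  f <- EBImage::filter2(p, kernel, boundary = "circular")
  f[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))]
}

#' Rolling-ball background subtraction
#'
#' Estimates a slowly varying background as the grayscale morphological
#' opening of the plane with a disc of the given radius (the ball rolled
#' under the intensity surface) and subtracts it, clipping at zero. On a
#' constant plane the result is identically zero, and the output is
#' invariant to adding a constant offset to the input.
#'
#' @param plane Numeric matrix.
#' @param ball_radius_px Ball radius in pixels (>= 1). Structures wider than
#'   about twice the radius are treated as background; the default of 50 px
#'   comfortably exceeds the diameter of individual inclusions.
#' @param presmooth_sigma_px Gaussian sigma applied to the copy of the plane
#'   on which the background is estimated (the estimate is still subtracted
#'   from the original plane). 0 (default) disables it; on noisy images a
#'   small sigma suppresses the downward bias that pixel noise induces in a
#'   morphological minimum, as the common tool's pre-smoothing option does.
#' @return Background-subtracted matrix, non-negative.
#' @export
subtract_background <- function(plane, ball_radius_px = 50,
                                presmooth_sigma_px = 0) {
  check_scalar(ball_radius_px, "ball_radius_px", min = 1)
  check_scalar(presmooth_sigma_px, "presmooth_sigma_px", min = 0)
  if (ball_radius_px > min(dim(plane)))
    abort("`ball_radius_px` exceeds the smaller image dimension.")
  est_src <- if (presmooth_sigma_px > 0)
    gaussian_blur(plane, presmooth_sigma_px) else plane
  rng <- range(est_src)
  if (rng[1] == rng[2]) {
    out <- plane - rng[1]
    out[out < 0] <- 0
    return(out)
  }
  # EBImage grayscale morphology assumes [0,1]; min/max filters commute with
  # increasing affine maps, so rescale, open, and map the estimate back.
  s <- (est_src - rng[1]) / (rng[2] - rng[1])
  brush <- EBImage::makeBrush(2L * ceiling(ball_radius_px) + 1L, "disc")
  bg <- EBImage::opening(s, brush) * (rng[2] - rng[1]) + rng[1]
  out <- plane - bg
  out[out < 0] <- 0
  out
}

#' Fixed-value thresholding
#'
#' Pixels strictly greater than `t` become foreground. The strict inequality
#' is a deliberate, recorded convention; the threshold value is stored in the
#' mask's provenance so batch runs are auditable.
#'
#' @param plane Numeric matrix.
#' @param t Threshold value (finite).
#' @return A [binary_mask()].
#' @export
apply_threshold <- function(plane, t) {
  check_scalar(t, "t")
  binary_mask(plane > t, provenance = list(threshold = t, rule = ">"))
}

#' Zero everything outside a region of interest
#'
#' @param x Numeric matrix or `binary_mask`.
#' @param roi A `binary_mask` (or logical matrix) of identical geometry.
#' @return Same type as `x`, with values outside `roi` set to 0/`FALSE`.
#' @export
clear_outside <- function(x, roi) {
  if (!all(dim(x)[1:2] == dim(roi)[1:2]))
    abort("`x` and `roi` geometries differ.")
  r <- mask_values(roi)
  if (inherits(x, "binary_mask")) {
    prov <- attr(x, "provenance")
    prov$cleared_outside_roi <- TRUE
    return(binary_mask(mask_values(x) & r, provenance = prov))
  }
  out <- x
  out[!r] <- 0
  out
}

#' Label connected components with area filtering
#'
#' Connected components of the mask whose pixel area lies in
#' `[min_area_px, max_area_px]` receive consecutive labels `1..K`; all other
#' foreground pixels are dropped. This is the "analyze particles" step.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param connectivity 4 or 8 (default 8, matching common particle analysis).
#' @param min_area_px,max_area_px Inclusive area bounds in pixels.
#' @return A `labeled_components` object: integer matrix with attributes
#'   `n` (component count) and `areas` (pixel area per label) and
#'   `connectivity`.
#' @export
label_particles <- function(mask, connectivity = 8, min_area_px = 1,
                            max_area_px = Inf) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  check_scalar(min_area_px, "min_area_px", min = 1)
  if (!is.numeric(max_area_px) || length(max_area_px) != 1 || max_area_px < min_area_px)
    abort("`max_area_px` must be a single number >= min_area_px.")
  m <- mask_values(mask)
  lab <- .label_components_cpp(m, as.integer(connectivity))
  n_raw <- attr(lab, "n")
  if (n_raw > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n_raw)
    keep <- which(areas >= min_area_px & areas <= max_area_px)
    remap <- integer(n_raw)
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  structure(lab,
    n = length(areas), areas = as.integer(areas),
    connectivity = as.integer(connectivity),
    class = c("labeled_components", "matrix"))
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d x %d px, %d component(s), %d-connected\n",
              nrow(x), ncol(x), attr(x, "n"), attr(x, "connectivity")))
  invisible(x)
}

#' Sobel gradient magnitude ("find edge")
#'
#' @param plane Numeric matrix.
#' @return Matrix of `sqrt(gx^2 + gy^2)` from the 3x3 Sobel kernels, with
#'   reflective boundary handling.
#' @export
sobel_edges <- function(plane) {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gy <- t(gx)
  sqrt(conv2_reflect(plane, gx)^2 + conv2_reflect(plane, gy)^2)
}

#' Gaussian blur
#'
#' Convolution with a normalised, truncated 2-D Gaussian kernel
#' (radius `ceiling(4 * sigma_px)`), reflective boundary.
#'
#' @param plane Numeric matrix.
#' @param sigma_px Standard deviation in pixels (> 0); default 2.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(plane, sigma_px = 2) {
  check_scalar(sigma_px, "sigma_px", min = 0, strict = TRUE)
  k <- ceiling(4 * sigma_px)
  ax <- -k:k
  g1 <- exp(-ax^2 / (2 * sigma_px^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  conv2_reflect(plane, kern)
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a 1-pixel-wide, 8-connected skeleton. Thinning is
#' homotopic: the skeleton has the same number of connected components as the
#' input mask, and re-skeletonizing a 1-px-wide skeleton leaves it unchanged.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @return A [binary_mask()].
#' @export
skeletonize_mask <- function(mask) {
  m <- mask_values(mask)
  binary_mask(.thin_skeleton_cpp(m), provenance = list(op = "skeletonize"))
}

#' Repeated morphological closing ("dilation and erosion" refinement)
#'
#' Each cycle dilates then erodes with a 3x3 box structuring element
#' (a morphological closing); `n_cycles = 0` is the identity. Closing fills
#' gaps up to the element size and never removes foreground.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param n_cycles Number of dilate-erode cycles (>= 0); default 3.
#' @return A [binary_mask()].
#' @export
refine_mask <- function(mask, n_cycles = 3) {
  check_scalar(n_cycles, "n_cycles", min = 0)
  m <- mask_values(mask)
  if (n_cycles > 0) {
    brush <- EBImage::makeBrush(3, "box")
    storage.mode(m) <- "double"
    for (i in seq_len(n_cycles)) {
      m <- EBImage::erode(EBImage::dilate(m, brush), brush)
    }
    m <- m > 0.5
  }
  binary_mask(m, provenance = list(op = "refine", n_cycles = n_cycles))
}

# count of 8-neighbours within the skeleton, per pixel (vectorised shifts)
neighbor_counts <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  }
  acc
}

#' Count branch points of a skeleton
#'
#' A skeleton pixel qualifies as a branch pixel when its 8-neighbourhood
#' contains three or more skeleton pixels. Because a thick junction yields
#' several adjacent qualifying pixels, qualifying pixels that touch under
#' 8-connectivity are merged into one junction, and the merged junctions are
#' counted.
#'
#' @param skeleton A `binary_mask` from [skeletonize_mask()] (1 px wide).
#' @param merge_adjacent Merge adjacent qualifying pixels (default `TRUE`);
#'   with `FALSE` every qualifying pixel counts, which over-counts crossings.
#' @param min_arms Merged clusters are kept only when at least this many
#'   skeleton branches leave the cluster (default 3). Thinning can leave
#'   staircase elbows whose pixels touch 3 neighbours without any branching;
#'   requiring 3 departing arms rejects them while keeping every true
#'   junction (a Y has 3 arms, a merged X crossing 4).
#' @return A list with `count`, `points` (tibble of 0-based junction centroid
#'   `row`, `col`) and `raw_pixels` (tibble of all qualifying pixels in
#'   retained clusters).
#' @export
count_branch_points <- function(skeleton, merge_adjacent = TRUE,
                                min_arms = 3) {
  m <- mask_values(skeleton)
  storage.mode(m) <- "integer"
  qual <- m == 1L & neighbor_counts(m) >= 3L
  empty <- tibble::tibble(row = integer(0), col = integer(0))
  if (!any(qual)) {
    return(list(count = 0L, points = empty, raw_pixels = empty))
  }
  idx <- which(qual, arr.ind = TRUE)
  if (!merge_adjacent) {
    raw <- tibble::tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
    return(list(count = nrow(raw), points = raw, raw_pixels = raw))
  }
  lab <- .label_components_cpp(qual, 8L)
  labs <- lab[idx]
  keep <- vapply(seq_len(attr(lab, "n")), function(k) {
    cl <- idx[labs == k, , drop = FALSE]
    cluster_arm_count(m, qual, cl) >= min_arms
  }, logical(1))
  if (!any(keep)) {
    return(list(count = 0L, points = empty, raw_pixels = empty))
  }
  sel <- keep[labs]
  raw <- tibble::tibble(row = idx[sel, 1] - 1L, col = idx[sel, 2] - 1L)
  labs_kept <- labs[sel]
  pts <- tibble::tibble(
    row = as.vector(tapply(raw$row, labs_kept, mean)),
    col = as.vector(tapply(raw$col, labs_kept, mean))
  )
  list(count = sum(keep), points = pts, raw_pixels = raw)
}

# number of connected skeleton branches leaving a cluster of junction pixels
cluster_arm_count <- function(m, qual, cl) {
  nr <- nrow(m); nc <- ncol(m)
  nbr <- unique(do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    expand.grid(r = cl[i, 1] + (-1:1), c = cl[i, 2] + (-1:1))
  })))
  nbr <- nbr[nbr$r >= 1 & nbr$r <= nr & nbr$c >= 1 & nbr$c <= nc, ]
  in_cluster <- paste(nbr$r, nbr$c) %in% paste(cl[, 1], cl[, 2])
  nbr <- nbr[!in_cluster & m[cbind(nbr$r, nbr$c)] == 1L, , drop = FALSE]
  if (nrow(nbr) == 0) return(0L)
  # group the departing pixels by 8-adjacency among themselves
  sub <- matrix(FALSE, nr, nc)
  sub[cbind(nbr$r, nbr$c)] <- TRUE
  attr(.label_components_cpp(sub, 8L), "n")
}

#' Prune short terminal spurs from a skeleton
#'
#' Removes endpoint branches shorter than `min_length_px` that terminate at a
#' junction, a standard clean-up before branch-point counting: thinning of a
#' blurred outline can leave 1-3 px spurs that would otherwise register as
#' junctions.
#'
#' @param skeleton A `binary_mask` (1 px wide).
#' @param min_length_px Spurs strictly shorter than this many pixels are
#'   removed; 0 disables pruning.
#' @return A [binary_mask()].
#' @export
prune_spurs <- function(skeleton, min_length_px = 6) {
  m <- mask_values(skeleton)
  storage.mode(m) <- "integer"
  if (min_length_px <= 0 || !any(m == 1L)) return(binary_mask(m == 1L))
  repeat {
    nb <- neighbor_counts(m)
    endpoints <- which(m == 1L & nb == 1L, arr.ind = TRUE)
    removed_any <- FALSE
    for (i in seq_len(nrow(endpoints))) {
      path <- trace_from_endpoint(m, endpoints[i, 1], endpoints[i, 2],
                                  max_steps = min_length_px)
      if (!is.null(path)) {
        m[path] <- 0L
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  binary_mask(m == 1L, provenance = list(op = "prune_spurs",
                                         min_length_px = min_length_px))
}

# walk from an endpoint along degree-2 pixels; if a junction (>= 3 neighbours)
# is met within max_steps, return the linear indices of the spur pixels
# (junction excluded), else NULL (keep the branch)
trace_from_endpoint <- function(m, r, c, max_steps) {
  nr <- nrow(m)
  path <- integer(0)
  prev <- NULL
  cur <- c(r, c)
  for (step in seq_len(max_steps)) {
    path <- c(path, cur[1] + (cur[2] - 1L) * nr)
    nbrs <- skeleton_neighbors(m, cur[1], cur[2])
    if (!is.null(prev))
      nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), , drop = FALSE]
    if (nrow(nbrs) == 0) return(NULL)       # isolated short segment: keep
    if (nrow(nbrs) > 1) return(path)        # touching a junction cluster: prune
    nxt <- nbrs[1, ]
    deg_nxt <- nrow(skeleton_neighbors(m, nxt[1], nxt[2]))
    if (deg_nxt >= 3) return(path)          # next pixel is a junction: prune
    prev <- cur
    cur <- nxt
  }
  NULL                                      # long enough: keep
}

skeleton_neighbors <- function(m, r, c) {
  rr <- max(1L, r - 1L):min(nrow(m), r + 1L)
  cc <- max(1L, c - 1L):min(ncol(m), c + 1L)
  sub <- which(m[rr, cc, drop = FALSE] == 1L, arr.ind = TRUE)
  out <- cbind(rr[sub[, 1]], cc[sub[, 2]])
  out[!(out[, 1] == r & out[, 2] == c), , drop = FALSE]
}

#' Linear bit-depth conversion
#'
#' Min-max rescales intensities to the integer range of the target bit depth
#' (0-255 for 8-bit, 0-65535 for 16-bit) and rounds. A constant plane maps
#' to 0.
#'
#' @param plane Numeric matrix.
#' @param bits Target depth, 8 or 16.
#' @return Matrix of integers in the target range.
#' @export
convert_bits <- function(plane, bits = 16) {
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  top <- 2^bits - 1
  rng <- range(plane)
  if (rng[1] == rng[2]) return(matrix(0, nrow(plane), ncol(plane)))
  round((plane - rng[1]) / (rng[2] - rng[1]) * top)
}
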