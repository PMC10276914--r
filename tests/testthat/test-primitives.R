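test_that("rolling-ball background subtraction removes flat background and keeps compact peaks", {
  # background equals image
  expect_equal(subtract_background(matrix(500, 64, 64), 20),
               matrix(0, 64, 64))
  # bright 3x3 square on zero background survives a much larger ball
  plane <- matrix(0, 128, 128)
  plane[60:62, 60:62] <- 100
  out <- subtract_background(plane, 50)
  expect_lt(max(abs(out - plane)), 1)
  # oracle: opening-with-disc subtraction on a structured image
  set.seed(4)
  img <- matrix(runif(64 * 64, 0, 10), 64, 64)
  img[20:24, 30:34] <- img[20:24, 30:34] + 200
  brush <- EBImage::makeBrush(21, "disc")
  s <- (img - min(img)) / diff(range(img))
  oracle <- img - (EBImage::opening(s, brush) * diff(range(img)) + min(img))
  oracle[oracle < 0] <- 0
  expect_equal(subtract_background(img, 10), oracle, tolerance = 1e-12)
  # offset invariance
  expect_equal(subtract_background(img + 123, 10),
               subtract_background(img, 10), tolerance = 1e-9)
  # oversized radius is a parameter error
  expect_error(subtract_background(matrix(0, 32, 32), 40), "exceeds")
})

test_that("thresholding is strictly greater-than and records provenance", {
  plane <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(sum(apply_threshold(plane, 10)), 0)
  m <- apply_threshold(plane, 3)
  expect_equal(sum(m), 1)            # the pixel equal to t is excluded
  expect_equal(attr(m, "provenance")$threshold, 3)
  set.seed(1)
  p <- matrix(rnorm(400), 20, 20)
  expect_equal(sum(apply_threshold(p, 0.3)), sum(p > 0.3))
})

test_that("clear_outside zeroes the complement of the ROI and only that", {
  set.seed(2)
  plane <- matrix(runif(100), 10, 10)
  full <- binary_mask(matrix(TRUE, 10, 10))
  none <- binary_mask(matrix(FALSE, 10, 10))
  expect_equal(clear_outside(plane, full), plane)
  expect_equal(clear_outside(plane, none), matrix(0, 10, 10))
  roi <- binary_mask(matrix(runif(100) > 0.5, 10, 10))
  out <- clear_outside(plane, roi)
  expect_equal(sum(out[mask_roi <- as.logical(roi)]), sum(plane[mask_roi]))
  expect_equal(sum(out[!mask_roi]), 0)
  expect_error(clear_outside(plane, binary_mask(matrix(TRUE, 5, 5))),
               "geometries")
})

test_that("threshold-then-clear commutes with clear-then-threshold", {
  set.seed(3)
  plane <- matrix(runif(400, 0, 10), 20, 20)
  roi <- binary_mask(matrix(runif(400) > 0.4, 20, 20))
  a <- clear_outside(apply_threshold(plane, 5), roi)
  b <- apply_threshold(clear_outside(plane, roi), 5)
  expect_equal(unclass(mask_a <- matrix(as.logical(a), 20, 20)),
               matrix(as.logical(b), 20, 20))
})

test_that("component labeling matches a flood-fill oracle and honours connectivity", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 8:10] <- TRUE
  lab <- label_particles(m)
  expect_equal(attr(lab, "n"), 2L)
  expect_equal(attr(lab, "areas"), c(9L, 9L))
  # diagonal touch: one 8-connected component, two 4-connected
  d <- matrix(FALSE, 6, 6)
  d[2:3, 2:3] <- TRUE; d[4:5, 4:5] <- TRUE
  expect_equal(attr(label_particles(d, 8), "n"), 1L)
  expect_equal(attr(label_particles(d, 4), "n"), 2L)
  # random masks against the oracle, both connectivities
  set.seed(11)
  for (i in 1:25) {
    rm <- matrix(runif(32 * 32) < 0.4, 32, 32)
    for (conn in c(4, 8)) {
      got <- label_particles(rm, conn)
      want <- flood_fill_label(rm, conn)
      expect_true(same_partition(unclass(got), want))
    }
  }
})

test_that("area gates drop components outside the configured bounds", {
  m <- matrix(FALSE, 20, 20)
  m[2, 2] <- TRUE                        # area 1
  m[5:7, 5:7] <- TRUE                    # area 9
  m[12:17, 12:17] <- TRUE                # area 36
  lab <- label_particles(m, 8, min_area_px = 5, max_area_px = 20)
  expect_equal(attr(lab, "n"), 1L)
  expect_equal(attr(lab, "areas"), 9L)
})

test_that("max projection is the per-pixel maximum across z", {
  st <- image_stack(array(0, c(8, 8, 1, 3)), 1, "x")
  expect_equal(max_project(get_plane(st, 1)), get_plane(st, 1))
  arr <- array(0, c(8, 8, 1, 3))
  arr[4, 4, 1, ] <- c(1, 7, 3)
  st <- image_stack(arr, 1, "x")
  proj <- max_project(st, 1)
  expect_equal(proj[4, 4], 7)
  for (z in 1:3) expect_true(all(proj >= arr[, , 1, z]))
})

test_that("Sobel magnitude vanishes on constants and scales with step height", {
  expect_equal(sobel_edges(matrix(7, 16, 16)), matrix(0, 16, 16))
  step <- function(h) {
    p <- matrix(0, 16, 16); p[, 9:16] <- h; p
  }
  r1 <- sobel_edges(step(10)); r2 <- sobel_edges(step(20))
  expect_equal(max(r2), 2 * max(r1))
  expect_equal(which(r1[8, ] > max(r1) - 1e-6), c(8L, 9L))
  # 90-degree rotation equivariance
  set.seed(5)
  p <- matrix(runif(15 * 15), 15, 15)
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(sobel_edges(rot(p)), rot(sobel_edges(p)), tolerance = 1e-9)
})

test_that("Gaussian blur preserves DC, conserves interior mass, matches the closed form", {
  expect_equal(gaussian_blur(matrix(3, 20, 20), 2), matrix(3, 20, 20),
               tolerance = 1e-9)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- gaussian_blur(imp, 2)
  expect_equal(sum(out), 1, tolerance = 1e-3)
  k <- ceiling(4 * 2); ax <- -k:k
  g <- exp(-ax^2 / 8); kern <- outer(g, g) / sum(outer(g, g))
  expect_equal(out[(21 - k):(21 + k), (21 - k):(21 + k)], kern,
               tolerance = 1e-2)
})

test_that("skeletonization thins bars to single-pixel lines and preserves topology", {
  bar <- matrix(FALSE, 20, 40)
  bar[9:11, 5:35] <- TRUE
  sk <- skeletonize_mask(bar)
  expect_true(all(colSums(sk[, 8:32]) == 1))      # 1 px wide along the bar
  expect_equal(max(flood_fill_label(matrix(as.logical(sk), 20, 40))), 1)
  expect_equal(sum(skeletonize_mask(matrix(FALSE, 10, 10))), 0)
  # component count preserved on random blobby masks
  set.seed(6)
  m <- matrix(FALSE, 48, 48)
  for (i in 1:5) {
    r <- sample(5:42, 1); c <- sample(5:42, 1)
    m[r + (-2:2), c + (-2:2)] <- TRUE
  }
  sk2 <- skeletonize_mask(m)
  expect_equal(max(flood_fill_label(matrix(as.logical(sk2), 48, 48))),
               max(flood_fill_label(m)))
  # idempotence on an already-thin skeleton
  expect_equal(unclass(skeletonize_mask(sk)), unclass(sk))
})

test_that("mask refinement closes small gaps and leaves convex masks alone", {
  m <- matrix(FALSE, 10, 20)
  m[5, 2:9] <- TRUE; m[5, 11:18] <- TRUE   # 1-px gap
  expect_equal(refine_mask(m, 0), binary_mask(m), ignore_attr = TRUE)
  closed <- refine_mask(m, 1)
  expect_equal(max(flood_fill_label(matrix(as.logical(closed), 10, 20))), 1)
  solid <- matrix(FALSE, 12, 12); solid[3:9, 3:9] <- TRUE
  expect_equal(matrix(as.logical(refine_mask(solid, 3)), 12, 12), solid)
})

test_that("branch points: line 0, Y 1, X collapses to one junction", {
  line <- matrix(FALSE, 15, 15); line[8, 2:14] <- TRUE
  expect_equal(count_branch_points(skeletonize_mask(line))$count, 0L)
  y <- matrix(FALSE, 21, 21)
  y[11:20, 11] <- TRUE
  for (i in 0:9) { y[10 - i, 11 - i] <- TRUE; y[10 - i, 11 + i] <- TRUE }
  res <- count_branch_points(binary_mask(y))
  expect_equal(res$count, 1L)
  expect_lt(abs(res$points$row - 10), 2.1)
  x <- matrix(FALSE, 21, 21)
  for (i in -9:9) { x[11 + i, 11 + i] <- TRUE; x[11 + i, 11 - i] <- TRUE }
  resx <- count_branch_points(binary_mask(x))
  expect_equal(resx$count, 1L)
  expect_gt(nrow(resx$raw_pixels), 0)
})

test_that("raster operators are translation-equivariant in the interior", {
  set.seed(7)
  base <- matrix(0, 48, 48)
  base[15:20, 15:22] <- runif(48, 50, 100)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  inner <- 12:36
  for (op in list(function(m) subtract_background(m, 8),
                  function(m) gaussian_blur(m, 1.5),
                  function(m) sobel_edges(m))) {
    a <- op(shift(base, 5, 7))
    b <- shift(op(base), 5, 7)
    expect_equal(a[inner + 5, inner + 7], b[inner + 5, inner + 7],
                 tolerance = 1e-8)
  }
})

test_that("bit-depth conversion rescales linearly to the target range", {
  p <- matrix(c(0, 50, 100), 3, 3)
  expect_equal(range(convert_bits(p, 8)), c(0, 255))
  expect_equal(range(convert_bits(p, 16)), c(0, 65535))
  expect_equal(convert_bits(matrix(42, 4, 4), 8), matrix(0, 4, 4))
})
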