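test_that("nucleus segmentation recovers rendered nuclei and classifies states", {
  spec <- inclusion_field_spec(seed = 81, n_particles_per_class = c(0, 0, 0),
                               n_live_nuclei = 10, n_condensed_nuclei = 4,
                               noise_sd = 0)
  fld <- generate_inclusion_field(spec)
  cfg <- pipeline_config(pixel_size_um = 0.3)
  nuc <- segment_nuclei(get_plane(fld$stack, "nuclei"), cfg)
  expect_equal(nrow(nuc), 14)
  nuc <- classify_nucleus_state(nuc)
  expect_equal(sum(nuc$state == "live"), 10)
  expect_equal(sum(nuc$state == "condensed"), 4)
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64), cfg)), 0)
})

test_that("state classification boundaries are inclusive", {
  rec <- tibble::tibble(label = 1:3,
                        area_px = c(70, 70, 71),
                        mean_intensity = c(192, 191.9, 192))
  out <- classify_nucleus_state(rec, area_max_condensed_px = 70,
                                intensity_min_condensed = 192)
  expect_equal(out$state, c("condensed", "live", "live"))
})

test_that("fused nuclei merge without splitting and separate with watershed", {
  plane <- matrix(0, 64, 64)
  off <- expand.grid(dr = -5:5, dc = -5:5)
  off <- off[off$dr^2 + off$dc^2 <= 25, ]
  for (ctr in list(c(30, 28), c(30, 38))) {    # touching discs
    plane[cbind(ctr[1] + off$dr, ctr[2] + off$dc)] <- 130
  }
  cfg <- pipeline_config(pixel_size_um = 0.3)
  expect_equal(nrow(segment_nuclei(plane, cfg)), 1)
  cfg$split_touching_nuclei <- TRUE
  expect_equal(nrow(segment_nuclei(plane, cfg)), 2)
})

test_that("accumulation bins follow the 0/1-2/3-4/5+ scheme exactly", {
  # three astrocytes holding 0, 2 and 5 condensed nuclei
  lab <- matrix(0L, 40, 60)
  lab[5:15, 5:15] <- 1L; lab[5:15, 25:35] <- 2L; lab[5:15, 45:55] <- 3L
  mk_nuc <- function(rows, cols, state) tibble::tibble(
    label = seq_along(rows), centroid_row = rows, centroid_col = cols,
    area_px = 40, mean_intensity = 300, state = state)
  cond <- mk_nuc(c(9, 10, 8, 9, 10, 11, 12), c(27, 30, 46, 48, 50, 52, 54),
                 "condensed")
  res <- score_accumulation(cond, lab)
  expect_equal(res$summary$condensed_per_live, 7 / 3)
  expect_equal(c(res$summary$bin_0, res$summary$bin_1_2,
                 res$summary$bin_3_4, res$summary$bin_5plus),
               c(1 / 3, 1 / 3, 0, 1 / 3))
  expect_equal(res$per_astrocyte$n_condensed, c(0L, 2L, 5L))
  # no condensed nuclei
  res0 <- score_accumulation(mk_nuc(8, 8, "live"), lab)
  expect_equal(res0$summary$condensed_per_live, 0)
  expect_equal(res0$summary$bin_0, 1)
  # unassigned condensed nuclei count in the total but in no bin
  outside <- mk_nuc(c(30, 35), c(3, 58), "condensed")
  reso <- score_accumulation(outside, lab)
  expect_equal(reso$summary$n_condensed_total, 2)
  expect_equal(reso$summary$bin_0, 1)
  expect_warning(score_accumulation(cond, matrix(0L, 10, 10)), "undefined|no live")
})

test_that("random assignments match a brute-force per-astrocyte tally", {
  set.seed(12)
  for (rep in 1:20) {
    n_astro <- sample(2:6, 1)
    lab <- matrix(0L, 30, 30 * n_astro)
    for (k in seq_len(n_astro)) lab[3:28, (k - 1) * 30 + 3:28] <- k
    n_cond <- sample(0:12, 1)
    host <- sample(n_astro, n_cond, replace = TRUE)
    rows <- sample(5:25, n_cond, replace = TRUE)
    cols <- (host - 1) * 30 + sample(5:25, n_cond, replace = TRUE)
    nuclei <- tibble::tibble(label = seq_len(n_cond), centroid_row = rows,
                             centroid_col = cols, area_px = 40,
                             mean_intensity = 300, state = "condensed")
    res <- score_accumulation(nuclei, lab)
    tallies <- tabulate(host, nbins = n_astro)
    expect_equal(res$per_astrocyte$n_condensed, tallies)
    bins <- c(sum(tallies == 0), sum(tallies %in% 1:2),
              sum(tallies %in% 3:4), sum(tallies >= 5)) / n_astro
    expect_equal(c(res$summary$bin_0, res$summary$bin_1_2,
                   res$summary$bin_3_4, res$summary$bin_5plus), bins)
    expect_equal(res$summary$bin_0 + res$summary$bin_1_2 +
                   res$summary$bin_3_4 + res$summary$bin_5plus, 1)
  }
})

test_that("branching morphometry recovers per-cell counts on rendered trees", {
  cfg <- pipeline_config(pixel_size_um = 0.3)
  one_y <- branch_field_spec(seed = 91, branch_points_per_cell = 1,
                             noise_sd = 0)
  fld <- generate_branch_field(one_y)
  br <- measure_branching(get_plane(fld$stack, "gfap"),
                          get_plane(fld$stack, "nuclei"), cfg)
  expect_equal(br$summary$branch_points_per_cell, 1)
  straight <- branch_field_spec(seed = 92, branch_points_per_cell = c(0, 0),
                                noise_sd = 0)
  fld2 <- generate_branch_field(straight)
  br2 <- measure_branching(get_plane(fld2$stack, "gfap"),
                           get_plane(fld2$stack, "nuclei"), cfg)
  expect_equal(br2$summary$total_branch_points, 0)
  expect_equal(br2$summary$n_cells, 2)
  mixed <- branch_field_spec(seed = 93, branch_points_per_cell = c(2, 4),
                             noise_sd = 0)
  fld3 <- generate_branch_field(mixed)
  br3 <- measure_branching(get_plane(fld3$stack, "gfap"),
                           get_plane(fld3$stack, "nuclei"), cfg)
  expect_equal(br3$summary$branch_points_per_cell, 3)
  expect_equal(sort(br3$per_cell$n_branch_points), c(2L, 4L))
})

test_that("branch counts are invariant to field translation and rotation", {
  spec <- branch_field_spec(seed = 94, branch_points_per_cell = 3,
                            noise_sd = 0)
  fld <- generate_branch_field(spec)
  g <- get_plane(fld$stack, "gfap"); d <- get_plane(fld$stack, "nuclei")
  cfg <- pipeline_config(pixel_size_um = 0.3)
  base <- measure_branching(g, d, cfg)$summary$total_branch_points
  shift <- function(m, dr, dc) {
    out <- matrix(min(m), nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(measure_branching(shift(g, 7, 9), shift(d, 7, 9),
                                 cfg)$summary$total_branch_points, base)
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(measure_branching(rot(g), rot(d),
                                 cfg)$summary$total_branch_points, base)
})

test_that("closing cycles never disconnect a connected mask", {
  spec <- branch_field_spec(seed = 95, branch_points_per_cell = 4,
                            stroke_width_px = 3, noise_sd = 0)
  fld <- generate_branch_field(spec)
  mask <- apply_threshold(get_plane(fld$stack, "gfap"), 50)
  n0 <- max(flood_fill_label(matrix(as.logical(mask), nrow(mask), ncol(mask))))
  for (cycles in 1:4) {
    ref <- refine_mask(mask, cycles)
    expect_lte(max(flood_fill_label(matrix(as.logical(ref), nrow(ref),
                                           ncol(ref)))), n0)
  }
})

test_that("cell area is pixel count times squared pixel size", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(measure_cell_area(m, 0.3), 100 * 0.09)
  expect_equal(measure_cell_area(matrix(FALSE, 5, 5), 0.3), 0)
  m2 <- matrix(FALSE, 20, 20); m2[15:18, 15:18] <- TRUE
  expect_equal(measure_cell_area(m | m2, 0.3),
               measure_cell_area(m, 0.3) + measure_cell_area(m2, 0.3))
})
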