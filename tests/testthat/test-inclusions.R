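test_that("size classification honours the printed pixel cut-offs", {
  rec <- tibble::tibble(area_px = c(4, 5, 200, 201, 2000, 2001))
  out <- classify_sizes(rec)
  expect_equal(attr(out, "n_discarded"), 1L)
  expect_equal(as.character(out$size_class),
               c("small", "small", "medium", "medium", "large"))
  # random areas against brute-force interval assignment
  set.seed(8)
  areas <- sample(1:3000, 100, replace = TRUE)
  got <- classify_sizes(tibble::tibble(area_px = areas))
  want <- cut(areas[areas >= 5], c(4, 200, 2000, Inf),
              labels = c("small", "medium", "large"))
  expect_equal(as.character(got$size_class), as.character(want))
  expect_equal(sum(attr(got, "class_counts")), nrow(got))
  expect_error(size_class_cutoffs(small_min = 10, small_max = 5), "cut-offs")
})

test_that("marker-derived ROI covers the configured cell fraction", {
  cfg <- test_config()
  full <- build_roi(matrix(100, 64, 64), cfg)
  expect_true(all(full))
  spec <- inclusion_field_spec(seed = 61, roi_fraction = 0.5, noise_sd = 0,
                               n_particles_per_class = c(1, 0, 0),
                               n_live_nuclei = 2)
  fld <- generate_inclusion_field(spec)
  roi <- build_roi(get_plane(fld$stack, "marker"), cfg)
  expect_lt(abs(sum(roi) / (256 * 256) - 0.5), 0.05)
  expect_warning(build_roi(matrix(0, 32, 32), cfg), "empty")
})

test_that("the inclusion macro chain recovers the ledger exactly on clean fields", {
  spec <- inclusion_field_spec(seed = 62, n_particles_per_class = c(3, 2, 1),
                               noise_sd = 0, n_live_nuclei = 10)
  fld <- generate_inclusion_field(spec)
  cfg <- test_config()
  res <- quantify_inclusions(fld$stack, cfg)
  tr <- fld$truth$particles
  expect_equal(res$summary$n_particles, 6)
  expect_equal(c(res$summary$n_small, res$summary$n_medium, res$summary$n_large),
               c(3, 2, 1))
  expect_equal(res$summary$total_area_px, sum(tr$area_px))
  expect_equal(res$summary$sum_int_den, sum(tr$intensity_sum))
  expect_equal(res$summary$n_live_nuclei, 10)
  # per-particle IntDen equals the ledger's true intensity sum
  got <- sort(res$particles$int_den)
  expect_equal(got, sort(tr$intensity_sum))
  # int_den = area x mean intensity by construction
  expect_equal(res$particles$int_den,
               res$particles$area_px * res$particles$mean_intensity)
})

test_that("a threshold above all deposits yields zero metrics", {
  spec <- inclusion_field_spec(seed = 63, noise_sd = 0)
  fld <- generate_inclusion_field(spec)
  res <- quantify_inclusions(fld$stack, test_config(deposit_threshold = 1e6))
  expect_equal(res$summary$n_particles, 0)
  expect_equal(res$summary$sum_int_den, 0)
  expect_equal(res$summary$total_area_px, 0)
})

test_that("per-live-cell normalisation is linear and flagged when undefined", {
  base <- inclusion_field_spec(seed = 64, n_particles_per_class = c(3, 0, 0),
                               noise_sd = 0, n_live_nuclei = 5)
  cfg <- test_config()
  r1 <- quantify_inclusions(generate_inclusion_field(base)$stack, cfg)
  expect_equal(r1$summary$int_den_per_live * 5, r1$summary$sum_int_den)
  expect_equal(r1$summary$particles_per_live, 3 / 5)
  none <- inclusion_field_spec(seed = 64, n_particles_per_class = c(3, 0, 0),
                               noise_sd = 0, n_live_nuclei = 0)
  expect_warning(
    r0 <- quantify_inclusions(generate_inclusion_field(none)$stack, cfg),
    "no live nucleus")
  expect_false(r0$summary$normalization_defined)
  expect_true(is.na(r0$summary$int_den_per_live))
  expect_equal(r0$summary$n_particles, 3)   # raw metrics still emitted
})

test_that("deposits outside the cellular ROI are excluded from measurement", {
  spec <- inclusion_field_spec(seed = 65, n_particles_per_class = c(2, 0, 0),
                               roi_fraction = 0.5, n_particles_outside_roi = 2,
                               noise_sd = 0)
  fld <- generate_inclusion_field(spec)
  expect_equal(sum(!fld$truth$particles$in_roi), 2)
  res <- quantify_inclusions(fld$stack, test_config())
  expect_equal(res$summary$n_particles, 2)
  expect_equal(res$summary$sum_int_den,
               sum(fld$truth$particles$intensity_sum[fld$truth$particles$in_roi]))
})

test_that("raising the threshold never increases count or area", {
  spec <- inclusion_field_spec(seed = 66, noise_sd = 20)
  fld <- generate_inclusion_field(spec)
  prev_n <- Inf; prev_a <- Inf
  for (t in c(50, 150, 400, 700)) {
    r <- quantify_inclusions(fld$stack, test_config(deposit_threshold = t))
    expect_lte(r$summary$n_particles, prev_n)
    expect_lte(r$summary$total_area_px, prev_a)
    prev_n <- r$summary$n_particles; prev_a <- r$summary$total_area_px
  }
})

test_that("classification depends only on pixel area, never on pixel scale", {
  spec <- inclusion_field_spec(seed = 67, noise_sd = 0)
  fld <- generate_inclusion_field(spec)
  r1 <- quantify_inclusions(fld$stack, test_config(pixel_size_um = 0.3))
  r2 <- quantify_inclusions(fld$stack, test_config(pixel_size_um = 0.9))
  expect_equal(as.character(r1$particles$size_class),
               as.character(r2$particles$size_class))
  expect_equal(r2$particles$area_um2, 9 * r1$particles$area_um2)
})

test_that("puncta counting normalises to the total nucleus count", {
  spec <- inclusion_field_spec(seed = 68, n_particles_per_class = c(40, 0, 0),
                               noise_sd = 0, n_live_nuclei = 8,
                               n_condensed_nuclei = 2, roi_fraction = 1)
  fld <- generate_inclusion_field(spec)
  out <- count_puncta(fld$stack, "deposit", test_config())
  expect_equal(out$n_puncta, 40)
  expect_equal(out$n_nuclei, 10)
  expect_equal(out$puncta_per_cell, 4)
  empty <- inclusion_field_spec(seed = 69, n_particles_per_class = c(0, 0, 0),
                                noise_sd = 0, n_live_nuclei = 5)
  out0 <- count_puncta(generate_inclusion_field(empty)$stack, "deposit",
                       test_config())
  expect_equal(out0$puncta_per_cell, 0)
})

test_that("puncta rendered closer than the resolution merge into one detection", {
  nuc <- matrix(0, 64, 64)
  nuc[8:16, 8:16] <- 130                   # one nucleus for the normaliser
  mk_stack <- function(dep) image_stack(
    array(c(nuc, matrix(100, 64, 64), dep), c(64, 64, 3, 1)), 0.3,
    c("nuclei", "marker", "deposit"))
  plane <- matrix(0, 64, 64)
  plane[30:31, 30:31] <- 500               # two 2x2 puncta, 1 px apart
  plane[30:31, 33:34] <- 500
  plane[50:51, 50:51] <- 500               # one isolated punctum
  cfg <- test_config()
  expect_equal(count_puncta(mk_stack(plane), "deposit", cfg)$n_puncta, 3)
  bridged <- plane
  bridged[30:31, 32] <- 500                # bridge the close pair
  expect_equal(count_puncta(mk_stack(bridged), "deposit", cfg)$n_puncta, 2)
})

test_that("a missing channel role or threshold is a configuration error", {
  st <- stack_from_plane(matrix(0, 32, 32))
  expect_error(quantify_inclusions(st, test_config()), "channel")
  spec <- inclusion_field_spec(seed = 70, noise_sd = 0)
  fld <- generate_inclusion_field(spec)
  cfg <- test_config(); cfg$deposit_threshold <- NULL
  expect_error(quantify_inclusions(fld$stack, cfg), "mandatory")
})
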