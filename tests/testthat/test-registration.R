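gauss_spot_stack <- function(centers_nm, voxel = c(90, 90, 200),
                             dims = c(40, 40, 12), fwhm = c(250, 750)) {
  arr <- array(0, dims)
  sig <- c(rep(fwhm[1], 2), fwhm[2]) / (2 * sqrt(2 * log(2)))
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * voxel[k])
  for (r in seq_len(nrow(centers_nm))) {
    gx <- exp(-(ax[[1]] - centers_nm[r, 1])^2 / (2 * sig[1]^2))
    gy <- exp(-(ax[[2]] - centers_nm[r, 2])^2 / (2 * sig[2]^2))
    gz <- exp(-(ax[[3]] - centers_nm[r, 3])^2 / (2 * sig[3]^2))
    arr <- arr + outer(outer(gx, gy), gz)
  }
  confocal_stack(arr, voxel)
}

test_that("rescaling preserves a constant field and flips are involutions", {
  st <- confocal_stack(array(3.7, c(10, 10, 3)), c(90, 90, 200))
  out <- rescale_confocal(st, 10)
  expect_equal(dim(out[[1]]), c(90, 90))
  expect_true(all(abs(out[[1]] - 3.7) < 1e-12))
  ## flip x twice = identity
  st2 <- gauss_spot_stack(matrix(c(1000, 2000, 1200), 1))
  a <- rescale_confocal(st2, 30)
  b <- rescale_confocal(st2, 30, flip = c(x = TRUE, y = FALSE))
  expect_equal(a[[6]], b[[6]][nrow(b[[6]]):1, ], tolerance = 1e-9)
})

test_that("a delta-like voxel stays within one source pixel after rescale", {
  arr <- array(0, c(20, 20, 1)); arr[7, 13, 1] <- 100
  st <- confocal_stack(arr, c(90, 90, 200))
  out <- rescale_confocal(st, 10)
  am <- which(out[[1]] == max(out[[1]]), arr.ind = TRUE)[1, ]
  ## source voxel 7 center = 585 nm -> target pixel ~ 59
  expect_lt(abs(am[1] * 10 - 5 - 585), 90)
  expect_lt(abs(am[2] * 10 - 5 - 1125), 90)
})

test_that("moving projections have the right count and linearity", {
  slices <- lapply(1:7, function(i) matrix(i, 4, 4))
  pr <- moving_projections(slices, window = 5)
  expect_length(pr, 3L)
  expect_equal(pr[[1]], matrix(sum(1:5), 4, 4))
  expect_equal(pr[[3]], matrix(sum(3:7), 4, 4))
  ## all-zero slices stay zero; pixel sums add up
  z <- moving_projections(lapply(1:5, function(i) matrix(0, 3, 3)), 5)
  expect_true(all(z[[1]] == 0))
  expect_error(moving_projections(slices, 0), "window")
  expect_error(moving_projections(slices[1:3], 5), "slices")
})

test_that("rigid registration recovers identity, shifts and rotations", {
  sc <- make_test_scene(21, n_rds = 15)
  ev <- make_test_events(sc, 22, n_frames = 2000, events = 50)
  fixed <- unclass(render_events(ev, 10, roi = c(0, 3000, 0, 3000))) * 1.0

  self <- register_rigid(fixed, fixed, rot_range = 2)
  expect_equal(unname(self$translation_px), c(0, 0))
  expect_lt(abs(self$rotation), 0.5)
  expect_gt(self$score, 0.999)

  ## +230 nm x, -140 nm y shift: recovered within one 10-nm pixel,
  ## matching the exhaustive integer-shift NCC oracle
  mov <- shift_image(fixed, 23, -14)
  tr <- register_rigid(mov, fixed, rot_range = 0)
  orc <- ncc_shift_oracle(fixed, mov, max_shift = 30)
  expect_equal(unname(tr$translation_px), unname(orc[c("dx", "dy")]))
  expect_equal(unname(tr$translation_nm), c(-230, 140))

  ## 3-degree rotation recovered within the grid refinement step
  mov3 <- domainscope:::rotate_image(fixed, 3)
  tr3 <- register_rigid(mov3, fixed, rot_range = 5, rot_step = 0.5)
  expect_lt(abs(tr3$rotation - (-3)), 0.5)
  expect_gt(tr3$score, 0.9)

  flat <- matrix(1, nrow(fixed), ncol(fixed))
  expect_error(register_rigid(flat, fixed), "contrast")
})

test_that("NCC score is invariant to affine intensity rescaling", {
  set.seed(23)
  a <- matrix(runif(2500), 50)
  b <- matrix(runif(2500), 50)
  s1 <- register_rigid(a, b, rot_range = 0)$score
  s2 <- register_rigid(3 * a + 7, b, rot_range = 0)$score
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("the best substack window is found by construction", {
  ## structures live only in slices 6-10; window 5 must pick z-start 6
  set.seed(24)
  pts <- cbind(runif(12, 300, 3300), runif(12, 300, 3300))
  storm <- matrix(0, 120, 120)
  for (r in seq_len(nrow(pts))) {
    i <- ceiling(pts[r, 2] / 30); j <- ceiling(pts[r, 1] / 30)
    storm[max(1, i - 1):min(120, i + 1), max(1, j - 1):min(120, j + 1)] <- 5
  }
  slices <- lapply(1:14, function(z) {
    if (z >= 6 && z <= 10) {
      m <- matrix(0, 120, 120)
      for (r in seq_len(nrow(pts))) {
        i <- ceiling(pts[r, 2] / 30); j <- ceiling(pts[r, 1] / 30)
        m[max(1, i - 1):min(120, i + 1), max(1, j - 1):min(120, j + 1)] <- 1
      }
      m
    } else matrix(rnorm(14400, 0, 0.01), 120, 120)
  })
  pr <- moving_projections(slices, 5)
  ov <- select_best_substack(pr, storm, rot_range = 0)
  expect_identical(unname(ov$window["z_start"]), 6L)
  expect_identical(ov$best_index, 6L)

  ## single projection trivially wins; duplicated stack ties to lower z
  ov1 <- select_best_substack(pr[10], storm, rot_range = 0)
  expect_identical(ov1$best_index, 1L)
  dup <- moving_projections(slices[c(6:10, 6:10)], 5)
  expect_message(ov2 <- select_best_substack(dup, storm, rot_range = 0),
                 "tie")
  expect_identical(unname(ov2$window["z_start"]), 1L)
})

test_that("substack choice is permutation-equivariant", {
  sc <- make_test_scene(25, n_rds = 10)
  ev <- make_test_events(sc, 26, n_frames = 1000, events = 60)
  storm <- unclass(render_events(ev, 30, roi = c(0, 3000, 0, 3000))) * 1.0
  set.seed(27)
  projections <- c(list(storm + matrix(rnorm(length(storm), 0, 0.05),
                                       nrow(storm))),
                   lapply(1:3, function(i)
                     matrix(runif(length(storm)), nrow(storm))))
  perm <- c(3, 1, 4, 2)
  ov_a <- select_best_substack(projections, storm, rot_range = 0)
  ov_b <- select_best_substack(projections[perm], storm, rot_range = 0)
  expect_equal(perm[ov_b$best_index], ov_a$best_index)
})

test_that("ROI crops mask pixels and events consistently", {
  sc <- make_test_scene(28, n_rds = 8)
  ev <- make_test_events(sc, 29, n_frames = 500, events = 30)
  img <- render_events(ev, 10, roi = c(0, 3000, 0, 3000))
  full <- list(data.frame(x = c(0, 300, 300, 0), y = c(0, 0, 300, 300)))
  out <- crop_to_rois(img, full, events = ev)
  expect_equal(unclass(out[[1]]$image), unclass(img), ignore_attr = TRUE)
  expect_identical(nrow(out[[1]]$events), nrow(ev))

  ## left and right halves partition the frame
  rois <- list(data.frame(x = c(0, 150, 150, 0), y = c(0, 0, 300, 300)),
               data.frame(x = c(150, 300, 300, 150),
                          y = c(0, 0, 300, 300)))
  parts <- crop_to_rois(img, rois, events = ev)
  ## disjoint ROIs give disjoint supports and bounded pixel counts
  expect_identical(sum(parts[[1]]$image > 0 & parts[[2]]$image > 0), 0L)
  for (k in 1:2)
    expect_lte(sum(parts[[k]]$image > 0), 150L * 300L)
  expect_identical(nrow(parts[[1]]$events) + nrow(parts[[2]]$events),
                   nrow(ev))
  expect_warning(crop_to_rois(img, list(data.frame(x = 1, y = 1))),
                 "vertices")
})
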