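test_that("zero-noise events sit exactly on their stretches", {
  sc <- make_test_scene(1, n_rds = 5, field = c(1500, 1500))
  img <- imaging_config(loc_precision_sigma = 0, n_frames = 100,
                        events_per_stretch_mean = 10)
  ev <- simulate_event_list(sc, img, seed = 2)
  expect_equal(ev$x_nm, sc$stretches$x_nm[ev$stretch_id])
  expect_equal(ev$y_nm, sc$stretches$y_nm[ev$stretch_id])
})

test_that("a linear drift ramp moves late events by its expectation", {
  sc <- make_test_scene(2, n_rds = 10)
  img <- imaging_config(loc_precision_sigma = 0, n_frames = 100,
                        events_per_stretch_mean = 400,
                        drift_model = drift_linear(100, 0, 100))
  ev <- simulate_event_list(sc, img, seed = 3)
  true_x <- sc$stretches$x_nm[ev$stretch_id]
  off <- ev$x_nm - true_x
  lo <- mean(off[ev$frame < 10])     # first decile of frames
  hi <- mean(off[ev$frame >= 90])    # last decile
  ## deciles are centered on frames 4.5 and 94.5 of a 0..99 ramp to 100 nm:
  ## expected gap 100 * 90 / 99 = 90.9 nm
  expect_equal(hi - lo, 100 * 90 / 99, tolerance = 0.03)
})

test_that("event totals follow the Poisson bookkeeping", {
  sc <- make_test_scene(3, n_rds = 4, field = c(1200, 1200),
                        solitary_fraction = 0)
  n_st <- nrow(sc$stretches)
  img <- imaging_config(events_per_stretch_mean = 50, n_frames = 500)
  ev <- simulate_event_list(sc, img, seed = 4)
  total <- n_st * 50
  expect_lt(abs(nrow(ev) - total), 4 * sqrt(total))
  ## exact per-stretch conservation of the ground-truth linkage
  expect_identical(sort(unique(ev$stretch_id)),
                   seq_len(n_st)[tabulate(ev$stretch_id, n_st) > 0])
  expect_identical(sum(tabulate(ev$stretch_id, n_st)), nrow(ev))
})

test_that("identical seed and config give bit-identical event lists", {
  sc <- make_test_scene(4, n_rds = 5, field = c(1500, 1500))
  img <- imaging_config(n_frames = 200)
  expect_identical(simulate_event_list(sc, img, seed = 9),
                   simulate_event_list(sc, img, seed = 9))
})

test_that("photon laws have the configured mean", {
  for (law in list(list(dist = "constant", mean = 800),
                   list(dist = "exp", mean = 800),
                   list(dist = "gamma", mean = 800, shape = 2),
                   list(dist = "lognormal", mean = 800, sdlog = 0.4))) {
    set.seed(5)
    x <- domainscope:::draw_photons(2e4, law)
    expect_lt(abs(mean(x) / 800 - 1), 0.05)
    expect_true(all(x > 0))
  }
})

test_that("confocal rendering is diffraction-limited and linear", {
  img <- imaging_config()
  ## single stretch: argmax within one voxel of the true position
  cfg1 <- scene_config(n_rds = 1, stretch_p = 1, min_stretches = 1,
                       solitary_fraction = 0, field_size = c(1800, 1800))
  sc1 <- sample_scene(cfg1, seed = 1)
  st <- simulate_confocal_stack(sc1, img, z_extent = 2400)
  am <- which(st$data == max(st$data), arr.ind = TRUE)[1, ]
  pos <- (am - 0.5) * st$voxel
  expect_lt(abs(pos[1] - sc1$stretches$x_nm[1]), st$voxel[1])
  expect_lt(abs(pos[2] - sc1$stretches$y_nm[1]), st$voxel[2])
  expect_lt(abs(pos[3] - 1200), st$voxel[3])

  ## two stretches 63 nm apart render as one blob without an internal dip
  sc2 <- sc1
  sc2$stretches <- data.frame(rd_id = c(1L, 1L), x_nm = c(900 - 31.5, 900 + 31.5),
                              y_nm = c(900, 900), channel = c(1L, 1L))
  st2 <- simulate_confocal_stack(sc2, img, z_extent = 2400)
  zmax <- which.max(apply(st2$data, 3, max))
  prof <- st2$data[, 10, zmax]
  i <- which(prof > 0.05 * max(prof))
  run <- prof[min(i):max(i)]
  ## profile rises then falls: a single mode, no local minimum between peaks
  expect_identical(sum(diff(sign(diff(run))) == 2), 0L)

  ## total intensity is proportional to the stretch count
  expect_equal(sum(st2$data) / sum(st$data), 2, tolerance = 1e-6)
})

test_that("confocal simulation rejects fields smaller than 3 PSFs", {
  cfg <- scene_config(n_rds = 1, field_size = c(400, 400))
  sc <- sample_scene(cfg, seed = 1)
  expect_error(simulate_confocal_stack(sc, imaging_config(), z_extent = 500),
               "PSF")
})

test_that("fully coupled noiseless pairs move identically", {
  mm <- motion_model(loc_noise_sigma = 0, confinement_radius = NULL)
  tr <- simulate_trajectory_pairs(3, 0, mm, n_frames = 30, seed = 1)
  for (pid in 1:3) {
    t1 <- as.matrix(tr[tr$pair_id == pid & tr$channel == 1L,
                       c("x_nm", "y_nm")])
    t2 <- as.matrix(tr[tr$pair_id == pid & tr$channel == 2L,
                       c("x_nm", "y_nm")])
    expect_equal(diff(t1), diff(t2), ignore_attr = TRUE)
    ca <- correlation_angles(t1, t2)
    ## zero up to acos() roundoff at cos = 1
    expect_lt(ca$mean_alpha, 1e-4)
  }
})

test_that("uncoupled pairs average 90 degrees", {
  mm <- motion_model(loc_noise_sigma = 0, confinement_radius = NULL)
  tr <- simulate_trajectory_pairs(300, 2000, mm, n_frames = 40, seed = 2)
  prof <- coupling_profile(tr)
  se <- sd(prof$points$mean_alpha) / sqrt(nrow(prof$points))
  expect_lt(abs(mean(prof$points$mean_alpha) - 90), 3 * se)
})

test_that("half coupling lands strictly between 0 and 90 degrees", {
  set.seed(3)
  oracle <- mc_mean_alpha(0.5, n = 2e5)
  expect_gt(oracle, 0); expect_lt(oracle, 90)
  mm <- motion_model(loc_noise_sigma = 0, confinement_radius = NULL)
  tr <- simulate_trajectory_pairs(400, 100, mm, n_frames = 40,
                                  coupling = 0.5, seed = 4)
  prof <- coupling_profile(tr)
  m <- mean(prof$points$mean_alpha)
  expect_gt(m, 10); expect_lt(m, 85)
  expect_equal(m, oracle, tolerance = 0.03)
})

test_that("mean angle rises monotonically with pair distance", {
  mm <- motion_model()
  d <- rep(seq(50, 1050, by = 200), each = 150)
  tr <- simulate_trajectory_pairs(length(d), d, mm, n_frames = 40, seed = 5)
  prof <- coupling_profile(tr, bin_width = 200)
  big <- prof$bins[prof$bins$n >= 50, ]
  ## non-decreasing up to binomial noise in the flat uncoupled regime
  expect_true(all(diff(big$mean_alpha) > -2))
  expect_gt(big$mean_alpha[nrow(big)] - big$mean_alpha[1], 10)
})

test_that("combed fibers divide exactly at zero noise", {
  f <- simulate_combed_fibers(c(4.36, 23.13), rate_kb_per_um = 1.77)
  expect_equal(f$measured_um, c(4.36, 23.13) / 1.77)
  expect_equal(f$measured_um[1], 2.463, tolerance = 1e-3)
  expect_equal(f$measured_um[2], 13.068, tolerance = 1e-4)
  ## CLT: per-class means within 1% at cv = 0.1, n = 1000
  g <- simulate_combed_fibers(c(4.36, 9.41, 23.13), 1.77,
                              length_noise_cv = 0.1, n_per_class = 1000,
                              seed = 6)
  for (k in c(4.36, 9.41, 23.13)) {
    m <- mean(g$measured_um[g$known_kbp == k])
    expect_lt(abs(m / (k / 1.77) - 1), 0.01)
  }
})
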