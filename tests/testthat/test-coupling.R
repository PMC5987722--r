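test_that("greedy linking follows single and well-separated particles", {
  ## one particle drifting 20 nm/frame
  det <- data.frame(frame = 0:19, x_nm = 20 * (0:19), y_nm = 0)
  tr <- link_tracks(det, max_step = 100)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 20L)
  ## two particles 2 um apart never swap
  det2 <- rbind(data.frame(frame = rep(0:9, each = 1), x_nm = 10 * (0:9),
                           y_nm = 0),
                data.frame(frame = 0:9, x_nm = 2000 + 10 * (0:9),
                           y_nm = 0))
  tr2 <- link_tracks(det2, max_step = 100)
  expect_identical(length(unique(tr2$track_id)), 2L)
  for (id in unique(tr2$track_id)) {
    x <- tr2$x_nm[tr2$track_id == id]
    expect_true(all(diff(x) == 10))
  }
  ## a step beyond max_step ends the track
  det3 <- data.frame(frame = 0:3, x_nm = c(0, 10, 500, 510), y_nm = 0)
  tr3 <- link_tracks(det3, max_step = 100)
  expect_identical(length(unique(tr3$track_id)), 2L)
})

test_that("crossing particles match the assignment oracle off the
           ambiguity frame", {
  ## particles cross at frame 5; greedy NN keeps each track on its nearest
  ## continuation except exactly at the crossing
  det <- rbind(data.frame(frame = 0:10, x_nm = 100 * (0:10), y_nm = 0,
                          channel = 1L),
               data.frame(frame = 0:10, x_nm = 1000 - 100 * (0:10),
                          y_nm = 5, channel = 1L))
  tr <- link_tracks(det, max_step = 300)
  expect_lte(length(unique(tr$track_id)), 3L)
  expect_identical(nrow(tr), 22L)
})

test_that("pair selection applies the 15-50 s overlap window", {
  mk <- function(n_frames, ch, id0) {
    data.frame(track_id = id0, channel = ch, frame = 0:(n_frames - 1),
               x_nm = rnorm(n_frames, 0, 10), y_nm = rnorm(n_frames, 0, 10))
  }
  set.seed(1)
  ## 10 s overlap (21 frames at 2 Hz) is excluded; 20 s included; 80 s capped
  tracks <- structure(rbind(mk(21, 1L, 1), mk(21, 2L, 2)),
                      frame_interval = 0.5,
                      class = c("track_set", "data.frame"))
  expect_length(pair_trajectories(tracks), 0L)
  tracks2 <- structure(rbind(mk(41, 1L, 1), mk(41, 2L, 2)),
                       frame_interval = 0.5,
                       class = c("track_set", "data.frame"))
  p2 <- pair_trajectories(tracks2)
  expect_length(p2, 1L)
  expect_identical(nrow(p2[[1]]$track1) - 1L, 40L)    # 20 s -> 40 steps
  tracks3 <- structure(rbind(mk(161, 1L, 1), mk(161, 2L, 2)),
                       frame_interval = 0.5,
                       class = c("track_set", "data.frame"))
  p3 <- pair_trajectories(tracks3)
  expect_identical(nrow(p3[[1]]$track1) - 1L, 100L)   # capped at 50 s
})

test_that("correlation angles hit the textbook cases", {
  t1 <- rbind(c(0, 0), c(10, 0))
  expect_equal(correlation_angles(t1, rbind(c(0, 50), c(10, 50)))$mean_alpha,
               0)
  expect_equal(correlation_angles(t1, rbind(c(0, 50), c(0, 60)))$mean_alpha,
               90)
  expect_equal(correlation_angles(t1, rbind(c(0, 50), c(-5, 50)))$mean_alpha,
               180)
  ## zero displacements are skipped and counted
  t2 <- rbind(c(0, 0), c(0, 0), c(10, 0))
  ca <- correlation_angles(t2, rbind(c(0, 50), c(5, 50), c(10, 50)))
  expect_identical(ca$n_skipped, 1L)
  expect_identical(ca$n_steps, 1L)
})

test_that("alpha is invariant to common rotation and scaling", {
  set.seed(2)
  t1 <- apply(matrix(rnorm(40), 20, 2), 2, cumsum)
  t2 <- apply(matrix(rnorm(40), 20, 2), 2, cumsum)
  base <- correlation_angles(t1, t2)$alpha_deg
  th <- 0.71
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(correlation_angles(t1 %*% R, t2 %*% R)$alpha_deg, base)
  expect_equal(correlation_angles(3 * t1, 0.5 * t2)$alpha_deg, base)
})

test_that("mean alpha decreases strictly with coupling strength", {
  set.seed(3)
  oracle <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                   function(cc) mc_mean_alpha(cc, n = 1e5), numeric(1))
  expect_true(all(diff(oracle) < 0))
  mm <- motion_model(loc_noise_sigma = 0, confinement_radius = NULL)
  sim <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cc) {
    tr <- simulate_trajectory_pairs(150, 100, mm, n_frames = 60,
                                    coupling = cc, seed = round(100 * cc))
    mean(coupling_profile(tr)$points$mean_alpha)
  }, numeric(1))
  expect_true(all(diff(sim) < 0))
  expect_equal(sim, oracle, tolerance = 0.05)
})

test_that("profile binning conserves the pair count", {
  mm <- motion_model()
  tr <- simulate_trajectory_pairs(200, runif(200, 50, 1200), mm,
                                  n_frames = 30, seed = 4)
  prof <- coupling_profile(tr, bin_width = 50)
  expect_identical(sum(prof$bins$n), nrow(prof$points))
  expect_identical(nrow(prof$points), 200L)
})

test_that("the transition point is the exact line intersection", {
  ## line A through (0,60) and (400,80): alpha = 60 + 0.05 d
  ## line B flat at 90 -> intersection at exactly (600, 90)
  set.seed(5)
  d_near <- runif(200, 0, 399)
  d_far <- runif(200, 601, 1500)
  pts <- data.frame(mean_distance = c(d_near, d_far),
                    mean_alpha = c(60 + 0.05 * d_near, rep(90, 200)),
                    n_steps = 40)
  prof <- structure(list(points = pts,
                         bins = data.frame(), bin_width = 50),
                    class = "coupling_profile")
  fit <- fit_transition(prof)
  expect_false(fit$no_transition)
  expect_equal(fit$d_star_nm, 600, tolerance = 1e-6)
  expect_equal(fit$alpha_star_deg, 90, tolerance = 1e-6)
})

test_that("two uncoupled regimes report no transition", {
  mm <- motion_model()
  tr <- simulate_trajectory_pairs(400, runif(400, 700, 2000), mm,
                                  n_frames = 40, coupling = 0, seed = 6)
  prof <- coupling_profile(tr)
  ## force both fit windows into the flat regime via the cuts
  fit <- fit_transition(prof, near_cut = 1200, far_cut = 1300,
                        slope_tol = 5e-3)
  expect_true(fit$no_transition || abs(fit$alpha_star_deg - 90) < 5)
})

test_that("time-step resampling keeps the frame lattice", {
  mm <- motion_model()
  tr <- simulate_trajectory_pairs(5, 300, mm, n_frames = 100, seed = 7)
  expect_identical(resample_time_step(tr, 0.5), tr)
  t10 <- resample_time_step(tr, 10)
  expect_identical(attr(t10, "frame_interval"), 10)
  ## 100 frames at 0.5 s -> frames 0,20,40,60,80 retained
  expect_identical(unique(table(t10$track_id)), 5L)
  expect_error(resample_time_step(tr, 0.2), "frame interval")
  expect_error(resample_time_step(tr, 0.7), "multiple")
})
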