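peaks_df <- function(x, y, pixel = 10) {
  structure(data.frame(x_nm = x, y_nm = y, intensity = 1),
            pixel = pixel, class = c("peak_set", "data.frame"))
}

test_that("Perona-Malik with zero iterations is the identity", {
  set.seed(1)
  m <- matrix(runif(400), 20)
  expect_identical(perona_malik(m, 0), m)
  ## diffusion shrinks the intensity range but conserves smoothness order
  sm <- perona_malik(m, 10, kappa = 10)
  expect_lt(diff(range(sm)), diff(range(m)))
})

test_that("3x3 median matches its brute-force oracle", {
  set.seed(2)
  m <- matrix(rpois(15 * 12, 2), 15, 12)
  expect_equal(domainscope:::median3x3(m), median3x3_oracle(m))
  ## a binary cross through the median equals the plain 3x3 median
  cr <- matrix(0, 9, 9); cr[5, ] <- 1; cr[, 5] <- 1
  pre <- preprocess_storm_image(cr, pm_iterations = 0,
                                intensity_threshold = 0, min_connected = 0)
  expect_equal(unclass(pre), median3x3_oracle(cr))
})

test_that("connectivity pruning keeps 2x2 blocks and drops single pixels", {
  m <- matrix(FALSE, 12, 12)
  m[2, 2] <- TRUE                   # isolated pixel: 0 neighbors
  m[5:6, 5:6] <- TRUE               # 2x2 block: each touches 3 others
  m[9, 9:10] <- TRUE                # 1x2 pair: 1 neighbor each
  nc <- domainscope:::neighbor_count_8(m)
  keep <- m & nc >= 3
  expect_false(keep[2, 2])
  expect_true(all(keep[5:6, 5:6]))
  expect_false(any(keep[9, 9:10]))
  ## the full chain drops a lone bright pixel in a realistic image
  img <- matrix(0, 20, 20)
  img[4:8, 4:8] <- 6               # solid blob survives end to end
  img[15, 15] <- 9
  out <- preprocess_storm_image(img, pm_iterations = 0,
                                intensity_threshold = 0.5)
  expect_identical(unname(out[15, 15]), 0)
  expect_gt(sum(out[4:8, 4:8] > 0), 0)
})

test_that("empty-after-threshold images warn and return all zeros", {
  m <- matrix(1, 5, 5)
  expect_warning(out <- preprocess_storm_image(m, pm_iterations = 0,
                                               intensity_threshold = 99),
                 "threshold")
  expect_true(all(out == 0))
})

test_that("grayscale dilation matches the per-pixel disc oracle", {
  set.seed(3)
  m <- matrix(rpois(20 * 16, 1), 20, 16)
  for (r in c(1, 2, 4))
    expect_equal(domainscope:::dilate_disc(m, r), dilate_oracle(m, r))
})

test_that("peak detection resolves blobs by the dilation window", {
  blob <- function(m, cx, cy, h) {
    for (di in -2:2) for (dj in -2:2)
      m[cy + di, cx + dj] <- m[cy + di, cx + dj] +
        h * exp(-(di^2 + dj^2) / 2)
    m
  }
  base <- matrix(0, 40, 40)
  ## one blob -> one peak at its maximum pixel
  m1 <- blob(base, 20, 20, 8)
  p1 <- detect_peaks(structure(m1, pixel = 10, origin = c(0, 0)), 4)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$x_nm, 195)  # pixel center of column 20
  ## 120 nm apart (12 px) with radius 4 -> two peaks
  m2 <- blob(blob(base, 14, 20, 8), 26, 20, 6)
  p2 <- detect_peaks(structure(m2, pixel = 10, origin = c(0, 0)), 4)
  expect_identical(nrow(p2), 2L)
  ## 30 nm apart (3 px) -> the lesser maximum is inside the window: one peak
  m3 <- blob(blob(base, 19, 20, 8), 22, 20, 6)
  p3 <- detect_peaks(structure(m3, pixel = 10, origin = c(0, 0)), 4)
  expect_identical(nrow(p3), 1L)
})

test_that("plateau maxima merge to their centroid", {
  m <- matrix(0, 20, 20)
  m[10, 10:11] <- 3                 # two equal adjacent maxima
  p <- detect_peaks(structure(m, pixel = 10, origin = c(0, 0)), 4)
  expect_identical(nrow(p), 1L)
  expect_equal(p$x_nm, 100)         # centroid of pixel centers 95 and 105
})

test_that("DBSCAN clusters density-connected peaks and flags solitaries", {
  ## 3 peaks pairwise within reach -> one cluster of 3
  p <- peaks_df(c(0, 100, 50), c(0, 0, 80))
  cl <- cluster_peaks(p, eps = 14, min_pts = 2, pixel = 10)
  expect_identical(unique(cl$cluster), 1L)
  ## isolated peak -> label -1
  p2 <- peaks_df(c(0, 1000), c(0, 0))
  cl2 <- cluster_peaks(p2, eps = 14, min_pts = 2, pixel = 10)
  expect_identical(cl2$cluster, c(-1L, -1L))
  ## eps interpreted in rendered pixels: 14 px * 10 nm = 140 nm reach
  p3 <- peaks_df(c(0, 139), c(0, 0))
  expect_identical(unique(cluster_peaks(p3)$cluster), 1L)
  p4 <- peaks_df(c(0, 141), c(0, 0))
  expect_identical(cluster_peaks(p4)$cluster, c(-1L, -1L))
})

test_that("DBSCAN matches the brute-force density-reachability oracle on
           200 random instances", {
  set.seed(4)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    p <- cbind(runif(n, 0, 600), runif(n, 0, 600))
    eps_nm <- runif(1, 60, 200)
    min_pts <- sample(2:4, 1)
    cl <- cluster_peaks(peaks_df(p[, 1], p[, 2]), min_pts = min_pts,
                        eps_nm = eps_nm)
    expect_dbscan_matches_oracle(cl$cluster, p, eps_nm, min_pts)
  }
})

test_that("cluster metrics compute NND, Feret and solitary fraction", {
  ## collinear peaks at 60-nm steps
  p <- peaks_df(c(0, 60, 120), c(0, 0, 0))
  cl <- cluster_peaks(p)
  met <- cluster_metrics(cl)
  expect_equal(met$nnd_nm, c(60, 60, 60))
  expect_equal(met$per_cluster$feret_x_nm, 120)
  expect_true(met$per_cluster$degenerate_hull)
  ## square of side 100 nm
  sq <- peaks_df(c(0, 100, 100, 0), c(0, 0, 100, 100))
  msq <- cluster_metrics(cluster_peaks(sq))
  expect_equal(msq$per_cluster$feret_x_nm, 100)
  expect_equal(msq$nnd_nm, rep(100, 4))
  expect_equal(msq$per_cluster$feret_max_nm, sqrt(2) * 100)
  ## 12 peaks: 10 clustered, 2 solitary -> 16.7% solitary
  p12 <- peaks_df(c(seq(0, 90, 10), 2000, 5000),
                  c(rep(0, 10), 0, 0))
  m12 <- cluster_metrics(cluster_peaks(p12))
  expect_equal(m12$summary$solitary_fraction, 2 / 12, tolerance = 1e-12)
  expect_identical(m12$summary$n_solitary, 2L)
})

test_that("Feret diameter never shrinks when a member is added", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    p <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    f1 <- diff(range(p[-n, 1]))
    f2 <- diff(range(p[, 1]))
    expect_gte(f2, f1)
  }
})

test_that("metrics are invariant to translation and swap under rotation", {
  set.seed(6)
  p <- cbind(runif(8, 0, 200), runif(8, 0, 200))
  base <- cluster_metrics(cluster_peaks(peaks_df(p[, 1], p[, 2]),
                                        eps_nm = 500))
  shifted <- cluster_metrics(cluster_peaks(
    peaks_df(p[, 1] + 1234, p[, 2] - 567), eps_nm = 500))
  expect_equal(shifted$nnd_nm, base$nnd_nm)
  expect_equal(shifted$per_cluster$feret_x_nm, base$per_cluster$feret_x_nm)
  expect_equal(shifted$summary, base$summary)
  ## rotating 90 degrees swaps the horizontal Feret with the vertical extent
  rot <- cluster_metrics(cluster_peaks(peaks_df(-p[, 2], p[, 1]),
                                       eps_nm = 500))
  expect_equal(rot$per_cluster$feret_x_nm, diff(range(p[, 2])))
  expect_equal(rot$nnd_nm, base$nnd_nm)
})

test_that("pipeline recovery on default scenes matches ground truth", {
  ## median stretches/domain exact, intra-NND within 10%, solitary within
  ## 5 percentage points -- pooled over 20 seeds of the default preset
  rec_counts <- c(); tru_counts <- c()
  rec_nnd <- c(); tru_nnd <- c()
  rec_sol <- c(); tru_sol <- c()
  for (s in 1:20) {
    sc <- make_test_scene(s)
    ev <- filter_by_photons(make_test_events(sc, s + 1000), 500)
    pre <- preprocess_storm_image(render_events(ev, 10))
    met <- cluster_metrics(cluster_peaks(detect_peaks(pre)))
    tru <- scene_truth(sc)
    rec_counts <- c(rec_counts, met$per_cluster$n)
    tru_counts <- c(tru_counts, tru$stretch_counts)
    rec_nnd <- c(rec_nnd, met$nnd_nm)
    tru_nnd <- c(tru_nnd, tru$intra_nnd)
    rec_sol <- c(rec_sol, met$summary$solitary_fraction)
    tru_sol <- c(tru_sol, tru$solitary_fraction)
  }
  expect_equal(median(rec_counts), median(tru_counts))
  expect_lt(abs(median(rec_nnd) / median(tru_nnd) - 1), 0.10)
  expect_lt(abs(mean(rec_sol) - mean(tru_sol)), 0.05)
})
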