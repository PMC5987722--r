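## Independent brute-force oracles and small fixtures used across tests.

## Monte-Carlo oracle for the mean correlation angle of the coupled-step
## mixture: u = sqrt(c) S + sqrt(1-c) I1, v = sqrt(c) S + sqrt(1-c) I2,
## all components N(0, sigma^2) per axis (direct draws, no track machinery).
mc_mean_alpha <- function(coupling, n = 1e5, sigma = 1) {
  S <- matrix(rnorm(2 * n, 0, sigma), n, 2)
  u <- sqrt(coupling) * S + sqrt(1 - coupling) * matrix(rnorm(2 * n, 0, sigma), n, 2)
  v <- sqrt(coupling) * S + sqrt(1 - coupling) * matrix(rnorm(2 * n, 0, sigma), n, 2)
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  mean(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
}

## Brute-force DBSCAN oracle: all-pairs distances, core points by
## neighborhood count (self included), clusters = connected components of
## the core-core adjacency; border points may join any adjacent core's
## cluster. Returns list(core, components, labels_possible) where
## labels_possible[[i]] is the set of admissible cluster ids (component
## index of an adjacent core), or -1 for noise.
dbscan_oracle <- function(p, eps_nm, min_pts) {
  n <- nrow(p)
  d <- as.matrix(stats::dist(p))
  nb <- d <= eps_nm
  core <- rowSums(nb) >= min_pts
  comp <- rep(NA_integer_, n)
  if (any(core)) {
    idx <- which(core)
    adj <- nb[idx, idx, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp[idx] <- igraph::components(g)$membership
  }
  labels_possible <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    adj_cores <- which(core & nb[i, ])
    if (length(adj_cores)) unique(comp[adj_cores]) else -1L
  })
  list(core = core, comp = comp, labels_possible = labels_possible)
}

## Check a cluster_peaks() labeling against the oracle (labels equal up to
## renaming; border points must lie in an admissible cluster).
expect_dbscan_matches_oracle <- function(labels, p, eps_nm, min_pts) {
  orc <- dbscan_oracle(p, eps_nm, min_pts)
  ## core partition must match up to renaming
  core_idx <- which(orc$core)
  if (length(core_idx)) {
    got <- labels[core_idx]
    want <- orc$comp[core_idx]
    expect_true(all(got > 0))
    ## same partition: equality pattern of labels identical
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
  for (i in which(!orc$core)) {
    adm <- orc$labels_possible[[i]]
    if (identical(adm, -1L)) {
      expect_identical(labels[i], -1L)
    } else {
      ## admissible components, translated through a core representative
      reps <- vapply(adm, function(cmp) labels[which(orc$comp == cmp &
                                                       orc$core)[1]],
                     integer(1))
      expect_true(labels[i] %in% reps)
    }
  }
  invisible(NULL)
}

## Brute-force grayscale dilation with a disc footprint (per-pixel loop).
dilate_oracle <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  r <- ceiling(radius)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- max(vals)
  }
  out
}

## Brute-force 3x3 median (zero padding), per-pixel loop.
median3x3_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- stats::median(as.vector(p[i:(i + 2), j:(j + 2)]))
  out
}

## Exhaustive integer-shift NCC oracle over a small search window.
ncc_shift_oracle <- function(fixed, moving, max_shift = 30) {
  best <- c(score = -Inf, dx = NA, dy = NA)
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    nr <- nrow(fixed); nc <- ncol(fixed)
    rs <- max(1, 1 + dy):min(nr, nr + dy)
    cs <- max(1, 1 + dx):min(nc, nc + dx)
    if (length(rs) < 2 || length(cs) < 2) next
    a <- fixed[rs, cs]; b <- moving[rs - dy, cs - dx]
    if (sd(a) == 0 || sd(b) == 0) next
    sc <- stats::cor(as.vector(a), as.vector(b))
    if (sc > best["score"]) best <- c(score = sc, dx = dx, dy = dy)
  }
  best
}

## Integer-pixel shift of an image with zero fill.
shift_image <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  cs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

## Small default-preset scene + event list used by several suites.
make_test_scene <- function(seed, n_rds = 20, field = c(3000, 3000), ...) {
  sample_scene(scene_config(n_rds = n_rds, field_size = field, ...),
               seed = seed)
}

make_test_events <- function(scene, seed, sigma = 8, n_frames = 5000,
                             events = 50, drift = drift_none()) {
  simulate_event_list(scene,
                      imaging_config(loc_precision_sigma = sigma,
                                     n_frames = n_frames,
                                     events_per_stretch_mean = events,
                                     drift_model = drift),
                      seed = seed)
}
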