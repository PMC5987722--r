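#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing: per iteration the image is updated by
#' `lambda * sum_d g(grad_d) * grad_d` over the four axial neighbors, with
#' conduction `g(x) = exp(-(x/kappa)^2)` (option `"exponential"`) or
#' `g(x) = 1 / (1 + (x/kappa)^2)` (`"quadratic"`). Zero iterations return
#' the input unchanged.
#'
#' @param img numeric matrix.
#' @param iterations number of diffusion steps.
#' @param kappa conduction scale in intensity units; default 10% of the
#'   intensity range.
#' @param lambda integration step, must be in (0, 0.25] for stability.
#' @param option conduction function.
#' @return smoothed matrix (attributes of `img` preserved).
#' @export
perona_malik <- function(img, iterations = 10, kappa = NULL, lambda = 0.25,
                         option = c("exponential", "quadratic")) {
  option <- match.arg(option)
  stop_if_not(is_number(lambda) && lambda > 0 && lambda <= 0.25,
              "lambda must be in (0, 0.25]")
  stop_if_not(is_number(iterations) && iterations >= 0, "iterations >= 0")
  a <- attributes(img)
  m <- unclass(img) * 1.0
  if (iterations == 0) return(img)
  rng <- diff(range(m))
  if (is.null(kappa)) kappa <- if (rng > 0) 0.1 * rng else 1
  g <- if (option == "exponential") function(x) exp(-(x / kappa)^2)
       else function(x) 1 / (1 + (x / kappa)^2)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(iterations)) {
    ## replicate-padded axial gradients
    dn <- rbind(m[1, , drop = FALSE], m[-nr, ]) - m
    ds <- rbind(m[-1, ], m[nr, , drop = FALSE]) - m
    dw <- cbind(m[, 1, drop = FALSE], m[, -nc]) - m
    de <- cbind(m[, -1], m[, nc, drop = FALSE]) - m
    m <- m + lambda * (g(dn) * dn + g(ds) * ds + g(dw) * dw + g(de) * de)
  }
  attributes(m) <- a
  m
}

## 3x3 median filter, zero-padded borders.
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  stack <- vapply(expand_shifts(), function(s)
    as.vector(p[s[1] + seq_len(nr), s[2] + seq_len(nc)]),
    numeric(nr * nc))
  matrix(apply(stack, 1L, stats::median), nr, nc)
}

expand_shifts <- function() {
  s <- expand.grid(0:2, 0:2)
  lapply(seq_len(nrow(s)), function(i) as.integer(s[i, ]))
}

## Otsu threshold (256-bin histogram); returns the threshold value (keep
## pixels strictly above it). Rendered localization images are overwhelmingly
## zero, which would push a whole-image Otsu split into the far tail, so the
## histogram is taken over the positive support only.
otsu_threshold <- function(m) {
  v <- as.vector(m)
  v <- v[v > 0]
  if (length(v) == 0L) return(0)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  h <- as.numeric(tabulate(findInterval(v, breaks, all.inside = TRUE), 256L))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(256L))
  tot <- w[256L]; mt <- mu[256L]
  wb <- w[-256L]; wf <- tot - wb
  ok <- wb > 0 & wf > 0
  sb2 <- rep(-Inf, 255L)
  sb2[ok] <- (mt * wb[ok] - mu[-256L][ok] * tot)^2 / (wb[ok] * wf[ok])
  k <- which.max(sb2)
  breaks[k + 1L]
}

## Label 8-connected (2D) components of a logical mask; returns an integer
## matrix, 0 = background.
label_components_8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- match(idx, idx)
  lookup <- integer(length(mask)); lookup[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  edges <- integer(0)
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[nb] > 0L
    edges <- c(edges, rbind(which(ok)[hit], lookup[nb[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Preprocess a STORM image for stretch detection
#'
#' Perona-Malik anisotropic diffusion, a 3x3 median filter, global intensity
#' thresholding, then a single connectivity-pruning pass that discards every
#' nonzero pixel with fewer than `min_connected` nonzero pixels among its
#' eight neighbors (a 2x2 block, where each pixel touches three others, is
#' the smallest surviving structure).
#'
#' @param image a [render_events()] image (or plain matrix).
#' @param pm_iterations,pm_kappa,pm_lambda Perona-Malik parameters.
#' @param intensity_threshold a numeric threshold in image intensity units
#'   (pixels at or below it are zeroed), or `"otsu"`. The default 0.5 —
#'   half a localization count — removes the sub-count debris that
#'   diffusion and median filtering smear around blobs while keeping every
#'   pixel that genuinely held an event; Otsu is the better choice for
#'   images with a non-trivial background level.
#' @param min_connected minimum number of nonzero 8-neighbors a pixel needs
#'   to survive.
#' @return the filtered image (same class and attributes).
#' @export
preprocess_storm_image <- function(image, pm_iterations = 2,
                                   pm_kappa = NULL, pm_lambda = 0.25,
                                   intensity_threshold = 0.5,
                                   min_connected = 3) {
  a <- attributes(image)
  m <- unclass(image) * 1.0
  stop_if_not(length(m) > 0, "image is empty")
  m <- perona_malik(m, pm_iterations, pm_kappa, pm_lambda)
  m <- median3x3(m)
  thr <- if (identical(intensity_threshold, "otsu")) otsu_threshold(m)
         else intensity_threshold
  if (thr >= max(m)) {
    warning("intensity threshold at or above image maximum; empty image")
    m[] <- 0
  } else {
    m[m <= thr] <- 0
  }
  m[neighbor_count_8(m > 0) < min_connected] <- 0
  attributes(m) <- a
  m
}

## number of TRUE 8-neighbors of each pixel (zero-padded borders)
neighbor_count_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  out <- matrix(0L, nr, nc)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    out <- out + p[2:(nr + 1L) + dy, 2:(nc + 1L) + dx]
  }
  out
}

## Disc footprint offsets (dx, dy) with dx^2 + dy^2 <= radius^2, minus the
## center.
disc_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2 & !(g$dx == 0 & g$dy == 0), ]
  g
}

## Grayscale dilation with a disc structuring element: per-pixel max over
## the footprint (zero outside the image).
dilate_disc <- function(m, radius) {
  off <- disc_offsets(radius)
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (k in seq_len(nrow(off))) {
    dx <- off$dx[k]; dy <- off$dy[k]
    sr <- max(1, 1 - dy):min(nr, nr - dy)
    sc <- max(1, 1 - dx):min(nc, nc - dx)
    out[sr, sc] <- pmax(out[sr, sc], m[sr + dy, sc + dx])
  }
  out
}

#' Detect co-replicating stretches as local intensity maxima
#'
#' A pixel is a peak iff it is nonzero and equals the grayscale dilation of
#' the image (disc structuring element of the given radius) at its position,
#' i.e. it is the maximum within the disc. Connected plateaus of equal
#' maxima are merged to their centroid. Positions are reported in nm at
#' pixel centers.
#'
#' @param image a preprocessed [render_events()] image.
#' @param dilation_radius disc radius, pixels.
#' @return data.frame of class `peak_set`: `x_nm`, `y_nm`, `intensity`
#'   (attribute `pixel` carried over).
#' @export
detect_peaks <- function(image, dilation_radius = 4) {
  pixel <- attr(image, "pixel") %||% 1
  origin <- attr(image, "origin") %||% c(0, 0)
  m <- unclass(image) * 1.0
  dil <- dilate_disc(m, dilation_radius)
  peak <- m > 0 & m == dil
  lab <- label_components_8(peak)
  if (!any(peak)) {
    out <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      intensity = numeric(0))
  } else {
    idx <- which(peak)
    r <- (idx - 1L) %% nrow(m) + 1L
    cc <- (idx - 1L) %/% nrow(m) + 1L
    grp <- lab[idx]
    out <- data.frame(
      x_nm = tapply((cc - 0.5) * pixel + origin[1], grp, mean),
      y_nm = tapply((r - 0.5) * pixel + origin[2], grp, mean),
      intensity = tapply(m[idx], grp, max))
    rownames(out) <- NULL
  }
  structure(out, pixel = pixel, class = c("peak_set", "data.frame"))
}

#' Cluster detected stretches into replication domains (DBSCAN)
#'
#' Density-based clustering of peak coordinates with reach `eps` (in
#' rendered pixels by default, i.e. `eps * pixel` nm) and neighborhood size
#' `min_pts` (neighborhoods include the point itself). Unreachable points
#' get label `-1`: solitary stretches. Classic core-point expansion in
#' input order, so the labeling is deterministic.
#'
#' @param peaks a [detect_peaks()] result (or data.frame with `x_nm`,
#'   `y_nm`).
#' @param eps reach in rendered pixels (see `eps_nm` to give it in nm).
#' @param min_pts minimum neighborhood size for a core point.
#' @param pixel rendered pixel size, nm.
#' @param eps_nm optional reach in nm, overriding `eps * pixel`.
#' @return object of class `cluster_set`: the peak table plus a `cluster`
#'   column (`-1` = solitary), with `eps_nm` and `min_pts` attributes.
#' @export
cluster_peaks <- function(peaks, eps = 14, min_pts = 2, pixel = 10,
                          eps_nm = NULL) {
  stop_if_not(is.null(eps_nm) || eps_nm > 0, "eps_nm must be > 0")
  if (is.null(eps_nm)) {
    stop_if_not(is_number(eps) && eps > 0, "eps must be > 0")
    eps_nm <- eps * (attr(peaks, "pixel") %||% pixel)
  }
  stop_if_not(is_number(min_pts) && min_pts >= 1, "min_pts must be >= 1")
  p <- as.matrix(peaks[, c("x_nm", "y_nm")])
  n <- nrow(p)
  labels <- rep.int(-1L, n)
  if (n > 0) {
    d <- cross_dist(p, p)
    nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps_nm))
    core <- vapply(nb, length, integer(1)) >= min_pts
    cl <- 0L
    visited <- logical(n)
    for (i in seq_len(n)) {
      if (visited[i] || !core[i]) next
      cl <- cl + 1L
      queue <- i
      visited[i] <- TRUE
      labels[i] <- cl
      while (length(queue) > 0) {
        q <- queue[1L]; queue <- queue[-1L]
        if (!core[q]) next
        for (j in nb[[q]]) {
          if (labels[j] == -1L) labels[j] <- cl     # border or new core
          if (!visited[j]) {
            visited[j] <- TRUE
            if (core[j]) queue <- c(queue, j)
          }
        }
      }
    }
  }
  out <- as.data.frame(peaks)
  out$cluster <- labels
  structure(out, eps_nm = eps_nm, min_pts = as.integer(min_pts),
            pixel = attr(peaks, "pixel") %||% pixel,
            class = c("cluster_set", "data.frame"))
}

#' @export
print.cluster_set <- function(x, ...) {
  k <- sum(unique(x$cluster) > 0)
  cat("<cluster_set> ", nrow(x), " peaks, ", k, " clusters, ",
      sum(x$cluster == -1L), " solitary (eps ", attr(x, "eps_nm"),
      " nm, MinPts ", attr(x, "min_pts"), ")\n", sep = "")
  invisible(x)
}

#' Per-cluster morphometrics and scene-level summary
#'
#' For every cluster: member count, intra-cluster nearest-neighbor
#' distances (each member to its nearest co-member), the horizontal Feret
#' diameter (extent of member centers along the image x-axis), the maximum
#' Feret diameter (largest pairwise member distance, a rotation-robust
#' companion measure) and the convex hull. The summary gives the median
#' stretch count per cluster, the pooled median intra-cluster NND, the
#' median horizontal Feret over clusters of at least `feret_min_size`
#' members (plus the variant including 2-member clusters) and the solitary
#' fraction (solitary peaks / all peaks).
#'
#' @param clusters a [cluster_peaks()] result.
#' @param feret_min_size minimum members for the headline Feret median.
#' @return list with `per_cluster` (data.frame), `nnd_nm` (pooled vector),
#'   `hulls` (list of vertex matrices) and `summary` (named list).
#' @export
cluster_metrics <- function(clusters, feret_min_size = 3) {
  stopifnot(inherits(clusters, "cluster_set"))
  cl <- clusters[clusters$cluster > 0, , drop = FALSE]
  ids <- sort(unique(cl$cluster))
  per <- lapply(ids, function(k) {
    p <- as.matrix(cl[cl$cluster == k, c("x_nm", "y_nm")])
    stop_if_not(nrow(p) >= 2, "cluster of a single peak cannot occur")
    nnd <- self_nnd(p)
    hull <- p[grDevices::chull(p), , drop = FALSE]
    list(row = data.frame(cluster = k, n = nrow(p),
                          feret_x_nm = diff(range(p[, 1])),
                          feret_max_nm = max(cross_dist(p, p)),
                          degenerate_hull = nrow(unique(hull)) < 3),
         nnd = nnd, hull = hull)
  })
  per_cluster <- do.call(rbind, lapply(per, `[[`, "row")) %||%
    data.frame(cluster = integer(0), n = integer(0),
               feret_x_nm = numeric(0), feret_max_nm = numeric(0),
               degenerate_hull = logical(0))
  nnd_all <- unlist(lapply(per, `[[`, "nnd"), use.names = FALSE)
  big <- per_cluster$n >= feret_min_size
  summary <- list(
    n_peaks = nrow(clusters),
    n_clusters = length(ids),
    n_solitary = sum(clusters$cluster == -1L),
    median_stretches_per_cluster =
      if (length(ids)) stats::median(per_cluster$n) else NA_real_,
    median_intra_nnd_nm =
      if (length(nnd_all)) stats::median(nnd_all) else NA_real_,
    median_feret_nm =
      if (any(big)) stats::median(per_cluster$feret_x_nm[big]) else NA_real_,
    median_feret_incl_pairs_nm =
      if (length(ids)) stats::median(per_cluster$feret_x_nm) else NA_real_,
    solitary_fraction =
      if (nrow(clusters)) sum(clusters$cluster == -1L) / nrow(clusters)
      else NA_real_)
  list(per_cluster = per_cluster, nnd_nm = nnd_all,
       hulls = lapply(per, `[[`, "hull"), summary = summary)
}
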