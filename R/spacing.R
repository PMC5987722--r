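#' Detect diffraction-limited particles in a 3D confocal stack
#'
#' Thresholds the stack at a global intensity quantile, labels 26-connected
#' voxel components, discards components below `min_voxels`, and reports the
#' intensity-weighted 3D center of mass of each component in nm.
#'
#' @param stack a [confocal_stack()] (single channel).
#' @param intensity_quantile threshold quantile over all voxels.
#' @param min_voxels minimum component size, voxels.
#' @return data.frame of class `detection_set`: `x_nm, y_nm, z_nm, mass,
#'   n_voxels`, attribute `channel`.
#' @export
detect_particles_3d <- function(stack, intensity_quantile = 0.995,
                                min_voxels = 4L) {
  stopifnot(inherits(stack, "confocal_stack"))
  arr <- stack$data
  thr <- stats::quantile(arr, intensity_quantile, names = FALSE)
  mask <- arr > thr
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), mass = numeric(0),
                      n_voxels = integer(0))
  if (!any(mask)) {
    warning("no voxels above the intensity threshold")
    return(structure(empty, channel = stack$channel,
                     class = c("detection_set", "data.frame")))
  }
  dims <- dim(arr)
  idx <- which(mask)
  ## voxel coordinates
  i <- (idx - 1L) %% dims[1] + 1L
  j <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  k <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  lookup <- integer(length(arr)); lookup[idx] <- seq_along(idx)
  ## 26-connectivity: half the offsets suffice for an undirected graph
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[offs$dk > 0 | (offs$dk == 0 & (offs$dj > 0 |
             (offs$dj == 0 & offs$di > 0))), ]
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    i2 <- i + offs$di[o]; j2 <- j + offs$dj[o]; k2 <- k + offs$dk[o]
    ok <- i2 >= 1L & i2 <= dims[1] & j2 >= 1L & j2 <= dims[2] &
      k2 >= 1L & k2 <= dims[3]
    nb <- (k2[ok] - 1L) * dims[1] * dims[2] + (j2[ok] - 1L) * dims[1] + i2[ok]
    hit <- lookup[nb] > 0L
    edges <- c(edges, rbind(which(ok)[hit], lookup[nb[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  keep_comp <- which(tabulate(comp) >= min_voxels)
  if (length(keep_comp) == 0L) {
    warning("no component of at least ", min_voxels, " voxels")
    return(structure(empty, channel = stack$channel,
                     class = c("detection_set", "data.frame")))
  }
  vox <- stack$voxel
  w <- arr[idx]
  rows <- lapply(keep_comp, function(cmp) {
    sel <- comp == cmp
    ww <- w[sel]
    data.frame(x_nm = sum((i[sel] - 0.5) * vox[1] * ww) / sum(ww),
               y_nm = sum((j[sel] - 0.5) * vox[2] * ww) / sum(ww),
               z_nm = sum((k[sel] - 0.5) * vox[3] * ww) / sum(ww),
               mass = sum(ww), n_voxels = sum(sel))
  })
  structure(do.call(rbind, rows), channel = stack$channel,
            class = c("detection_set", "data.frame"))
}

#' Directed cross-channel nearest-neighbor distances
#'
#' For every detection in the first (early-label) set, the Euclidean 3D
#' distance to the nearest detection of the second (later-label) set. The
#' convention is directed: swapping the channels may change the table. All
#' distances — including those beyond 1 um — enter the quantiles.
#'
#' @param first,second [detect_particles_3d()] results (or data.frames with
#'   `x_nm, y_nm, z_nm`).
#' @param delta_t pulse interval annotation, minutes.
#' @return data.frame of class `nnd_table` with one `nnd_nm` per first-set
#'   detection; attributes `delta_t` and `summary` (median, quartiles, n).
#' @export
cross_channel_nnd <- function(first, second, delta_t = NA_real_) {
  stop_if_not(nrow(first) > 0 && nrow(second) > 0,
              "no detections in channel")
  cols <- intersect(c("x_nm", "y_nm", "z_nm"), intersect(names(first),
                                                         names(second)))
  d <- cross_dist(as.matrix(first[cols]), as.matrix(second[cols]))
  nnd <- apply(d, 1L, min)
  q <- stats::quantile(nnd, c(0.25, 0.5, 0.75), names = FALSE)
  structure(data.frame(nnd_nm = nnd),
            delta_t = delta_t,
            summary = list(median = q[2], q25 = q[1], q75 = q[3],
                           n = length(nnd)),
            class = c("nnd_table", "data.frame"))
}

#' Summarize cross-channel NND tables across pulse intervals
#'
#' @param tables list of [cross_channel_nnd()] tables; duplicate `delta_t`
#'   entries are pooled with a warning.
#' @return data.frame (one row per `delta_t`, ordered): `delta_t`,
#'   `median_nm`, `q25_nm`, `q75_nm`, `n`; attribute `monotone_median`
#'   reports whether the median is non-decreasing in `delta_t`.
#' @export
summarize_by_dt <- function(tables) {
  stop_if_not(length(tables) >= 1, "need at least one table")
  dts <- vapply(tables, function(t) attr(t, "delta_t"), numeric(1))
  if (anyDuplicated(dts))
    warning("duplicate delta_t entries pooled")
  out <- lapply(sort(unique(dts)), function(dt) {
    v <- unlist(lapply(tables[dts == dt], function(t) t$nnd_nm))
    data.frame(delta_t = dt,
               median_nm = stats::median(v),
               q25_nm = stats::quantile(v, 0.25, names = FALSE),
               q75_nm = stats::quantile(v, 0.75, names = FALSE),
               n = length(v))
  })
  res <- do.call(rbind, out)
  attr(res, "monotone_median") <- !is.unsorted(res$median_nm)
  res
}
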