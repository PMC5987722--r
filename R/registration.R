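#' Rescale confocal slices to the STORM pixel grid
#'
#' Bilinearly interpolates each z-slice from the confocal lateral pixel size
#' to `target_pixel` over the same physical extent, with optional axis
#' flips. Pixel values are interpolated (a constant field stays at the same
#' value); the summed intensity therefore scales with the pixel-area ratio,
#' which is the convention used throughout the registration.
#'
#' @param stack a [confocal_stack()].
#' @param target_pixel output lateral pixel, nm.
#' @param flip named logical flags `c(x = , y = )`.
#' @return list of matrices (one per z-slice) with attribute `pixel`.
#' @export
rescale_confocal <- function(stack, target_pixel = 10,
                             flip = c(x = FALSE, y = FALSE)) {
  stopifnot(inherits(stack, "confocal_stack"))
  src <- stack$voxel[1]
  stop_if_not(target_pixel <= src, "target_pixel must be <= source pixel")
  dims <- dim(stack$data)
  ext <- dims[1:2] * src
  nout <- ceiling(ext / target_pixel)
  ## physical coordinates of output pixel centers -> source index space
  cx <- ((seq_len(nout[1]) - 0.5) * target_pixel) / src + 0.5
  cy <- ((seq_len(nout[2]) - 0.5) * target_pixel) / src + 0.5
  if (isTRUE(flip[["x"]])) cx <- dims[1] + 1 - cx
  if (isTRUE(flip[["y"]])) cy <- dims[2] + 1 - cy
  bil <- function(m, xi, yi) {
    x0 <- pmin(pmax(floor(xi), 1L), nrow(m) - 1L)
    y0 <- pmin(pmax(floor(yi), 1L), ncol(m) - 1L)
    fx <- pmin(pmax(xi - x0, 0), 1)
    fy <- pmin(pmax(yi - y0, 0), 1)
    m00 <- m[cbind(rep(x0, length(y0)), rep(y0, each = length(x0)))]
    m10 <- m[cbind(rep(x0 + 1L, length(y0)), rep(y0, each = length(x0)))]
    m01 <- m[cbind(rep(x0, length(y0)), rep(y0 + 1L, each = length(x0)))]
    m11 <- m[cbind(rep(x0 + 1L, length(y0)), rep(y0 + 1L, each = length(x0)))]
    FX <- rep(fx, length(y0)); FY <- rep(fy, each = length(x0))
    v <- m00 * (1 - FX) * (1 - FY) + m10 * FX * (1 - FY) +
      m01 * (1 - FX) * FY + m11 * FX * FY
    matrix(v, length(x0), length(y0))
  }
  out <- lapply(seq_len(dims[3]), function(z) bil(stack$data[, , z], cx, cy))
  attr(out, "pixel") <- target_pixel
  out
}

#' Moving sum z-projections of a slice series
#'
#' Projection `i` is the pixelwise sum of slices `i .. i + window - 1`;
#' there are `n_slices - window + 1` projections.
#'
#' @param slices list of equally sized matrices.
#' @param window sliding window length, slices.
#' @return list of projection matrices; attribute `z_start` gives each
#'   projection's first slice index.
#' @export
moving_projections <- function(slices, window = 5) {
  stop_if_not(is_number(window) && window >= 1, "window must be >= 1")
  n <- length(slices)
  stop_if_not(n >= window, "need at least `window` slices")
  k <- n - window + 1L
  out <- vector("list", k)
  acc <- Reduce(`+`, slices[seq_len(window)])
  out[[1L]] <- acc
  if (k > 1L) for (i in 2:k) {
    acc <- acc - slices[[i - 1L]] + slices[[i + window - 1L]]
    out[[i]] <- acc
  }
  attr(out, "z_start") <- seq_len(k)
  attr(out, "window") <- as.integer(window)
  out
}

## Rotate a matrix by `angle` degrees about its center (bilinear inverse
## mapping, zero fill outside the support).
rotate_image <- function(m, angle) {
  if (angle == 0) return(m)
  th <- rad(angle)
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  i <- rep(seq_len(nr), nc) - cy
  j <- rep(seq_len(nc), each = nr) - cx
  ## inverse rotation of output coordinates into source space
  si <- cos(th) * i - sin(th) * j + cy
  sj <- sin(th) * i + cos(th) * j + cx
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    v <- numeric(length(ii))
    v[ok] <- m[cbind(ii[ok], jj[ok])]
    v
  }
  v <- val(i0, j0) * (1 - fi) * (1 - fj) + val(i0 + 1L, j0) * fi * (1 - fj) +
    val(i0, j0 + 1L) * (1 - fi) * fj + val(i0 + 1L, j0 + 1L) * fi * fj
  matrix(v, nr, nc)
}

## Normalized cross-correlation of two equally sized images on the overlap
## implied by an integer pixel shift (dx = columns, dy = rows) of `moving`.
ncc_at_shift <- function(fixed, moving, dx, dy) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) < 2 || length(cs) < 2) return(-Inf)
  a <- fixed[rs, cs]
  b <- moving[rs - dy, cs - dx]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid registration of an image onto a fixed reference
#'
#' Rotation + translation only (calibrated pixels, no scaling). The
#' translation at each candidate rotation comes from the FFT
#' cross-correlation peak; rotations are searched on a coarse grid with
#' parabolic refinement of the normalized cross-correlation (NCC) score,
#' which is always evaluated on the mean-subtracted overlapping support.
#'
#' @param moving,fixed equally sized matrices.
#' @param rot_range half-width of the rotation search, degrees.
#' @param rot_step rotation grid step, degrees.
#' @param pixel pixel size, nm (used only to report the translation in nm).
#' @return object of class `rigid_transform`: `rotation` (degrees) and
#'   `translation_px`/`translation_nm` (`c(dx, dy)`, columns/rows) are the
#'   motion to apply to `moving` so that it aligns with `fixed`; `score`
#'   is the NCC at the optimum.
#' @export
register_rigid <- function(moving, fixed, rot_range = 5, rot_step = 0.5,
                           pixel = attr(fixed, "pixel") %||% 1) {
  stop_if_not(all(dim(moving) == dim(fixed)), "images must have equal size")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("no contrast", call. = FALSE)
  angles <- if (rot_range > 0) seq(-rot_range, rot_range, by = rot_step) else 0
  eval_angle <- function(a) {
    rot <- rotate_image(moving, a)
    if (stats::sd(rot) == 0) return(list(score = -Inf))
    s <- xcorr_shift(rot, fixed)  # fixed approx rot shifted by s
    dx <- round(s[["dx"]]); dy <- round(s[["dy"]])
    ## local integer refinement of the NCC around the FFT peak
    best <- list(score = -Inf)
    for (ddx in (dx - 1):(dx + 1)) for (ddy in (dy - 1):(dy + 1)) {
      sc <- ncc_at_shift(fixed, rot, ddx, ddy)
      if (sc > best$score) best <- list(score = sc, dx = ddx, dy = ddy)
    }
    best
  }
  evals <- lapply(angles, eval_angle)
  scores <- vapply(evals, `[[`, numeric(1), "score")
  k <- which.max(scores)
  angle <- angles[k]
  ## parabolic refinement over the rotation grid
  if (length(angles) >= 3 && k > 1 && k < length(angles)) {
    den <- scores[k - 1] + scores[k + 1] - 2 * scores[k]
    if (is.finite(den) && den < 0) {
      d <- 0.5 * (scores[k - 1] - scores[k + 1]) / den
      angle <- angles[k] + max(-0.5, min(0.5, d)) * rot_step
    }
  }
  best <- evals[[k]]
  structure(list(rotation = angle,
                 translation_px = c(dx = best$dx, dy = best$dy),
                 translation_nm = c(dx = best$dx * pixel,
                                    dy = best$dy * pixel),
                 score = best$score),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rotation ", round(x$rotation, 2), " deg, shift (",
      x$translation_px[1], ", ", x$translation_px[2], ") px, NCC ",
      round(x$score, 4), "\n", sep = "")
  invisible(x)
}

#' Select the moving z-projection best matching a STORM image
#'
#' Registers every projected substack against the STORM image and keeps the
#' one with the highest normalized cross-correlation; ties break toward the
#' lower z-start.
#'
#' @param projections output of [moving_projections()].
#' @param storm_image matrix to match (same grid as the projections).
#' @param ... passed to [register_rigid()].
#' @return object of class `overlay_result`: `window` (`c(z_start, z_end)`),
#'   `scores` per projection, `transform` of the winner, `best_index`.
#' @export
select_best_substack <- function(projections, storm_image, ...) {
  stop_if_not(length(projections) >= 1, "need at least one projection")
  z_start <- attr(projections, "z_start") %||% seq_along(projections)
  fits <- lapply(projections, function(p) {
    tryCatch(register_rigid(p, storm_image, ...),
             error = function(e) NULL)
  })
  scores <- vapply(fits, function(f) if (is.null(f)) -Inf else f$score,
                   numeric(1))
  if (all(!is.finite(scores))) stop("all registrations failed", call. = FALSE)
  k <- which.max(scores)               # first maximum = lowest z-start
  if (sum(scores == scores[k]) > 1L)
    message("substack score tie; keeping lower z-start (", z_start[k], ")")
  structure(list(window = c(z_start = z_start[k],
                            z_end = z_start[k] +
                              (attr(projections, "window") %||% 5L) - 1L),
                 scores = scores, transform = fits[[k]], best_index = k),
            class = "overlay_result")
}

## Even-odd rule point-in-polygon; poly = data.frame/matrix with x, y.
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Crop a STORM image (and optionally its events) to ROI polygons
#'
#' Zeroes all pixels outside each region of interest; returns one masked
#' image per ROI. If an event list is supplied, the events inside each
#' polygon (in nm coordinates) are returned alongside.
#'
#' @param storm_image a [render_events()] image.
#' @param rois list of polygons (data.frame/matrix with columns x, y in
#'   pixel coordinates of the STORM frame).
#' @param events optional [event_list()] to crop symmetrically.
#' @return list with one element per ROI: `image` (masked) and, when events
#'   are given, `events`. Empty ROIs are skipped with a warning.
#' @export
crop_to_rois <- function(storm_image, rois, events = NULL) {
  stop_if_not(length(rois) >= 1, "rois must be non-empty")
  pixel <- attr(storm_image, "pixel") %||% 1
  origin <- attr(storm_image, "origin") %||% c(0, 0)
  nr <- nrow(storm_image); nc <- ncol(storm_image)
  px <- rep(seq_len(nc), each = nr) - 0.5   # pixel centers, x = column
  py <- rep(seq_len(nr), nc) - 0.5
  out <- list()
  for (k in seq_along(rois)) {
    poly <- as.matrix(rois[[k]])
    if (nrow(poly) < 3L) {
      warning("ROI ", k, " has fewer than 3 vertices; skipped")
      next
    }
    mask <- matrix(points_in_polygon(px, py, poly), nr, nc)
    if (!any(mask)) {
      warning("ROI ", k, " covers no pixels; skipped")
      next
    }
    img <- storm_image
    img[!mask] <- 0L
    item <- list(image = img)
    if (!is.null(events)) {
      ex <- (events$x_nm - origin[1]) / pixel
      ey <- (events$y_nm - origin[2]) / pixel
      keep <- points_in_polygon(ex, ey, poly)
      ev <- events[keep, , drop = FALSE]
      attributes(ev)[c("n_frames", "pixel_hint")] <-
        attributes(events)[c("n_frames", "pixel_hint")]
      class(ev) <- class(events)
      item$events <- ev
    }
    out[[length(out) + 1L]] <- item
  }
  out
}
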