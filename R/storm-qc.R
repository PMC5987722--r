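#' Filter localization events by photon count
#'
#' Removes events below the photon threshold (low photon count means poor
#' localization precision). The boundary is kept: events with exactly
#' `min_photons` photons survive.
#'
#' @param events an [event_list()].
#' @param min_photons threshold, counts.
#' @return the filtered [event_list()], order preserved.
#' @export
filter_by_photons <- function(events, min_photons = 500) {
  stopifnot(inherits(events, "event_list"))
  stop_if_not(is_number(min_photons) && min_photons >= 0,
              "min_photons must be >= 0")
  keep <- events$photons >= min_photons
  out <- events[keep, , drop = FALSE]
  attributes(out)[c("n_frames", "pixel_hint")] <-
    attributes(events)[c("n_frames", "pixel_hint")]
  class(out) <- class(events)
  out
}

#' Render an event list into a super-resolution count image
#'
#' Adds a single gray value per localization: pixel `(i, j)` counts the
#' events with `floor((y - ymin) / pixel) == i - 1` and likewise in x
#' (half-open bins; an event exactly on a boundary belongs to the
#' higher-index pixel). The matrix is indexed `[row = y, col = x]` with the
#' origin at the top-left pixel corner; x grows with column, y with row.
#'
#' @param events an [event_list()] (or data.frame with `x_nm`, `y_nm`).
#' @param pixel rendering pixel, nm.
#' @param roi region `c(xmin, xmax, ymin, ymax)` in nm (half-open); default
#'   `c(0, max(x), 0, max(y))` rounded up to whole pixels.
#' @return integer matrix of class `storm_image` with attributes `pixel`,
#'   `origin` (nm of the top-left corner) and `n_dropped` (events outside
#'   the roi).
#' @export
render_events <- function(events, pixel = 10, roi = NULL) {
  stop_if_not(is_number(pixel) && pixel > 0, "pixel must be > 0")
  x <- events$x_nm; y <- events$y_nm
  if (is.null(roi)) {
    roi <- c(0, max(x, 0) + pixel / 2, 0, max(y, 0) + pixel / 2)
  }
  stop_if_not(roi[2] > roi[1] && roi[4] > roi[3], "roi has non-positive area")
  nc <- ceiling((roi[2] - roi[1]) / pixel)
  nr <- ceiling((roi[4] - roi[3]) / pixel)
  j <- floor((x - roi[1]) / pixel) + 1
  i <- floor((y - roi[3]) / pixel) + 1
  inside <- i >= 1 & i <= nr & j >= 1 & j <= nc
  img <- matrix(0L, nr, nc)
  if (any(inside)) {
    tab <- table((j[inside] - 1) * nr + i[inside])
    img[as.integer(names(tab))] <- as.integer(tab)
  }
  structure(img, pixel = pixel, origin = c(roi[1], roi[3]),
            n_dropped = sum(!inside), class = c("storm_image", "matrix"))
}

## Integer + subpixel shift (dx, dy) in pixels such that img2 is img1
## translated by that amount, estimated from the circular FFT
## cross-correlation peak with a quadratic fit of its 3-point neighborhood
## per axis.
xcorr_shift <- function(img1, img2) {
  a <- img1 - mean(img1)
  b <- img2 - mean(img2)
  if (all(a == 0) || all(b == 0)) stop("no contrast", call. = FALSE)
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  nr <- nrow(C); nc <- ncol(C)
  p <- which(C == max(C), arr.ind = TRUE)[1L, ]
  wrap <- function(idx, n) ifelse(idx - 1 > n / 2, idx - 1 - n, idx - 1)
  at <- function(i, j) C[(i - 1) %% nr + 1, (j - 1) %% nc + 1]
  subpix <- function(cm, c0, cp) {
    den <- cm + cp - 2 * c0
    if (den >= 0) return(0)           # not a local max; keep integer peak
    d <- 0.5 * (cm - cp) / den
    max(-0.5, min(0.5, d))
  }
  dy <- wrap(p[1], nr) +
    subpix(at(p[1] - 1, p[2]), at(p[1], p[2]), at(p[1] + 1, p[2]))
  dx <- wrap(p[2], nc) +
    subpix(at(p[1], p[2] - 1), at(p[1], p[2]), at(p[1], p[2] + 1))
  c(dx = unname(dx), dy = unname(dy))
}

#' Estimate and correct lateral stage drift by block cross-correlation
#'
#' Splits the event stream into temporal blocks of `block_frames` frames,
#' renders each block on a common grid, and estimates each block's lateral
#' displacement relative to the first block from the FFT cross-correlation
#' peak (quadratic sub-pixel interpolation). Per-event corrections are
#' linearly interpolated between block centers, and the residual drift is
#' re-measured on the corrected events.
#'
#' @param events an [event_list()].
#' @param block_frames frames per temporal block.
#' @param render_pixel rendering pixel for the block images, nm.
#' @return list with `events` (corrected [event_list()]) and `drift`
#'   (class `drift_estimate`): per-block `center_frame`, `dx_nm`, `dy_nm`,
#'   and `residual_nm`, the largest remaining block displacement after
#'   correction.
#' @export
estimate_and_correct_drift <- function(events, block_frames,
                                       render_pixel = 10) {
  stopifnot(inherits(events, "event_list"))
  n_frames <- attr(events, "n_frames")
  stop_if_not(n_frames >= 2 * block_frames,
              "need at least two blocks' worth of frames")
  pad <- 4 * render_pixel
  roi <- c(min(events$x_nm) - pad, max(events$x_nm) + pad,
           min(events$y_nm) - pad, max(events$y_nm) + pad)

  measure <- function(ev) {
    block <- floor(ev$frame / block_frames)
    nb <- floor((n_frames - 1) / block_frames) + 1L
    ref <- NULL
    dx <- rep(NA_real_, nb); dy <- rep(NA_real_, nb)
    for (b in seq_len(nb) - 1L) {
      sel <- block == b
      if (!any(sel)) next
      img <- render_events(ev[sel, , drop = FALSE], render_pixel, roi)
      if (is.null(ref)) {
        ref <- img
        dx[b + 1L] <- 0; dy[b + 1L] <- 0
      } else {
        s <- xcorr_shift(ref, img)
        dx[b + 1L] <- s[["dx"]] * render_pixel
        dy[b + 1L] <- s[["dy"]] * render_pixel
      }
    }
    centers <- (seq_len(nb) - 0.5) * block_frames
    if (anyNA(dx)) {
      warning("empty drift block(s); shifts interpolated from neighbors")
      ok <- !is.na(dx)
      dx <- stats::approx(centers[ok], dx[ok], centers, rule = 2)$y
      dy <- stats::approx(centers[ok], dy[ok], centers, rule = 2)$y
    }
    data.frame(center_frame = centers, dx_nm = dx, dy_nm = dy)
  }

  est <- measure(events)
  out <- events
  if (nrow(est) > 1L) {
    out$x_nm <- out$x_nm -
      stats::approx(est$center_frame, est$dx_nm, out$frame, rule = 2)$y
    out$y_nm <- out$y_nm -
      stats::approx(est$center_frame, est$dy_nm, out$frame, rule = 2)$y
  }
  resid <- measure(out)
  residual_nm <- max(sqrt(resid$dx_nm^2 + resid$dy_nm^2))
  drift <- structure(list(blocks = est, residual_nm = residual_nm,
                          block_frames = block_frames),
                     class = "drift_estimate")
  list(events = out, drift = drift)
}

#' @export
print.drift_estimate <- function(x, ...) {
  tot <- sqrt(x$blocks$dx_nm^2 + x$blocks$dy_nm^2)
  cat("<drift_estimate> ", nrow(x$blocks), " blocks of ", x$block_frames,
      " frames, max displacement ", round(max(tot), 1),
      " nm, residual after correction ", round(x$residual_nm, 2), " nm\n",
      sep = "")
  invisible(x)
}

#' Fourier ring correlation between two images
#'
#' Correlation of the two images' Fourier transforms, radially averaged over
#' rings of spatial frequency. The threshold curve is either the 3-sigma
#' criterion `3 / sqrt(N_q / 2)` (with `N_q` the number of Fourier pixels in
#' ring `q`) or the fixed 1/7 rule. The resolution is `1 / q*` at the first
#' ring where the curve falls below the threshold; if it never does within
#' the frequency support, the resolution is the finest representable,
#' `2 * pixel`.
#'
#' @param img1,img2 equally sized matrices (e.g. [render_events()] halves).
#' @param pixel pixel size, nm.
#' @param threshold_rule `"3sigma"` or `"fixed_1_over_7"`.
#' @return object of class `frc_result`: `freq` (1/nm), `frc`, `threshold`,
#'   `resolution_nm`, `crossed` (logical: threshold crossing found).
#' @export
frc_curve <- function(img1, img2, pixel,
                      threshold_rule = c("3sigma", "fixed_1_over_7")) {
  threshold_rule <- match.arg(threshold_rule)
  stop_if_not(all(dim(img1) == dim(img2)), "images must have equal size")
  stop_if_not(sum(img1) > 0 && sum(img2) > 0, "empty image")
  ## pad to a common square even size so rings are isotropic
  n <- max(dim(img1)); n <- n + n %% 2
  pad <- function(m) {
    out <- matrix(0, n, n)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  F1 <- stats::fft(pad(img1)); F2 <- stats::fft(pad(img2))
  f <- c(0:(n / 2), -((n / 2 - 1):1))      # FFT frequency indices
  r <- round(sqrt(outer(f^2, f^2, "+")))
  rmax <- floor(n / 2) - 1L
  keep <- r <= rmax
  ridx <- r[keep] + 1L
  num <- as.vector(tapply(Re(F1 * Conj(F2))[keep], ridx, sum))
  p1 <- as.vector(tapply(abs(F1[keep])^2, ridx, sum))
  p2 <- as.vector(tapply(abs(F2[keep])^2, ridx, sum))
  nq <- as.vector(tapply(rep(1, sum(keep)), ridx, sum))
  den <- sqrt(p1 * p2)
  frc <- ifelse(den > 0, num / den, 0)
  thr <- if (threshold_rule == "3sigma") 3 / sqrt(nq / 2) else
    rep(1 / 7, length(nq))
  rr <- seq_along(frc) - 1L                # ring radius in index units
  freq <- rr / (n * pixel)
  ## the 3-sigma curve exceeds 1 in the innermost rings (few Fourier
  ## pixels); a crossing is only meaningful where the threshold is < 1
  below <- which(rr >= 1L & thr < 1 & frc < thr)
  crossed <- length(below) > 0L
  resolution <- if (crossed) (n * pixel) / rr[below[1L]] else 2 * pixel
  structure(list(freq = freq, frc = frc, threshold = thr, n_ring = nq,
                 resolution_nm = resolution, crossed = crossed,
                 rule = threshold_rule),
            class = "frc_result")
}

#' Estimate image resolution by Fourier ring correlation of temporal halves
#'
#' Splits the event list into two temporal blocks at the median frame,
#' renders both halves on a common grid and computes [frc_curve()]. The
#' image passes QC if the estimated resolution is at most `max_resolution`.
#'
#' @param events an [event_list()].
#' @param pixel rendering pixel, nm.
#' @param threshold_rule see [frc_curve()].
#' @param max_resolution QC gate, nm.
#' @return the [frc_curve()] result with an added logical `pass`.
#' @export
frc_resolution <- function(events, pixel = 10,
                           threshold_rule = c("3sigma", "fixed_1_over_7"),
                           max_resolution = 50) {
  stopifnot(inherits(events, "event_list"))
  threshold_rule <- match.arg(threshold_rule)
  med <- stats::median(events$frame)
  first <- events$frame <= med
  if (all(first) || !any(first))           # degenerate frame distribution
    first <- seq_len(nrow(events)) <= nrow(events) / 2
  stop_if_not(any(first) && any(!first), "both temporal halves must be non-empty")
  pad <- 2 * pixel
  roi <- c(min(events$x_nm) - pad, max(events$x_nm) + pad,
           min(events$y_nm) - pad, max(events$y_nm) + pad)
  h1 <- render_events(events[first, , drop = FALSE], pixel, roi)
  h2 <- render_events(events[!first, , drop = FALSE], pixel, roi)
  res <- frc_curve(h1, h2, pixel, threshold_rule)
  res$pass <- res$resolution_nm <= max_resolution
  res$max_resolution <- max_resolution
  res
}

#' @export
print.frc_result <- function(x, ...) {
  cat("<frc_result> resolution ", round(x$resolution_nm, 1), " nm (",
      x$rule, if (!x$crossed) ", no threshold crossing", ")",
      if (!is.null(x$pass)) paste0(", QC ", if (x$pass) "pass" else "FAIL"),
      "\n", sep = "")
  invisible(x)
}
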