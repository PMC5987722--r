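#' Imaging configuration for synthetic acquisitions
#'
#' Parameters of the simulated STORM and confocal acquisitions. Defaults
#' follow the instrument this analysis targets: 10-nm STORM rendering pixel,
#' 90 x 90 x 200 nm confocal voxels, 12-nm (1 sigma per axis) localization
#' precision, and a 250/750-nm lateral/axial diffraction-limited PSF.
#'
#' @param storm_pixel STORM rendering pixel, nm.
#' @param confocal_voxel confocal voxel sizes `c(x, y, z)`, nm.
#' @param loc_precision_sigma localization precision, nm, 1 sigma per axis.
#' @param events_per_stretch_mean Poisson mean of localization events per
#'   co-replicating stretch over the whole movie.
#' @param photons_law per-event photon-count law: list with `dist` in
#'   `"constant"`, `"exp"`, `"gamma"`, `"lognormal"` and its parameters
#'   (`mean`, plus `shape` for gamma, `sdlog` for lognormal).
#' @param n_frames number of acquisition frames.
#' @param drift_model a drift function built by [drift_none()],
#'   [drift_linear()] or [drift_sinusoidal()].
#' @param psf_fwhm lateral/axial PSF full width at half maximum, nm.
#' @return an object of class `imaging_config`.
#' @export
imaging_config <- function(storm_pixel = 10,
                           confocal_voxel = c(90, 90, 200),
                           loc_precision_sigma = 12,
                           events_per_stretch_mean = 50,
                           photons_law = list(dist = "gamma", mean = 1500,
                                              shape = 2),
                           n_frames = 10000L,
                           drift_model = drift_none(),
                           psf_fwhm = c(250, 750)) {
  stop_if_not(is_number(storm_pixel) && storm_pixel > 0, "storm_pixel > 0")
  stop_if_not(length(confocal_voxel) == 3L && all(confocal_voxel > 0),
              "confocal_voxel must be 3 positive sizes")
  stop_if_not(is_number(loc_precision_sigma) && loc_precision_sigma >= 0,
              "loc_precision_sigma must be >= 0")
  stop_if_not(is_number(n_frames) && n_frames >= 1, "n_frames >= 1")
  stop_if_not(is.function(drift_model), "drift_model must be a function")
  structure(list(storm_pixel = storm_pixel, confocal_voxel = confocal_voxel,
                 loc_precision_sigma = loc_precision_sigma,
                 events_per_stretch_mean = events_per_stretch_mean,
                 photons_law = photons_law, n_frames = as.integer(n_frames),
                 drift_model = drift_model, psf_fwhm = psf_fwhm),
            class = "imaging_config")
}

#' Stage-drift models
#'
#' Each constructor returns a function mapping a frame index vector to an
#' `n x 2` matrix of lateral stage displacements in nm.
#'
#' @param dx_total,dy_total total displacement accumulated linearly over
#'   `n_frames`, nm.
#' @param n_frames number of frames over which the total is accumulated.
#' @param amplitude sinusoid amplitude, nm.
#' @param period_frames sinusoid period, frames.
#' @param axis `"x"`, `"y"` or `"xy"`.
#' @return a `function(frame) -> matrix(n, 2)` of nm offsets.
#' @export
drift_none <- function() function(frame) matrix(0, length(frame), 2L)

#' @rdname drift_none
#' @export
drift_linear <- function(dx_total, dy_total = 0, n_frames) {
  force(dx_total); force(dy_total); force(n_frames)
  function(frame) cbind(dx_total * frame / (n_frames - 1),
                        dy_total * frame / (n_frames - 1))
}

#' @rdname drift_none
#' @export
drift_sinusoidal <- function(amplitude, period_frames, axis = "x") {
  force(amplitude); force(period_frames); force(axis)
  function(frame) {
    s <- amplitude * sin(2 * pi * frame / period_frames)
    switch(axis,
           x = cbind(s, 0 * s),
           y = cbind(0 * s, s),
           xy = cbind(s, s))
  }
}

draw_photons <- function(n, law) {
  m <- law$mean %||% 1500
  switch(law$dist %||% "gamma",
         constant = rep.int(m, n),
         exp = stats::rexp(n, rate = 1 / m),
         gamma = {
           shape <- law$shape %||% 2
           stats::rgamma(n, shape = shape, rate = shape / m)
         },
         lognormal = {
           sdlog <- law$sdlog %||% 0.5
           stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
         },
         stop("unknown photon law: ", law$dist, call. = FALSE))
}

#' Construct a localization event list
#'
#' The canonical single-molecule localization table of the package:
#' one row per blinking event with acquisition frame, lateral position in nm
#' and photon count.
#'
#' @param frame integer frame indices in `[0, n_frames)`.
#' @param x_nm,y_nm positions, nm.
#' @param photons per-event photon counts, > 0.
#' @param n_frames total number of frames in the movie.
#' @param pixel_hint rendering pixel suggestion, nm.
#' @param stretch_id optional ground-truth stretch index per event.
#' @return data.frame of class `event_list` with attributes `n_frames` and
#'   `pixel_hint`.
#' @export
event_list <- function(frame, x_nm, y_nm, photons, n_frames,
                       pixel_hint = 10, stretch_id = NULL) {
  stop_if_not(all(frame >= 0 & frame < n_frames), "frames out of range")
  stop_if_not(all(is.finite(x_nm)) && all(is.finite(y_nm)),
              "positions must be finite")
  stop_if_not(all(photons > 0), "photon counts must be > 0")
  df <- data.frame(frame = as.integer(frame), x_nm = x_nm, y_nm = y_nm,
                   photons = photons)
  if (!is.null(stretch_id)) df$stretch_id <- as.integer(stretch_id)
  structure(df, n_frames = as.integer(n_frames), pixel_hint = pixel_hint,
            class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  cat("<event_list> ", nrow(x), " events over ", attr(x, "n_frames"),
      " frames\n", sep = "")
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Simulate a STORM acquisition from a ground-truth scene
#'
#' Each stretch emits `Poisson(events_per_stretch_mean)` blinking events at
#' frames drawn uniformly over the movie; each event position is the true
#' stretch position plus isotropic Gaussian localization noise
#' (`loc_precision_sigma` per axis) plus the stage drift at its frame.
#' Photon counts follow `photons_law`. The ground-truth stretch index of
#' every event is retained for testing.
#'
#' @param scene an `rd_scene` (its `z_nm`, if any, is ignored: STORM is 2D).
#' @param img an [imaging_config()].
#' @param channel which scene channel to image.
#' @param seed optional integer seed.
#' @return an [event_list()] with a `stretch_id` column.
#' @export
simulate_event_list <- function(scene, img, channel = 1L, seed = NULL) {
  stopifnot(inherits(scene, "rd_scene"), inherits(img, "imaging_config"))
  with_seed(seed, {
    st <- scene$stretches[scene$stretches$channel == channel, , drop = FALSE]
    stop_if_not(nrow(st) > 0, "scene has no stretches in channel ", channel)
    n_ev <- stats::rpois(nrow(st), img$events_per_stretch_mean)
    total <- sum(n_ev)
    sid <- rep.int(seq_len(nrow(st)), n_ev)
    frame <- sample.int(img$n_frames, total, replace = TRUE) - 1L
    noise <- matrix(stats::rnorm(2L * total, 0, img$loc_precision_sigma),
                    ncol = 2L)
    dr <- img$drift_model(frame)
    event_list(frame = frame,
               x_nm = st$x_nm[sid] + noise[, 1] + dr[, 1],
               y_nm = st$y_nm[sid] + noise[, 2] + dr[, 2],
               photons = draw_photons(total, img$photons_law),
               n_frames = img$n_frames, pixel_hint = img$storm_pixel,
               stretch_id = sid)
  })
}
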