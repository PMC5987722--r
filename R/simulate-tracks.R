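#' Motion model for paired replication-domain trajectories
#'
#' Diffusive motion with distance-dependent coupling. At pair distance `d`
#' the coupling strength is `c(d) = max(0, 1 - d / coupling_cutoff)`. Each
#' frame, the displacement of particle `i` of a pair is
#' `sqrt(c) * S + sqrt(1 - c) * I_i`, with `S` shared between the two
#' particles and `I_1`, `I_2` independent zero-mean isotropic Gaussians of
#' per-axis standard deviation `step_sigma`; the `sqrt` weights keep the
#' per-particle step variance independent of `c`, so coupling is isolated
#' from mobility. An optional Ornstein-Uhlenbeck tether of stationary
#' per-axis radius `confinement_radius` emulates chromatin confinement, and
#' `loc_noise_sigma` adds per-frame measurement noise to the reported
#' positions (tracking precision).
#'
#' @param step_sigma per-frame per-axis displacement sigma, nm.
#' @param coupling_cutoff distance at which coupling vanishes, nm.
#' @param frame_interval seconds between frames.
#' @param loc_noise_sigma per-frame per-axis position measurement noise, nm.
#' @param confinement_radius stationary per-axis confinement radius, nm, or
#'   `NULL` for free diffusion.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(step_sigma = 40, coupling_cutoff = 550,
                         frame_interval = 0.5, loc_noise_sigma = 30,
                         confinement_radius = 150) {
  stop_if_not(is_number(step_sigma) && step_sigma > 0, "step_sigma > 0")
  stop_if_not(is_number(coupling_cutoff) && coupling_cutoff > 0,
              "coupling_cutoff > 0")
  stop_if_not(is_number(frame_interval) && frame_interval > 0,
              "frame_interval > 0")
  stop_if_not(is.null(confinement_radius) ||
                (is_number(confinement_radius) &&
                   confinement_radius > step_sigma),
              "confinement_radius must exceed step_sigma")
  structure(list(step_sigma = step_sigma, coupling_cutoff = coupling_cutoff,
                 frame_interval = frame_interval,
                 loc_noise_sigma = loc_noise_sigma,
                 confinement_radius = confinement_radius),
            class = "motion_model")
}

#' Coupling strength at a given pair distance
#'
#' @param motion a [motion_model()].
#' @param d pair distance(s), nm.
#' @return coupling in `[0, 1]`, zero at and beyond the cutoff.
#' @export
coupling_strength <- function(motion, d) {
  pmax(0, 1 - d / motion$coupling_cutoff)
}

#' Simulate coupled trajectory pairs
#'
#' Generates `n_pairs` two-particle 2D tracks. Pair `i` starts at separation
#' `distances[i]` and moves with the coupling `c(distances[i])` of the
#' motion model (fixed per pair, from the initial separation); ground truth
#' is retained. One track of each pair is labeled channel 1, the other
#' channel 2.
#'
#' @param n_pairs number of pairs.
#' @param distances initial separations, nm (recycled to `n_pairs`).
#' @param motion a [motion_model()].
#' @param n_frames frames per track (>= 2).
#' @param coupling optional explicit coupling value(s) in `[0, 1]`
#'   overriding `c(distances)`.
#' @param seed optional integer seed.
#' @return object of class `track_set`: data.frame
#'   (`track_id, pair_id, channel, frame, x_nm, y_nm`) with attributes
#'   `frame_interval` and `truth` (data.frame `pair_id, distance, coupling`).
#' @export
simulate_trajectory_pairs <- function(n_pairs, distances, motion,
                                      n_frames = 40L, coupling = NULL,
                                      seed = NULL) {
  stopifnot(inherits(motion, "motion_model"))
  stop_if_not(is_number(n_frames) && n_frames >= 2, "n_frames >= 2")
  with_seed(seed, {
    d0 <- rep_len(distances, n_pairs)
    cc <- if (is.null(coupling)) coupling_strength(motion, d0)
          else rep_len(coupling, n_pairs)
    stop_if_not(all(cc >= 0 & cc <= 1), "coupling must be in [0, 1]")
    s <- motion$step_sigma
    L <- motion$loc_noise_sigma
    R <- motion$confinement_radius
    kappa <- if (is.null(R)) 0 else 1 - sqrt(1 - (s / R)^2)
    nf <- as.integer(n_frames)
    nsteps <- nf - 1L

    res <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      a1 <- c(0, 0); a2 <- c(d0[i], 0)           # anchors
      p1 <- matrix(NA_real_, nf, 2L); p2 <- matrix(NA_real_, nf, 2L)
      p1[1L, ] <- a1; p2[1L, ] <- a2
      sc <- sqrt(cc[i]); si <- sqrt(1 - cc[i])
      S  <- matrix(stats::rnorm(2L * nsteps, 0, s), nsteps, 2L)
      I1 <- matrix(stats::rnorm(2L * nsteps, 0, s), nsteps, 2L)
      I2 <- matrix(stats::rnorm(2L * nsteps, 0, s), nsteps, 2L)
      for (t in seq_len(nsteps)) {
        p1[t + 1L, ] <- p1[t, ] + kappa * (a1 - p1[t, ]) +
          sc * S[t, ] + si * I1[t, ]
        p2[t + 1L, ] <- p2[t, ] + kappa * (a2 - p2[t, ]) +
          sc * S[t, ] + si * I2[t, ]
      }
      if (L > 0) {
        p1 <- p1 + matrix(stats::rnorm(2L * nf, 0, L), nf, 2L)
        p2 <- p2 + matrix(stats::rnorm(2L * nf, 0, L), nf, 2L)
      }
      res[[i]] <- data.frame(
        track_id = rep(c(2L * i - 1L, 2L * i), each = nf),
        pair_id = i,
        channel = rep(c(1L, 2L), each = nf),
        frame = rep.int(0:(nf - 1L), 2L),
        x_nm = c(p1[, 1], p2[, 1]),
        y_nm = c(p1[, 2], p2[, 2]))
    }
    df <- do.call(rbind, res)
    structure(df,
              frame_interval = motion$frame_interval,
              truth = data.frame(pair_id = seq_len(n_pairs), distance = d0,
                                 coupling = cc),
              class = c("track_set", "data.frame"))
  })
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set> ", length(unique(x$track_id)), " tracks, ",
      nrow(x), " detections, frame interval ",
      attr(x, "frame_interval"), " s\n", sep = "")
  invisible(x)
}
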