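#' Link per-frame detections into tracks (greedy nearest neighbor)
#'
#' Frame-to-frame linking within `max_step`: each open track claims its
#' nearest detection in the next frame (processed in track order, a
#' detection is claimed once); unclaimed detections open new tracks; a
#' track ends on its first miss. No gap closing. Equidistant candidates
#' resolve to the lower detection index (logged via `message`).
#'
#' @param detections data.frame `frame, x_nm, y_nm` and optional `channel`.
#' @param max_step maximum frame-to-frame displacement, nm.
#' @param frame_interval seconds between frames.
#' @return a `track_set` data.frame (`track_id, channel, frame, x_nm, y_nm`).
#' @export
link_tracks <- function(detections, max_step, frame_interval = 0.5) {
  stop_if_not(length(unique(detections$frame)) >= 2, "need >= 2 frames")
  if (is.null(detections$channel)) detections$channel <- 1L
  out <- list()
  next_id <- 1L
  for (ch in sort(unique(detections$channel))) {
    d <- detections[detections$channel == ch, , drop = FALSE]
    frames <- sort(unique(d$frame))
    ## active: list of track state (id, x, y)
    active <- list()
    rows <- list()
    for (f in frames) {
      cur <- d[d$frame == f, , drop = FALSE]
      taken <- logical(nrow(cur))
      surviving <- list()
      for (tr in active) {
        if (nrow(cur) == 0) break
        dist <- sqrt((cur$x_nm - tr$x)^2 + (cur$y_nm - tr$y)^2)
        dist[taken] <- Inf
        jmin <- which(dist == min(dist))
        if (length(jmin) > 1L) {
          message("ambiguous link at frame ", f, "; lower index kept")
          jmin <- jmin[1L]
        }
        if (is.finite(dist[jmin]) && dist[jmin] <= max_step) {
          taken[jmin] <- TRUE
          tr$x <- cur$x_nm[jmin]; tr$y <- cur$y_nm[jmin]
          rows[[length(rows) + 1L]] <-
            data.frame(track_id = tr$id, channel = ch, frame = f,
                       x_nm = tr$x, y_nm = tr$y)
          surviving[[length(surviving) + 1L]] <- tr
        }
      }
      for (j in which(!taken)) {
        tr <- list(id = next_id, x = cur$x_nm[j], y = cur$y_nm[j])
        next_id <- next_id + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(track_id = tr$id, channel = ch, frame = f,
                     x_nm = tr$x, y_nm = tr$y)
        surviving[[length(surviving) + 1L]] <- tr
      }
      active <- surviving
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$track_id, df$frame), ]
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            class = c("track_set", "data.frame"))
}

#' Select cross-channel trajectory pairs by overlap duration
#'
#' All channel-1 x channel-2 track pairs whose temporal overlap lasts at
#' least `min_duration` seconds are kept; overlaps longer than
#' `max_duration` are truncated to `max_duration` from their start. Pairs
#' whose mean separation exceeds `max_pair_distance` are dropped.
#'
#' @param tracks a `track_set` with both channels.
#' @param min_duration,max_duration overlap bounds, seconds.
#' @param max_pair_distance mean-separation cap, nm.
#' @return list of trajectory pairs; each has `track1`, `track2` (aligned
#'   position matrices over the common frames), `frames`, and ids.
#' @export
pair_trajectories <- function(tracks, min_duration = 15, max_duration = 50,
                              max_pair_distance = Inf) {
  dt <- attr(tracks, "frame_interval") %||% 0.5
  stop_if_not(all(c(1L, 2L) %in% tracks$channel), "two channels required")
  split_tr <- split(tracks[c("frame", "x_nm", "y_nm")], tracks$track_id)
  chan <- vapply(split(tracks$channel, tracks$track_id), `[`, integer(1), 1L)
  ids1 <- names(split_tr)[chan == 1L]
  ids2 <- names(split_tr)[chan == 2L]
  pairs <- list()
  for (a in ids1) for (b in ids2) {
    ta <- split_tr[[a]]; tb <- split_tr[[b]]
    common <- intersect(ta$frame, tb$frame)
    if (length(common) < 2L) next
    common <- sort(common)
    dur <- (length(common) - 1L) * dt
    if (dur < min_duration) next
    keep_n <- min(length(common), floor(max_duration / dt) + 1L)
    common <- common[seq_len(keep_n)]
    pa <- as.matrix(ta[match(common, ta$frame), c("x_nm", "y_nm")])
    pb <- as.matrix(tb[match(common, tb$frame), c("x_nm", "y_nm")])
    md <- mean(sqrt(rowSums((pa - pb)^2)))
    if (md > max_pair_distance) next
    pairs[[length(pairs) + 1L]] <-
      list(id1 = a, id2 = b, frames = common, track1 = pa, track2 = pb,
           mean_distance = md)
  }
  pairs
}

#' Correlation angles of a trajectory pair
#'
#' For every common time step, the angle between the two displacement
#' vectors: `alpha_t = acos(u.v / (|u||v|))` in degrees (0 = fully coupled,
#' 90 on average = uncoupled, 180 = antiparallel). Steps where either
#' displacement is zero are skipped and counted, not imputed.
#'
#' @param track1,track2 aligned position matrices (n x 2, nm), or a pair
#'   object from [pair_trajectories()] as the first argument.
#' @return list: `alpha_deg` (per defined step), `mean_alpha`,
#'   `mean_distance` (mean separation over the overlap, nm), `n_steps`,
#'   `n_skipped`.
#' @export
correlation_angles <- function(track1, track2 = NULL) {
  if (is.list(track1) && !is.null(track1$track1)) {
    track2 <- track1$track2
    track1 <- track1$track1
  }
  stop_if_not(nrow(track1) >= 2 && all(dim(track1) == dim(track2)),
              "need two aligned tracks with >= 2 positions")
  u <- diff(track1); v <- diff(track2)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ok <- nu > 0 & nv > 0
  if (!any(ok)) {
    warning("no step with two nonzero displacements; pair dropped")
    return(NULL)
  }
  cosang <- rowSums(u * v)[ok] / (nu[ok] * nv[ok])
  alpha <- deg(acos(pmin(1, pmax(-1, cosang))))
  list(alpha_deg = alpha,
       mean_alpha = mean(alpha),
       mean_distance = mean(sqrt(rowSums((track1 - track2)^2))),
       n_steps = sum(ok),
       n_skipped = sum(!ok))
}

#' Per-pair coupling points and the binned profile
#'
#' Computes `(mean_distance, mean_alpha)` for every pair and bins the mean
#' correlation angle by distance for display; the per-pair points stay
#' unbinned for fitting.
#'
#' @param pairs list from [pair_trajectories()] (or a `track_set` from
#'   [simulate_trajectory_pairs()], whose pairs are taken by `pair_id`).
#' @param bin_width distance bin width, nm.
#' @return object of class `coupling_profile`: `points` (data.frame
#'   `mean_distance, mean_alpha, n_steps`), `bins` (data.frame
#'   `d_mid, mean_alpha, sd_alpha, n`, with `sparse = n < 3` flagged).
#' @export
coupling_profile <- function(pairs, bin_width = 50) {
  if (inherits(pairs, "track_set")) pairs <- pairs_from_track_set(pairs)
  stop_if_not(length(pairs) >= 2, "need at least two pairs")
  pts <- do.call(rbind, lapply(pairs, function(p) {
    ca <- correlation_angles(p$track1, p$track2)
    if (is.null(ca)) return(NULL)
    data.frame(mean_distance = ca$mean_distance, mean_alpha = ca$mean_alpha,
               n_steps = ca$n_steps)
  }))
  b <- floor(pts$mean_distance / bin_width)
  bins <- do.call(rbind, lapply(sort(unique(b)), function(k) {
    v <- pts$mean_alpha[b == k]
    data.frame(d_mid = (k + 0.5) * bin_width, mean_alpha = mean(v),
               sd_alpha = stats::sd(v), n = length(v))
  }))
  bins$sparse <- bins$n < 3
  structure(list(points = pts, bins = bins, bin_width = bin_width),
            class = "coupling_profile")
}

## Split a simulated track_set into the pair list coupling_profile expects.
pairs_from_track_set <- function(tracks) {
  lapply(split(seq_len(nrow(tracks)), tracks$pair_id), function(rows) {
    d <- tracks[rows, , drop = FALSE]
    t1 <- d[d$channel == 1L, ]; t2 <- d[d$channel == 2L, ]
    list(track1 = as.matrix(t1[order(t1$frame), c("x_nm", "y_nm")]),
         track2 = as.matrix(t2[order(t2$frame), c("x_nm", "y_nm")]))
  })
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat("<coupling_profile> ", nrow(x$points), " pairs, distances ",
      round(min(x$points$mean_distance)), "-",
      round(max(x$points$mean_distance)), " nm\n", sep = "")
  invisible(x)
}

#' Locate the coupling transition point from two regression lines
#'
#' Ordinary least squares of the per-pair mean correlation angle on the
#' per-pair mean distance, fitted separately to pairs closer than
#' `near_cut` and farther than `far_cut` (the gap between the cuts enters
#' neither fit). The transition point is the exact intersection of the two
#' lines; near-parallel lines yield an explicit no-transition result.
#'
#' @param profile a [coupling_profile()].
#' @param near_cut,far_cut distance cuts, nm.
#' @param slope_tol minimum slope difference (deg/nm) to intersect.
#' @return list of class `transition_fit`: `d_star_nm`, `alpha_star_deg`,
#'   `fit_near`, `fit_far` (lm objects), `n_near`, `n_far`,
#'   `no_transition` flag.
#' @export
fit_transition <- function(profile, near_cut = 400, far_cut = 600,
                           slope_tol = 1e-4) {
  stopifnot(inherits(profile, "coupling_profile"))
  pts <- profile$points
  near <- pts[pts$mean_distance < near_cut, ]
  far <- pts[pts$mean_distance > far_cut, ]
  stop_if_not(nrow(near) >= 2 && nrow(far) >= 2,
              "need >= 2 pairs on each side of the cuts")
  fn <- stats::lm(mean_alpha ~ mean_distance, data = near)
  ff <- stats::lm(mean_alpha ~ mean_distance, data = far)
  bn <- stats::coef(fn); bf <- stats::coef(ff)
  dslope <- bn[2] - bf[2]
  if (!is.finite(dslope) || abs(dslope) < slope_tol) {
    return(structure(list(d_star_nm = NA_real_, alpha_star_deg = NA_real_,
                          fit_near = fn, fit_far = ff,
                          n_near = nrow(near), n_far = nrow(far),
                          no_transition = TRUE),
                     class = "transition_fit"))
  }
  d_star <- unname((bf[1] - bn[1]) / dslope)
  structure(list(d_star_nm = d_star,
                 alpha_star_deg = unname(bn[1] + bn[2] * d_star),
                 fit_near = fn, fit_far = ff,
                 n_near = nrow(near), n_far = nrow(far),
                 no_transition = FALSE),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  if (x$no_transition) {
    cat("<transition_fit> no transition (near-parallel regimes)\n")
  } else {
    cat("<transition_fit> d* = ", round(x$d_star_nm), " nm, alpha* = ",
        round(x$alpha_star_deg, 1), " deg (", x$n_near, " near / ",
        x$n_far, " far pairs)\n", sep = "")
  }
  invisible(x)
}

#' Resample a track set to a coarser time step
#'
#' Keeps every k-th frame, `k = step / frame_interval` (must be a whole
#' number); frames are kept on a common global lattice (`frame %% k == 0`)
#' so cross-channel steps stay simultaneous.
#'
#' @param tracks a `track_set`.
#' @param step new time step, seconds.
#' @return the thinned `track_set` with updated `frame_interval`.
#' @export
resample_time_step <- function(tracks, step) {
  dt <- attr(tracks, "frame_interval") %||% 0.5
  stop_if_not(step >= dt, "step must be >= the frame interval")
  k <- step / dt
  stop_if_not(abs(k - round(k)) < 1e-9, "step must be a multiple of the frame interval")
  k <- as.integer(round(k))
  if (k == 1L) return(tracks)
  out <- tracks[tracks$frame %% k == 0L, , drop = FALSE]
  out$frame <- out$frame %/% k
  for (at in c("truth")) attr(out, at) <- attr(tracks, at)
  attr(out, "frame_interval") <- step
  class(out) <- class(tracks)
  rownames(out) <- NULL
  out
}
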