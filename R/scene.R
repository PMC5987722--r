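#' Configuration for synthetic replication-domain scenes
#'
#' Describes the ground-truth geometry of a field of replication domains
#' (RDs): how many domains, how many co-replicating stretches each contains,
#' how large the domains are and how far apart the stretches within them sit.
#' The defaults encode the structural model measured on real nuclei: domains
#' of median four stretches (shifted-geometric counts), 150-nm domain
#' diameter, 63-nm intra-domain nearest-neighbor spacing, and 12.6% of all
#' stretches solitary (unclustered).
#'
#' @param n_rds number of replication domains in the field.
#' @param stretch_p success probability of the shifted-geometric law for
#'   per-domain stretch counts: `K = min_stretches - 1 + G` with
#'   `P(G = g) = p (1-p)^(g-1)`, support g >= 1. With the defaults
#'   (`min_stretches = 2`, `p = 0.25`) the per-domain count has median 4,
#'   the value measured on real domains.
#' @param min_stretches smallest per-domain stretch count. The default 2
#'   reflects that a single-stretch domain is observationally identical to
#'   a solitary stretch, which the generator models as its own population
#'   (`solitary_fraction`); set to 1 for the plain shifted-geometric law.
#' @param rd_diameter domain disc diameter in nm; every stretch of a domain
#'   lies within `rd_diameter / 2` of its center.
#' @param target_intra_nnd target median nearest-neighbor distance between
#'   stretches of one domain, nm.
#' @param solitary_fraction fraction of all stretches placed unclustered,
#'   in `[0, 1)`.
#' @param field_size extent of the field in nm; length 2 (2D) or 3 (3D).
#' @param min_center_spacing minimum center-to-center distance between
#'   domains, nm.
#' @param solitary_exclusion_nm minimum distance of a solitary stretch from
#'   every other stretch (clustered or solitary), nm. Matches the physical
#'   clustering reach (DBSCAN Eps) so solitaries are solitary by construction.
#' @param spacing_law neighbor-spacing law for dual-color scenes: a list with
#'   `median_by_dt` (named numeric, nm, names = pulse interval in minutes)
#'   and `sdlog` (log-normal spread of center-to-center distances).
#' @param max_retries bound on rejection-sampling retries per placement.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(n_rds = 30,
                         stretch_p = 0.25,
                         min_stretches = 2L,
                         rd_diameter = 150,
                         target_intra_nnd = 63,
                         solitary_fraction = 0.126,
                         field_size = c(4000, 4000),
                         min_center_spacing = 300,
                         solitary_exclusion_nm = 140,
                         spacing_law = list(
                           median_by_dt = c(`0` = 0, `15` = 180, `30` = 240,
                                            `45` = 270, `60` = 300, `90` = 360,
                                            `120` = 420),
                           sdlog = 0.35),
                         max_retries = 500L) {
  stop_if_not(is_number(n_rds) && n_rds >= 1, "n_rds must be a positive count")
  stop_if_not(is_number(stretch_p) && stretch_p > 0 && stretch_p <= 1,
              "stretch_p must be in (0, 1]")
  stop_if_not(is_number(min_stretches) && min_stretches >= 1,
              "min_stretches must be >= 1")
  stop_if_not(is_number(rd_diameter) && rd_diameter > 0,
              "rd_diameter must be > 0")
  stop_if_not(is_number(target_intra_nnd) && target_intra_nnd > 0,
              "target_intra_nnd must be > 0")
  stop_if_not(is_number(solitary_fraction) &&
                solitary_fraction >= 0 && solitary_fraction < 1,
              "solitary_fraction must be in [0, 1)")
  stop_if_not(length(field_size) %in% c(2L, 3L) && all(field_size > 0),
              "field_size must be 2 or 3 positive extents (nm)")
  structure(
    list(n_rds = as.integer(n_rds), stretch_p = stretch_p,
         min_stretches = as.integer(min_stretches),
         rd_diameter = rd_diameter, target_intra_nnd = target_intra_nnd,
         solitary_fraction = solitary_fraction, field_size = field_size,
         min_center_spacing = min_center_spacing,
         solitary_exclusion_nm = solitary_exclusion_nm,
         spacing_law = spacing_law,
         max_retries = as.integer(max_retries)),
    class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config> ", x$n_rds, " RDs, p=", x$stretch_p,
      " (count median ", stretch_count_median(x), "), diameter ",
      x$rd_diameter, " nm, target intra-NND ", x$target_intra_nnd,
      " nm, solitary ", round(100 * x$solitary_fraction, 1), "%\n", sep = "")
  invisible(x)
}

#' Median of the shifted-geometric stretch-count law
#'
#' Smallest k with `P(K <= k) >= 1/2` for `P(K = k) = p (1-p)^(k-1)`.
#' @param p success probability in (0, 1].
#' @return integer median of the law.
#' @export
shifted_geom_median <- function(p) {
  stop_if_not(is_number(p) && p > 0 && p <= 1, "p must be in (0, 1]")
  ## P(K <= k) = 1 - (1-p)^k
  if (p == 1) return(1L)
  as.integer(ceiling(log(0.5) / log(1 - p)))
}

## Draw per-domain stretch counts, support k >= 1.
rshifted_geom <- function(n, p) 1L + stats::rgeom(n, p)

#' Median per-domain stretch count of a scene configuration
#'
#' @param cfg a [scene_config()].
#' @return integer median of the configured count law.
#' @export
stretch_count_median <- function(cfg) {
  cfg$min_stretches - 1L + shifted_geom_median(cfg$stretch_p)
}

## Uniform point in a d-ball of given radius around center.
runif_ball <- function(center, radius) {
  d <- length(center)
  repeat {
    u <- stats::runif(d, -1, 1)
    if (sum(u^2) <= 1) return(center + radius * u)
  }
}

## Place k stretches inside a disc/ball so that nearest-neighbor spacings
## track `target`: each new stretch is dropped at ~target distance from a
## randomly chosen existing one (sequential rejection against the disc and
## against crowding closer than 0.8 * target; the crowding constraint is
## relaxed when the disc is too full to honor it).
place_stretches <- function(k, center, diameter, target, max_retries) {
  d <- length(center)
  radius <- diameter / 2
  pts <- matrix(NA_real_, k, d)
  pts[1L, ] <- runif_ball(center, radius)
  if (k == 1L) return(pts)
  for (j in 2:k) {
    placed <- FALSE
    for (strict in c(TRUE, FALSE)) {
      for (it in seq_len(max_retries)) {
        parent <- pts[sample.int(j - 1L, 1L), ]
        dist <- target * stats::runif(1, 1.0, 1.1)
        dir <- stats::rnorm(d)
        cand <- parent + dist * dir / sqrt(sum(dir^2))
        if (sqrt(sum((cand - center)^2)) > radius) next
        if (strict) {
          dd <- sqrt(colSums((t(pts[seq_len(j - 1L), , drop = FALSE]) - cand)^2))
          if (min(dd) < 0.9 * target) next
        }
        pts[j, ] <- cand
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed)
      stop(sprintf(paste0("cannot place stretch at target NND %.1f nm inside ",
                          "a %.1f-nm domain disc (infeasible rd_diameter/",
                          "target_intra_nnd pair)"), target, diameter),
           call. = FALSE)
  }
  pts
}

## Per-domain disc diameter: the configured diameter is the size of a
## median-count domain; larger stretch counts get area-proportionally
## larger discs (uniform packing density), emulating domains that range
## from the median size up to a few-fold larger.
rd_diameters <- function(counts, rd_diameter, ref_median) {
  rd_diameter * sqrt(pmax(counts, ref_median) / ref_median)
}

## Sample RD centers uniformly, keeping each domain disc inside the field
## and enforcing both a minimum center-to-center spacing and a minimum
## disc-surface gap (so neighboring domains stay resolvable as distinct
## clusters under the physical clustering reach).
place_centers <- function(n, field, diameter, min_spacing, max_retries,
                          surface_gap = 0) {
  d <- length(field)
  margin <- rep_len(diameter, n) / 2
  stop_if_not(all(field > 2 * max(margin)), "field smaller than one domain")
  centers <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    need <- pmax(min_spacing, margin[seq_len(i - 1L)] + margin[i] +
                   surface_gap)
    ok <- FALSE
    for (it in seq_len(max_retries)) {
      cand <- stats::runif(d, margin[i], field - margin[i])
      if (i == 1L ||
          all(sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) -
                              cand)^2)) >= need)) {
        centers[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf("cannot place %d domains %.0f nm apart in the field", n,
                   min_spacing), call. = FALSE)
  }
  centers
}

#' Sample a ground-truth replication-domain scene
#'
#' Generates domain centers, per-domain stretch positions and solitary
#' stretches according to a [scene_config()]. Per-domain stretch counts are
#' shifted-geometric; stretches are placed by sequential rejection sampling
#' so the realized intra-domain median nearest-neighbor distance tracks
#' `target_intra_nnd`; solitary stretches keep at least
#' `solitary_exclusion_nm` from every other stretch.
#'
#' @param cfg a [scene_config()].
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `rd_scene`: a list with `centers` (matrix, nm),
#'   `stretches` (data.frame `rd_id`, `x_nm`, `y_nm`[, `z_nm`], `channel`;
#'   `rd_id = -1` marks solitary stretches), `field_size` and `config`.
#' @export
sample_scene <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(seed, {
    d <- length(cfg$field_size)
    counts <- cfg$min_stretches - 1L + rshifted_geom(cfg$n_rds, cfg$stretch_p)
    diams <- rd_diameters(counts, cfg$rd_diameter, stretch_count_median(cfg))
    centers <- place_centers(cfg$n_rds, cfg$field_size, diams,
                             cfg$min_center_spacing, cfg$max_retries,
                             surface_gap = cfg$solitary_exclusion_nm)
    pts <- vector("list", cfg$n_rds)
    for (i in seq_len(cfg$n_rds))
      pts[[i]] <- place_stretches(counts[i], centers[i, ], diams[i],
                                  cfg$target_intra_nnd, cfg$max_retries)
    clustered <- do.call(rbind, pts)
    rd_id <- rep.int(seq_len(cfg$n_rds), counts)

    n_sol <- round(cfg$solitary_fraction / (1 - cfg$solitary_fraction) *
                     nrow(clustered))
    sol <- matrix(NA_real_, n_sol, d)
    if (n_sol > 0) {
      excl <- cfg$solitary_exclusion_nm
      all_pts <- clustered
      for (i in seq_len(n_sol)) {
        ok <- FALSE
        for (it in seq_len(cfg$max_retries)) {
          cand <- stats::runif(d, 0, cfg$field_size)
          if (min(sqrt(colSums((t(all_pts) - cand)^2))) >= excl) {
            sol[i, ] <- cand
            all_pts <- rbind(all_pts, cand)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("field too crowded to place solitary stretches ",
               excl, " nm from all others", call. = FALSE)
      }
    }

    xyz <- rbind(clustered, sol)
    df <- data.frame(rd_id = c(rd_id, rep.int(-1L, n_sol)),
                     x_nm = xyz[, 1], y_nm = xyz[, 2])
    if (d == 3L) df$z_nm <- xyz[, 3]
    df$channel <- 1L
    structure(list(centers = centers, stretches = df,
                   rd_diameter_nm = diams,
                   field_size = cfg$field_size, delta_t = NA_real_,
                   config = cfg),
              class = "rd_scene")
  })
}

#' Sample a dual-color neighbor-pair scene
#'
#' Emulates dual-pulse labeling with pulse interval `delta_t` minutes. For
#' `delta_t > 0`, each first-channel domain gets a second-channel neighbor
#' whose center-to-center distance is log-normal with median
#' `spacing_law$median_by_dt[delta_t]` (overridable via `spacing_median`).
#' For `delta_t = 0` both pulses hit the same domains and each stretch is
#' assigned to one of the two channels at random — the two channels then see
#' different stochastic subsets of the same object.
#'
#' @param cfg a [scene_config()]; `n_rds` counts first-channel domains.
#' @param delta_t pulse interval, minutes.
#' @param spacing_median optional override of the law median, nm.
#' @param seed optional integer seed.
#' @return an `rd_scene` whose `stretches$channel` is 1 or 2; second-channel
#'   domains have `rd_id` offset by `n_rds`.
#' @export
sample_dual_scene <- function(cfg, delta_t, spacing_median = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(seed, {
    scene <- sample_scene(cfg)
    d <- length(cfg$field_size)
    if (delta_t == 0) {
      keep <- scene$stretches$rd_id > 0
      ch <- ifelse(stats::runif(nrow(scene$stretches)) < 0.5, 1L, 2L)
      scene$stretches$channel <- ch
      scene$delta_t <- 0
      return(scene)
    }
    med <- spacing_median %||%
      unname(cfg$spacing_law$median_by_dt[as.character(delta_t)])
    stop_if_not(is_number(med) && med > 0,
                "no spacing-law median for delta_t = ", delta_t)
    sdlog <- cfg$spacing_law$sdlog %||% 0.35
    counts2 <- cfg$min_stretches - 1L + rshifted_geom(cfg$n_rds, cfg$stretch_p)
    diams2 <- rd_diameters(counts2, cfg$rd_diameter, stretch_count_median(cfg))
    out <- vector("list", cfg$n_rds)
    centers2 <- matrix(NA_real_, cfg$n_rds, d)
    for (i in seq_len(cfg$n_rds)) {
      for (it in seq_len(cfg$max_retries)) {
        dist <- stats::rlnorm(1, meanlog = log(med), sdlog = sdlog)
        dir <- stats::rnorm(d)
        cand <- scene$centers[i, ] + dist * dir / sqrt(sum(dir^2))
        if (all(cand > diams2[i] / 2) &&
            all(cand < cfg$field_size - diams2[i] / 2)) break
        if (it == cfg$max_retries)
          stop("cannot place neighbor domain inside the field", call. = FALSE)
      }
      centers2[i, ] <- cand
      out[[i]] <- place_stretches(counts2[i], cand, diams2[i],
                                  cfg$target_intra_nnd, cfg$max_retries)
    }
    xyz2 <- do.call(rbind, out)
    df2 <- data.frame(rd_id = rep.int(cfg$n_rds + seq_len(cfg$n_rds), counts2),
                      x_nm = xyz2[, 1], y_nm = xyz2[, 2])
    if (d == 3L) df2$z_nm <- xyz2[, 3]
    df2$channel <- 2L
    scene$stretches <- rbind(scene$stretches, df2)
    scene$centers <- rbind(scene$centers, centers2)
    scene$rd_diameter_nm <- c(scene$rd_diameter_nm, diams2)
    scene$delta_t <- delta_t
    scene
  })
}

#' @export
print.rd_scene <- function(x, ...) {
  n_sol <- sum(x$stretches$rd_id < 0)
  cat("<rd_scene> ", nrow(x$centers), " domains, ",
      nrow(x$stretches) - n_sol, " clustered + ", n_sol,
      " solitary stretches, field ",
      paste(x$field_size, collapse = " x "), " nm",
      if (!is.na(x$delta_t)) paste0(", dt = ", x$delta_t, " min"), "\n",
      sep = "")
  invisible(x)
}

#' Ground-truth summary statistics of a scene
#'
#' @param scene an `rd_scene`.
#' @return list with per-domain stretch counts, their median, the pooled
#'   intra-domain nearest-neighbor distances and median, and the solitary
#'   fraction.
#' @export
scene_truth <- function(scene) {
  st <- scene$stretches
  cl <- st[st$rd_id > 0, , drop = FALSE]
  counts <- as.integer(table(cl$rd_id))
  cols <- intersect(c("x_nm", "y_nm", "z_nm"), names(st))
  nnds <- unlist(lapply(split(cl[cols], cl$rd_id), function(p) {
    v <- self_nnd(as.matrix(p)); v[!is.na(v)]
  }), use.names = FALSE)
  list(stretch_counts = counts,
       median_stretches = stats::median(counts),
       intra_nnd = nnds,
       median_intra_nnd = stats::median(nnds),
       solitary_fraction = mean(st$rd_id < 0))
}

#' Write a scene's stretch table to CSV
#'
#' One row per stretch: `scene_id, rd_id, x_nm, y_nm, z_nm, channel`
#' (`rd_id = -1` for solitary stretches; `z_nm = 0` for 2D scenes).
#' @param scene an `rd_scene`.
#' @param path output file.
#' @param scene_id identifier written in the first column.
#' @export
write_scene_csv <- function(scene, path, scene_id = 1L) {
  df <- scene$stretches
  if (is.null(df$z_nm)) df$z_nm <- 0
  out <- data.frame(scene_id = scene_id, rd_id = df$rd_id, x_nm = df$x_nm,
                    y_nm = df$y_nm, z_nm = df$z_nm, channel = df$channel)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
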