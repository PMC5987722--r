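#' Fit the combing stretching rate from length standards
#'
#' Least-squares fit of genomic length (kbp) on measured fiber length (um)
#' over standards of known size; the slope is the stretching rate in
#' kb per micrometer. Through the origin by default (zero physical length
#' corresponds to zero genomic length); a free intercept is available.
#'
#' @param standards data.frame with `measured_um` and `known_kbp` (e.g.
#'   from [simulate_combed_fibers()]).
#' @param through_origin fit without intercept (default).
#' @return object of class `calibration_fit`: `rate_kb_per_um`,
#'   `rate_se`, `intercept_kbp`, `sigma_kbp` (residual sd), `n_per_class`,
#'   and the underlying `lm` fit.
#' @export
fit_stretching_rate <- function(standards, through_origin = TRUE) {
  stop_if_not(all(c("measured_um", "known_kbp") %in% names(standards)),
              "standards need measured_um and known_kbp")
  stop_if_not(all(standards$measured_um > 0), "lengths must be > 0")
  if (length(unique(standards$known_kbp)) < 2L)
    stop("degenerate fit: need >= 2 distinct standard lengths",
         call. = FALSE)
  fit <- if (through_origin)
    stats::lm(known_kbp ~ 0 + measured_um, data = standards)
  else
    stats::lm(known_kbp ~ measured_um, data = standards)
  ## noiseless standards fit exactly; summary.lm warns about that
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope_row <- if (through_origin) 1L else 2L
  sig <- sm$sigma
  structure(list(rate_kb_per_um = unname(co[slope_row, 1]),
                 rate_se = unname(co[slope_row, 2]),
                 intercept_kbp = if (through_origin) 0
                                 else unname(co[1, 1]),
                 sigma_kbp = if (is.finite(sig)) sig else 0,
                 n_per_class = table(standards$known_kbp),
                 fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> stretching rate ", round(x$rate_kb_per_um, 3),
      " +/- ", signif(x$rate_se, 2), " kb/um",
      if (x$intercept_kbp != 0)
        paste0(", intercept ", round(x$intercept_kbp, 2), " kbp"),
      "\n", sep = "")
  invisible(x)
}

#' Convert a measured comet length to genomic length
#'
#' `kbp = rate * length_um + intercept`, with uncertainty combining the
#' rate standard error (scaled by the length) and the calibration residual
#' spread in quadrature.
#'
#' @param length_um measured length(s), um, non-negative.
#' @param fit a [fit_stretching_rate()] result.
#' @return data.frame `length_um, kbp, kbp_se`.
#' @export
comet_length_to_kbp <- function(length_um, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  stop_if_not(all(length_um >= 0), "lengths must be non-negative")
  kbp <- fit$rate_kb_per_um * length_um + fit$intercept_kbp
  se <- sqrt((length_um * fit$rate_se)^2 + fit$sigma_kbp^2)
  data.frame(length_um = length_um, kbp = kbp, kbp_se = se)
}

#' Replicated DNA per domain from fork count, speed and duration
#'
#' The consistency check linking the observed stretch count per domain to
#' genomic domain size: `n_forks * fork_speed * duration` kb.
#'
#' @param n_forks number of active forks.
#' @param fork_speed_kb_per_min replication speed.
#' @param duration_min replication time.
#' @return replicated DNA, kb.
#' @export
replication_yield <- function(n_forks = 4, fork_speed_kb_per_min = 2,
                              duration_min = 60) {
  stop_if_not(all(c(n_forks, fork_speed_kb_per_min, duration_min) >= 0),
              "inputs must be >= 0")
  n_forks * fork_speed_kb_per_min * duration_min
}

#' Linear compaction ratio of domains versus linkers
#'
#' Ratio of genomic density per physical length (kbp/nm) of replication
#' domains to that of their linkers: with ~500 kbp per 150-nm domain and
#' ~50 kbp per 150-nm linker, linkers are ~10-fold less compact.
#'
#' @param rd_kbp,rd_nm genomic and physical domain size.
#' @param linker_kbp,linker_nm genomic and physical linker size.
#' @return fold difference in linear compaction.
#' @export
compaction_ratio <- function(rd_kbp = 500, rd_nm = 150,
                             linker_kbp = 50, linker_nm = 150) {
  stop_if_not(all(c(rd_kbp, rd_nm, linker_kbp, linker_nm) > 0),
              "all sizes must be > 0")
  (rd_kbp / rd_nm) / (linker_kbp / linker_nm)
}

#' Linker gap between neighboring domains
#'
#' Median center-to-center spacing minus median domain diameter: the
#' physical length of the linker bridging two neighboring domains.
#'
#' @param spacing_nm center-to-center spacing, nm.
#' @param diameter_nm domain diameter, nm.
#' @return gap length, nm.
#' @export
linker_gap <- function(spacing_nm = 300, diameter_nm = 150) {
  spacing_nm - diameter_nm
}
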