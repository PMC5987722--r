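#' Simulate combed DNA fiber measurements
#'
#' Emulates measuring stretched DNA fibers of known genomic lengths under a
#' combing stretching rate: `measured_um = true_kbp / rate * (1 + e)` with
#' `e ~ N(0, cv)`. Fragment identity is retained so the calibration fit can
#' be tested against ground truth.
#'
#' @param true_lengths_kbp genomic lengths of the standards, kbp (e.g. the
#'   HindIII lambda-DNA fragments 4.36, 9.41, 23.13 kbp).
#' @param rate_kb_per_um stretching rate, kb per micrometer.
#' @param length_noise_cv coefficient of variation of the measured length.
#' @param n_per_class fibers measured per standard.
#' @param seed optional integer seed.
#' @return data.frame (`known_kbp`, `measured_um`) of class
#'   `fiber_measurements`.
#' @export
simulate_combed_fibers <- function(true_lengths_kbp,
                                   rate_kb_per_um = 1.77,
                                   length_noise_cv = 0,
                                   n_per_class = 1L,
                                   seed = NULL) {
  stop_if_not(is_number(rate_kb_per_um) && rate_kb_per_um > 0, "rate > 0")
  stop_if_not(all(true_lengths_kbp > 0), "lengths must be > 0")
  with_seed(seed, {
    kbp <- rep(true_lengths_kbp, each = n_per_class)
    noiseless <- kbp / rate_kb_per_um
    um <- noiseless * (1 + stats::rnorm(length(kbp), 0, length_noise_cv))
    um <- pmax(um, 1e-6)
    structure(data.frame(known_kbp = kbp, measured_um = um),
              class = c("fiber_measurements", "data.frame"))
  })
}
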