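#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a temporary RNG state. seed = NULL leaves the caller's
## stream untouched so composite simulations stay reproducible end to end.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Euclidean distances from each row of a (n x d) to each row of b (m x d).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

## Nearest-neighbor distance within one point set (rows). Returns NA for n < 2.
self_nnd <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 2L) return(rep(NA_real_, n))
  d <- cross_dist(p, p)
  diag(d) <- Inf
  apply(d, 1L, min)
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180
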