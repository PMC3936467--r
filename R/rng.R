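#' Seeded Gaussian deviates from the package's own stream
#'
#' Draws standard-normal deviates from a dedicated xoshiro256++ stream,
#' independent of R's global RNG, so large noise fields can be generated
#' reproducibly from explicit integer seeds.
#'
#' @param n number of deviates.
#' @param seed non-negative integer-valued seed (< 2^53).
#' @return numeric vector of length `n`.
#' @export
rnorm_seeded <- function(n, seed) {
  stopifnot(is.numeric(n), n >= 0, is.numeric(seed), seed >= 0)
  .rng_normal(as.double(n), as.double(seed))
}

#' Seeded uniform deviates in (0, 1)
#' @inheritParams rnorm_seeded
#' @return numeric vector of length `n`.
#' @export
runif_seeded <- function(n, seed) {
  stopifnot(is.numeric(n), n >= 0, is.numeric(seed), seed >= 0)
  .rng_unif(as.double(n), as.double(seed))
}

#' Derive a child seed from a master seed and a stream path
#'
#' Deterministic counter-scheme fan-out: a master seed plus a numeric path
#' (stage index, subject index, ...) hashes to an independent child seed,
#' so any subset of a run can be regenerated without replaying the rest.
#'
#' @param master master seed (non-negative, < 2^53).
#' @param ... numeric path components identifying the stream.
#' @return a child seed (non-negative double < 2^53).
#' @export
child_seed <- function(master, ...) {
  path <- as.double(unlist(list(...), use.names = FALSE))
  stopifnot(length(path) >= 1, all(is.finite(path)))
  .rng_child_seed(as.double(master), path)
}
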