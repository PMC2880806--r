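#' Derive a child seed deterministically from a run seed
#'
#' Sub-simulations (replicates, sweep cells, pipeline stages) must not share
#' a random stream with each other or with the parent run. Child seeds are
#' derived from the run seed by a fixed integer recurrence so that a run is
#' reproducible from its master seed alone.
#'
#' @param seed master run seed (integer).
#' @param k child index (positive integer, vectorised).
#' @return integer vector of child seeds, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1:3)
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, all(k >= 1))
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- (abs(as.numeric(seed)) %% m)
  out <- numeric(length(k))
  for (i in seq_along(k)) {
    # Lehmer-style mix of (seed, k); coefficients are fixed package constants
    out[i] <- ((s + 1) * 48271 + as.numeric(k[i]) * 16807) %% m
  }
  as.integer(out + 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent parameter validation error
stop_param <- function(...) stop(..., call. = FALSE)
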