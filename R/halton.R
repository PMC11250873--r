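# Halton quasi-random draws for simulated maximum likelihood.
#
# Everything here is deterministic: no random state is consulted.  Draws for
# the mixing distribution are radical inverses in distinct prime bases,
# mapped through the standard-normal quantile function.

#' Radical inverse of an integer in a prime base
#'
#' Reverses the base-`base` digit expansion of `index` about the radix
#' point: index `d0 + d1*b + d2*b^2 + ...` maps to
#' `d0/b + d1/b^2 + d2/b^3 + ...`.  This is the Halton sequence in one
#' dimension.
#'
#' @param index Positive integer (vectorized).  Index 0 is rejected: it maps
#'   to 0, whose normal quantile is infinite.
#' @param base Integer base >= 2.
#' @return Values in the open interval (0, 1).
#' @export
radical_inverse <- function(index, base) {
  index <- as.numeric(index)
  if (any(index < 1)) stop("index must be >= 1")
  if (base < 2) stop("base must be >= 2")
  out <- numeric(length(index))
  f <- 1 / base
  i <- index
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

first_primes <- function(n) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (n > length(primes)) stop("at most ", length(primes), " dimensions supported")
  primes[seq_len(n)]
}

#' Standard-normal Halton draw matrix
#'
#' Builds the per-observation, per-draw standard-normal values used to
#' simulate the mixing distribution of the random coefficients.  Dimension
#' `d` uses the `d`-th smallest prime base by default (2, 3, 5, 7, 11 for
#' five random coefficients).  After discarding `discard` leading sequence
#' elements, elements are allocated to observations in consecutive blocks of
#' `D` (observation `i` receives sequence positions
#' `discard + (i-1)*D + 1, ..., discard + i*D`), then transformed by the
#' standard-normal quantile function.
#'
#' @param n_obs Number of observations.
#' @param n_dims Number of random-coefficient dimensions.
#' @param D Draws per observation (the study default elsewhere is 900).
#' @param discard Leading sequence elements skipped (default 10), avoiding
#'   the degenerate early points of the sequence.
#' @param primes Optional prime bases, one per dimension, all distinct.
#' @return A `draw_matrix` list: `values` (array `n_obs x D x n_dims`),
#'   `primes`, `discard`, `D`.
#' @export
halton_normal_draws <- function(n_obs, n_dims, D, discard = 10, primes = NULL) {
  if (D < 1) stop("D must be >= 1")
  if (is.null(primes)) primes <- first_primes(n_dims)
  if (length(primes) != n_dims) stop("need one prime per dimension")
  if (anyDuplicated(primes)) stop("prime bases must be distinct")
  idx <- discard + seq_len(n_obs * D)
  values <- array(NA_real_, dim = c(n_obs, D, n_dims))
  for (d in seq_len(n_dims)) {
    u <- radical_inverse(idx, primes[d])
    # consecutive blocks of D per observation: fill draws-fastest
    values[, , d] <- matrix(stats::qnorm(u), nrow = n_obs, ncol = D, byrow = TRUE)
  }
  structure(list(values = values, primes = primes, discard = discard, D = D),
            class = "draw_matrix")
}

#' @export
print.draw_matrix <- function(x, ...) {
  cat(sprintf("draw_matrix: %d obs x %d draws x %d dims (primes %s, discard %d)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              paste(x$primes, collapse = ","), x$discard))
  invisible(x)
}
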