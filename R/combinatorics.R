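#' Combinatorial index-to-tuple mapping via the generalized triangular array
#'
#' Work items in an iterated-overlap run are all size-`sigma` combinations of
#' the `N` active (meta-)chromosomes.  To shard the work without materializing
#' the combination list, a flat 0-based index `I` is decoded into the
#' corresponding strictly increasing tuple of 1-based chromosome indices by
#' peeling layers off a sigma-dimensional triangular array: for fixed first
#' index `i1` there are choose(N - i1, sigma - 1) combinations left, and the
#' partial sums of these layer sizes telescope through the hockey-stick
#' identity (see [partial_binomial_sum()]).
#'
#' All arithmetic is carried out in double precision, which is exact for
#' integers below 2^53; any input whose total combination count would exceed
#' that bound is rejected rather than silently rounded.
#'
#' @name combinatorics
NULL

.choose_exact <- function(n, k) {
  v <- choose(n, k)
  if (any(v >= 2^53)) {
    stop("binomial coefficient exceeds 2^53; exact integer arithmetic ",
         "is not guaranteed for N = ", n[which.max(v)], ", sigma = ", k)
  }
  v
}

#' Partial sum of binomial coefficients (hockey-stick identity)
#'
#' Computes `sum_{j=0}^{N-sigma} choose(N-j, sigma)`, the total number of
#' cells in a sigma-dimensional triangular array with longest edge
#' `N - sigma + 1`, which telescopes to `choose(N+1, sigma+1)`.
#'
#' @param N Positive integer, total item count.
#' @param sigma Positive integer tuple size, `sigma <= N`.
#' @return The exact integer value of the sum (as a double).
#' @examples
#' partial_binomial_sum(3, 1)  # 3 + 2 + 1 = 6
#' partial_binomial_sum(10, 4) # choose(11, 5) = 462
#' @export
partial_binomial_sum <- function(N, sigma) {
  stopifnot(length(N) == 1, length(sigma) == 1)
  if (sigma < 1 || N < 1) stop("N and sigma must be positive integers")
  if (sigma > N) stop("sigma (", sigma, ") must not exceed N (", N, ")")
  sum(.choose_exact(N - (0:(N - sigma)), sigma))
}

#' Decode a flat combination index into a chromosome tuple
#'
#' Returns the `I`-th (0-based) strictly increasing `sigma`-tuple over items
#' `1..N`, in the enumeration order induced by the triangular array (first
#' index slowest-varying, i.e. lexicographic order).  With
#' `allow_repeats = TRUE` the same machinery enumerates non-decreasing tuples
#' by decoding over `N + sigma - 1` items and applying the replacement
#' `i_j <- i_j - j + 1`.
#'
#' @param I 0-based flat index, `0 <= I < choose(N, sigma)` (or
#'   `choose(N + sigma - 1, sigma)` when `allow_repeats`).
#' @param N Item (chromosome) count.
#' @param sigma Tuple size.
#' @param allow_repeats If `TRUE`, enumerate non-decreasing tuples.
#' @return Integer vector of `sigma` 1-based indices, strictly increasing
#'   (non-decreasing when `allow_repeats`).
#' @examples
#' index_to_combination(0, 4, 2)  # c(1, 2)
#' index_to_combination(5, 4, 2)  # c(3, 4)
#' @seealso [combination_to_index()] for the inverse.
#' @export
index_to_combination <- function(I, N, sigma, allow_repeats = FALSE) {
  stopifnot(length(I) == 1, length(N) == 1, length(sigma) == 1)
  if (N < 1 || sigma < 1) stop("N and sigma must be positive integers")
  N_eff <- if (allow_repeats) N + sigma - 1 else N
  if (sigma > N_eff) stop("sigma (", sigma, ") must not exceed N (", N, ")")
  total <- .choose_exact(N_eff, sigma)
  if (I < 0 || I >= total) {
    stop("index I = ", I, " out of range: valid range is 0..", total - 1,
         " for N = ", N, ", sigma = ", sigma,
         if (allow_repeats) " (allow_repeats)" else "")
  }
  idx <- integer(sigma)
  rem <- I          # position within the current sub-array
  base <- 0L        # value the next index must exceed
  n_left <- N_eff   # items available to the remaining dimensions
  for (j in seq_len(sigma)) {
    d <- sigma - j + 1L  # dimensionality of the remaining array
    if (d == 1L) {
      idx[j] <- base + rem + 1L
      break
    }
    # peel layers: layer k (k = 1, 2, ...) holds choose(n_left - k, d - 1) cells
    k <- 1L
    repeat {
      layer <- .choose_exact(n_left - k, d - 1L)
      if (rem < layer) break
      rem <- rem - layer
      k <- k + 1L
    }
    idx[j] <- base + k
    base <- idx[j]
    n_left <- n_left - k
  }
  if (allow_repeats) idx <- idx - seq_len(sigma) + 1L
  as.integer(idx)
}

#' Encode a chromosome tuple as a flat combination index
#'
#' Exact inverse of [index_to_combination()]: given a strictly increasing
#' tuple over `1..N` (non-decreasing when `allow_repeats`), returns its
#' 0-based position in the triangular-array enumeration.
#'
#' @param multiindex Increasing integer vector of item indices.
#' @inheritParams index_to_combination
#' @return 0-based flat index (double, exact below 2^53).
#' @examples
#' combination_to_index(c(2, 3), 4)  # 3
#' @export
combination_to_index <- function(multiindex, N, allow_repeats = FALSE) {
  sigma <- length(multiindex)
  if (sigma < 1) stop("multiindex must be nonempty")
  if (allow_repeats) {
    if (any(diff(multiindex) < 0)) stop("multiindex must be non-decreasing")
    multiindex <- multiindex + seq_len(sigma) - 1L
    N <- N + sigma - 1L
  } else if (sigma > 1 && any(diff(multiindex) <= 0)) {
    stop("multiindex must be strictly increasing")
  }
  if (multiindex[1] < 1 || multiindex[sigma] > N) {
    stop("multiindex entries must lie in 1..", N)
  }
  I <- 0
  prev <- 0L
  for (j in seq_len(sigma)) {
    d <- sigma - j + 1L
    kj <- multiindex[j]
    if (kj - 1L >= prev + 1L) {
      # full layers skipped before reaching value kj in this dimension
      skipped <- (prev + 1L):(kj - 1L)
      I <- I + sum(.choose_exact(N - skipped, d - 1L))
    }
    prev <- kj
  }
  I
}
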