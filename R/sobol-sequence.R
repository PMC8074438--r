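# Base-2 Sobol' low-discrepancy sequence in Gray-code order.
#
# Direction numbers follow the standard Joe–Kuo parameterization (primitive
# polynomial per dimension plus odd initial values m_k); the table shipped
# here covers the first 64 dimensions, ample for curated factor subsets.
# 30 output bits are used so all integer work stays inside R's 32-bit
# bitwAnd/bitwXor range.

# primitive polynomial (binary encoding, MSB = leading term) per dimension;
# dimension 1 is the van der Corput sequence
.sobol_poly <- c(
  1, 3, 7, 11, 13, 19, 25, 37, 41, 47, 55, 59, 61, 67, 91, 97, 103, 109,
  115, 131, 137, 143, 145, 157, 167, 171, 185, 191, 193, 203, 211, 213,
  229, 239, 241, 247, 253, 285, 299, 301, 333, 351, 355, 357, 361, 369,
  391, 397, 425, 451, 463, 487, 501, 529, 539, 545, 557, 563, 601, 607,
  617, 623, 631, 637)

.sobol_mlen <- c(
  1, 1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 5, 5, 6, 6, 6, 6, 6, 6, 7, 7, 7, 7, 7,
  7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8,
  8, 8, 8, 8, 8, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9)

.sobol_mval <- c(
  1, 1, 1, 3, 1, 3, 1, 1, 1, 1, 1, 1, 3, 3, 1, 3, 5, 13, 1, 1, 5, 5, 17,
  1, 1, 5, 5, 5, 1, 1, 7, 11, 19, 1, 1, 5, 1, 1, 1, 1, 1, 3, 11, 1, 3, 5,
  5, 31, 1, 3, 3, 9, 7, 49, 1, 1, 1, 15, 21, 21, 1, 3, 1, 13, 27, 49, 1,
  1, 1, 15, 7, 5, 1, 3, 1, 15, 13, 25, 1, 1, 5, 5, 19, 61, 1, 3, 7, 11,
  23, 15, 103, 1, 3, 7, 13, 13, 15, 69, 1, 1, 3, 13, 7, 35, 63, 1, 3, 5,
  9, 1, 25, 53, 1, 3, 1, 13, 9, 35, 107, 1, 3, 1, 5, 27, 61, 31, 1, 1, 5,
  11, 19, 41, 61, 1, 3, 5, 3, 3, 13, 69, 1, 1, 7, 13, 1, 19, 1, 1, 3, 7,
  5, 13, 19, 59, 1, 1, 3, 9, 25, 29, 41, 1, 3, 5, 13, 23, 1, 55, 1, 3, 7,
  3, 13, 59, 17, 1, 3, 1, 3, 5, 53, 69, 1, 1, 5, 5, 23, 33, 13, 1, 1, 7,
  7, 1, 61, 123, 1, 1, 7, 9, 13, 61, 49, 1, 3, 3, 5, 3, 55, 33, 1, 3, 1,
  15, 31, 13, 49, 245, 1, 3, 5, 15, 31, 59, 63, 97, 1, 3, 1, 11, 11, 11,
  77, 249, 1, 3, 1, 11, 27, 43, 71, 9, 1, 1, 7, 15, 21, 11, 81, 45, 1, 3,
  7, 3, 25, 31, 65, 79, 1, 3, 1, 1, 19, 11, 3, 205, 1, 1, 5, 9, 19, 21,
  29, 157, 1, 3, 7, 11, 1, 33, 89, 185, 1, 3, 3, 3, 15, 9, 79, 71, 1, 3,
  7, 11, 15, 39, 119, 27, 1, 1, 3, 1, 11, 31, 97, 225, 1, 1, 1, 3, 23, 43,
  57, 177, 1, 3, 7, 7, 17, 17, 37, 71, 1, 3, 1, 5, 27, 63, 123, 213, 1, 1,
  3, 5, 11, 43, 53, 133, 1, 3, 5, 5, 29, 17, 47, 173, 479, 1, 3, 3, 11, 3,
  1, 109, 9, 69, 1, 1, 1, 5, 17, 39, 23, 5, 343, 1, 3, 1, 5, 25, 15, 31,
  103, 499, 1, 1, 1, 11, 11, 17, 63, 105, 183, 1, 1, 5, 11, 9, 29, 97,
  231, 363, 1, 1, 5, 15, 19, 45, 41, 7, 383, 1, 3, 7, 7, 31, 19, 83, 137,
  221, 1, 1, 1, 3, 23, 15, 111, 223, 83, 1, 1, 5, 13, 31, 15, 55, 25, 161,
  1, 1, 3, 13, 25, 47, 39, 87, 257)

.sobol_max_dim <- length(.sobol_poly)
.sobol_bits <- 30L

# direction numbers v_k (k = 1..bits) for one dimension, as integers
# scaled by 2^(bits - k)
sobol_directions <- function(dim, bits = .sobol_bits) {
  if (dim == 1) {
    return(bitwShiftL(1L, bits - seq_len(bits)))
  }
  poly <- .sobol_poly[dim]
  s <- .sobol_mlen[dim]
  off <- sum(.sobol_mlen[seq_len(dim - 1)])
  mval <- .sobol_mval[off + seq_len(s)]
  # polynomial coefficients a_1..a_{s-1} (below the leading term)
  a <- if (s > 1) as.integer(intToBits(poly))[seq(s, 2)] else integer(0)
  mm <- integer(bits)
  mm[seq_len(s)] <- mval
  if (bits > s) {
    for (k in (s + 1):bits) {
      val <- bitwXor(mm[k - s], bitwShiftL(mm[k - s], s))
      if (s > 1) {
        for (i in seq_len(s - 1)) {
          if (a[i] == 1L) {
            val <- bitwXor(val, bitwShiftL(mm[k - i], i))
          }
        }
      }
      mm[k] <- val
    }
  }
  bitwShiftL(mm, bits - seq_len(bits))
}

#' Generate points of the Sobol' low-discrepancy sequence
#'
#' Deterministic quasi-random points in the half-open unit hypercube, in
#' Gray-code order. For `n` a power of two each coordinate visits every
#' dyadic interval of width `1/n` exactly once, which is what makes
#' Saltelli designs built on this sequence converge faster than plain
#' Monte Carlo.
#'
#' @param n number of points (>= 1).
#' @param d dimension (1 to 64 with the shipped direction-number table).
#' @param skip number of initial points to drop. The sequence proper starts
#'   at the origin; callers that cannot use an all-zeros point (e.g. designs
#'   whose rows parameterize intake bounds) skip it.
#' @return An `n x d` numeric matrix with entries in `[0, 1)`.
#' @export
#' @examples
#' sobol_sequence(8, 2)
sobol_sequence <- function(n, d, skip = 0) {
  n <- assert_scalar_count(n, "n")
  d <- assert_scalar_count(d, "d")
  skip <- assert_scalar_count(skip, "skip", min = 0L)
  if (d > .sobol_max_dim) {
    abort(sprintf(
      "Direction numbers are available for up to %d dimensions (asked %d).",
      .sobol_max_dim, d), class = "fluxsens_capability_error")
  }
  total <- n + skip
  if (total >= 2^.sobol_bits) {
    abort(sprintf("n + skip must be below 2^%d.", .sobol_bits),
          class = "fluxsens_capability_error")
  }
  V <- vapply(seq_len(d), sobol_directions, integer(.sobol_bits))
  X <- matrix(0L, total, d)
  state <- integer(d)
  if (total > 1) {
    for (i in seq_len(total - 1)) {
      # Gray code: bit flipped between i-1 and i is the lowest zero bit of i-1
      c_i <- 1L
      val <- i - 1L
      while (bitwAnd(val, 1L) == 1L) {
        val <- bitwShiftR(val, 1L)
        c_i <- c_i + 1L
      }
      state <- bitwXor(state, V[c_i, ])
      X[i + 1L, ] <- state
    }
  }
  out <- X[(skip + 1):total, , drop = FALSE] / 2^.sobol_bits
  dimnames(out) <- NULL
  out
}
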