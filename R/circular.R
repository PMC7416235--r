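#' Circular signal primitives
#'
#' A "circular signal" is a numeric vector whose index is understood modulo
#' its length: element N is followed by element 1.  Spatial channel vectors
#' are closed into a ring this way so that envelope construction has no free
#' ends.  These helpers provide wrap-around extrema detection, zero-crossing
#' counting, rotation, and the end-to-end jump used to quantify end effects.
#'
#' @name circular
NULL

#' Locate strict local extrema under circular neighbours
#'
#' An index is a maximum iff its value exceeds both circular neighbours
#' (symmetrically for minima).  Plateaus — runs of equal values, possibly
#' wrapping across the seam — are resolved to their middle index (the
#' left-middle one for even-length runs), so detection commutes with
#' rotation.  A signal that is constant on the whole circle has no extrema.
#'
#' @param x numeric vector, length >= 3, interpreted circularly.
#' @return list with sorted integer vectors `maxima` and `minima`
#'   (1-based indices).
#' @examples
#' circular_extrema(c(0, 1, 0, -1))
#' @export
circular_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) stop("circular extrema need a signal of length >= 3")
  if (!all(is.finite(x))) stop("signal values must be finite")

  ## collapse plateaus: runs of circularly-adjacent equal values
  r <- rle(x)
  vals <- r$values
  lens <- r$lengths
  starts <- cumsum(c(1L, lens[-length(lens)]))
  if (length(vals) == 1L) {                      # constant signal
    return(list(maxima = integer(0), minima = integer(0)))
  }
  ## merge the wrap-around plateau (first and last run equal)
  if (vals[1L] == vals[length(vals)] && length(vals) > 1L) {
    k <- length(vals)
    starts[1L] <- starts[k] - n                  # run begins before index 1
    lens[1L] <- lens[1L] + lens[k]
    vals <- vals[-k]; lens <- lens[-k]; starts <- starts[-k]
  }
  if (length(vals) < 2L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  m <- length(vals)
  prev <- vals[c(m, seq_len(m - 1L))]
  nxt  <- vals[c(seq_len(m)[-1L], 1L)]
  ## representative index: middle of the run (left-middle on even length)
  rep_idx <- ((starts + (lens - 1L) %/% 2L) - 1L) %% n + 1L
  maxima <- rep_idx[vals > prev & vals > nxt]
  minima <- rep_idx[vals < prev & vals < nxt]
  list(maxima = sort(as.integer(maxima)), minima = sort(as.integer(minima)))
}

#' Count circular zero crossings
#'
#' Counts circularly adjacent pairs with strictly opposite signs.
#' Exact zeros are skipped: the nearest nonzero values on either side are
#' compared, so a sign change across a run of zeros counts once.  The count
#' over a full circle is always even.
#'
#' @param x numeric vector, length >= 2, interpreted circularly.
#' @return integer crossing count.
#' @export
circular_zero_crossings <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s != c(s[-1L], s[1L]))
}

#' Rotate a circular signal
#'
#' `rotate_signal(x, k)[i] == x[(i + k) mod N]`: positive `k` shifts the
#' viewing window forward along the ring.
#'
#' @param x numeric vector.
#' @param k integer shift (any sign).
#' @return rotated numeric vector of the same length.
#' @export
rotate_signal <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((as.integer(k) %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(k + 1L):n], x[1:k])
}

#' End-to-end jump of a signal
#'
#' The absolute difference between the first and last samples — the
#' discontinuity a decomposition introduces at the seam when the vector is
#' read as a ring.  Used to compare periodic-envelope against classic
#' (free-end) decompositions.
#'
#' @param x numeric vector, length >= 2.
#' @return nonnegative scalar `|x[1] - x[N]|`.
#' @export
boundary_discontinuity <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  abs(x[1L] - x[length(x)])
}
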