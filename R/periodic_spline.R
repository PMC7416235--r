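#' Periodic cubic spline interpolation
#'
#' Fits the C2-continuous periodic cubic spline through knots arranged on a
#' circle of circumference `period`.  The spline is parameterised by its
#' second derivatives at the knots (the "moments" M_j), which solve the
#' cyclic tridiagonal system
#'
#'   mu_j M_{j-1} + 2 M_j + lambda_j M_{j+1} = 6 f[t_{j-1}, t_j, t_{j+1}]
#'
#' with mu_j = h_{j-1}/(h_{j-1}+h_j), lambda_j = h_j/(h_{j-1}+h_j), gaps
#' h_j = t_{j+1} - t_j taken circularly (the wrap gap closes the ring), and
#' f the usual second divided difference.  All indices are cyclic, so the
#' closure rows couple the last knot back to the first and the interpolant
#' has continuous first and second derivatives across the seam — this is
#' what removes envelope end effects.
#'
#' @param x knot positions, strictly increasing, all in `[0, period)`.
#' @param y knot values, same length as `x`.
#' @param period circumference of the circle (positive).
#' @return an object of class `"periodic_spline"` with fields `x`, `y`,
#'   `period`, `moments`, and `h` (circular gaps).  Evaluate with
#'   [predict.periodic_spline()].
#' @examples
#' ps <- periodic_spline(0:7, cos(2 * pi * (0:7) / 8), period = 8)
#' predict(ps, seq(0, 8, by = 0.5))
#' @export
periodic_spline <- function(x, y, period) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0L) stop("at least one knot is required")
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("period must be a positive scalar")
  if (any(duplicated(x))) stop("duplicate knot positions")
  if (is.unsorted(x, strictly = TRUE)) stop("knot positions must be strictly increasing")
  if (any(x < 0 | x >= period)) stop("knot positions must lie in [0, period)")
  if (!all(is.finite(y))) stop("knot values must be finite")
  m <- length(x)

  if (m == 1L) {
    out <- list(x = x, y = y, period = period, moments = 0, h = period)
    class(out) <- "periodic_spline"
    return(out)
  }

  h <- c(diff(x), period - x[m] + x[1L])        # h[m] is the wrap gap
  ip <- c(m, seq_len(m - 1L))                   # j - 1 (cyclic)
  im <- c(seq_len(m)[-1L], 1L)                  # j + 1 (cyclic)
  hm1 <- h[ip]                                  # h_{j-1}
  mu <- hm1 / (hm1 + h)
  la <- h / (hm1 + h)
  ## second divided difference f[t_{j-1}, t_j, t_{j+1}]
  d <- 6 * ((y[im] - y) / h - (y - y[ip]) / hm1) / (hm1 + h)

  A <- matrix(0, m, m)
  idx <- seq_len(m)
  A[cbind(idx, idx)] <- A[cbind(idx, idx)] + 2
  A[cbind(idx, ip)] <- A[cbind(idx, ip)] + mu   # accumulate: for m = 2 the
  A[cbind(idx, im)] <- A[cbind(idx, im)] + la   # off-diagonals coincide
  moments <- solve(A, d)

  res <- max(abs(A %*% moments - d))
  scale <- max(1, max(abs(d)))
  if (res > 1e-10 * scale)
    stop("cyclic tridiagonal solve failed to reach residual tolerance")

  out <- list(x = x, y = y, period = period, moments = as.numeric(moments), h = h)
  class(out) <- "periodic_spline"
  out
}

#' Evaluate a periodic cubic spline
#'
#' Query positions are reduced modulo the period; evaluation at a knot
#' returns the knot value to machine precision.
#'
#' @param object a fitted [periodic_spline()].
#' @param newx numeric query positions (any real values).
#' @param ... unused.
#' @return numeric vector of spline values.
#' @export
predict.periodic_spline <- function(object, newx, ...) {
  m <- length(object$x)
  if (m == 1L) return(rep(object$y, length(newx)))
  x <- object$x; y <- object$y; M <- object$moments; h <- object$h
  P <- object$period
  ## work in offsets from the first knot so the wrap segment is the last one
  u <- (newx - x[1L]) %% P
  brk <- c(x - x[1L], P)                        # segment boundaries, length m+1
  j <- findInterval(u, brk, rightmost.closed = TRUE)
  j[j > m] <- m
  jp <- ifelse(j == m, 1L, j + 1L)              # right knot (cyclic)
  s <- u - brk[j]
  hj <- h[j]
  t1 <- M[j] * (hj - s)^3 / (6 * hj)
  t2 <- M[jp] * s^3 / (6 * hj)
  t3 <- (y[j] - M[j] * hj^2 / 6) * (hj - s) / hj
  t4 <- (y[jp] - M[jp] * hj^2 / 6) * s / hj
  as.numeric(t1 + t2 + t3 + t4)
}

#' @export
print.periodic_spline <- function(x, ...) {
  cat("Periodic cubic spline:", length(x$x), "knots on a circle of period",
      format(x$period), "\n")
  invisible(x)
}
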