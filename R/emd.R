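#' Sifting configuration
#'
#' Tolerances and caps controlling the sifting loop and the decomposition
#' stop.  A candidate is accepted as an intrinsic mode function (IMF) when
#' its circular extrema and zero-crossing counts differ by at most one AND
#' the mean of its upper/lower envelopes is negligible; sifting also stops
#' when the Cauchy criterion between successive iterates falls below
#' `sd_tol`, or after `max_sift_iters` subtractions.
#'
#' @param mean_env_tol mean-envelope amplitude threshold, relative to the
#'   candidate's peak amplitude (default 0.05).
#' @param sd_tol Cauchy sifting criterion
#'   `sum((h_prev - h_new)^2) / sum(h_prev^2)` (default 0.2).
#' @param max_sift_iters cap on envelope subtractions per IMF (default 100).
#' @param max_imfs cap on extracted IMFs (default 10).
#' @param residual_amp_tol decomposition stops once the residual's
#'   peak-to-peak amplitude falls below this fraction of the input's
#'   (default 1e-12).
#' @return a list of class `"sift_config"`.
#' @export
sift_config <- function(mean_env_tol = 0.05, sd_tol = 0.2,
                        max_sift_iters = 100L, max_imfs = 10L,
                        residual_amp_tol = 1e-12) {
  stopifnot(mean_env_tol >= 0, sd_tol >= 0, residual_amp_tol >= 0,
            max_sift_iters >= 1, max_imfs >= 1)
  structure(list(mean_env_tol = mean_env_tol, sd_tol = sd_tol,
                 max_sift_iters = as.integer(max_sift_iters),
                 max_imfs = as.integer(max_imfs),
                 residual_amp_tol = residual_amp_tol),
            class = "sift_config")
}

#' Mean of the circular upper and lower envelopes
#'
#' Fits one periodic cubic spline through the maxima and one through the
#' minima (knot positions are the extremum indices on a circle of period N)
#' and returns their pointwise average at the integer sample positions.
#' Because both envelopes satisfy periodic continuity across the seam there
#' is no end effect.
#'
#' @param x numeric vector read circularly, with at least 2 maxima and
#'   2 minima.
#' @return numeric vector, the envelope mean at positions `1..N`.
#' @export
envelope_mean_circular <- function(x) {
  n <- length(x)
  ex <- circular_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L)
    stop("too few extrema to build circular envelopes")
  pos <- seq_len(n) - 1
  up <- periodic_spline(ex$maxima - 1, x[ex$maxima], period = n)
  lo <- periodic_spline(ex$minima - 1, x[ex$minima], period = n)
  (predict(up, pos) + predict(lo, pos)) / 2
}

## non-periodic counterpart for the classic baseline: natural cubic splines
## through the extrema, no end extension -- deliberately exhibits end effects
envelope_mean_classic <- function(x) {
  n <- length(x)
  ex <- linear_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L)
    stop("too few extrema to build envelopes")
  pos <- seq_len(n)
  up <- stats::spline(ex$maxima, x[ex$maxima], xout = pos,
                      method = "natural")$y
  lo <- stats::spline(ex$minima, x[ex$minima], xout = pos,
                      method = "natural")$y
  (up + lo) / 2
}

## strict interior extrema without wrap-around (classic EMD view)
linear_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  s <- sign(d)
  ## resolve flats by carrying the previous slope forward
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(s[-1L] != s[-length(s)]) + 1L
  maxima <- idx[s[idx - 1L] > 0]
  minima <- idx[s[idx - 1L] < 0]
  list(maxima = maxima, minima = minima)
}

linear_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Test the intrinsic-mode conditions on a circular candidate
#'
#' An IMF must (1) have extrema and zero-crossing counts that differ by at
#' most one over the whole circle, and (2) have upper/lower envelopes that
#' average to (numerically) zero everywhere.
#'
#' @param x candidate vector, read circularly.
#' @param config a [sift_config()].
#' @return logical, with attribute `"diagnostics"` (extrema count,
#'   zero-crossing count, max mean-envelope amplitude).
#' @export
is_valid_imf <- function(x, config = sift_config()) {
  n_ext <- tryCatch({
    ex <- circular_extrema(x)
    length(ex$maxima) + length(ex$minima)
  }, error = function(e) NA_integer_)
  n_zc <- circular_zero_crossings(x)
  diag <- list(n_extrema = n_ext, n_zero_crossings = n_zc,
               mean_env_max = NA_real_)
  if (is.na(n_ext) || abs(n_ext - n_zc) > 1L)
    return(structure(FALSE, diagnostics = diag))
  me <- tryCatch(envelope_mean_circular(x), error = function(e) NULL)
  if (is.null(me)) return(structure(FALSE, diagnostics = diag))
  diag$mean_env_max <- max(abs(me))
  amp <- max(abs(x))
  ok <- amp == 0 || diag$mean_env_max <= config$mean_env_tol * amp
  structure(ok, diagnostics = diag)
}

## one candidate extraction: repeated mean-envelope subtraction.
## Returns the final iterate and the number of subtractions performed.
sift <- function(x, config = sift_config(), periodic = TRUE) {
  env_fun <- if (periodic) envelope_mean_circular else envelope_mean_classic
  valid_fun <- if (periodic) {
    function(h) isTRUE(as.logical(is_valid_imf(h, config)))
  } else {
    function(h) {
      ex <- linear_extrema(h)
      n_ext <- length(ex$maxima) + length(ex$minima)
      if (abs(n_ext - linear_zero_crossings(h)) > 1L) return(FALSE)
      me <- tryCatch(env_fun(h), error = function(e) NULL)
      !is.null(me) && max(abs(me)) <= config$mean_env_tol * max(abs(h))
    }
  }
  h <- x
  iters <- 0L
  while (iters < config$max_sift_iters) {
    if (valid_fun(h)) break
    m <- tryCatch(env_fun(h), error = function(e) NULL)
    if (is.null(m)) break                      # cannot refine further
    h_new <- h - m
    sd <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    iters <- iters + 1L
    if (sd < config$sd_tol) break
  }
  list(imf = h, iterations = iters)
}

emd_engine <- function(x, config, periodic) {
  n <- length(x)
  if (n < 4L) stop("decomposition needs at least 4 samples")
  if (!all(is.finite(x))) stop("signal values must be finite")
  input <- as.numeric(x)
  ptp0 <- diff(range(input))
  residual <- input
  imfs <- list()
  sift_counts <- integer(0)

  repeat {
    if (length(imfs) >= config$max_imfs) break
    if (diff(range(residual)) <= config$residual_amp_tol * max(ptp0, 1e-300))
      break
    ex <- if (periodic) circular_extrema(residual) else linear_extrema(residual)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
    s <- sift(residual, config, periodic = periodic)
    if (max(abs(s$imf)) == 0) break            # no oscillatory content left
    imfs[[length(imfs) + 1L]] <- s$imf
    sift_counts <- c(sift_counts, s$iterations)
    residual <- residual - s$imf
  }

  structure(list(
    input = input,
    imfs = if (length(imfs)) do.call(rbind, imfs) else
      matrix(numeric(0), nrow = 0, ncol = n),
    residual = residual,
    sift_counts = sift_counts,
    method = if (periodic) "circle" else "classic",
    config = config
  ), class = "emd")
}

#' Circle-EMD: empirical mode decomposition on a ring
#'
#' Decomposes a spatial signal vector, read circularly, into intrinsic mode
#' functions plus a residual:  `x = sum(IMFs) + residual` holds exactly (to
#' round-off) by construction.  Envelopes are periodic cubic splines, so no
#' end effect is introduced and the decomposition commutes with rotation of
#' the ring.  Extraction stops when the residual has fewer than two maxima
#' or two minima (the circular analogue of "monotonic or constant"), when
#' its amplitude is negligible, or when `max_imfs` is reached.
#'
#' @param x numeric vector (length >= 4), the channel sequence read as a
#'   ring in its given order.
#' @param config a [sift_config()].
#' @return an object of class `"emd"`: list with `input`, `imfs` (one row
#'   per IMF, fast to slow), `residual`, `sift_counts`, `method`, `config`.
#' @examples
#' i <- 0:255
#' x <- cos(2 * pi * 8 * i / 256) + cos(2 * pi * 2 * i / 256)
#' fit <- circle_emd(x)
#' fit
#' @export
circle_emd <- function(x, config = sift_config()) {
  emd_engine(x, config, periodic = TRUE)
}

#' Classic EMD baseline (free ends)
#'
#' Same sifting loop as [circle_emd()] but with non-periodic natural cubic
#' spline envelopes through the extrema and no data extension, so the
#' boundary distortion of conventional EMD is reproduced.  Kept as the
#' comparison baseline for end-effect studies.
#'
#' @inheritParams circle_emd
#' @return an object of class `"emd"` with `method = "classic"`.
#' @export
classic_emd <- function(x, config = sift_config()) {
  emd_engine(x, config, periodic = FALSE)
}

#' Sum selected IMFs of a decomposition
#'
#' @param fit an `"emd"` object.
#' @param which 1-based IMF indices, or `"all"` for every IMF.  The residual
#'   is never included: summing all IMFs reconstructs the input minus its
#'   residual trend.
#' @return numeric vector of the same length as the input.
#' @export
combine_imfs <- function(fit, which = "all") {
  stopifnot(inherits(fit, "emd"))
  n_imf <- nrow(fit$imfs)
  if (identical(which, "all")) which <- seq_len(n_imf)
  which <- as.integer(which)
  if (length(which) == 0L) return(rep(0, length(fit$input)))
  if (any(which < 1L | which > n_imf))
    stop("IMF selection out of range: decomposition has ", n_imf, " IMFs")
  colSums(fit$imfs[which, , drop = FALSE])
}

#' @export
print.emd <- function(x, ...) {
  cat(sprintf("%s-EMD decomposition: %d samples, %d IMFs + residual\n",
              x$method, length(x$input), nrow(x$imfs)))
  if (nrow(x$imfs))
    cat("sift iterations per IMF:", paste(x$sift_counts, collapse = ", "), "\n")
  err <- max(abs(x$input - colSums(rbind(x$imfs, x$residual))))
  cat(sprintf("max reconstruction error: %.3g\n", err))
  invisible(x)
}

#' @export
residuals.emd <- function(object, ...) object$residual

#' Plot an EMD decomposition
#'
#' Stacked panels: input on top, then each IMF, then the residual.
#'
#' @param x an `"emd"` object.
#' @param ... passed to [plot.default()].
#' @export
plot.emd <- function(x, ...) {
  k <- nrow(x$imfs)
  op <- graphics::par(mfrow = c(k + 2L, 1L), mar = c(1.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  plot(x$input, type = "l", ylab = "input", xlab = "", ...)
  for (i in seq_len(k))
    plot(x$imfs[i, ], type = "l", ylab = paste0("IMF ", i), xlab = "", ...)
  plot(x$residual, type = "l", ylab = "residual", xlab = "channel", ...)
  invisible(x)
}
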