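## Independent brute-force oracles and signal builders used across tests.

## Periodic cubic spline by direct construction: one cubic per segment,
## 4m unknowns solved from interpolation + C1 + C2 continuity (all cyclic).
## Deliberately shares no code with periodic_spline().
brute_force_periodic_spline <- function(x, y, period) {
  m <- length(x)
  stopifnot(m >= 2)
  h <- c(diff(x), period - x[m] + x[1])
  ## unknown layout: for segment j, coefficients a,b,c,d at 4*(j-1)+1..4
  A <- matrix(0, 4 * m, 4 * m)
  rhs <- numeric(4 * m)
  row <- 0
  nxt <- c(seq_len(m)[-1], 1)
  for (j in seq_len(m)) {
    cj <- 4 * (j - 1)
    ck <- 4 * (nxt[j] - 1)
    hj <- h[j]
    ## S_j(0) = y_j
    row <- row + 1; A[row, cj + 1] <- 1; rhs[row] <- y[j]
    ## S_j(h_j) = y_{j+1}
    row <- row + 1
    A[row, cj + 1:4] <- c(1, hj, hj^2, hj^3); rhs[row] <- y[nxt[j]]
    ## S_j'(h_j) = S_{j+1}'(0)
    row <- row + 1
    A[row, cj + 2:4] <- c(1, 2 * hj, 3 * hj^2); A[row, ck + 2] <- -1
    ## S_j''(h_j) = S_{j+1}''(0)
    row <- row + 1
    A[row, cj + 3:4] <- c(2, 6 * hj); A[row, ck + 3] <- -2
  }
  coef <- solve(A, rhs)
  function(q) {
    u <- (q - x[1]) %% period
    brk <- c(x - x[1], period)
    j <- findInterval(u, brk, rightmost.closed = TRUE)
    j[j > m] <- m
    s <- u - brk[j]
    cj <- 4 * (j - 1)
    coef[cj + 1] + coef[cj + 2] * s + coef[cj + 3] * s^2 + coef[cj + 4] * s^3
  }
}

## random smooth circular signal: a few integer-cycle harmonics + offset
random_circular_signal <- function(n, n_tones = 3, max_cycles = NULL,
                                   noise_sd = 0) {
  if (is.null(max_cycles)) max_cycles <- max(2, n %/% 8)
  cyc <- sample(seq_len(max_cycles), n_tones)
  comps <- lapply(cyc, function(k)
    c(k, stats::runif(1, 0.5, 2), stats::runif(1, 0, 2 * pi)))
  make_circular_tones(n, comps, offset = stats::rnorm(1),
                      noise_sd = noise_sd,
                      seed = sample.int(1e6, 1))$signal
}

reconstruction_error <- function(fit) {
  rec <- colSums(rbind(fit$imfs, fit$residual))
  max(abs(fit$input - rec)) / max(abs(fit$input), 1e-300)
}

## tiny raw study used by preprocessing unit tests (deterministic)
toy_study <- function(n_runs = 2, nv = 12, nch = 5) {
  runs <- lapply(seq_len(n_runs), function(r) {
    matrix(100 + seq_len(nv * nch) %% 7 + r, nv, nch)
  })
  conds <- lapply(seq_len(n_runs), function(r)
    c(1L, 1L, rep(2:4, length.out = nv - 4L), 1L, 1L))
  raw_study(runs, paste0("roi", seq_len(nch) %% 2 + 1), conds)
}
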