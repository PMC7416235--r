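#' Seeded multi-tone circular test signal
#'
#' Sum of exact circular harmonics (integer cycles per circle, so every
#' component is exactly periodic on the ring) plus an offset and optional
#' Gaussian noise.  Ground-truth components are returned separately so
#' recovery by the decomposition can be scored.
#'
#' @param N signal length (must be at least 4 times the fastest component).
#' @param components list of `c(cycles, amplitude, phase)` triples; cycles
#'   must be positive integers.
#' @param offset constant added to the signal (default 0).
#' @param noise_sd standard deviation of additive Gaussian noise (default 0).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return list: `signal` (numeric length N), `components` (matrix, one row
#'   per component, in the given order), `offset`.
#' @examples
#' tones <- make_circular_tones(256, list(c(8, 1, 0), c(2, 1, 0)))
#' @export
make_circular_tones <- function(N, components, offset = 0, noise_sd = 0,
                                seed = 1L) {
  stopifnot(N >= 4, length(components) >= 1)
  cyc <- vapply(components, `[`, numeric(1), 1L)
  if (any(cyc != round(cyc) | cyc < 1))
    stop("component cycles must be positive integers")
  if (N < 4 * max(cyc)) stop("N must be at least 4 x the fastest cycle count")
  i <- seq_len(N) - 1
  comp <- t(vapply(components, function(co) {
    amp <- if (length(co) >= 2) co[2L] else 1
    ph <- if (length(co) >= 3) co[3L] else 0
    amp * cos(2 * pi * co[1L] * i / N + ph)
  }, numeric(N)))
  signal <- colSums(comp) + offset
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    signal <- signal + stats::rnorm(N, sd = noise_sd)
  }
  list(signal = signal, components = comp, offset = offset)
}

#' Emulate the multi-run rock/scissors/paper study
#'
#' Generates a raw multi-run study with the canonical design: `n_runs` runs
#' of `states_per_run` volumes each, the rest states split as a block at the
#' beginning and end of every run (the acquisition breaks), and the task
#' states balanced over the classes in cycling order.  Task volumes of class
#' c add a class-specific spatial activation across the signal channels — a
#' circular harmonic of `class_pattern_frequencies[c]` cycles on top of a
#' common task offset — lagged by `hemodynamic_lag_TRs` volumes to mimic the
#' delayed hemodynamic response the preprocessing shift compensates.
#' Channels beyond `n_channels_signal` carry baseline, drift and noise only,
#' so t-value selection has something to reject.  Per-channel smooth drift
#' (random linear slope per run) and Gaussian noise are added everywhere.
#'
#' @param n_runs number of runs (default 10).
#' @param states_per_run volumes per run (default 32).
#' @param rest_states_per_run rest volumes per run, split half at the start
#'   and half at the end (default 8).
#' @param n_classes number of task classes (default 3; task states per run
#'   must divide evenly).
#' @param n_channels_raw total channels (default 300).
#' @param n_channels_signal leading channels carrying class information
#'   (default 250).
#' @param class_pattern_frequencies cycles per circle of each class's
#'   spatial harmonic (default `c(4, 10, 25)`).
#' @param class_amplitude amplitude of the class harmonic, raw signal units
#'   (default 2).
#' @param task_amplitude common task-vs-rest offset on signal channels
#'   (default 2).
#' @param drift_amplitude scale of the per-run linear drift (default 0.5).
#' @param noise_sd additive Gaussian noise SD (default 0.5).
#' @param baseline_level baseline signal level (default 100).
#' @param hemodynamic_lag_TRs lag of the activation behind the condition
#'   labels, volumes (default 1).
#' @param TR repetition time, seconds (default 5).
#' @param seed integer seed; generation is a pure function of the arguments.
#' @return list: `study` (a [raw_study()]), `truth` (list with the class
#'   patterns matrix `class_patterns` (classes x signal channels), signal
#'   channel indices, and the per-run condition codes).
#' @export
make_emulated_study <- function(n_runs = 10L, states_per_run = 32L,
                                rest_states_per_run = 8L, n_classes = 3L,
                                n_channels_raw = 300L,
                                n_channels_signal = 250L,
                                class_pattern_frequencies = c(4, 10, 25),
                                class_amplitude = 2, task_amplitude = 2,
                                drift_amplitude = 0.5, noise_sd = 0.5,
                                baseline_level = 100,
                                hemodynamic_lag_TRs = 1L, TR = 5,
                                seed = 1L) {
  task_per_run <- states_per_run - rest_states_per_run
  if (task_per_run %% n_classes != 0L)
    stop("task states per run must be divisible by the class count")
  if (length(class_pattern_frequencies) != n_classes)
    stop("one spatial frequency per class is required")
  if (n_channels_signal > n_channels_raw)
    stop("signal channels cannot exceed raw channels")
  set.seed(as.integer(seed))

  S <- n_channels_signal
  j <- seq_len(S) - 1
  class_patterns <- t(vapply(seq_len(n_classes), function(c) {
    task_amplitude + class_amplitude *
      cos(2 * pi * class_pattern_frequencies[c] * j / S)
  }, numeric(S)))

  rest_head <- ceiling(rest_states_per_run / 2)
  rest_tail <- rest_states_per_run - rest_head
  task_seq <- rep(seq_len(n_classes) + 1L, length.out = task_per_run)
  cond_run <- c(rep(1L, rest_head), task_seq, rep(1L, rest_tail))

  rois <- c("M1_RHand", "SMA_RHand", "CB_RHand",
            "M1_LHand", "SMA_LHand", "CB_LHand")
  channel_roi <- rois[ceiling(seq_len(n_channels_raw) /
                                (n_channels_raw / length(rois)))]

  runs <- vector("list", n_runs)
  conditions <- vector("list", n_runs)
  nv <- states_per_run
  lag <- as.integer(hemodynamic_lag_TRs)
  for (r in seq_len(n_runs)) {
    m <- matrix(baseline_level, nv, n_channels_raw)
    ## activation lags the condition labels by `lag` volumes
    act_cond <- c(rep(1L, lag), cond_run)[seq_len(nv)]
    for (v in seq_len(nv)) {
      if (act_cond[v] >= 2L) {
        cls <- act_cond[v] - 1L
        m[v, seq_len(S)] <- m[v, seq_len(S)] + class_patterns[cls, ]
      }
    }
    slope <- stats::rnorm(n_channels_raw)
    tc <- (seq_len(nv) - (nv + 1) / 2) / nv
    m <- m + drift_amplitude * tc %*% t(slope)
    m <- m + matrix(stats::rnorm(nv * n_channels_raw, sd = noise_sd),
                    nv, n_channels_raw)
    runs[[r]] <- m
    conditions[[r]] <- cond_run
  }

  list(study = raw_study(runs, channel_roi, conditions, TR = TR),
       truth = list(class_patterns = class_patterns,
                    signal_channels = seq_len(S),
                    conditions = cond_run))
}
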