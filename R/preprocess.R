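#' Multi-run raw study container
#'
#' Holds the raw material of a multi-run acquisition: one volumes-by-channels
#' signal matrix per run, a region-of-interest (ROI) label per channel, and a
#' condition code per volume per run.  Condition conventions follow the
#' decoding-toolbox surface: code 1 is the rest/baseline block, codes 2-4 are
#' the task classes (rock / scissors / paper).
#'
#' @param runs list of numeric matrices (volumes x channels), identical
#'   channel count and ordering across runs.
#' @param channel_roi character vector, one ROI label per channel.
#' @param conditions list of integer vectors, one condition code per volume
#'   of each run.
#' @param TR repetition time in seconds (nominal 5).
#' @return an object of class `"raw_study"`.
#' @export
raw_study <- function(runs, channel_roi, conditions, TR = 5) {
  stopifnot(is.list(runs), length(runs) >= 1L, is.list(conditions),
            length(conditions) == length(runs))
  nch <- unique(vapply(runs, ncol, integer(1)))
  if (length(nch) != 1L) stop("all runs must have the same channel count")
  if (length(channel_roi) != nch) stop("one ROI label per channel required")
  for (r in seq_along(runs)) {
    if (nrow(runs[[r]]) != length(conditions[[r]]))
      stop("run ", r, ": condition codes must cover every volume")
  }
  structure(list(runs = lapply(runs, as.matrix),
                 channel_roi = as.character(channel_roi),
                 conditions = lapply(conditions, as.integer),
                 TR = TR),
            class = "raw_study")
}

#' @export
print.raw_study <- function(x, ...) {
  cat(sprintf("raw study: %d runs x %d channels; %s volumes per run; TR = %gs\n",
              length(x$runs), ncol(x$runs[[1L]]),
              paste(unique(vapply(x$runs, nrow, integer(1))), collapse = "/"),
              x$TR))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Parameters of the standard task-state preprocessing flow: hemodynamic
#' shift, t-value channel selection, iterative outlier clipping, baseline
#' normalisation, and task-condition extraction.
#'
#' @param shift_TRs volumes to advance the signal relative to the condition
#'   labels (hemodynamic delay; default 1).
#' @param n_channels_keep number of top-t channels to retain (default 200).
#' @param tval_min minimum t statistic for a channel to be eligible
#'   (default 3.2).
#' @param outlier_std_thres clip bound in per-channel standard deviations
#'   (default 4).
#' @param outlier_iters clipping passes (default 2).
#' @param base_conds condition codes defining the normalisation baseline
#'   (default `1:4`, i.e. the whole run).
#' @param task_conds condition codes of the task classes (default `2:4`).
#' @return list of class `"preproc_config"`.
#' @export
preproc_config <- function(shift_TRs = 1L, n_channels_keep = 200L,
                           tval_min = 3.2, outlier_std_thres = 4,
                           outlier_iters = 2L, base_conds = 1:4,
                           task_conds = 2:4) {
  stopifnot(shift_TRs >= 0, n_channels_keep >= 1, outlier_std_thres > 0,
            outlier_iters >= 1, length(task_conds) >= 1)
  structure(list(shift_TRs = as.integer(shift_TRs),
                 n_channels_keep = as.integer(n_channels_keep),
                 tval_min = tval_min,
                 outlier_std_thres = outlier_std_thres,
                 outlier_iters = as.integer(outlier_iters),
                 base_conds = as.integer(base_conds),
                 task_conds = as.integer(task_conds)),
            class = "preproc_config")
}

#' Advance the signal relative to the condition labels
#'
#' Compensates the hemodynamic delay: within each run, volume `t + shift`'s
#' signal is paired with the condition code of volume `t`; the trailing
#' `shift` volumes lose their label and are dropped, so each run shortens by
#' `shift` volumes.
#'
#' @param study a [raw_study()].
#' @param shift_TRs nonnegative integer shift.
#' @return shifted `"raw_study"`.
#' @export
shift_data <- function(study, shift_TRs = 1L) {
  stopifnot(inherits(study, "raw_study"))
  s <- as.integer(shift_TRs)
  if (s == 0L) return(study)
  if (s < 0L) stop("shift must be nonnegative")
  for (r in seq_along(study$runs)) {
    nv <- nrow(study$runs[[r]])
    if (s >= nv) stop("shift of ", s, " exceeds run ", r, " length ", nv)
    study$runs[[r]] <- study$runs[[r]][(s + 1L):nv, , drop = FALSE]
    study$conditions[[r]] <- study$conditions[[r]][1:(nv - s)]
  }
  study
}

#' Keep only channels belonging to selected ROIs
#'
#' @param study a [raw_study()].
#' @param rois character vector of ROI names to keep.
#' @return filtered `"raw_study"` (original channel order preserved).
#' @export
select_roi_channels <- function(study, rois) {
  stopifnot(inherits(study, "raw_study"))
  if (length(rois) == 0L) stop("at least one ROI must be selected")
  unknown <- setdiff(rois, unique(study$channel_roi))
  if (length(unknown)) stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
  keep <- study$channel_roi %in% rois
  study$runs <- lapply(study$runs, function(m) m[, keep, drop = FALSE])
  study$channel_roi <- study$channel_roi[keep]
  study
}

#' Per-channel task-vs-baseline t statistics
#'
#' Pooled two-sample t per channel: task-condition volumes against
#' rest/baseline volumes, pooled across runs (classic pooled-variance
#' two-sample t).
#'
#' @param study a [raw_study()].
#' @param task_conds task condition codes.
#' @return numeric vector, one t value per channel.
#' @export
channel_tvalues <- function(study, task_conds = 2:4) {
  stopifnot(inherits(study, "raw_study"))
  X <- do.call(rbind, study$runs)
  cond <- unlist(study$conditions)
  task <- cond %in% task_conds
  if (!any(task)) stop("no task volumes present")
  if (all(task)) stop("no baseline volumes present")
  x1 <- X[task, , drop = FALSE]
  x0 <- X[!task, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2L, stats::var); v0 <- apply(x0, 2L, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  (m1 - m0) / (sp * sqrt(1 / n1 + 1 / n0))
}

#' Select channels by t value
#'
#' Keeps channels whose task-vs-baseline t statistic reaches `tval_min`,
#' then retains the `n_channels_keep` largest (fewer if fewer pass the
#' threshold, with a warning if none do).
#'
#' @param study a [raw_study()].
#' @param config a [preproc_config()].
#' @return list: `study` (filtered `"raw_study"`), `tvalues` (statistic per
#'   retained channel, in retained-channel order).
#' @export
select_channels_by_tvalue <- function(study, config = preproc_config()) {
  tv <- channel_tvalues(study, config$task_conds)
  eligible <- which(tv >= config$tval_min)
  if (length(eligible) == 0L)
    warning("no channel reaches the t threshold; zero channels retained")
  keep <- eligible[order(tv[eligible], decreasing = TRUE)]
  keep <- sort(utils::head(keep, config$n_channels_keep))
  study$runs <- lapply(study$runs, function(m) m[, keep, drop = FALSE])
  study$channel_roi <- study$channel_roi[keep]
  list(study = study, tvalues = tv[keep])
}

#' Iteratively clip outlying volumes
#'
#' Per channel and per run, values beyond `mean +/- std_thres * SD` are
#' clipped to the bound; mean and SD are recomputed on each of the
#' `num_its` passes.
#'
#' @param study a [raw_study()].
#' @param std_thres clip bound in standard deviations.
#' @param num_its number of passes.
#' @return clipped `"raw_study"`.
#' @export
reduce_outliers <- function(study, std_thres = 4, num_its = 2L) {
  stopifnot(inherits(study, "raw_study"), std_thres > 0, num_its >= 1)
  study$runs <- lapply(study$runs, function(m) {
    for (it in seq_len(num_its)) {
      mu <- colMeans(m)
      sd <- apply(m, 2L, stats::sd)
      hi <- rep(mu + std_thres * sd, each = nrow(m))
      lo <- rep(mu - std_thres * sd, each = nrow(m))
      m <- pmin(pmax(m, lo), hi)
    }
    m
  })
  study
}

#' Remove per-run linear trends
#'
#' Per channel and per run, the least-squares linear trend (slope and
#' intercept) is removed and the run mean re-added, so baseline levels stay
#' meaningful for the subsequent percent-change normalisation.  A pure ramp
#' becomes its constant mean; the operation is idempotent.
#'
#' @param study a [raw_study()].
#' @return detrended `"raw_study"`.
#' @export
detrend_runs <- function(study) {
  stopifnot(inherits(study, "raw_study"))
  study$runs <- lapply(study$runs, function(m) {
    nv <- nrow(m)
    if (nv < 3L) stop("detrending needs runs of length >= 3")
    t <- seq_len(nv)
    tc <- t - mean(t)
    slope <- crossprod(tc, m) / sum(tc^2)      # 1 x channels
    m - tc %*% slope
  })
  study
}

#' Percent-signal-change normalisation against a baseline
#'
#' Per channel and per run, `x -> 100 * (x - b) / b` where `b` is the mean
#' over the baseline-condition volumes of that run.
#'
#' @param study a [raw_study()].
#' @param base_conds condition codes defining the baseline.
#' @return normalised `"raw_study"`.
#' @export
normalize_by_baseline <- function(study, base_conds = 1:4) {
  stopifnot(inherits(study, "raw_study"))
  for (r in seq_along(study$runs)) {
    sel <- study$conditions[[r]] %in% base_conds
    if (!any(sel)) stop("run ", r, ": no baseline volumes for conditions ",
                        paste(base_conds, collapse = ","))
    b <- colMeans(study$runs[[r]][sel, , drop = FALSE])
    if (any(abs(b) < .Machine$double.eps * 100))
      stop("run ", r, ": degenerate (zero) baseline mean in some channel")
    study$runs[[r]] <- 100 * sweep(sweep(study$runs[[r]], 2L, b), 2L, b, "/")
  }
  study
}

#' Extract task-condition samples
#'
#' Keeps only task-condition volumes, each becoming one sample, with its
#' class label (factor rock/scissors/paper for codes 2/3/4), run id and
#' condition code.
#'
#' @param study a [raw_study()].
#' @param task_conds task condition codes.
#' @return a `"study_dataset"`: list with `samples` (samples x channels
#'   matrix), `labels` (factor), `run_id` (integer), `condition` (integer),
#'   `channel_roi`.
#' @export
select_task_conditions <- function(study, task_conds = 2:4) {
  stopifnot(inherits(study, "raw_study"))
  rows <- list(); labs <- integer(0); runs <- integer(0)
  for (r in seq_along(study$runs)) {
    sel <- which(study$conditions[[r]] %in% task_conds)
    if (length(sel)) {
      rows[[length(rows) + 1L]] <- study$runs[[r]][sel, , drop = FALSE]
      labs <- c(labs, study$conditions[[r]][sel])
      runs <- c(runs, rep(r, length(sel)))
    }
  }
  if (length(rows) == 0L) stop("no task-condition volumes present")
  class_names <- c(`2` = "rock", `3` = "scissors", `4` = "paper")
  lab <- factor(unname(class_names[as.character(labs)]),
                levels = c("rock", "scissors", "paper"))
  if (anyNA(lab)) lab <- factor(paste0("class", labs))
  structure(list(samples = do.call(rbind, rows), labels = lab,
                 run_id = runs, condition = labs,
                 channel_roi = study$channel_roi),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study dataset: %d samples x %d channels; classes: %s\n",
              nrow(x$samples), ncol(x$samples),
              paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Z-score each sample across channels
#'
#' Every sample vector is centred and scaled along the spatial dimension
#' (population SD, i.e. divide by n), so each row has mean 0 and SD 1.
#'
#' @param dataset a `"study_dataset"`.
#' @return the dataset with z-scored samples.
#' @export
znorm_spatial <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  m <- dataset$samples
  if (ncol(m) < 2L) stop("spatial z-scoring needs at least 2 channels")
  mu <- rowMeans(m)
  ctr <- m - mu
  sd_pop <- sqrt(rowMeans(ctr^2))
  if (any(sd_pop == 0)) stop("zero-variance sample cannot be z-scored")
  dataset$samples <- ctr / sd_pop
  dataset
}

#' Full task-state preprocessing pipeline
#'
#' Runs the standard flow in order: hemodynamic shift, ROI selection,
#' t-value channel selection, iterative outlier clipping, per-run linear
#' detrending, percent-change baseline normalisation, spatial z-scoring,
#' and task-condition extraction.  (Spatial z-scoring acts on each volume
#' independently, so applying it after task-condition extraction is
#' equivalent to applying it before.)  On the emulated 10-run design this
#' yields 240 samples x 200 channels with balanced 80/80/80 classes.
#'
#' @param study a [raw_study()].
#' @param config a [preproc_config()].
#' @param rois ROI names to keep (default: all present).
#' @return a `"study_dataset"`, with the per-channel t statistics of the
#'   retained channels in attribute `"tvalues"`.
#' @export
preprocess_study <- function(study, config = preproc_config(),
                             rois = unique(study$channel_roi)) {
  study <- shift_data(study, config$shift_TRs)
  study <- select_roi_channels(study, rois)
  sel <- select_channels_by_tvalue(study, config)
  study <- sel$study
  study <- reduce_outliers(study, config$outlier_std_thres, config$outlier_iters)
  study <- detrend_runs(study)
  study <- normalize_by_baseline(study, config$base_conds)
  dataset <- select_task_conditions(study, config$task_conds)
  dataset <- znorm_spatial(dataset)
  attr(dataset, "tvalues") <- sel$tvalues
  dataset
}
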