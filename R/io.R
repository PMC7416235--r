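#' Study directory I/O
#'
#' A study directory holds delimited text only: one `run_XX.csv` signal
#' matrix per run (volumes x channels, header row of channel names), a
#' `labels.csv` table (`run, volume, condition`; 0-based volume indices) and
#' a `channels.csv` table (`channel, roi`; 0-based channel indices).  Floats
#' are written with 17 significant digits so round trips are bit-exact.
#'
#' @param study a [raw_study()].
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "raw_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nch <- ncol(study$runs[[1L]])
  ch_names <- sprintf("ch%03d", seq_len(nch) - 1L)
  for (r in seq_along(study$runs)) {
    write_matrix(study$runs[[r]], file.path(dir, sprintf("run_%02d.csv", r)),
                 col_names = ch_names)
  }
  labels <- do.call(rbind, lapply(seq_along(study$conditions), function(r) {
    data.frame(run = r - 1L,
               volume = seq_along(study$conditions[[r]]) - 1L,
               condition = study$conditions[[r]])
  }))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  chans <- data.frame(channel = seq_len(nch) - 1L, roi = study$channel_roi)
  utils::write.csv(chans, file.path(dir, "channels.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(sprintf("TR,%g", study$TR), file.path(dir, "meta.csv"))
  invisible(dir)
}

#' @rdname write_study
#' @param dir directory written by [write_study()].
#' @export
read_study <- function(dir) {
  run_files <- sort(list.files(dir, pattern = "^run_[0-9]+\\.csv$",
                               full.names = TRUE))
  if (length(run_files) == 0L) stop("no run_XX.csv files in ", dir)
  runs <- lapply(run_files, read_matrix)
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  chans <- utils::read.csv(file.path(dir, "channels.csv"))
  conditions <- lapply(sort(unique(labels$run)), function(r) {
    sub <- labels[labels$run == r, ]
    sub$condition[order(sub$volume)]
  })
  TR <- 5
  meta_path <- file.path(dir, "meta.csv")
  if (file.exists(meta_path)) {
    meta <- strsplit(readLines(meta_path)[1L], ",")[[1L]]
    TR <- as.numeric(meta[2L])
  }
  raw_study(runs, chans$roi, conditions, TR = TR)
}

#' Delimited numeric matrix I/O with full-precision floats
#'
#' @param m numeric matrix.
#' @param path output file.
#' @param col_names header names (default `V1..Vk`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, col_names = NULL) {
  if (is.null(col_names)) col_names <- paste0("V", seq_len(ncol(m)))
  txt <- apply(m, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(c(paste(col_names, collapse = ","), txt), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(lines[1L]))
    stop("empty or malformed matrix file: ", path)
  body <- lines[-1L]
  if (length(body) == 0L) stop("matrix file has a header but no rows: ", path)
  ncol <- length(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  out <- matrix(NA_real_, length(body), ncol)
  for (i in seq_along(body)) {
    vals <- suppressWarnings(
      as.numeric(strsplit(body[i], ",", fixed = TRUE)[[1L]]))
    if (length(vals) != ncol || anyNA(vals))
      stop("parse error in ", path, " at line ", i + 1L)
    out[i, ] <- vals
  }
  out
}
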