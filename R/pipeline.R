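#' Decompose every row of a sample matrix to files
#'
#' Reads a delimited sample matrix (header row; one spatial channel vector
#' per row), decomposes each row, and writes one IMF matrix per sample
#' (rows: IMF_1..IMF_n then the residual) plus a summary table with the IMF
#' count, sift iteration counts and per-IMF boundary discontinuities.
#'
#' @param input path to a delimited sample matrix, or a numeric matrix.
#' @param outdir output directory (created if needed).
#' @param method `"circle"` (periodic envelopes) or `"classic"` (free ends).
#' @param config a [sift_config()].
#' @return path of the summary file, invisibly.
#' @export
run_decompose <- function(input, outdir, method = c("circle", "classic"),
                          config = sift_config()) {
  method <- match.arg(method)
  X <- if (is.character(input)) read_matrix(input) else as.matrix(input)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  decomp <- if (method == "circle") circle_emd else classic_emd
  summary_rows <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    fit <- decomp(X[i, ], config)
    m <- rbind(fit$imfs, fit$residual)
    rn <- c(sprintf("IMF_%d", seq_len(nrow(fit$imfs))), "residual")
    path <- file.path(outdir, sprintf("sample_%04d_imfs.csv", i))
    write_matrix(m, path, col_names = sprintf("ch%03d", seq_len(ncol(m)) - 1L))
    writeLines(c("component", rn),
               file.path(outdir, sprintf("sample_%04d_components.csv", i)))
    bd <- if (nrow(fit$imfs)) mean(apply(fit$imfs, 1L, boundary_discontinuity))
          else NA_real_
    summary_rows[[i]] <- data.frame(
      sample = i - 1L, n_imfs = nrow(fit$imfs),
      sift_iters = paste(fit$sift_counts, collapse = "+"),
      mean_boundary_discontinuity = bd)
  }
  sm <- do.call(rbind, summary_rows)
  sm_path <- file.path(outdir, "decomposition_summary.csv")
  utils::write.csv(sm, sm_path, row.names = FALSE, quote = FALSE)
  invisible(sm_path)
}

#' End-to-end pipeline: preprocess, decompose, cross-validate
#'
#' Runs the full workflow on a study directory: Table-style preprocessing to
#' the task-state sample matrix, feature construction for each requested
#' mode, and run-wise cross-validation for each requested classifier.
#' Writes per-(feature, classifier) report files (per-fold accuracies,
#' pooled confusion matrix, weighted metrics) and returns the reports.
#'
#' @param study_dir directory in the layout written by [write_study()], or a
#'   [raw_study()] object.
#' @param outdir output directory for report files (`NULL` to skip writing).
#' @param feature_modes character vector: `"original"`, `"all_imfs"`,
#'   `"imf:K"` (single IMF) or `"imfsum:1+2"` (IMF combination).
#' @param classifiers character vector among `"svm_rbf"`, `"logistic"`,
#'   `"mlp"`.
#' @param preproc a [preproc_config()].
#' @param sift a [sift_config()].
#' @param seed integer seed passed to every classifier.
#' @param mlp_epochs training epochs for the network classifier.
#' @return named list of `"cv_report"` objects, one per
#'   (feature mode x classifier) pair, named `"<mode>|<classifier>"`.
#' @export
run_pipeline <- function(study_dir, outdir = NULL,
                         feature_modes = c("original", "all_imfs"),
                         classifiers = c("svm_rbf", "logistic"),
                         preproc = preproc_config(), sift = sift_config(),
                         seed = 1L, mlp_epochs = 200L) {
  study <- if (inherits(study_dir, "raw_study")) study_dir else
    read_study(study_dir)
  dataset <- preprocess_study(study, preproc)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  reports <- list()
  for (fm in feature_modes) {
    feats <- parse_feature_mode(fm, dataset, sift)
    for (cl in classifiers) {
      spec <- classifier_spec(cl, seed = seed, mlp_epochs = mlp_epochs)
      rep <- run_cross_validation(feats, dataset$labels, dataset$run_id, spec)
      key <- paste(fm, cl, sep = "|")
      reports[[key]] <- rep
      if (!is.null(outdir)) write_cv_report(rep, outdir, fm, cl)
    }
  }
  reports
}

parse_feature_mode <- function(fm, dataset, sift) {
  if (fm == "original") return(build_features(dataset, "original"))
  if (fm == "all_imfs" || fm == "all-imfs")
    return(build_features(dataset, "all_imfs", config = sift))
  if (grepl("^imf:[0-9]+$", fm))
    return(build_features(dataset, "imf",
                          which = as.integer(sub("^imf:", "", fm)),
                          config = sift))
  if (grepl("^imfsum:[0-9+]+$", fm)) {
    idx <- as.integer(strsplit(sub("^imfsum:", "", fm), "+", fixed = TRUE)[[1L]])
    return(build_features(dataset, "imf_sum", which = idx, config = sift))
  }
  stop("unknown feature mode: ", fm)
}

write_cv_report <- function(rep, outdir, feature_mode, classifier) {
  stem <- file.path(outdir, sprintf("cv_%s_%s", gsub("[^a-z0-9]+", "-",
                                                     feature_mode), classifier))
  folds <- data.frame(fold = names(rep$per_fold_accuracy),
                      accuracy = sprintf("%.17g", rep$per_fold_accuracy))
  utils::write.csv(folds, paste0(stem, "_folds.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame.matrix(rep$confusion),
                   paste0(stem, "_confusion.csv"), quote = FALSE)
  summ <- data.frame(metric = c("mean_accuracy", "precision", "recall", "f1"),
                     value = sprintf("%.17g", c(rep$mean_accuracy,
                                                rep$precision, rep$recall,
                                                rep$f1)))
  utils::write.csv(summ, paste0(stem, "_summary.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(stem)
}

#' Write an emulated study fixture directory
#'
#' Materialises a complete synthetic study (see [make_emulated_study()]) as
#' the delimited files [read_study()] consumes.
#'
#' @param dir target directory.
#' @param ... passed to [make_emulated_study()].
#' @return `dir`, invisibly.
#' @export
simulate_study_dir <- function(dir, ...) {
  sim <- make_emulated_study(...)
  write_study(sim$study, dir)
  invisible(dir)
}
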