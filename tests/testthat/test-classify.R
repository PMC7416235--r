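make_separable <- function(n_per = 30, d = 12, sd = 0.3, seed = 61) {
  set.seed(seed)
  mu <- rbind(c(rep(3, d / 2), rep(0, d / 2)),
              c(rep(0, d / 2), rep(3, d / 2)),
              rep(1.5, d))
  x <- do.call(rbind, lapply(1:3, function(c)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(mu[c, ], n_per, d, byrow = TRUE)))
  list(x = x,
       y = factor(rep(c("rock", "scissors", "paper"), each = n_per),
                  levels = c("rock", "scissors", "paper")),
       run = rep(rep(1:5, length.out = n_per), 3))
}

test_that("feature modes respect the decomposition identity", {
  set.seed(62)
  X <- t(replicate(6, random_circular_signal(64)))
  ds <- structure(list(samples = X,
                       labels = factor(rep(c("rock", "scissors", "paper"), 2)),
                       run_id = rep(1:2, each = 3), condition = rep(2:4, 2),
                       channel_roi = rep("a", 64)),
                  class = "study_dataset")
  f_all <- build_features(ds, "all_imfs")
  for (i in 1:6) {
    fit <- circle_emd(X[i, ])
    expect_equal(f_all[i, ], X[i, ] - fit$residual, tolerance = 1e-10)
  }
  f1 <- build_features(ds, "imf", which = 1)
  expect_equal(f1[1, ], circle_emd(X[1, ])$imfs[1, ], tolerance = 1e-12)
  f12 <- build_features(ds, "imf_sum", which = c(1, 2))
  fit1 <- circle_emd(X[1, ])
  expect_equal(f12[1, ], colSums(fit1$imfs[1:2, ]), tolerance = 1e-12)
  ## dimension never changes with the mode
  expect_equal(dim(f_all), dim(X))
  expect_equal(dim(f1), dim(X))
  ## a missing IMF index contributes zeros
  suppressMessages(f9 <- build_features(ds, "imf", which = 9))
  expect_true(all(f9 == 0))
  expect_equal(attr(f9, "n_missing"), 6L)
})

test_that("a high-frequency class pattern survives in the first IMF", {
  i <- 0:199
  pattern <- cos(2 * pi * 40 * i / 200)
  x <- pattern + 0.3 * cos(2 * pi * 3 * i / 200) + 0.5
  fit <- circle_emd(x)
  expect_gt(cor(fit$imfs[1, ], pattern), 0.9)
})

test_that("RBF kernel facts hold for the fitted SVM", {
  d <- 12
  rbf <- function(a, b) exp(-sum((a - b)^2) / d)   # 1/(2 sigma^2) = 1/d
  set.seed(63)
  a <- rnorm(d); b <- rnorm(d)
  expect_equal(rbf(a, a), 1)
  expect_equal(rbf(a, b), rbf(b, a))
  expect_true(rbf(a, b) > 0 && rbf(a, b) <= 1)
  dat <- make_separable()
  m <- train_svm_rbf(dat$x, dat$y)
  expect_equal(m$gamma, 1 / ncol(dat$x))
  expect_gt(mean(predict(m, dat$x) == dat$y), 0.95)
})

test_that("logistic separates a one-dimensional toy problem", {
  x <- matrix(c(-1, -1.1, 1, 1.1), ncol = 1)
  y <- factor(c("A", "A", "B", "B"))
  set.seed(64)
  m <- train_logistic(x, y)
  expect_equal(as.character(predict(m, newdata = data.frame(V1 = c(-2, 2)))),
               c("A", "B"))
  expect_error(train_logistic(x, factor(rep("A", 4))), "single class")
})

test_that("network training reduces the loss and predicts deterministically", {
  dat <- make_separable(n_per = 20)
  m <- train_mlp(dat$x, dat$y, hidden = c(32, 16), epochs = 80,
                 dropout = 0.2, seed = 5)
  expect_lt(m$epoch_loss[80], m$epoch_loss[1])
  p1 <- predict(m, dat$x)
  p2 <- predict(m, dat$x)
  expect_identical(p1, p2)
  expect_gt(mean(p1 == dat$y), 0.9)
  ## bit-reproducible retraining under the same seed
  m2 <- train_mlp(dat$x, dat$y, hidden = c(32, 16), epochs = 80,
                  dropout = 0.2, seed = 5)
  expect_identical(m$net$out$W, m2$net$out$W)
})

test_that("metric arithmetic: identity, uniform and degenerate confusions", {
  id <- diag(c(80, 80, 80))
  m <- compute_metrics(id)
  expect_equal(c(m$accuracy, m$precision, m$recall, m$f1), rep(1, 4))

  unif <- matrix(80 / 3, 3, 3)
  mu <- compute_metrics(unif)
  expect_equal(c(mu$accuracy, mu$precision, mu$recall, mu$f1), rep(1 / 3, 4))

  ## a never-predicted class contributes zero precision, with a warning
  conf <- rbind(c(5, 0, 5), c(2, 0, 8), c(0, 0, 10))
  expect_warning(md <- compute_metrics(conf), "never predicted")
  expect_equal(md$per_class$precision[2], 0)
  expect_error(compute_metrics(matrix(0, 3, 3)), "all zero")
})

test_that("cross-validation folds are run-disjoint with the 216/24 split", {
  sim <- make_emulated_study(seed = 13)
  ds <- preprocess_study(sim$study)
  expect_equal(as.vector(table(ds$run_id)), rep(24L, 10))
  ## per fold: 216 train / 24 test by construction of run-wise folds
  for (r in unique(ds$run_id)) {
    expect_equal(sum(ds$run_id == r), 24)
    expect_equal(sum(ds$run_id != r), 216)
  }
})

test_that("separable classes are recovered by every classifier kind", {
  dat <- make_separable()
  for (kind in c("svm_rbf", "logistic")) {
    rep <- run_cross_validation(dat$x, dat$y, dat$run,
                                classifier_spec(kind, seed = 2))
    expect_gte(rep$mean_accuracy, 0.95)
    ## balanced pooled folds: weighted recall == pooled accuracy
    expect_equal(rep$recall, sum(diag(rep$confusion)) / sum(rep$confusion),
                 tolerance = 1e-10)
    expect_equal(sum(rep$confusion), length(dat$y))
  }
  repm <- run_cross_validation(dat$x, dat$y, dat$run,
                               classifier_spec("mlp", seed = 2,
                                               mlp_hidden = c(32, 16),
                                               mlp_epochs = 80,
                                               mlp_dropout = 0.2))
  expect_gte(repm$mean_accuracy, 0.95)
})

test_that("permuted labels drop SVM accuracy to chance", {
  dat <- make_separable(n_per = 40)
  set.seed(65)
  yperm <- sample(dat$y)
  rep <- run_cross_validation(dat$x, yperm, dat$run,
                              classifier_spec("svm_rbf", seed = 2))
  se <- sqrt((1 / 3) * (2 / 3) / length(yperm))
  expect_lt(abs(rep$mean_accuracy - 1 / 3), 3 * se + 1e-12)
})

test_that("cross-validation is reproducible under a fixed seed", {
  dat <- make_separable(n_per = 15)
  r1 <- run_cross_validation(dat$x, dat$y, dat$run,
                             classifier_spec("logistic", seed = 7))
  r2 <- run_cross_validation(dat$x, dat$y, dat$run,
                             classifier_spec("logistic", seed = 7))
  expect_identical(r1$per_fold_accuracy, r2$per_fold_accuracy)
  expect_identical(r1$confusion, r2$confusion)
})
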