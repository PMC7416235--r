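test_that("hemodynamic shift pairs advanced signal with earlier labels", {
  runs <- list(matrix(1:15, 5, 3))             # volume v has value v in col 1
  st <- raw_study(runs, rep("r1", 3), list(c(1L, 2L, 3L, 4L, 1L)))
  sh <- shift_data(st, 1)
  expect_equal(nrow(sh$runs[[1]]), 4)
  expect_equal(sh$runs[[1]][, 1], 2:5)         # signal advanced by one volume
  expect_equal(sh$conditions[[1]], c(1L, 2L, 3L, 4L))
  expect_identical(shift_data(st, 0), st)
  expect_error(shift_data(st, 5), "exceeds")
})

test_that("ROI selection keeps order and validates names", {
  st <- toy_study()
  all_sel <- select_roi_channels(st, unique(st$channel_roi))
  expect_identical(all_sel$runs, st$runs)
  one <- select_roi_channels(st, "roi1")
  expect_true(all(one$channel_roi == "roi1"))
  expect_identical(one$runs[[1]],
                   st$runs[[1]][, st$channel_roi == "roi1", drop = FALSE])
  expect_error(select_roi_channels(st, "nope"), "unknown ROI")
  expect_error(select_roi_channels(st, character(0)), "at least one")
})

test_that("t-value selection ranks by the pooled two-sample statistic", {
  set.seed(51)
  nv <- 40
  cond <- rep(c(1L, 2L, 3L, 4L, 1L), each = 8)
  ## channel 1: huge effect, tiny variance; channel 2: moderate; channel 3: none
  task <- cond >= 2
  mk <- function(effect, sd) 100 + effect * task + rnorm(nv, sd = sd)
  runs <- list(cbind(mk(5, 0.05), mk(2, 1), mk(0, 1)))
  st <- raw_study(runs, paste0("r", 1:3), list(cond))
  tv <- channel_tvalues(st, 2:4)
  ## hand-computed pooled t for channel 1
  x1 <- st$runs[[1]][task, 1]; x0 <- st$runs[[1]][!task, 1]
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
               (nv - 2))
  expect_equal(tv[1], (mean(x1) - mean(x0)) /
                 (sp * sqrt(1 / length(x1) + 1 / length(x0))),
               tolerance = 1e-12)
  expect_true(which.max(tv) == 1)

  sel <- select_channels_by_tvalue(st, preproc_config(n_channels_keep = 2))
  expect_equal(ncol(sel$study$runs[[1]]), 2)
  expect_equal(sel$study$runs[[1]], st$runs[[1]][, 1:2])

  expect_warning(
    select_channels_by_tvalue(st, preproc_config(tval_min = 1e6)),
    "zero channels")
})

test_that("more channels pass the threshold than are kept: top-N wins", {
  sim <- make_emulated_study(seed = 3)
  st <- shift_data(sim$study, 1)
  tv <- channel_tvalues(st, 2:4)
  expect_gt(sum(tv >= 3.2), 200)
  sel <- select_channels_by_tvalue(st, preproc_config())
  expect_equal(ncol(sel$study$runs[[1]]), 200)
  expect_true(all(sel$tvalues >= sort(tv, decreasing = TRUE)[200]))
})

test_that("outlier clipping tightens iteratively and never expands the range", {
  set.seed(52)
  base <- rnorm(20)
  ch <- c(base[1:19], 10 * sd(base))            # a single large spike
  st <- raw_study(list(matrix(ch, 20, 1)), "r1",
                  list(rep(c(1L, 2L), 10)))
  ## hand-computed two-pass clipping
  expect_hand <- ch
  for (p in 1:2) {
    mu <- mean(expect_hand); s <- sd(expect_hand)
    expect_hand <- pmin(pmax(expect_hand, mu - 4 * s), mu + 4 * s)
  }
  out <- reduce_outliers(st, 4, 2)
  expect_equal(out$runs[[1]][, 1], expect_hand, tolerance = 1e-12)
  expect_lte(diff(range(out$runs[[1]])), diff(range(ch)))

  clean <- raw_study(list(matrix(rnorm(20), 20, 1)), "r1",
                     list(rep(c(1L, 2L), 10)))
  expect_equal(reduce_outliers(clean, 4, 2)$runs, clean$runs)
})

test_that("detrending removes ramps, keeps means, and is idempotent", {
  nv <- 20
  t <- seq_len(nv)
  ramp <- 3 + 0.5 * t
  harm <- sin(2 * pi * t / 10)
  st <- raw_study(list(cbind(ramp, ramp + harm)), c("r1", "r1"),
                  list(rep(c(1L, 2L), nv / 2)))
  de <- detrend_runs(st)
  expect_equal(de$runs[[1]][, 1], rep(mean(ramp), nv), tolerance = 1e-10)
  ## least-squares oracle for the ramp+harmonic channel
  fitted <- lm(I(ramp + harm) ~ t)
  oracle <- residuals(fitted) + mean(ramp + harm)
  expect_equal(de$runs[[1]][, 2], unname(oracle), tolerance = 1e-10)
  expect_equal(detrend_runs(de)$runs[[1]], de$runs[[1]], tolerance = 1e-10)
})

test_that("baseline normalisation gives percent change and scale invariance", {
  nv <- 8
  cond <- c(1L, 1L, 2L, 3L, 4L, 2L, 1L, 1L)
  x <- c(10, 10, 11, 12, 9, 10, 10, 10)
  st <- raw_study(list(cbind(x, 3 * x)), c("a", "a"), list(cond))
  nb <- normalize_by_baseline(st, base_conds = 1L)
  b <- mean(x[cond == 1])
  expect_equal(nb$runs[[1]][, 1], 100 * (x - b) / b)
  expect_equal(nb$runs[[1]][, 2], nb$runs[[1]][, 1], tolerance = 1e-12)
  expect_equal(unname(nb$runs[[1]][3, 1]), 10,
               tolerance = 1e-12)                # 11 vs baseline 10 -> +10%

  zero <- raw_study(list(matrix(0, 4, 1)), "a", list(rep(1L, 4)))
  expect_error(normalize_by_baseline(zero, 1L), "degenerate")
})

test_that("spatial z-scoring uses the population-SD convention", {
  ds <- structure(list(samples = rbind(c(1, 3), c(2, 8)),
                       labels = factor(c("rock", "paper")),
                       run_id = c(1L, 1L), condition = c(2L, 4L),
                       channel_roi = c("a", "b")),
                  class = "study_dataset")
  z <- znorm_spatial(ds)
  expect_equal(z$samples[1, ], c(-1, 1))
  expect_equal(rowMeans(z$samples), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z$samples^2)), c(1, 1), tolerance = 1e-12)

  const <- ds; const$samples <- rbind(c(2, 2), c(1, 5))
  expect_error(znorm_spatial(const), "zero-variance")
})

test_that("task-condition extraction yields the balanced sample table", {
  sim <- make_emulated_study(seed = 5)
  st <- shift_data(sim$study, 1)
  ds <- select_task_conditions(st, 2:4)
  expect_equal(nrow(ds$samples), 240)
  expect_equal(as.vector(table(ds$labels)), rep(80L, 3))
  expect_equal(length(unique(ds$run_id)), 10)
  ## selecting every condition returns every state
  all_states <- select_task_conditions(st, 1:4)
  expect_equal(nrow(all_states$samples),
               sum(vapply(st$runs, nrow, integer(1))))
})

test_that("full pipeline meets the 240 x 200 shape contract", {
  sim <- make_emulated_study(seed = 9)
  ds <- preprocess_study(sim$study)
  expect_equal(dim(ds$samples), c(240L, 200L))
  expect_equal(as.vector(table(ds$labels)), rep(80L, 3))
  expect_equal(rowMeans(ds$samples), rep(0, 240), tolerance = 1e-10)
  expect_equal(length(attr(ds, "tvalues")), 200)
})
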