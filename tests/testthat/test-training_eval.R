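test_that("confusion-matrix metrics follow the textbook formulas", {
  m <- confusion_metrics(matrix(c(8, 4, 2, 6), 2))   # rows truth
  expect_equal(m$sensitivity, c(0.8, 0.6))
  expect_equal(m$balanced_accuracy, 0.7)
  expect_equal(m$precision, c(8 / 12, 6 / 8))
  expect_equal(m$accuracy, 14 / 20)
  # perfect predictions
  p <- confusion_metrics(diag(c(5, 3, 2)))
  expect_equal(p$accuracy, 1)
  expect_equal(p$balanced_accuracy, 1)
  expect_equal(p$precision, rep(1, 3))
  expect_equal(p$sensitivity, rep(1, 3))
})

test_that("balanced accuracy is macro-averaged sensitivity on random matrices", {
  set.seed(41)
  for (rep in 1:20) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 4), C)
    cm[cbind(1:C, 1:C)] <- cm[cbind(1:C, 1:C)] + 1  # nonzero support
    m <- confusion_metrics(cm)
    expect_equal(m$balanced_accuracy,
                 mean(diag(cm) / rowSums(cm)))
  }
})

test_that("eval reports flag classes that receive no predictions", {
  r <- eval_report(truth = c(1, 1, 2, 2), predicted = c(1, 1, 1, 1),
                   classes = c(1, 2))
  expect_true(r$undefined_precision[2])
  expect_equal(r$precision[2], 0)
  # a single-class test set: balanced accuracy is that class's sensitivity
  r1 <- eval_report(truth = rep(1, 6), predicted = c(1, 1, 1, 2, 2, 1),
                    classes = c(1, 2))
  expect_equal(r1$balanced_accuracy, unname(r1$sensitivity[1]))
  expect_equal(r1$balanced_accuracy, 4 / 6)
})

test_that("training reduces the loss on a small task (median over seeds)", {
  samples <- tiny_band_task(n_per = 16, seed = 50)
  first <- numeric(3); last <- numeric(3)
  for (s in 1:3) {
    fit <- ebdl(samples, n_filters = 2, encoder = tiny_encoder(),
                epochs = 3, batch_size = 16, lr_encoder = 3e-3,
                lr_proxies = 3e-3, seed = s)
    first[s] <- fit$history$loss[1]
    last[s] <- fit$history$loss[3]
  }
  expect_lt(median(last), median(first))
})

test_that("a zero filter learning rate freezes mu and sigma", {
  samples <- tiny_band_task(n_per = 12, seed = 51)
  fit <- ebdl(samples, n_filters = 3, encoder = tiny_encoder(),
              epochs = 2, batch_size = 12, lr_encoder = 3e-3,
              lr_filters = 0, seed = 1)
  init <- init_filter_bank(3, fit$freq_axis)
  expect_equal(fit$filters$mu, init$mu)
  expect_equal(fit$filters$sigma, init$sigma)
})

test_that("fits are deterministic under a fixed seed", {
  samples <- tiny_band_task(n_per = 12, seed = 52)
  f1 <- ebdl(samples, n_filters = 2, encoder = tiny_encoder(),
             epochs = 2, batch_size = 12, seed = 77)
  f2 <- ebdl(samples, n_filters = 2, encoder = tiny_encoder(),
             epochs = 2, batch_size = 12, seed = 77)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$encoder$params, f2$encoder$params)
  expect_identical(unclass(f1$proxies), unclass(f2$proxies))
  expect_identical(f1$history, f2$history)
})

test_that("the fitted object exposes the standard S3 surface", {
  samples <- tiny_band_task(n_per = 12, seed = 53)
  split <- split_dataset(samples, c(6, 2, 2), seed = 1)
  fit <- ebdl(split$train, val = split$validation, n_filters = 2,
              encoder = tiny_encoder(), epochs = 2, batch_size = 8,
              lr_encoder = 3e-3, seed = 5)
  expect_s3_class(fit, "ebdl")
  co <- coef(fit)
  expect_identical(dim(co), c(2L, 2L))
  expect_identical(colnames(co), c("mu", "sigma"))
  expect_output(print(fit), "sub-band filters")
  expect_output(print(summary(fit)), "training loss")
  pred <- predict(fit, split$test)
  expect_length(pred, length(split$test))
  expect_true(all(pred %in% fit$classes))
  emb <- predict(fit, split$test[1:2], type = "embedding")
  expect_length(emb, 2L)
  expect_equal(sqrt(rowSums(emb[[1]]^2)), rep(1, 2), tolerance = 1e-6)
  ev <- evaluate(fit, split$test)
  expect_s3_class(ev, "ebdl_eval")
  expect_gte(ev$accuracy, 0)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "history"))
})

test_that("checkpoints survive a save/load round trip", {
  samples <- tiny_band_task(n_per = 12, seed = 54)
  fit <- ebdl(samples, n_filters = 2, encoder = tiny_encoder(),
              epochs = 1, batch_size = 12, seed = 2)
  path <- tempfile(fileext = ".rds")
  save_ebdl(fit, path)
  back <- load_ebdl(path)
  expect_identical(coef(back), coef(fit))
  expect_identical(predict(back, samples[1:4]), predict(fit, samples[1:4]))
  unlink(path)
})

test_that("the cross-entropy baseline trains on unfiltered TFRs", {
  samples <- tiny_band_task(n_per = 20, seed = 55, power_ratio_db = 0)
  split <- split_dataset(samples, c(7, 1.5, 1.5), seed = 2)
  fit <- ebdl(split$train, val = split$validation, loss = "cross_entropy",
              encoder = tiny_encoder(), epochs = 6, batch_size = 16,
              lr_encoder = 3e-3, seed = 3)
  expect_null(fit$filters)
  expect_null(coef(fit))
  pred <- predict(fit, split$test)
  expect_true(all(pred %in% fit$classes))
})

test_that("filter-count selection reports one row per candidate", {
  samples <- tiny_band_task(n_per = 16, seed = 56)
  split <- split_dataset(samples, c(6, 2, 2), seed = 3)
  sw <- select_filter_count(split$train, split$validation, split$test,
                            candidates = c(1, 2), encoder = tiny_encoder(),
                            epochs = 2, batch_size = 16, lr_encoder = 3e-3,
                            seed = 4)
  expect_s3_class(sw, "ebdl_sweep")
  expect_identical(sw$report$filter_count, c(1, 2))
  expect_true(sw$best %in% c(1, 2))
  # the learned-parameter column lists exactly m (mu, sigma) pairs
  pairs <- strsplit(sw$report$learned, "; ")
  expect_length(pairs[[1]], 1L)
  expect_length(pairs[[2]], 2L)
  # a single candidate returns without comparison
  sw1 <- select_filter_count(split$train, split$validation,
                             candidates = 1, encoder = tiny_encoder(),
                             epochs = 1, batch_size = 16, seed = 4)
  expect_identical(sw1$best, 1)
})

test_that("mix balancing equalizes minority classes during training", {
  mixbal <- ebdl:::.mix_balance
  set.seed(60)
  x <- array(rnorm(8 * 8 * 30), dim = c(8, 8, 30))
  y <- c(rep(1L, 20), rep(2L, 6), rep(3L, 4))
  out <- mixbal(x, y, resting = 1L)
  expect_equal(as.vector(table(out$y)), c(20, 20, 20))
  # augmented entries lie between their parents elementwise: midpoint of
  # a resting and a minority sample
  expect_identical(dim(out$x)[3], 60L)
  # training accepts the option end to end
  samples <- tiny_band_task(n_per = 8, seed = 57)
  samples <- c(samples, samples[1:8])  # imbalance class 1
  fit <- ebdl(samples, n_filters = 2, encoder = tiny_encoder(),
              epochs = 1, batch_size = 8, mix_class = 1, seed = 6)
  expect_s3_class(fit, "ebdl")
})

test_that("divergence is reported with its epoch and batch", {
  samples <- tiny_band_task(n_per = 8, seed = 58)
  expect_error(
    ebdl(samples, n_filters = 2, encoder = tiny_encoder(), epochs = 2,
         batch_size = 8, lr_encoder = 1e154, seed = 1),
    "epoch")
})
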