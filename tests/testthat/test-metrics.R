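# Privacy and evaluation metrics.

test_that("set_distance matches geometry and a brute-force oracle", {
  expect_equal(set_distance(matrix(c(0, 0), 2), matrix(c(3, 4), 2)), 5)
  A <- matrix(rnorm(10), 2)
  expect_equal(set_distance(A, A[, 3, drop = FALSE]), 0)
  set.seed(12)
  for (rep in 1:20) {
    A <- matrix(rnorm(10 * sample(5:30, 1)), 10)
    B <- matrix(rnorm(10 * sample(5:30, 1)), 10)
    oracle <- Inf
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      oracle <- min(oracle, sqrt(sum((A[, i] - B[, j])^2)))
    }
    expect_equal(set_distance(A, B), oracle, tolerance = 1e-12)
    expect_equal(set_distance(A, B), set_distance(B, A))
  }
  expect_error(set_distance(matrix(0, 2, 0), A), "non-empty")
  expect_error(set_distance(matrix(0, 3, 2), matrix(0, 2, 2)), "dimensions")
})

test_that("ssim is 1 on identical images and matches a reference oracle", {
  set.seed(7)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- pmin(pmax(x + matrix(rnorm(32 * 32, sd = 0.2), 32, 32), 0), 1)
  expect_equal(ssim(x, x), 1)
  # frozen values from an independent reference implementation of
  # Gaussian-window SSIM (11x11, sigma 1.5, data range 1)
  expect_equal(ssim(x, y), 0.8167813706, tolerance = 1e-9)
  x2 <- matrix(runif(24 * 20), 24, 20)
  y2 <- matrix(runif(24 * 20), 24, 20)
  expect_equal(ssim(x2, y2), 0.1547558079, tolerance = 1e-9)
  # a flat image against noise is far from similar
  expect_lt(ssim(matrix(0.5, 32, 32), x), 0.3)
  expect_error(ssim(x, x2), "identical dimensions")
})

test_that("max_ssim equals the maximum over all individually computed pairs", {
  set.seed(13)
  A <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  B <- array(runif(16 * 16 * 4), c(16, 16, 1, 4))
  oracle <- max(vapply(1:3, function(i) {
    vapply(1:4, function(j) ssim(A[, , 1, i], B[, , 1, j]), numeric(1))
  }, numeric(4)))
  expect_equal(max_ssim(A, B), oracle)
  # an exact copy forces the maximum to 1
  B2 <- B; B2[, , 1, 2] <- A[, , 1, 1]
  expect_equal(max_ssim(A, B2), 1)
})

test_that("dpgo equals the absolute mean loss gap under fixed logits", {
  # stub model with hand-fixed class scores per image
  logits_real <- cbind(c(2, 0), c(0, 1))       # two samples
  logits_gen <- cbind(c(1, 1), c(3, 0))
  stub <- list(predict = function(params, imgs) {
    if (dim(imgs)[4] == 2 && imgs[1, 1, 1, 1] == 0) logits_real else logits_gen
  }, params = list())
  mk <- function(first_px, labs) {
    imgs <- array(0.5, c(4, 4, 1, 2)); imgs[1, 1, 1, ] <- first_px
    image_dataset(imgs, factor(labs, levels = c("a", "b")))
  }
  real <- mk(0, c("a", "b"))
  gen <- mk(1, c("a", "b"))
  ce <- function(L, y) {
    mean(vapply(seq_along(y), function(i) {
      log(sum(exp(L[, i]))) - L[y[i], i]
    }, numeric(1)))
  }
  expected <- abs(ce(logits_real, c(1, 2)) - ce(logits_gen, c(1, 2)))
  expect_equal(dpgo(stub, real, gen), expected)
  expect_equal(dpgo(stub, real, real), 0)
  expect_gte(dpgo(stub, gen, real), 0)
  # permutation of samples within a set leaves the value unchanged
  gen_perm <- mk(1, c("b", "a"))
  gen_perm$images <- gen$images[, , , 2:1, drop = FALSE]
  stub2 <- list(predict = function(params, imgs) {
    if (imgs[1, 1, 1, 1] == 0) logits_real else logits_gen[, 2:1]
  }, params = list())
  expect_equal(dpgo(stub2, real, gen_perm), expected)
  bad <- mk(1, c("a", "b")); levels(bad$labels) <- c("x", "y")
  expect_error(dpgo(stub, real, bad), "vocabularies")
})

test_that("delta accuracy loss is a signed percent difference", {
  expect_equal(delta_accuracy_loss(80, 80), 0)
  expect_equal(delta_accuracy_loss(82, 80), 2)
  expect_equal(delta_accuracy_loss(78.5, 81.75), -3.25)
  expect_error(delta_accuracy_loss(101, 50), "percent")
})

test_that("accuracy scores argmax predictions with low-index tie-breaks", {
  imgs <- array(0.5, c(4, 4, 1, 4))
  balanced <- image_dataset(imgs, factor(c("a", "a", "b", "b")))
  const_stub <- list(predict = function(p, x) {
    matrix(c(1, 0), 2, dim(x)[4])  # always class 1
  }, params = list())
  expect_equal(evaluate_accuracy(const_stub, balanced), 50)
  perfect <- list(predict = function(p, x) {
    sapply(seq_len(dim(x)[4]), function(i) if (i <= 2) c(1, 0) else c(0, 1))
  }, params = list())
  expect_equal(evaluate_accuracy(perfect, balanced), 100)
  tie <- list(predict = function(p, x) matrix(0, 2, dim(x)[4]),
              params = list())
  expect_equal(evaluate_accuracy(tie, balanced), 50)  # all scored class "a"
  empty <- image_dataset(array(0, c(4, 4, 1, 0)), factor(character()))
  expect_error(evaluate_accuracy(const_stub, empty), "empty")
})

test_that("trained-classifier metrics run end to end on the tiny fixture", {
  cnn <- tiny_factory(3)
  fit <- train_local(cnn, tiny_fx$train,
                     training_config(learning_rate = 1e-3, batch_size = 8),
                     epochs = 6, seed = 3)
  acc <- evaluate_accuracy(cnn, tiny_fx$test, fit$params)
  expect_gte(acc, 50)
  expect_lte(acc, 100)
  expect_equal(dpgo(cnn, tiny_fx$train, tiny_fx$train, fit$params), 0)
})

test_that("metrics reports serialize to JSON and CSV", {
  rep <- metrics_report(acc = 91.25,
                        rounds = data.frame(round = 1:2, accuracy = c(50, 91)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.json")
  write_metrics_report(rep, path, csv_dir = dir)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$acc, 91.25)
  expect_true(file.exists(file.path(dir, "rounds.csv")))
})
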