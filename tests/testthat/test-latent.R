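# Sigma-point expansion, distribution estimation and latent sampling.

test_that("sigma points land at m +/- alpha*sqrt(var) per dimension", {
  sp <- sigma_points(latent_encoding(0, 1), alpha = 1)
  expect_equal(sort(as.vector(sp$points)), c(-1, 1))

  sp <- sigma_points(latent_encoding(c(2, -1), c(4, 9)), alpha = 2)
  expect_equal(sp$points[, , 1],
               cbind(c(6, -1), c(2, 5), c(-2, -1), c(2, -7)))
  # reflection pairing: point n and point n+d mirror about the mean
  expect_equal(sp$points[, 1:2, 1] + sp$points[, 3:4, 1],
               matrix(c(2, -1), 2, 2) * 2)
  expect_error(sigma_points(latent_encoding(0, 1), alpha = 0), "positive")
  expect_error(sigma_points(latent_encoding(0, 1), alpha = -2), "positive")
})

test_that("sigma-point sets reproduce mean and scaled covariance exactly", {
  set.seed(11)
  for (rep in 1:30) {
    d <- sample(1:16, 1)
    m <- rnorm(d, sd = 2)
    v <- runif(d, 0.1, 4)
    a <- runif(1, 0.3, 3)
    pts <- matrix(sigma_points(latent_encoding(m, v), a)$points[, , 1],
                  d, 2 * d)
    expect_equal(rowMeans(pts), m, tolerance = 1e-12)
    centred <- pts - m
    pop_cov <- tcrossprod(centred) / (2 * d)
    expect_lt(max(abs(pop_cov - diag(a^2 / d * v, d, d))), 1e-10)
  }
})

test_that("reparameterized sets have 2dk points and conserve labels", {
  shard <- client_dataset("c1", tiny_fx$train$images[, , , 1:6, drop = FALSE],
                          tiny_fx$train$labels[1:6])
  rs <- reparameterized_set(shard, tiny_vae, alpha = 2)
  d <- tiny_vae$d
  expect_equal(ncol(rs$z), 2 * d * 6)
  expect_equal(as.vector(table(rs$labels)),
               as.vector(table(shard$labels)) * 2 * d)
  # identical shards give identical sets
  rs2 <- reparameterized_set(shard, tiny_vae, alpha = 2)
  expect_identical(rs$z, rs2$z)
  # single image reduces to its sigma-point expansion
  one <- client_dataset("c1", shard$images[, , , 1, drop = FALSE],
                        shard$labels[1])
  sp <- sigma_points(vae_encode(tiny_vae, one$images), alpha = 2)
  expect_equal(reparameterized_set(one, tiny_vae, alpha = 2)$z,
               matrix(sp$points, d, 2 * d))
  empty <- client_dataset("c0", array(0, c(16, 16, 1, 0)), factor(character()))
  expect_error(reparameterized_set(empty, tiny_vae), "empty")
})

test_that("distribution estimators follow their per-dimension definitions", {
  z <- rbind(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.6))
  th <- estimate_distribution(z, "uniform")
  expect_equal(th$lower, c(0.1, 0.2))
  expect_equal(th$upper, c(0.9, 0.6))

  th <- estimate_distribution(matrix(c(-1, 1), 1, 2), "normal")
  expect_equal(th$mean, 0)
  expect_equal(th$sd, sqrt(2))  # sample (n-1) convention

  th <- estimate_distribution(z, "truncated_normal")
  expect_named(th, c("mean", "sd", "lower", "upper"))
  expect_equal(th$lower, c(0.1, 0.2))

  expect_error(estimate_distribution(matrix(1, 2, 1), "normal"),
               "at least 2")
  expect_warning(
    th <- estimate_distribution(matrix(1, 1, 5), "normal"), "clamped")
  expect_gt(th$sd, 0)
})

test_that("uniform bounds recovered from draws within 0.01 of truth", {
  z <- make_latent_fixture("uniform", list(lower = -2, upper = 3),
                           n = 10000, d = 4, seed = 3)
  th <- estimate_distribution(z, "uniform")
  expect_lt(max(abs(th$lower - (-2))), 0.01)
  expect_lt(max(abs(th$upper - 3)), 0.01)
})

test_that("sampling respects n, support and seeding", {
  th <- list(lower = rep(0, 3), upper = rep(1, 3))
  expect_equal(dim(sample_latent(th, "uniform", 0)), c(3, 0))
  z <- sample_latent(th, "uniform", 500, seed = 5)
  expect_true(all(z >= 0 & z <= 1))
  expect_identical(z, sample_latent(th, "uniform", 500, seed = 5))
  tn <- list(mean = rep(0, 2), sd = rep(1, 2),
             lower = rep(-0.5, 2), upper = rep(0.25, 2))
  zt <- sample_latent(tn, "truncated_normal", 400, seed = 6)
  expect_true(all(zt >= -0.5 & zt <= 0.25))
  expect_error(sample_latent(list(lower = 1, upper = 0), "uniform", 5),
               "lower <= upper")
  expect_error(sample_latent(list(mean = 0, sd = -1), "normal", 5), "std")
})

test_that("sample-then-estimate round trip recovers parameters", {
  set.seed(9)
  d <- 4
  cases <- list(
    list(family = "normal",
         theta = list(mean = runif(d, 1, 2), sd = runif(d, 0.5, 1.5))),
    list(family = "uniform",
         theta = list(lower = runif(d, -3, -1), upper = runif(d, 1, 3))),
    # truncated case: parameters bounded away from zero so that relative
    # recovery error is well defined, bounds at 3 sd so the truncation
    # barely biases the sample sd
    list(family = "truncated_normal",
         theta = local({
           mu <- runif(d, 8, 10); sd <- runif(d, 0.5, 1)
           list(mean = mu, sd = sd, lower = mu - 3 * sd, upper = mu + 3 * sd)
         })))
  for (cs in cases) {
    z <- sample_latent(cs$theta, cs$family, 10000, seed = 17)
    th <- estimate_distribution(z, cs$family)
    for (nm in names(cs$theta)) {
      rel <- abs(th[[nm]] - cs$theta[[nm]]) / abs(cs$theta[[nm]])
      expect_lt(max(rel), 0.05,
                label = sprintf("%s/%s recovery", cs$family, nm))
    }
  }
})

test_that("distribution info validates its invariants and round-trips JSON", {
  di <- uniform_di("c2", c(A = 30L, B = 70L))
  expect_equal(di$total_count, 100L)
  expect_error(distribution_info("c", "uniform",
                                 list(A = list(lower = 0, upper = 1)),
                                 c(B = 5L)),
               "labels")
  expect_error(uniform_di("c", c(A = -1L)), "non-negative")

  path <- withr::local_tempfile(fileext = ".json")
  write_di_json(di, path)
  back <- read_di_json(path)
  expect_equal(back$per_class_params, di$per_class_params)
  expect_identical(back$per_class_counts, di$per_class_counts)
  expect_identical(back$family, di$family)
  expect_identical(back$total_count, di$total_count)
})
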