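# FedAvg aggregation and the two-stage orchestration.

rand_params <- function(seed) {
  set.seed(seed)
  list(a = matrix(rnorm(6), 2, 3), b = rnorm(4))
}

test_that("fedavg_aggregate is the weight-normalized average", {
  p <- rand_params(1)
  expect_identical(fedavg_aggregate(list(p), 5), p)
  expect_equal(fedavg_aggregate(list(p, p, p), c(2, 5, 1)), p,
               tolerance = 1e-14)
  expect_equal(fedavg_aggregate(list(list(w = 1), list(w = 3)), c(1, 1))$w, 2)
  expect_equal(fedavg_aggregate(list(list(w = 0), list(w = 4)), c(1, 3))$w, 3)
  bad <- p; bad$a <- matrix(0, 3, 2)
  expect_error(fedavg_aggregate(list(p, bad), c(1, 1)), "shape mismatch")
  expect_error(fedavg_aggregate(list(p, p), c(1, 0)), "positive")
  expect_error(fedavg_aggregate(list(p, p), c(1)), "one weight")
})

test_that("aggregation is permutation-invariant and degree-1 homogeneous", {
  ps <- lapply(1:3, rand_params)
  w <- c(2, 3, 7)
  agg <- fedavg_aggregate(ps, w)
  perm <- c(3, 1, 2)
  agg2 <- fedavg_aggregate(ps[perm], w[perm])
  expect_equal(agg, agg2, tolerance = 1e-14)
  scaled <- lapply(ps, function(p) lapply(p, `*`, 2.5))
  expect_equal(fedavg_aggregate(scaled, w), lapply(agg, `*`, 2.5),
               tolerance = 1e-14)
  # equal weights coincide with the plain unweighted mean
  eq <- fedavg_aggregate(ps, c(1, 1, 1))
  manual <- Map(function(x, y, z) (x + y + z) / 3,
                ps[[1]], ps[[2]], ps[[3]])
  expect_equal(eq, manual, tolerance = 1e-14)
})

test_that("stage 1 trains federally and emits one DI per client", {
  clients <- partition_by_proportions(
    tiny_fx$train, rbind(c(0.2, 0.2, 0.6), c(0.6, 0.2, 0.2)), seed = 3)
  s1 <- run_stage1(clients, tiny_vae,
                   federation_config(3, 1, seed = 4),
                   training_config(batch_size = 8))
  expect_length(s1$dis, 3)
  for (k in 1:3) {
    expect_equal(s1$dis[[k]]$total_count, dim(clients[[k]]$images)[4])
    expect_identical(s1$dis[[k]]$client_id, clients[[k]]$client_id)
    # every client can receive the others' payloads
    expect_length(s1$dis[-k], 2)
  }
  # identical shards produce identical per-class counts
  twin <- list(
    client_dataset("a", clients[[1]]$images, clients[[1]]$labels),
    client_dataset("b", clients[[1]]$images, clients[[1]]$labels))
  s1b <- run_stage1(twin, tiny_vae, federation_config(2, 1, seed = 4),
                    training_config(batch_size = 8))
  expect_identical(s1b$dis[[1]]$per_class_counts,
                   s1b$dis[[2]]$per_class_counts)
  empty <- list(client_dataset("e", array(0, c(16, 16, 1, 0)),
                               factor(character(), levels = "x")),
                twin[[1]])
  expect_error(run_stage1(empty, tiny_vae, federation_config(2, 1)),
               "non-empty")
})

test_that("stage 2 samples ceil(r*m) distinct clients per round", {
  set.seed(5)
  shards <- lapply(1:20, function(k) {
    ix <- sample(dataset_size(tiny_fx$train), 4)
    client_dataset(paste0("c", k),
                   tiny_fx$train$images[, , , ix, drop = FALSE],
                   tiny_fx$train$labels[ix])
  })
  s2 <- run_stage2(shards, tiny_factory,
                   federation_config(20, 2, r = 0.5, seed = 6),
                   training_config(batch_size = 4))
  expect_equal(s2$records$n_participants, c(10L, 10L))
  # r = 1 lists every client
  small <- shards[1:3]
  s3 <- run_stage2(small, tiny_factory, federation_config(3, 1, seed = 7),
                   training_config(batch_size = 4))
  expect_equal(s3$records$n_participants, 3L)
})

test_that("zero rounds return the factory's initial parameters", {
  clients <- partition_by_proportions(
    tiny_fx$train, rbind(c(0.5, 0.5), c(0.5, 0.5)), seed = 8)
  cfg <- federation_config(2, 0, seed = 9)
  s2 <- run_stage2(clients, tiny_factory, cfg)
  init <- tiny_factory(feddis:::derive_seed(9, 2L, 0L))
  expect_identical(s2$params, init$params)
})

test_that("the full two-stage pipeline removes label heterogeneity", {
  clients <- partition_by_proportions(
    tiny_fx$train, rbind(c(0.1, 0.1, 0.8), c(0.8, 0.1, 0.1)), seed = 10)
  expect_gt(max(pairwise_emd(clients)), 0)
  res <- run_feddis(clients, tiny_vae, tiny_factory,
                    federation_config(3, 1), federation_config(3, 1),
                    training_config(batch_size = 8),
                    test_set = tiny_fx$test, seed = 11)
  expect_equal(max(res$emd_after), 0)
  total <- dataset_size(tiny_fx$train)
  for (cl in res$clients_augmented) {
    expect_equal(dataset_size(cl), total)
  }
  expect_true(all(is.finite(res$stage2$records$accuracy)))
})
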