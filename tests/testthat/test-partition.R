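# Non-IID partitioners and the EMD heterogeneity measure.

test_that("proportion splits match the round/remainder rule", {
  set.seed(1)
  ds <- label_only_dataset(c(dem = 2561L, nondem = 2560L))
  # rows in level order (dem, nondem): 60/20/20 and 20/20/60
  props <- rbind(c(0.6, 0.2, 0.2), c(0.2, 0.2, 0.6))
  clients <- partition_by_proportions(ds, props, seed = 2)
  expect_equal(vapply(clients, dataset_size, integer(1)),
               c(2049L, 1024L, 2048L))

  # uniform fractions give near-equal shards
  cl <- partition_by_proportions(ds, matrix(1 / 3, 2, 3), seed = 3)
  sizes <- vapply(cl, dataset_size, integer(1))
  expect_lte(max(sizes) - min(sizes), 2L)

  # degenerate fractions put everything on one client
  cl <- partition_by_proportions(ds, rbind(c(1, 0, 0), c(1, 0, 0)), seed = 4)
  expect_equal(dataset_size(cl[[1]]), 5121L)
  expect_equal(dataset_size(cl[[2]]), 0L)

  expect_error(partition_by_proportions(ds, rbind(c(0.5, 0.2), c(1, 0))),
               "sum to 1")
})

test_that("both partition modes are disjoint covers, reproducibly", {
  set.seed(5)
  ds <- label_only_dataset(c(a = 300L, b = 200L, c = 100L))
  for (mode in c("proportions", "dirichlet")) {
    for (seed in c(2, 9)) {
      clients <- if (mode == "proportions") {
        partition_by_proportions(ds, matrix(runif(9) |>
          (\(x) matrix(x, 3) / rowSums(matrix(x, 3)))(), 3), seed = seed)
      } else {
        partition_dirichlet(ds, beta = 0.3, m = 3, seed = seed)
      }
      ids <- unlist(lapply(clients, `[[`, "ids"))
      expect_equal(sort(ids), sort(ds$ids))  # cover, no duplicates
      again <- if (mode == "proportions") {
        partition_by_proportions(ds, matrix(1 / 3, 3, 3), seed = seed)
      } else {
        partition_dirichlet(ds, beta = 0.3, m = 3, seed = seed)
      }
      if (mode == "dirichlet") {
        expect_identical(lapply(clients, `[[`, "ids"),
                         lapply(again, `[[`, "ids"))
      }
    }
  }
})

test_that("huge Dirichlet concentration approaches the global distribution", {
  set.seed(6)
  ds <- label_only_dataset(c(a = 1200L, b = 800L))
  clients <- partition_dirichlet(ds, beta = 1e6, m = 3, seed = 7)
  global <- class_distribution(ds)
  for (cl in clients) {
    expect_lt(max(abs(class_distribution(cl) - global)), 0.05)
  }
  expect_error(partition_dirichlet(ds, beta = 0, m = 3), "beta")
})

test_that("emd is half the L1 distance and a metric on the simplex", {
  expect_equal(emd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(emd(c(1, 0), c(0, 1)), 1)
  expect_equal(emd(c(0.25, 0.75), c(0.75, 0.25)), 0.5)
  expect_error(emd(c(0.5, 0.4), c(0.5, 0.5)), "summing to 1")
  expect_error(emd(c(1, 0), c(1, 0, 0)), "length")
  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    rs <- function() { x <- rexp(k); x / sum(x) }
    p <- rs(); q <- rs(); r <- rs()
    expect_gte(emd(p, q), 0)
    expect_equal(emd(p, q), emd(q, p))
    expect_lte(emd(p, r), emd(p, q) + emd(q, r) + 1e-12)
  }
})

test_that("pairwise EMD matches hand-computed client frequencies", {
  set.seed(9)
  ds <- label_only_dataset(c(a = 300L, b = 300L))
  clients <- partition_by_proportions(
    ds, rbind(c(0.1, 0.1, 0.8), c(0.8, 0.1, 0.1)), seed = 10)
  M <- pairwise_emd(clients)
  expect_equal(diag(M), rep(0, 3), ignore_attr = TRUE)
  expect_equal(M, t(M))
  # client 1 holds (30, 240), client 2 (30, 30): EMD = |1/9-1/2| = 0.389
  expect_equal(M[1, 2], 7 / 18, tolerance = 1e-12)
  same <- list(clients[[1]], clients[[1]])
  expect_equal(max(pairwise_emd(same)), 0)
  expect_error(pairwise_emd(clients[1]), "at least 2")
})

test_that("partition manifests replay to identical shards", {
  set.seed(11)
  ds <- label_only_dataset(c(a = 40L, b = 20L))
  clients <- partition_dirichlet(ds, 0.5, 3, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_partition_manifest(clients, path)
  back <- read_partition_manifest(ds, path)
  for (k in 1:3) {
    expect_identical(back[[k]]$ids, clients[[k]]$ids)
    expect_identical(back[[k]]$images, clients[[k]]$images)
    expect_identical(back[[k]]$labels, clients[[k]]$labels)
  }
})
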