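# Small shared fixtures, built once per test run.

# tiny 16x16 grayscale fixture: 2 classes x 15 train, 6 test per class
tiny_fx <- make_image_dataset(2, 15, c(1, 16, 16), "easy",
                              n_test_per_class = 6, seed = 101)

# tiny untrained VAE over the same shape (decoder contracts don't need
# training)
tiny_vae <- build_vae(c(1, 16, 16), d = 4, widths = c(4L, 6L), seed = 7)

tiny_factory <- function(seed) {
  build_cnn_classifier(c(1, 16, 16), 2, widths = c(3L, 4L), seed = seed)
}

# labels-only dataset (1x1 images) for partitioning arithmetic
label_only_dataset <- function(counts, classes = names(counts)) {
  n <- sum(counts)
  image_dataset(array(stats::runif(n), c(1, 1, 1, n)),
                factor(rep(classes, counts), levels = classes))
}

# deterministic uniform DI payload for augmentation tests
uniform_di <- function(client_id, counts, d = 4) {
  params <- lapply(counts, function(cnt) {
    list(lower = rep(-1, d), upper = rep(1, d))
  })
  distribution_info(client_id, "uniform", params, counts)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
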