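# Synthetic labeled-image generation. Each class is defined by a
# deterministic structural motif — a Gaussian blob at a class-specific
# position plus an oriented sinusoidal grating — with additive pixel noise
# and small positional jitter, so classes are separable by a small CNN while
# every pipeline stage stays testable without external datasets.

DIFFICULTY_LEVELS <- list(
  easy = list(noise_sd = 0.05, jitter = 1),
  medium = list(noise_sd = 0.15, jitter = 2),
  hard = list(noise_sd = 0.30, jitter = 4)
)

class_motif <- function(ci, n_classes, H, W, dx = 0, dy = 0) {
  ang <- 2 * pi * (ci - 1) / n_classes
  rad <- 0.28 * min(H, W)
  cy <- H / 2 + rad * sin(ang) + dy
  cx <- W / 2 + rad * cos(ang) + dx
  sg <- min(H, W) / 7
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  blob <- 0.8 * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sg^2))
  th <- pi * (ci - 1) / n_classes
  u <- (xx * cos(th) + yy * sin(th)) / min(H, W)
  grating <- 0.12 * (1 + sin(2 * pi * 3 * u)) / 2
  0.05 + blob + grating
}

#' Generate a synthetic labeled image dataset
#'
#' Produces a stratified train/test split of grayscale (or RGB) images in
#' `[0, 1]`. Class `c`'s motif is a Gaussian blob centred at angle
#' `2*pi*(c-1)/K` on a circle around the image centre plus a grating
#' oriented at `pi*(c-1)/K`; per-image variation comes from positional
#' jitter and additive Gaussian pixel noise whose scale is set by
#' `difficulty`. Identical seeds give bit-identical pixel arrays.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class training images per class (default 300).
#' @param shape `c(channels, height, width)`, at least 16x16.
#' @param difficulty `"easy"`, `"medium"` or `"hard"` — noise amplitude and
#'   jitter; `"easy"` classes are separable by a small CNN.
#' @param n_test_per_class held-out test images per class (default 100).
#' @param seed RNG seed.
#' @return list with `train` and `test` ([image_dataset()]s sharing factor
#'   levels) and `classes` (label vector).
#' @export
make_image_dataset <- function(n_classes = 2L, n_per_class = 300L,
                               shape = c(1L, 32L, 32L),
                               difficulty = c("easy", "medium", "hard"),
                               n_test_per_class = 100L, seed = NULL) {
  difficulty <- match.arg(difficulty)
  if (n_classes < 2) stopf("need at least 2 classes")
  C <- shape[1]; H <- shape[2]; W <- shape[3]
  if (length(shape) != 3 || H < 16 || W < 16 || !C %in% c(1L, 3L)) {
    stopf("shape must be c(channels, height, width) with height/width >= 16")
  }
  lv <- DIFFICULTY_LEVELS[[difficulty]]
  classes <- sprintf("class%02d", seq_len(n_classes))
  ntr <- n_classes * n_per_class
  nte <- n_classes * n_test_per_class
  chan_w <- if (C == 1) 1 else c(1, 0.8, 0.6)
  with_seed(seed, {
    gen <- function(n_each) {
      n <- n_classes * n_each
      imgs <- array(0, c(H, W, C, n))
      labs <- factor(rep(classes, each = n_each), levels = classes)
      i <- 0L
      for (ci in seq_len(n_classes)) {
        for (k in seq_len(n_each)) {
          i <- i + 1L
          motif <- class_motif(ci, n_classes, H, W,
                               dx = stats::runif(1, -lv$jitter, lv$jitter),
                               dy = stats::runif(1, -lv$jitter, lv$jitter))
          amp <- stats::runif(1, 0.85, 1.15)
          for (ch in seq_len(C)) {
            px <- amp * chan_w[ch] * motif +
              stats::rnorm(H * W, sd = lv$noise_sd)
            imgs[, , ch, i] <- pmin(pmax(px, 0), 1)
          }
        }
      }
      image_dataset(imgs, labs)
    }
    train <- gen(n_per_class)
    test <- gen(n_test_per_class)
    test$ids <- ntr + seq_len(nte)
    list(train = train, test = test, classes = classes)
  })
}

#' Draw a ground-truth latent sample fixture
#'
#' Seeded draws from a named latent family, used as ground truth in
#' estimator-recovery tests. Scalar parameter entries are recycled across
#' the `d` dimensions.
#'
#' @param family latent distribution family.
#' @param theta parameter list (see [estimate_distribution()]); scalar
#'   fields are expanded to length `d`.
#' @param n number of samples (`n = 0` gives a `d x 0` matrix).
#' @param d latent dimensionality.
#' @param seed RNG seed.
#' @return `d x n` matrix.
#' @export
make_latent_fixture <- function(family, theta, n, d, seed = NULL) {
  family <- check_family(family)
  theta <- lapply(theta, function(v) {
    if (length(v) == 1) rep(v, d) else v
  })
  validate_theta(theta, family, d)
  sample_latent(theta, family, n, seed = seed)
}
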