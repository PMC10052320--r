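# Latent-space mathematics: sigma-point expansion of encoder outputs,
# per-class distribution estimation, and sampling from shared parameters.
#
# The encoder's covariance is diagonal (a per-dimension variance head), so
# the matrix square root is taken element-wise: the n-th column of sqrt(Sigma)
# is sqrt(sigma^2_n) * e_n, and the 2d sigma points of one encoding are
# m +/- alpha * sqrt(sigma^2_n) * e_n.

LATENT_FAMILIES <- c("normal", "truncated_normal", "uniform")
STD_FLOOR <- 1e-6

#' Construct a latent encoding
#'
#' Container for the per-image latent mean and the diagonal of the latent
#' covariance. [vae_encode()] returns this class directly; the constructor is
#' exposed so the latent machinery can be used independently of a VAE.
#'
#' @param mean `d x N` matrix (or length-`d` vector) of latent means.
#' @param variance matching matrix of strictly positive variances.
#' @export
latent_encoding <- function(mean, variance) {
  if (is.null(dim(mean))) mean <- matrix(mean, ncol = 1)
  if (is.null(dim(variance))) variance <- matrix(variance, ncol = 1)
  if (!identical(dim(mean), dim(variance))) {
    stopf("mean and variance must have identical dimensions")
  }
  if (any(variance <= 0)) stopf("all variance entries must be > 0")
  structure(list(mean = mean, variance = variance, d = nrow(mean)),
            class = "latent_encoding")
}

#' @export
print.latent_encoding <- function(x, ...) {
  cat(sprintf("<latent_encoding> d=%d, %d image(s)\n", x$d, ncol(x$mean)))
  invisible(x)
}

#' Sigma-point expansion of latent encodings
#'
#' Expands each encoded image into `2d` deterministic latent samples placed
#' at `m + alpha * sqrt(sigma^2_n) * e_n` for `n = 1..d` and at the mirror
#' images `m - alpha * sqrt(sigma^2_n) * e_n` for `n = d+1..2d`. The set has
#' empirical mean exactly `m` and population covariance (divisor `2d`) equal
#' to `(alpha^2 / d) * diag(sigma^2)`.
#'
#' @param enc a [latent_encoding()] (possibly holding several images).
#' @param alpha positive placement constant; the reference setting is 2.
#' @return object of class `sigma_point_set`: list with `points` (a `d x 2d x
#'   N` array; point `n` and point `n + d` are reflections about the mean)
#'   and `alpha`.
#' @export
sigma_points <- function(enc, alpha = 2) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0) {
    stopf("`alpha` must be a single positive number")
  }
  d <- enc$d
  n <- ncol(enc$mean)
  pts <- array(0, c(d, 2 * d, n))
  for (i in seq_len(n)) {
    off <- diag(alpha * sqrt(enc$variance[, i]), d, d)
    pts[, , i] <- cbind(enc$mean[, i] + off, enc$mean[, i] - off)
  }
  structure(list(points = pts, alpha = alpha, d = d),
            class = "sigma_point_set")
}

#' @export
print.sigma_point_set <- function(x, ...) {
  cat(sprintf("<sigma_point_set> d=%d, %d points per image, %d image(s), alpha=%g\n",
              x$d, 2 * x$d, dim(x$points)[3], x$alpha))
  invisible(x)
}

#' Reparameterized latent sample set of a client shard
#'
#' Encodes every image of the shard, expands each encoding into its `2d`
#' sigma points, and returns the pooled latent samples with each point
#' labeled by its source image's class. For `k` images the set holds exactly
#' `2 * d * k` points.
#'
#' @param shard a [client_dataset()] (or [image_dataset()]).
#' @param model a trained `vae_model` (the stage-one global VAE).
#' @param alpha sigma-point placement constant.
#' @param params VAE parameters, defaulting to the model's own.
#' @return list with `z` (`d x (2dk)` matrix) and `labels` (factor of length
#'   `2dk`, levels as in the shard).
#' @export
reparameterized_set <- function(shard, model, alpha = 2,
                                params = model$params) {
  n <- dataset_size(shard)
  if (n == 0) stopf("cannot reparameterize an empty dataset")
  enc <- vae_encode(model, shard$images, params)
  sp <- sigma_points(enc, alpha)
  d <- enc$d
  z <- matrix(sp$points, d, 2 * d * n)
  labels <- rep(shard$labels, each = 2 * d)
  list(z = z, labels = labels, d = d)
}

check_family <- function(family) {
  match.arg(family, LATENT_FAMILIES)
}

#' Estimate latent distribution parameters for one class
#'
#' Per-dimension estimators over a set of latent samples: `uniform` uses the
#' sample minimum/maximum as bounds; `normal` uses the sample mean and sample
#' (n-1 divisor) standard deviation; `truncated_normal` combines both —
#' sample mean/std plus min/max truncation bounds. Dimensions with (near)
#' zero spread have their std clamped to a small positive floor, with a
#' warning.
#'
#' @param z `d x n` matrix of latent samples from one class (`n >= 2`).
#' @param family one of `"normal"`, `"truncated_normal"`, `"uniform"`.
#' @param std_floor lower clamp for degenerate standard deviations.
#' @return named list of per-dimension parameter vectors (`mean`/`sd` and/or
#'   `lower`/`upper`, depending on family).
#' @export
estimate_distribution <- function(z, family = c("uniform", "normal",
                                                "truncated_normal"),
                                  std_floor = STD_FLOOR) {
  family <- check_family(family[1])
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) < 2) stopf("need at least 2 samples to estimate a distribution")
  lo <- apply(z, 1, min)
  hi <- apply(z, 1, max)
  if (family == "uniform") return(list(lower = lo, upper = hi))
  mu <- rowMeans(z)
  sd <- sqrt(rowSums((z - mu)^2) / (ncol(z) - 1))
  if (any(sd < std_floor)) {
    warnf("%d latent dimension(s) with (near) zero variance; std clamped to %g",
          sum(sd < std_floor), std_floor)
    sd <- pmax(sd, std_floor)
  }
  if (family == "normal") return(list(mean = mu, sd = sd))
  list(mean = mu, sd = sd, lower = lo, upper = hi)
}

validate_theta <- function(theta, family, d = NULL) {
  need <- switch(family,
                 uniform = c("lower", "upper"),
                 normal = c("mean", "sd"),
                 truncated_normal = c("mean", "sd", "lower", "upper"))
  if (!all(need %in% names(theta))) {
    stopf("theta for family '%s' requires fields %s", family,
          paste(need, collapse = ", "))
  }
  len <- unique(vapply(theta[need], length, integer(1)))
  if (length(len) != 1) stopf("theta fields have inconsistent lengths")
  if (!is.null(d) && len != d) stopf("theta dimension %d != expected %d", len, d)
  if (!all(vapply(theta[need], function(v) all(is.finite(v)), logical(1)))) {
    stopf("theta contains non-finite values")
  }
  if ("sd" %in% need && any(theta$sd <= 0)) stopf("theta stds must be > 0")
  if (all(c("lower", "upper") %in% need) && any(theta$lower > theta$upper)) {
    stopf("theta bounds must satisfy lower <= upper")
  }
  invisible(len)
}

# seeded truncated-normal draws: rejection sampling with a bounded number of
# passes, then clipped inverse-CDF for whatever is still missing
rtruncnorm_vec <- function(n, mean, sd, lower, upper, max_pass = 50L) {
  out <- numeric(n)
  todo <- seq_len(n)
  pass <- 0L
  while (length(todo) > 0 && pass < max_pass) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    pass <- pass + 1L
  }
  if (length(todo) > 0) {
    plo <- stats::pnorm(lower, mean, sd)
    phi <- stats::pnorm(upper, mean, sd)
    u <- stats::runif(length(todo), min(plo, phi), max(plo, phi))
    out[todo] <- pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
  }
  out
}

#' Sample latent vectors from shared distribution parameters
#'
#' Draws `n` i.i.d. latent vectors, independently per dimension, from the
#' named family with parameters `theta`. Uniform and truncated-normal draws
#' are guaranteed to lie within their bounds; a fixed `seed` makes the draw
#' reproducible without disturbing the caller's RNG state.
#'
#' @param theta parameter list as produced by [estimate_distribution()].
#' @param family distribution family of `theta`.
#' @param n number of vectors to draw (`n = 0` gives a `d x 0` matrix).
#' @param seed optional RNG seed.
#' @return `d x n` matrix.
#' @export
sample_latent <- function(theta, family, n, seed = NULL) {
  family <- check_family(family)
  if (length(n) != 1 || !is.finite(n) || n < 0 || n != as.integer(n)) {
    stopf("`n` must be a single non-negative integer")
  }
  d <- validate_theta(theta, family)
  n <- as.integer(n)
  if (n == 0) return(matrix(0, d, 0))
  with_seed(seed, {
    z <- matrix(0, d, n)
    for (j in seq_len(d)) {
      z[j, ] <- switch(family,
        uniform = stats::runif(n, theta$lower[j], theta$upper[j]),
        normal = stats::rnorm(n, theta$mean[j], theta$sd[j]),
        truncated_normal = rtruncnorm_vec(n, theta$mean[j], theta$sd[j],
                                          theta$lower[j], theta$upper[j]))
    }
    z
  })
}

# ---- distribution information payload --------------------------------------

#' Distribution information shared between clients
#'
#' The unit of exchange replacing raw data: the latent distribution family,
#' one parameter record per class, per-class sample counts, and the owning
#' client. `total_count` must equal the sum of per-class counts.
#'
#' @param client_id owner of the payload.
#' @param family latent distribution family.
#' @param per_class_params named list (one element per class label) of
#'   parameter records as from [estimate_distribution()].
#' @param per_class_counts named integer vector of per-class original sample
#'   counts, names matching `per_class_params`.
#' @export
distribution_info <- function(client_id, family, per_class_params,
                              per_class_counts) {
  family <- check_family(family)
  if (!setequal(names(per_class_params), names(per_class_counts))) {
    stopf("class labels of params and counts differ")
  }
  per_class_counts <- per_class_counts[names(per_class_params)]
  if (any(per_class_counts < 0)) stopf("class counts must be non-negative")
  for (cl in names(per_class_params)) {
    validate_theta(per_class_params[[cl]], family)
  }
  structure(list(client_id = client_id, family = family,
                 per_class_params = per_class_params,
                 per_class_counts = stats::setNames(
                   as.integer(per_class_counts), names(per_class_params)),
                 total_count = as.integer(sum(per_class_counts))),
            class = "distribution_info")
}

#' @export
print.distribution_info <- function(x, ...) {
  cat(sprintf("<distribution_info> client '%s', family %s, |X|=%d\n",
              x$client_id, x$family, x$total_count))
  cat("  classes:",
      paste(sprintf("%s=%d", names(x$per_class_counts), x$per_class_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Estimate a client's distribution information
#'
#' The encoder-side half of the sharing protocol: build the sigma-point
#' reparameterized set of the shard under the global VAE, then estimate one
#' latent parameter record per class label present in the shard.
#'
#' @inheritParams reparameterized_set
#' @param family latent family to fit.
#' @export
estimate_client_di <- function(shard, model, family = "uniform", alpha = 2,
                               params = model$params) {
  rs <- reparameterized_set(shard, model, alpha, params)
  labs <- levels(droplevels(shard$labels))
  per_params <- list()
  counts <- integer(0)
  for (cl in labs) {
    per_params[[cl]] <- estimate_distribution(
      rs$z[, rs$labels == cl, drop = FALSE], family)
    counts[cl] <- sum(shard$labels == cl)
  }
  distribution_info(shard$client_id, family, per_params, counts)
}

#' Write and read distribution information as JSON
#'
#' Serialization used for exchange between simulated clients:
#' `{client_id, family, total_count, classes: [{label, count, params}]}`,
#' with per-dimension parameter arrays in dimension order.
#' @param di a [distribution_info()].
#' @param path file path.
#' @export
write_di_json <- function(di, path) {
  classes <- lapply(names(di$per_class_params), function(cl) {
    list(label = cl, count = di$per_class_counts[[cl]],
         params = di$per_class_params[[cl]])
  })
  jsonlite::write_json(
    list(client_id = di$client_id, family = di$family,
         total_count = di$total_count, classes = classes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_di_json
#' @export
read_di_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- vapply(x$classes, function(e) as.character(e$label), "")
  counts <- vapply(x$classes, function(e) as.integer(e$count), integer(1))
  params <- lapply(x$classes, function(e) lapply(e$params, function(v)
    as.numeric(unlist(v))))
  names(params) <- labels
  distribution_info(x$client_id, x$family, params,
                    stats::setNames(counts, labels))
}
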