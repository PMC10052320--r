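# VAE and task-CNN model definitions.
#
# A model is a plain list: geometry, hyper-parameters, a named list of
# parameter arrays (`params`), and the names of the trainable subset
# (batch-norm running statistics are carried in `params` so that federated
# averaging aggregates them, but the optimiser never touches them).

# conv -> batchnorm -> leaky-ReLU stack shared by the encoder and the CNN
stack_fw <- function(x, params, prefix, geoms, slope, train) {
  caches <- vector("list", length(geoms))
  for (l in seq_along(geoms)) {
    cf <- conv_fw(x, params[[paste0(prefix, l, "_W")]],
                  params[[paste0(prefix, l, "_b")]], geoms[[l]])
    bn <- bn_fw(cf$y,
                params[[paste0(prefix, l, "_g")]],
                params[[paste0(prefix, l, "_be")]],
                params[[paste0(prefix, l, "_rm")]],
                params[[paste0(prefix, l, "_rv")]], train)
    params[[paste0(prefix, l, "_rm")]] <- bn$rmean
    params[[paste0(prefix, l, "_rv")]] <- bn$rvar
    lf <- lrelu_fw(bn$y, slope)
    x <- lf$y
    caches[[l]] <- list(cols = cf$cols, bn = bn, mask = lf$mask)
  }
  list(y = x, caches = caches, params = params)
}

stack_bw <- function(dy, caches, params, prefix, geoms, slope) {
  grads <- list()
  for (l in rev(seq_along(geoms))) {
    dy <- lrelu_bw(dy, caches[[l]]$mask, slope)
    bb <- bn_bw(dy, caches[[l]]$bn, params[[paste0(prefix, l, "_g")]])
    grads[[paste0(prefix, l, "_g")]] <- bb$dgamma
    grads[[paste0(prefix, l, "_be")]] <- bb$dbeta
    cb <- conv_bw(bb$dx, caches[[l]]$cols,
                  params[[paste0(prefix, l, "_W")]], geoms[[l]])
    grads[[paste0(prefix, l, "_W")]] <- cb$dW
    grads[[paste0(prefix, l, "_b")]] <- cb$db
    dy <- cb$dx
  }
  list(dx = dy, grads = grads)
}

make_stack_params <- function(prefix, geoms) {
  params <- list()
  for (l in seq_along(geoms)) {
    g <- geoms[[l]]
    params[[paste0(prefix, l, "_W")]] <- init_weight(g$out_c, g$K, g$K)
    params[[paste0(prefix, l, "_b")]] <- numeric(g$out_c)
    params[[paste0(prefix, l, "_g")]] <- rep(1, g$out_c)
    params[[paste0(prefix, l, "_be")]] <- numeric(g$out_c)
    params[[paste0(prefix, l, "_rm")]] <- numeric(g$out_c)
    params[[paste0(prefix, l, "_rv")]] <- rep(1, g$out_c)
  }
  params
}

build_geoms <- function(input_shape, widths, kernel, stride, pad = 1L) {
  C <- input_shape[1]; H <- input_shape[2]; W <- input_shape[3]
  geoms <- vector("list", length(widths))
  ch <- C; h <- H; w <- W
  for (l in seq_along(widths)) {
    geoms[[l]] <- conv_geom(h, w, ch, widths[l], kernel, stride, pad)
    h <- geoms[[l]]$oh; w <- geoms[[l]]$ow; ch <- widths[l]
  }
  geoms
}

#' Build a convolutional variational autoencoder
#'
#' Constructs the encoder/decoder pair used throughout the pipeline: a stack
#' of strided convolutions with batch normalization between them and
#' leaky-ReLU activations, two linear heads emitting the latent mean and
#' log-variance, and a mirrored transposed-convolution decoder ending in a
#' sigmoid so that outputs live in `[0, 1]` like the normalized inputs.
#'
#' @param input_shape integer vector `c(channels, height, width)`. Height and
#'   width must be divisible by `stride^length(widths)`.
#' @param d latent dimensionality.
#' @param widths channel counts of the successive convolution layers.
#' @param kernel,stride convolution kernel size and stride (padding 1).
#' @param kl_weight weight of the KL term in the training objective. The
#'   reconstruction term is a per-pixel mean, so the default `1e-3` makes the
#'   two terms commensurate for images of around a thousand pixels
#'   (equivalent to the classical summed reconstruction with unit KL weight).
#' @param lrelu_slope negative-side slope of the leaky ReLU.
#' @param seed integer; identical seeds give identical initial parameters.
#' @return an object of class `vae_model` with elements `params` (named list
#'   of arrays) and `trainable` (names updated by the optimiser).
#' @export
build_vae <- function(input_shape, d = 64L, widths = c(8L, 16L),
                      kernel = 4L, stride = 2L, kl_weight = 1e-3,
                      lrelu_slope = 0.2, seed = NULL) {
  d <- assert_positive_int(d, "d")
  geoms <- build_geoms(input_shape, widths, kernel, stride)
  L <- length(geoms)
  gl <- geoms[[L]]
  flat <- gl$oh * gl$ow * gl$out_c
  params <- with_seed(seed, {
    p <- make_stack_params("enc", geoms)
    p$mu_W <- init_weight(d, flat, flat)
    p$mu_b <- numeric(d)
    p$lv_W <- init_weight(d, flat, flat)
    p$lv_b <- numeric(d)
    p$fc_W <- init_weight(flat, d, d)
    p$fc_b <- numeric(flat)
    for (l in rev(seq_len(L))) {
      g <- geoms[[l]]
      p[[paste0("dec", l, "_W")]] <- init_weight(g$out_c, g$K, g$out_c * g$k * g$k)
      p[[paste0("dec", l, "_b")]] <- numeric(g$in_c)
      if (l > 1) {
        p[[paste0("dbn", l, "_g")]] <- rep(1, g$in_c)
        p[[paste0("dbn", l, "_be")]] <- numeric(g$in_c)
        p[[paste0("dbn", l, "_rm")]] <- numeric(g$in_c)
        p[[paste0("dbn", l, "_rv")]] <- rep(1, g$in_c)
      }
    }
    p
  })
  trainable <- setdiff(names(params),
                       grep("_(rm|rv)$", names(params), value = TRUE))
  structure(list(kind = "vae", input_shape = as.integer(input_shape), d = d,
                 widths = as.integer(widths), geoms = geoms, flat = flat,
                 kl_weight = kl_weight, slope = lrelu_slope,
                 params = params, trainable = trainable),
            class = c("vae_model", "feddis_model"))
}

#' Build a small convolutional classifier
#'
#' The task model used for federated classification experiments: the same
#' conv/batch-norm/leaky-ReLU stack as the VAE encoder followed by a single
#' linear layer producing class logits.
#'
#' @inheritParams build_vae
#' @param n_classes number of output classes.
#' @export
build_cnn_classifier <- function(input_shape, n_classes, widths = c(8L, 16L),
                                 kernel = 4L, stride = 2L, lrelu_slope = 0.2,
                                 seed = NULL) {
  n_classes <- assert_positive_int(n_classes, "n_classes")
  geoms <- build_geoms(input_shape, widths, kernel, stride)
  gl <- geoms[[length(geoms)]]
  flat <- gl$oh * gl$ow * gl$out_c
  params <- with_seed(seed, {
    p <- make_stack_params("enc", geoms)
    p$out_W <- init_weight(n_classes, flat, flat)
    p$out_b <- numeric(n_classes)
    p
  })
  trainable <- setdiff(names(params),
                       grep("_(rm|rv)$", names(params), value = TRUE))
  structure(list(kind = "cnn", input_shape = as.integer(input_shape),
                 n_classes = n_classes, widths = as.integer(widths),
                 geoms = geoms, flat = flat, slope = lrelu_slope,
                 params = params, trainable = trainable),
            class = c("cnn_model", "feddis_model"))
}

#' @export
print.feddis_model <- function(x, ...) {
  np <- sum(vapply(x$params[x$trainable], length, numeric(1)))
  cat(sprintf("<%s model> input %s, %s, %d trainable parameters\n",
              x$kind, paste(x$input_shape, collapse = "x"),
              if (x$kind == "vae") paste0("latent d=", x$d)
              else paste0(x$n_classes, " classes"),
              np))
  invisible(x)
}

check_input_shape <- function(model, images) {
  d <- dim(images)
  if (!identical(as.integer(d[1:3]),
                 as.integer(model$input_shape[c(2, 3, 1)]))) {
    stopf("image shape (%s) does not match the model input %s",
          paste(d[1:3], collapse = ", "),
          paste(model$input_shape[c(2, 3, 1)], collapse = "x"))
  }
}

# ---- VAE forward/backward --------------------------------------------------

vae_decoder_fw <- function(model, params, z, train) {
  L <- length(model$geoms)
  gl <- model$geoms[[L]]
  a0 <- dense_fw(z, params$fc_W, params$fc_b)
  t <- array(a0, c(gl$oh, gl$ow, gl$out_c, ncol(z)))
  caches <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g <- model$geoms[[l]]
    ct <- convT_fw(t, params[[paste0("dec", l, "_W")]],
                   params[[paste0("dec", l, "_b")]], g)
    cache <- list(xm = ct$xm)
    t <- ct$y
    if (l > 1) {
      bn <- bn_fw(t, params[[paste0("dbn", l, "_g")]],
                  params[[paste0("dbn", l, "_be")]],
                  params[[paste0("dbn", l, "_rm")]],
                  params[[paste0("dbn", l, "_rv")]], train)
      params[[paste0("dbn", l, "_rm")]] <- bn$rmean
      params[[paste0("dbn", l, "_rv")]] <- bn$rvar
      lf <- lrelu_fw(bn$y, model$slope)
      t <- lf$y
      cache$bn <- bn
      cache$mask <- lf$mask
    }
    caches[[l]] <- cache
  }
  list(pre = t, xhat = sigmoid(t), caches = caches, params = params)
}

vae_decoder_bw <- function(model, params, dpre, caches, n) {
  L <- length(model$geoms)
  grads <- list()
  dy <- dpre
  for (l in seq_len(L)) {
    g <- model$geoms[[l]]
    if (l > 1) {
      dy <- lrelu_bw(dy, caches[[l]]$mask, model$slope)
      bb <- bn_bw(dy, caches[[l]]$bn, params[[paste0("dbn", l, "_g")]])
      grads[[paste0("dbn", l, "_g")]] <- bb$dgamma
      grads[[paste0("dbn", l, "_be")]] <- bb$dbeta
      dy <- bb$dx
    }
    cb <- convT_bw(dy, caches[[l]]$xm, params[[paste0("dec", l, "_W")]], g)
    grads[[paste0("dec", l, "_W")]] <- cb$dW
    grads[[paste0("dec", l, "_b")]] <- cb$db
    dy <- cb$dx
  }
  gl <- model$geoms[[L]]
  da0 <- matrix(dy, gl$oh * gl$ow * gl$out_c, n)
  list(da0 = da0, grads = grads)
}

# one training step of the VAE objective: per-pixel mean squared
# reconstruction error + kl_weight * mean per-sample KL (summed over latent
# dimensions). Returns loss components, gradients and params with refreshed
# batch-norm running statistics.
vae_fb <- function(model, params, x, train = TRUE) {
  n <- dim(x)[4]
  ef <- stack_fw(x, params, "enc", model$geoms, model$slope, train)
  params <- ef$params
  hm <- matrix(ef$y, model$flat, n)
  mu <- dense_fw(hm, params$mu_W, params$mu_b)
  lv <- dense_fw(hm, params$lv_W, params$lv_b)
  if (train) {
    eps <- matrix(stats::rnorm(model$d * n), model$d, n)
    z <- mu + exp(0.5 * lv) * eps
  } else {
    eps <- NULL
    z <- mu
  }
  df <- vae_decoder_fw(model, params, z, train)
  params <- df$params
  xhat <- df$xhat

  recon <- mean((xhat - x)^2)
  klvec <- 0.5 * colSums(mu * mu + exp(lv) - lv - 1)
  kl <- mean(klvec)
  loss <- recon + model$kl_weight * kl
  if (!is.finite(loss)) stopf("non-finite VAE loss")

  # backward
  dpre <- (2 * (xhat - x) / length(x)) * xhat * (1 - xhat)
  db <- vae_decoder_bw(model, params, dpre, df$caches, n)
  grads <- db$grads
  fcb <- dense_bw(db$da0, z, params$fc_W)
  grads$fc_W <- fcb$dW
  grads$fc_b <- fcb$db
  dz <- fcb$dx
  dmu <- dz + model$kl_weight * mu / n
  if (train) {
    dlv <- dz * eps * 0.5 * exp(0.5 * lv) +
      model$kl_weight * 0.5 * (exp(lv) - 1) / n
  } else {
    dlv <- model$kl_weight * 0.5 * (exp(lv) - 1) / n
  }
  mb <- dense_bw(dmu, hm, params$mu_W)
  lb <- dense_bw(dlv, hm, params$lv_W)
  grads$mu_W <- mb$dW; grads$mu_b <- mb$db
  grads$lv_W <- lb$dW; grads$lv_b <- lb$db
  dhm <- mb$dx + lb$dx
  dh <- array(dhm, dim(ef$y))
  sb <- stack_bw(dh, ef$caches, params, "enc", model$geoms, model$slope)
  grads <- c(grads, sb$grads)
  list(loss = loss, recon = recon, kl = kl, grads = grads, params = params)
}

#' Variational autoencoder training objective
#'
#' Per-pixel mean squared reconstruction error plus the closed-form KL
#' divergence of the diagonal Gaussian posterior `N(mean, exp(log_variance))`
#' from the standard normal, `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)`
#' per sample, averaged over the batch.
#'
#' @param x image batch, `(H, W, C, N)` array.
#' @param recon decoder output of the same shape.
#' @param mean,log_variance `d x N` matrices from the encoder heads.
#' @param kl_weight weight applied to the KL term in `total`.
#' @return list with `total`, `reconstruction` and `kl` (unweighted) terms.
#' @export
vae_loss <- function(x, recon, mean, log_variance, kl_weight = 1) {
  if (!all(is.finite(x)) || !all(is.finite(recon)) ||
      !all(is.finite(mean)) || !all(is.finite(log_variance))) {
    stopf("non-finite inputs to vae_loss")
  }
  if (!identical(dim(x), dim(recon))) stopf("x and recon shapes differ")
  mean <- as.matrix(mean); log_variance <- as.matrix(log_variance)
  if (!identical(dim(mean), dim(log_variance))) {
    stopf("mean and log_variance shapes differ")
  }
  r <- base::mean((recon - x)^2)
  kl <- base::mean(0.5 * colSums(mean * mean + exp(log_variance) -
                                   log_variance - 1))
  list(total = r + kl_weight * kl, reconstruction = r, kl = kl)
}

# ---- CNN forward/backward --------------------------------------------------

cnn_fb <- function(model, params, x, y, train = TRUE) {
  n <- dim(x)[4]
  ef <- stack_fw(x, params, "enc", model$geoms, model$slope, train)
  params <- ef$params
  hm <- matrix(ef$y, model$flat, n)
  logits <- dense_fw(hm, params$out_W, params$out_b)
  mx <- apply(logits, 2, max)
  ex <- exp(logits - rep(mx, each = nrow(logits)))
  sm <- ex / rep(colSums(ex), each = nrow(logits))
  loss <- -mean(log(pmax(sm[cbind(y, seq_len(n))], 1e-300)))
  if (!is.finite(loss)) stopf("non-finite classifier loss")
  dlogits <- sm
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  dlogits <- dlogits / n
  ob <- dense_bw(dlogits, hm, params$out_W)
  grads <- list(out_W = ob$dW, out_b = ob$db)
  dh <- array(ob$dx, dim(ef$y))
  sb <- stack_bw(dh, ef$caches, params, "enc", model$geoms, model$slope)
  grads <- c(grads, sb$grads)
  list(loss = loss, grads = grads, params = params)
}

model_fb <- function(model, params, x, y = NULL, train = TRUE) {
  switch(model$kind,
         vae = vae_fb(model, params, x, train),
         cnn = cnn_fb(model, params, x, y, train),
         stopf("unknown model kind '%s'", model$kind))
}

# ---- inference entry points ------------------------------------------------

#' Encode images to latent mean and variance
#'
#' Runs the encoder in inference mode (batch-norm uses running statistics, no
#' latent noise) and returns, for each image, the latent mean vector and the
#' diagonal of the latent covariance. The variance is the exponential of the
#' log-variance head and is therefore strictly positive.
#'
#' @param model a `vae_model`.
#' @param images `(H, W, C)` or `(H, W, C, N)` array of normalized pixels.
#' @param params parameter list; defaults to the model's own.
#' @return object of class `latent_encoding`: list with `mean` and `variance`
#'   (`d x N` matrices) and `d`.
#' @export
vae_encode <- function(model, images, params = model$params) {
  images <- as_image_batch(images)
  check_input_shape(model, images)
  n <- dim(images)[4]
  ef <- stack_fw(images, params, "enc", model$geoms, model$slope, train = FALSE)
  hm <- matrix(ef$y, model$flat, n)
  mu <- dense_fw(hm, params$mu_W, params$mu_b)
  va <- exp(dense_fw(hm, params$lv_W, params$lv_b))
  if (!all(is.finite(mu)) || !all(is.finite(va))) {
    stopf("encoder produced non-finite output")
  }
  structure(list(mean = mu, variance = va, d = model$d),
            class = "latent_encoding")
}

#' Decode latent vectors to images
#'
#' Inference-mode decoder pass; output pixels are sigmoid-squashed into
#' `[0, 1]` and have the model's input shape.
#'
#' @param model a `vae_model`.
#' @param z `d x N` matrix (or length-`d` vector) of latent codes.
#' @param params parameter list; defaults to the model's own.
#' @export
vae_decode <- function(model, z, params = model$params) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (nrow(z) != model$d) stopf("latent dimension %d != model d %d",
                                nrow(z), model$d)
  vae_decoder_fw(model, params, z, train = FALSE)$xhat
}

#' Mean squared reconstruction error of a VAE on an image set
#'
#' Encodes each image, decodes its latent mean, and returns the mean squared
#' pixel error — the deterministic inference-mode reconstruction loss.
#' @inheritParams vae_encode
#' @export
reconstruction_error <- function(model, images, params = model$params) {
  images <- as_image_batch(images)
  enc <- vae_encode(model, images, params)
  xhat <- vae_decode(model, enc$mean, params)
  mean((xhat - images)^2)
}

predict_logits <- function(model, params, images, chunk = 256L) {
  images <- as_image_batch(images)
  check_input_shape(model, images)
  n <- dim(images)[4]
  out <- matrix(0, model$n_classes, n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    xb <- images[, , , s:e, drop = FALSE]
    ef <- stack_fw(xb, params, "enc", model$geoms, model$slope, train = FALSE)
    hm <- matrix(ef$y, model$flat, e - s + 1)
    out[, s:e] <- dense_fw(hm, params$out_W, params$out_b)
  }
  out
}

# ---- local training --------------------------------------------------------

#' Configuration of local model training
#'
#' Defaults mirror the reference setup: Adam with learning rate `1e-4`,
#' batch size 64, and parameter upload every two local epochs.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param local_epochs epochs per communication round.
#' @param seed base RNG seed for shuffling and latent noise.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 64L,
                            local_epochs = 2L, seed = NULL) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  batch_size <- assert_positive_int(batch_size, "batch_size")
  if (local_epochs < 0) stopf("local_epochs must be non-negative")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 local_epochs = as.integer(local_epochs), seed = seed),
            class = "training_config")
}

#' Train a model locally on one client shard
#'
#' Runs `epochs` epochs of Adam on the shard with seeded shuffling; for a VAE
#' the labels are ignored, for a classifier they supply the cross-entropy
#' targets. Fresh optimizer state is created per call, matching a federated
#' round where clients restart their optimizer after each global update.
#'
#' @param model a `feddis_model`; `params` defaults to its parameters.
#' @param shard a [client_dataset()] (or any list with `images` and `labels`).
#' @param config a [training_config()].
#' @param epochs number of passes over the shard; 0 returns the parameters
#'   unchanged.
#' @param seed RNG seed making the run reproducible.
#' @param params starting parameters (e.g. the current global model).
#' @return list with updated `params` and `loss_trace` (mean loss per epoch).
#' @export
train_local <- function(model, shard, config = training_config(),
                        epochs = config$local_epochs, seed = NULL,
                        params = model$params) {
  images <- as_image_batch(shard$images)
  n <- dim(images)[4]
  if (n == 0) stopf("cannot train on an empty shard")
  labels <- if (model$kind == "cnn") label_int(shard) else NULL
  with_seed(seed, {
    state <- adam_init(params, model$trainable)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      bl <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        ix <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, n)]
        fb <- model_fb(model, params,
                       images[, , , ix, drop = FALSE],
                       if (is.null(labels)) NULL else labels[ix],
                       train = TRUE)
        params <- fb$params
        st <- adam_step(state, params, fb$grads, config$learning_rate)
        state <- st$state
        params <- st$params
        bl[bi] <- fb$loss
      }
      trace[ep] <- mean(bl)
    }
    list(params = params, loss_trace = trace)
  })
}
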