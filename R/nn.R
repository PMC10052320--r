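# Minimal neural-network primitives used by the VAE and the task CNN.
#
# Tensors are base-R arrays laid out (H, W, C, N), column-major, batch last.
# Convolutions are computed by im2col + BLAS matrix products; the transposed
# convolution reuses the same geometry with the roles of the gather/scatter
# swapped, which makes the two exact adjoints of each other.

# Geometry of one strided convolution between a "big" (in_h, in_w, in_c) map
# and a "small" (oh, ow, out_c) map. The same object drives the forward
# convolution (big -> small) and the transposed convolution (small -> big).
conv_geom <- function(in_h, in_w, in_c, out_c, kernel = 4L, stride = 2L, pad = 1L) {
  oh <- (in_h + 2 * pad - kernel) / stride + 1
  ow <- (in_w + 2 * pad - kernel) / stride + 1
  if (oh != floor(oh) || ow != floor(ow) || oh < 1 || ow < 1) {
    stopf("input %dx%d is incompatible with kernel %d, stride %d, pad %d",
          in_h, in_w, kernel, stride, pad)
  }
  oh <- as.integer(oh); ow <- as.integer(ow)
  hp <- as.integer(in_h + 2 * pad); wp <- as.integer(in_w + 2 * pad)
  # kernel-element offsets within the padded image (row index fastest)
  dy <- rep(0:(kernel - 1L), times = kernel * in_c)
  dx <- rep(rep(0:(kernel - 1L), each = kernel), times = in_c)
  cc <- rep(0:(in_c - 1L), each = kernel * kernel)
  koff <- dy + dx * hp + cc * hp * wp
  # output positions, column-major over (oy, ox)
  oy <- rep(0:(oh - 1L), times = ow)
  ox <- rep(0:(ow - 1L), each = oh)
  base <- oy * stride + ox * stride * hp
  idx <- outer(koff, base, `+`) + 1L
  storage.mode(idx) <- "integer"
  idx <- as.vector(idx)
  list(in_h = as.integer(in_h), in_w = as.integer(in_w),
       in_c = as.integer(in_c), out_c = as.integer(out_c),
       k = as.integer(kernel), s = as.integer(stride), p = as.integer(pad),
       oh = oh, ow = ow, hp = hp, wp = wp,
       K = length(koff), P = oh * ow,
       idx = idx, uidx = sort(unique(idx)))
}

pad_input <- function(x, g) {
  n <- dim(x)[4]
  if (g$p == 0L) return(x)
  xp <- array(0, c(g$hp, g$wp, g$in_c, n))
  xp[(g$p + 1):(g$p + g$in_h), (g$p + 1):(g$p + g$in_w), , ] <- x
  xp
}

# gather patches: returns a K x (P*N) matrix
im2col <- function(x, g) {
  n <- dim(x)[4]
  xm <- matrix(pad_input(x, g), g$hp * g$wp * g$in_c, n)
  cols <- xm[g$idx, , drop = FALSE]
  dim(cols) <- c(g$K, g$P * n)
  cols
}

# scatter-add patches back: adjoint of im2col
col2im <- function(cols, g, n) {
  dim(cols) <- c(g$K * g$P, n)
  acc <- rowsum(cols, group = g$idx, reorder = TRUE)
  xm <- matrix(0, g$hp * g$wp * g$in_c, n)
  xm[g$uidx, ] <- acc
  xp <- array(xm, c(g$hp, g$wp, g$in_c, n))
  if (g$p > 0L) {
    xp <- xp[(g$p + 1):(g$p + g$in_h), (g$p + 1):(g$p + g$in_w), , , drop = FALSE]
  }
  xp
}

# W: (out_c x K), b: length out_c
conv_fw <- function(x, W, b, g) {
  n <- dim(x)[4]
  cols <- im2col(x, g)
  out <- W %*% cols + b
  y <- aperm(array(out, c(g$out_c, g$oh, g$ow, n)), c(2, 3, 1, 4))
  list(y = y, cols = cols)
}

conv_bw <- function(dy, cols, W, g) {
  n <- dim(dy)[4]
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), g$out_c, g$P * n)
  list(dx = col2im(crossprod(W, dym), g, n),
       dW = tcrossprod(dym, cols),
       db = rowSums(dym))
}

# transposed convolution small -> big; same W shape as the paired conv
convT_fw <- function(x, W, b, g) {
  n <- dim(x)[4]
  xm <- matrix(aperm(x, c(3, 1, 2, 4)), g$out_c, g$P * n)
  y <- col2im(crossprod(W, xm), g, n)
  y <- y + rep(b, each = g$in_h * g$in_w)
  list(y = y, xm = xm)
}

convT_bw <- function(dy, xm, W, g) {
  n <- dim(dy)[4]
  dcols <- im2col(dy, g)
  dxm <- W %*% dcols
  list(dx = aperm(array(dxm, c(g$out_c, g$oh, g$ow, n)), c(2, 3, 1, 4)),
       dW = tcrossprod(xm, dcols),
       db = rowSums(matrix(aperm(dy, c(3, 1, 2, 4)), g$in_c, g$in_h * g$in_w * n)))
}

# Batch normalization over (H, W, N) per channel. Running stats follow the
# usual convention: biased variance inside the batch, unbiased in the
# running estimate, momentum 0.1.
bn_fw <- function(x, gamma, beta, rmean, rvar, train,
                  eps = 1e-5, momentum = 0.1) {
  d <- dim(x); C <- d[3]; M <- d[1] * d[2] * d[4]
  xc <- matrix(aperm(x, c(3, 1, 2, 4)), C, M)
  if (train) {
    mu <- rowMeans(xc)
    v <- pmax(rowMeans(xc * xc) - mu * mu, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    corr <- if (M > 1) M / (M - 1) else 1
    rvar <- (1 - momentum) * rvar + momentum * v * corr
  } else {
    mu <- rmean; v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xc - mu) * inv
  y <- aperm(array(gamma * xhat + beta, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(y = y, xhat = xhat, inv = inv, rmean = rmean, rvar = rvar, dims = d,
       train = train)
}

bn_bw <- function(dy, cache, gamma) {
  d <- cache$dims; C <- d[3]; M <- d[1] * d[2] * d[4]
  dyc <- matrix(aperm(dy, c(3, 1, 2, 4)), C, M)
  dgamma <- rowSums(dyc * cache$xhat)
  dbeta <- rowSums(dyc)
  dxhat <- dyc * gamma
  if (cache$train) {
    dxc <- (cache$inv / M) *
      (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dxc <- dxhat * cache$inv
  }
  list(dx = aperm(array(dxc, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4)),
       dgamma = dgamma, dbeta = dbeta)
}

lrelu_fw <- function(x, slope) {
  list(y = pmax(x, 0) + slope * pmin(x, 0), mask = x > 0)
}

lrelu_bw <- function(dy, mask, slope) dy * (mask + slope * !mask)

sigmoid <- function(x) 1 / (1 + exp(-x))

# dense layer on (features x N) matrices
dense_fw <- function(x, W, b) W %*% x + b

dense_bw <- function(dy, x, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, trainable) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in trainable) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

# He-style initialisation for a weight matrix with given fan-in
init_weight <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}
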