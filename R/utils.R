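# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so seeded
#' operations do not perturb the surrounding random stream. With `seed = NULL`
#' the expression runs on the current stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation (Lehmer-style mixing, exact in doubles:
# every intermediate product stays below 2^53). Keeps results < 2^31.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 48271 + (as.numeric(k) + 1) * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483562) + 1L
}

assert_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x != as.integer(x) || x <= 0) {
    stopf("`%s` must be a single positive integer", name)
  }
  invisible(as.integer(x))
}

# images are stored as (H, W, C, N) arrays; accept (H, W, C) for a single image
as_image_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    stopf("images must be (H, W, C) or (H, W, C, N) arrays")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

n_images <- function(x) dim(as_image_batch(x))[4]

# flatten an image batch to a (pixels x N) matrix, column per image
flatten_images <- function(x) {
  x <- as_image_batch(x)
  d <- dim(x)
  matrix(x, prod(d[1:3]), d[4])
}
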