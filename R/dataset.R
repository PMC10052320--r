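# Labeled image-set containers.
#
# A dataset is images (H, W, C, N) plus a parallel factor of class labels;
# a client_dataset additionally knows its client id and which samples are
# original versus decoder-generated.

#' Construct a labeled image dataset
#'
#' @param images `(H, W, C, N)` array of normalized pixels in `[0, 1]`.
#' @param labels class labels, coerced to a factor of length `N`. Supply a
#'   factor with explicit levels to fix the class vocabulary across shards.
#' @param ids optional stable sample identifiers (default `1:N`).
#' @export
image_dataset <- function(images, labels, ids = NULL) {
  images <- as_image_batch(images)
  n <- dim(images)[4]
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(labels) != n) stopf("labels length %d != %d images",
                                 length(labels), n)
  ids <- ids %||% seq_len(n)
  structure(list(images = images, labels = labels, ids = ids),
            class = "image_dataset")
}

#' One client's labeled image shard
#'
#' @param client_id identifier of the owning client.
#' @param images,labels,ids as in [image_dataset()].
#' @param synthetic logical vector flagging decoder-generated samples;
#'   defaults to all-`FALSE` (an un-augmented shard).
#' @export
client_dataset <- function(client_id, images, labels, ids = NULL,
                           synthetic = NULL) {
  ds <- image_dataset(images, labels, ids)
  n <- dim(ds$images)[4]
  synthetic <- synthetic %||% rep(FALSE, n)
  if (length(synthetic) != n) stopf("synthetic flag length mismatch")
  structure(list(client_id = client_id, images = ds$images,
                 labels = ds$labels, ids = ds$ids, synthetic = synthetic),
            class = c("client_dataset", "image_dataset"))
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  hd <- if (inherits(x, "client_dataset")) {
    sprintf("<client_dataset '%s'>", x$client_id)
  } else "<image_dataset>"
  cat(sprintf("%s %d images (%dx%dx%d)\n", hd, d[4], d[3], d[1], d[2]))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (inherits(x, "client_dataset") && any(x$synthetic)) {
    cat(sprintf("  %d original + %d generated\n",
                sum(!x$synthetic), sum(x$synthetic)))
  }
  invisible(x)
}

#' Number of samples in a dataset or shard
#' @param ds an [image_dataset()] or [client_dataset()].
#' @export
dataset_size <- function(ds) dim(ds$images)[4]

label_int <- function(ds) as.integer(ds$labels)

subset_dataset <- function(ds, ix) {
  out <- ds
  out$images <- ds$images[, , , ix, drop = FALSE]
  out$labels <- ds$labels[ix]
  out$ids <- ds$ids[ix]
  if (!is.null(ds$synthetic)) out$synthetic <- ds$synthetic[ix]
  out
}

#' Empirical class distribution of a dataset
#'
#' Relative frequency of each factor level (including empty levels), in the
#' level order of the dataset's labels.
#' @param ds an [image_dataset()] or [client_dataset()].
#' @export
class_distribution <- function(ds) {
  tab <- table(ds$labels)
  as.numeric(tab) / sum(tab)
}
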