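# Client-side augmentation: decode latent draws from received distribution
# information into synthetic labeled images and merge them into the shard.
# After merging, every client's label histogram equals the global one, which
# removes label-distribution heterogeneity exactly.

#' Generate synthetic samples for a client from foreign distribution info
#'
#' For every received payload and every class in it, draws that class's count
#' of latent vectors from the shared parameters and decodes them with the
#' stage-one global decoder. The generated set therefore has exactly
#' `sum(total_count)` samples over the foreign payloads, with a label
#' histogram equal to the senders' pooled class counts.
#'
#' @param client_id the receiving client; its own payload must not be in
#'   `foreign_dis`.
#' @param foreign_dis list of [distribution_info()] from the other clients.
#' @param model the global `vae_model` whose decoder is used.
#' @param seed RNG seed; the same seed and payloads give bit-identical
#'   latent draws.
#' @param params decoder parameters, defaulting to the model's own.
#' @param class_levels optional character vector fixing the label levels of
#'   the generated samples (defaults to the classes seen in the payloads).
#' @return list with `images`, `labels` (factor) and `z` (the latent draws).
#' @export
generate_for_client <- function(client_id, foreign_dis, model, seed = NULL,
                                params = model$params, class_levels = NULL) {
  if (length(foreign_dis) == 0) {
    stopf("no foreign distribution information supplied")
  }
  own <- vapply(foreign_dis, function(di) identical(di$client_id, client_id),
                logical(1))
  if (any(own)) {
    stopf("client '%s' received its own distribution information", client_id)
  }
  fams <- unique(vapply(foreign_dis, `[[`, "", "family"))
  if (length(fams) != 1) {
    stopf("all shared payloads must use the same family (got: %s)",
          paste(fams, collapse = ", "))
  }
  zs <- list(); labs <- character(0)
  for (i in seq_along(foreign_dis)) {
    di <- foreign_dis[[i]]
    for (cl in names(di$per_class_params)) {
      cnt <- di$per_class_counts[[cl]]
      if (cnt == 0) next
      zs[[length(zs) + 1]] <- sample_latent(
        di$per_class_params[[cl]], di$family, cnt,
        seed = if (is.null(seed)) NULL else derive_seed(seed, i, match(cl, names(di$per_class_params))))
      labs <- c(labs, rep(cl, cnt))
    }
  }
  z <- do.call(cbind, zs)
  images <- decode_in_chunks(model, z, params)
  class_levels <- class_levels %||% sort(unique(labs))
  list(images = images, labels = factor(labs, levels = class_levels), z = z)
}

decode_in_chunks <- function(model, z, params, chunk = 256L) {
  n <- ncol(z)
  shp <- model$input_shape
  out <- array(0, c(shp[2], shp[3], shp[1], n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    out[, , , s:e] <- vae_decode(model, z[, s:e, drop = FALSE], params)
  }
  out
}

#' Merge generated samples into a client shard
#'
#' Returns the augmented shard `X' = X  union  D`: original samples keep
#' `synthetic = FALSE`, generated ones are flagged `TRUE`, and the merged
#' size is `|X| + |D|`. With payloads reporting true counts, every client's
#' merged label histogram equals the global training histogram.
#'
#' @param shard a [client_dataset()].
#' @param generated output of [generate_for_client()] (an empty/`NULL` value
#'   returns the shard unchanged).
#' @export
merge_augmented <- function(shard, generated) {
  if (is.null(generated) || length(generated$labels) == 0) return(shard)
  if (!all(levels(generated$labels) %in% levels(shard$labels))) {
    stopf("generated labels outside the shard's label vocabulary")
  }
  gl <- factor(as.character(generated$labels), levels = levels(shard$labels))
  n_new <- dim(generated$images)[4]
  images <- array(c(shard$images, generated$images),
                  dim = dim(shard$images) + c(0, 0, 0, n_new))
  client_dataset(
    shard$client_id, images,
    factor(c(as.character(shard$labels), as.character(gl)),
           levels = levels(shard$labels)),
    ids = c(shard$ids, sprintf("%s_gen%d", shard$client_id, seq_len(n_new))),
    synthetic = c(shard$synthetic, rep(TRUE, n_new)))
}

#' @rdname merge_augmented
#' @param x,y,... S3 method arguments: `x` is the shard, `y` the generated
#'   set.
#' @export
merge.client_dataset <- function(x, y, ...) merge_augmented(x, y)

#' Augment every client from the others' distribution information
#'
#' The broadcast-and-augment step: each client receives all payloads except
#' its own, generates the matching synthetic samples, and merges them into
#' its shard.
#'
#' @param clients list of [client_dataset()].
#' @param dis list of [distribution_info()] aligned with `clients`.
#' @param model global `vae_model`.
#' @param seed experiment seed; per-client generation seeds are derived from
#'   it.
#' @return list of augmented [client_dataset()].
#' @export
augment_clients <- function(clients, dis, model, seed = NULL) {
  stopifnot(length(clients) == length(dis))
  lapply(seq_along(clients), function(k) {
    gen <- generate_for_client(
      clients[[k]]$client_id, dis[-k], model,
      seed = if (is.null(seed)) NULL else derive_seed(seed, 7L, k),
      class_levels = levels(clients[[k]]$labels))
    merge_augmented(clients[[k]], gen)
  })
}
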