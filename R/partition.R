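# Non-IID partitioners and the earth mover's distance heterogeneity measure.

#' Specification of a non-IID partition
#'
#' @param mode `"proportions"` (explicit per-class client fractions) or
#'   `"dirichlet"` (label-skew with concentration `beta`).
#' @param proportions classes x clients matrix of fractions; each row must
#'   sum to 1 (tolerance 1e-9). Required for `mode = "proportions"`.
#' @param beta Dirichlet concentration; smaller values give more skew.
#' @param m number of clients.
#' @param seed RNG seed for the (seeded) shuffles and draws.
#' @export
partition_spec <- function(mode = c("proportions", "dirichlet"),
                           proportions = NULL, beta = NULL, m = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "proportions") {
    if (is.null(proportions)) stopf("proportions mode needs a fraction matrix")
    proportions <- as.matrix(proportions)
    if (any(proportions < 0) ||
        any(abs(rowSums(proportions) - 1) > 1e-9)) {
      stopf("each row of `proportions` must be non-negative and sum to 1")
    }
    m <- ncol(proportions)
  } else {
    if (is.null(beta) || beta <= 0) stopf("`beta` must be > 0")
    if (is.null(m) || m < 2) stopf("`m` must be >= 2")
  }
  structure(list(mode = mode, proportions = proportions, beta = beta,
                 m = as.integer(m), seed = seed),
            class = "partition_spec")
}

make_shards <- function(dataset, assignment, m) {
  lapply(seq_len(m), function(j) {
    ix <- which(assignment == j)
    client_dataset(sprintf("client%d", j),
                   dataset$images[, , , ix, drop = FALSE],
                   dataset$labels[ix], ids = dataset$ids[ix])
  })
}

#' Partition a dataset by explicit per-class proportions
#'
#' For every class, the samples are shuffled (seeded) and split so that
#' client `j < m` receives `round(fraction_j * n_class)` samples and the last
#' client takes the remainder. Shards are pairwise disjoint and cover the
#' dataset. An IID reference split is this mode with uniform fractions.
#'
#' @param dataset an [image_dataset()].
#' @param proportions classes x clients fraction matrix (rows sum to 1), rows
#'   ordered like `levels(dataset$labels)`.
#' @param seed RNG seed.
#' @return list of [client_dataset()] shards.
#' @export
partition_by_proportions <- function(dataset, proportions, seed = NULL) {
  spec <- partition_spec("proportions", proportions = proportions, seed = seed)
  proportions <- spec$proportions
  labs <- levels(dataset$labels)
  if (nrow(proportions) != length(labs)) {
    stopf("proportions has %d rows but the dataset has %d classes",
          nrow(proportions), length(labs))
  }
  m <- spec$m
  n <- dataset_size(dataset)
  assignment <- integer(n)
  with_seed(seed, {
    for (ci in seq_along(labs)) {
      ix <- sample(which(dataset$labels == labs[ci]))
      nc <- length(ix)
      counts <- round(proportions[ci, -m] * nc)
      counts <- c(counts, nc - sum(counts))
      if (counts[m] < 0) stopf("rounding left a negative remainder for class %s",
                               labs[ci])
      assignment[ix] <- rep(seq_len(m), counts)
    }
  })
  make_shards(dataset, assignment, m)
}

#' Dirichlet label-skew partition
#'
#' For each class a proportion vector is drawn from `Dirichlet(beta * 1_m)`
#' and the class's samples are allocated to clients by a multinomial draw.
#' Every sample is assigned exactly once; draws that leave any client empty
#' are rejected and redrawn up to `max_retry` times.
#'
#' @param dataset an [image_dataset()].
#' @param beta concentration parameter (> 0); smaller means more skew.
#' @param m number of clients.
#' @param seed RNG seed.
#' @param max_retry redraw cap for empty-shard rejection.
#' @return list of [client_dataset()] shards.
#' @export
partition_dirichlet <- function(dataset, beta, m, seed = NULL,
                                max_retry = 100L) {
  spec <- partition_spec("dirichlet", beta = beta, m = m, seed = seed)
  n <- dataset_size(dataset)
  labs <- levels(dataset$labels)
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      assignment <- integer(n)
      for (cl in labs) {
        ix <- which(dataset$labels == cl)
        g <- stats::rgamma(spec$m, shape = spec$beta)
        if (all(g == 0)) g <- rep(1, spec$m)
        assignment[ix] <- sample.int(spec$m, length(ix), replace = TRUE,
                                     prob = g / sum(g))
      }
      if (all(tabulate(assignment, spec$m) > 0)) {
        return(make_shards(dataset, assignment, spec$m))
      }
    }
    stopf("could not draw a partition without empty shards in %d attempts",
          max_retry)
  })
}

#' Earth mover's distance between two class distributions
#'
#' EMD under the categorical ground metric (unit cost between distinct class
#' labels), which for probability vectors equals half the L1 distance. It is
#' a metric on the simplex: non-negative, symmetric, zero iff `p == q`, and
#' satisfies the triangle inequality.
#'
#' @param p,q probability vectors of equal length, each summing to 1
#'   (tolerance 1e-8).
#' @export
emd <- function(p, q) {
  if (length(p) != length(q)) stopf("p and q must have the same length")
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stopf("p and q must be probability vectors summing to 1")
  }
  sum(abs(p - q)) / 2
}

#' Pairwise heterogeneity matrix of client shards
#'
#' Symmetric matrix of [emd()] between the empirical class distributions of
#' every pair of clients (zero diagonal). Label levels are shared across
#' shards, so classes absent from a shard count as probability zero.
#'
#' @param clients list of [client_dataset()] (at least 2).
#' @export
pairwise_emd <- function(clients) {
  if (length(clients) < 2) stopf("need at least 2 clients")
  dists <- lapply(clients, class_distribution)
  m <- length(clients)
  out <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      out[i, j] <- out[j, i] <- emd(dists[[i]], dists[[j]])
    }
  }
  rownames(out) <- colnames(out) <-
    vapply(clients, function(cl) as.character(cl$client_id), "")
  out
}

#' Write and read a partition manifest
#'
#' Records which sample ids each client holds, as JSON, so a partition can be
#' replayed exactly on the same dataset.
#' @param clients list of [client_dataset()].
#' @param path file path.
#' @export
write_partition_manifest <- function(clients, path) {
  manifest <- lapply(clients, function(cl) {
    list(client_id = cl$client_id, sample_ids = cl$ids)
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_manifest
#' @param dataset dataset the manifest indexes into.
#' @export
read_partition_manifest <- function(dataset, path) {
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(manifest, function(entry) {
    ix <- match(unlist(entry$sample_ids), dataset$ids)
    if (anyNA(ix)) stopf("manifest references unknown sample ids")
    client_dataset(entry$client_id,
                   dataset$images[, , , ix, drop = FALSE],
                   dataset$labels[ix], ids = dataset$ids[ix])
  })
}
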