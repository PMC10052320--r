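# Evaluation and privacy metrics: set distance, maximum structural
# similarity, the generated-vs-original training-loss gap, delta-accuracy
# loss, and test accuracy.

#' Minimum Euclidean distance between two image sets
#'
#' `inf over x in A, y in B of ||x - y||_2` with images flattened to
#' vectors: the privacy-leakage distance between a generated set and the
#' original set. Zero iff the sets share an element; symmetric in its
#' arguments.
#'
#' @param A,B non-empty image sets: `(H, W, C, N)` arrays or `p x n`
#'   matrices (column per point) of equal point dimension.
#' @export
set_distance <- function(A, B) {
  Am <- if (is.matrix(A)) A else flatten_images(A)
  Bm <- if (is.matrix(B)) B else flatten_images(B)
  if (ncol(Am) == 0 || ncol(Bm) == 0) stopf("sets must be non-empty")
  if (nrow(Am) != nrow(Bm)) {
    stopf("points of A and B have different dimensions (%d vs %d)",
          nrow(Am), nrow(Bm))
  }
  best <- Inf
  for (i in seq_len(ncol(Am))) {
    d2 <- colSums((Bm - Am[, i])^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# ---- structural similarity -------------------------------------------------

# reflect-pad a matrix by r pixels on every side (half-sample symmetric,
# edge pixel duplicated)
reflect_pad <- function(x, r) {
  n1 <- nrow(x); n2 <- ncol(x)
  i1 <- c(r:1, 1:n1, n1:(n1 - r + 1))
  i2 <- c(r:1, 1:n2, n2:(n2 - r + 1))
  x[i1, i2]
}

# separable Gaussian filtering with reflect padding; returns a map of the
# input's size
gauss_filter <- function(x, win = 11L, sigma = 1.5) {
  r <- (win - 1L) %/% 2L
  g <- exp(-((seq_len(win) - r - 1)^2) / (2 * sigma^2))
  g <- g / sum(g)
  xp <- reflect_pad(x, r)
  n1 <- nrow(x); n2 <- ncol(x)
  Fh <- matrix(0, n1, n1 + 2 * r)
  for (i in seq_len(n1)) Fh[i, i:(i + win - 1)] <- g
  Fw <- matrix(0, n2, n2 + 2 * r)
  for (i in seq_len(n2)) Fw[i, i:(i + win - 1)] <- g
  Fh %*% xp %*% t(Fw)
}

#' Structural similarity index of two grayscale images
#'
#' Standard windowed SSIM: an 11x11 Gaussian window (sigma 1.5), stabilizing
#' constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, population (uncentered
#' window) moments, and averaging over window positions whose support lies
#' inside the image (border positions touched by padding are cropped).
#'
#' @param x,y numeric matrices of the same dimensions; pixel values on
#'   `[0, data_range]`.
#' @param data_range dynamic range `L`; 1 for normalized images.
#' @param win,sigma Gaussian window size and width.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = 1, win = 11L, sigma = 1.5) {
  x <- drop(x); y <- drop(y)
  if (!is.matrix(x) || !is.matrix(y) || !identical(dim(x), dim(y))) {
    stopf("x and y must be matrices of identical dimensions")
  }
  r <- (win - 1L) %/% 2L
  if (any(dim(x) <= 2 * r)) stopf("images smaller than the SSIM window")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mx <- gauss_filter(x, win, sigma)
  my <- gauss_filter(y, win, sigma)
  sxx <- gauss_filter(x * x, win, sigma) - mx * mx
  syy <- gauss_filter(y * y, win, sigma) - my * my
  sxy <- gauss_filter(x * y, win, sigma) - mx * my
  S <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx * mx + my * my + C1) * (sxx + syy + C2))
  keep1 <- (r + 1):(nrow(x) - r)
  keep2 <- (r + 1):(ncol(x) - r)
  mean(S[keep1, keep2])
}

#' Maximum structural similarity between two image sets
#'
#' `max over x in A, y in B of SSIM(x, y)`: the privacy-leakage indicator. A
#' value of 1 means some generated image is an exact copy of an original.
#'
#' @param A,B grayscale image sets as `(H, W, 1, N)` arrays (or lists of
#'   matrices) with matching image shapes.
#' @inheritParams ssim
#' @export
max_ssim <- function(A, B, data_range = 1, win = 11L, sigma = 1.5) {
  as_list <- function(S) {
    if (is.list(S)) return(lapply(S, drop))
    S <- as_image_batch(S)
    if (dim(S)[3] != 1) stopf("max_ssim expects grayscale images")
    lapply(seq_len(dim(S)[4]), function(i) S[, , 1, i])
  }
  A <- as_list(A); B <- as_list(B)
  if (length(A) == 0 || length(B) == 0) stopf("sets must be non-empty")
  best <- -Inf
  for (x in A) for (y in B) {
    best <- max(best, ssim(x, y, data_range, win, sigma))
  }
  best
}

# ---- task-model based metrics ----------------------------------------------

mean_cross_entropy <- function(model, ds, params) {
  logits <- predict_logits(model, params, ds$images)
  y <- label_int(ds)
  if (max(y) > nrow(logits)) stopf("label outside the model's class range")
  mx <- apply(logits, 2, max)
  logz <- mx + log(colSums(exp(logits - rep(mx, each = nrow(logits)))))
  mean(logz - logits[cbind(y, seq_along(y))])
}

#' Training-loss gap between original and generated data
#'
#' Absolute difference between the mean cross-entropy loss of a fixed task
#' model on the original labeled set and on the generated labeled set:
#' values near zero mean the generated data drive the task loss like the
#' real data do.
#'
#' @param model a classifier with a `predict_logits` contract (any list with
#'   `kind = "cnn"` built by [build_cnn_classifier()], or a stub exposing
#'   `$predict(params, images)` for testing).
#' @param real,generated labeled [image_dataset()]s over the same label
#'   vocabulary.
#' @param params fixed model parameters.
#' @export
dpgo <- function(model, real, generated, params = model$params) {
  if (dataset_size(real) == 0 || dataset_size(generated) == 0) {
    stopf("both sets must be non-empty")
  }
  if (!identical(levels(real$labels), levels(generated$labels))) {
    stopf("label vocabularies of the two sets differ")
  }
  if (!is.null(model$predict)) {
    ce <- function(ds) {
      logits <- model$predict(params, ds$images)
      y <- label_int(ds)
      mx <- apply(logits, 2, max)
      logz <- mx + log(colSums(exp(logits - rep(mx, each = nrow(logits)))))
      mean(logz - logits[cbind(y, seq_along(y))])
    }
    return(abs(ce(real) - ce(generated)))
  }
  abs(mean_cross_entropy(model, real, params) -
        mean_cross_entropy(model, generated, params))
}

#' Delta-accuracy loss of a federated method
#'
#' Federated test accuracy minus centralized test accuracy, both in percent.
#' Negative values mean the federated method outperformed centralized
#' training (possible when augmentation enlarges the training data).
#'
#' @param federated_acc,centralized_acc accuracies in `[0, 100]`.
#' @export
delta_accuracy_loss <- function(federated_acc, centralized_acc) {
  if (federated_acc < 0 || federated_acc > 100 ||
      centralized_acc < 0 || centralized_acc > 100) {
    stopf("accuracies must be on the percent scale [0, 100]")
  }
  federated_acc - centralized_acc
}

#' Test-set accuracy of a classifier, in percent
#'
#' Fraction of argmax-correct predictions times 100; ties between class
#' scores are broken toward the lowest class index. Deterministic for fixed
#' parameters (inference-mode batch norm).
#'
#' @param model classifier model (or stub with `$predict`).
#' @param test_set labeled [image_dataset()].
#' @param params model parameters.
#' @export
evaluate_accuracy <- function(model, test_set, params = model$params) {
  if (dataset_size(test_set) == 0) stopf("empty test set")
  logits <- if (!is.null(model$predict)) {
    model$predict(params, test_set$images)
  } else {
    predict_logits(model, params, test_set$images)
  }
  pred <- apply(logits, 2, which.max)
  100 * mean(pred == label_int(test_set))
}

# ---- report ----------------------------------------------------------------

#' Bundle experiment metrics into a report
#'
#' @param ... named metric entries (scalars, vectors, matrices or round
#'   tables).
#' @export
metrics_report <- function(...) {
  structure(list(...), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1) {
      cat(sprintf("  %s: %.4g\n", nm, v))
    } else {
      cat(sprintf("  %s: <%s>\n", nm, paste(class(v), collapse = "/")))
    }
  }
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON; any element that is a data frame (e.g. a
#' per-round accuracy table) can also be written to CSV alongside.
#' @param report a [metrics_report()].
#' @param path JSON output path.
#' @param csv_dir optional directory for per-table CSV files.
#' @export
write_metrics_report <- function(report, path, csv_dir = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(report)) {
      if (is.data.frame(report[[nm]])) {
        utils::write.csv(report[[nm]],
                         file.path(csv_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  invisible(path)
}
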