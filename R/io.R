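# Dataset file formats: the class-subfolder PNG layout and an optional
# reader for IDX-format image/label files.

#' Write a dataset as class-named PNG subfolders
#'
#' Lays out `dir/<class>/<id>.png`, the on-disk format consumed by
#' [read_image_dir()] and the command-line interface.
#' @param ds an [image_dataset()] or [client_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_image_dir <- function(ds, dir) {
  for (cl in levels(ds$labels)) {
    dir.create(file.path(dir, cl), showWarnings = FALSE, recursive = TRUE)
  }
  n <- dataset_size(ds)
  for (i in seq_len(n)) {
    img <- ds$images[, , , i]
    if (length(dim(img)) == 3 && dim(img)[3] == 1) dim(img) <- dim(img)[1:2]
    png::writePNG(img, file.path(dir, as.character(ds$labels[i]),
                                 sprintf("%s.png", ds$ids[i])))
  }
  invisible(dir)
}

#' Read a class-subfolder image directory as a dataset
#'
#' Expects `dir/<class>/*.png` with all images of identical shape; grayscale
#' files become 1-channel images, RGB(A) files keep their first three
#' channels.
#' @param dir directory with one subfolder per class.
#' @export
read_image_dir <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stopf("no class subfolders under %s", dir)
  imgs <- list(); labs <- character(0); ids <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(dir, cl), pattern = "\\.png$",
                             full.names = TRUE))
    for (f in files) {
      x <- png::readPNG(f)
      if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
      if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
      imgs[[length(imgs) + 1]] <- x
      labs <- c(labs, cl)
      ids <- c(ids, sub("\\.png$", "", basename(f)))
    }
  }
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(x) identical(dim(x), d), logical(1)))) {
    stopf("images under %s have inconsistent shapes", dir)
  }
  arr <- array(unlist(imgs), c(d, length(imgs)))
  image_dataset(arr, factor(labs, levels = classes), ids = ids)
}

#' Read an IDX-format array file
#'
#' Minimal reader for the big-endian IDX format used by classic digit
#' datasets: unsigned-byte data with 1 (labels) or 3 (images) dimensions.
#' @param path IDX file path.
#' @return integer vector (1-D files) or `(H, W, 1, N)` array scaled to
#'   `[0, 1]` (3-D files).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0 || magic[3] != 8) {
    stopf("unsupported IDX file (expected unsigned-byte data)")
  }
  ndim <- magic[4]
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  data <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
  if (ndim == 1) return(as.integer(data))
  if (ndim != 3) stopf("unsupported IDX rank %d", ndim)
  # stored row-major as (n, rows, cols); convert to (H, W, 1, N) in [0, 1]
  arr <- aperm(array(data / 255, c(dims[3], dims[2], dims[1])), c(2, 1, 3))
  dim(arr) <- c(dims[2], dims[3], 1L, dims[1])
  arr
}

#' Load an IDX image/label pair as a dataset
#'
#' @param image_path,label_path IDX files with matching sample counts.
#' @export
load_idx_dataset <- function(image_path, label_path) {
  imgs <- read_idx(image_path)
  labs <- read_idx(label_path)
  if (dim(imgs)[4] != length(labs)) {
    stopf("image and label files disagree on the sample count")
  }
  image_dataset(imgs, factor(labs))
}
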