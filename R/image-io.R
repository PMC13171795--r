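# Thin adapters between in-memory gray-level matrices in [0, 1] and files on
# disk. Reading goes through EBImage (PNG/JPEG/TIFF, 8- or 16-bit); RGB
# inputs are converted to gray by the channel average. Writing uses png.

read_gray_image <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("reading images requires the EBImage package")
  }
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean) # luminance average
  img <- clip01(img)
  t(img) # EBImage stores (x, y); return a row-major-viewed (H, W) matrix
}

#' Read, regulate, and write back a grayscale image
#'
#' Convenience wrapper around [regulate_intensity()] for files on disk:
#' reads a PNG/JPEG image (8- or 16-bit; RGB converted to gray by the
#' channel average, everything normalized to \[0, 1\]), applies the
#' closed-loop intensity regulation, writes the adjusted image back as PNG
#' and the per-iteration trace as CSV (columns iteration, mean, error,
#' integral, signal).
#'
#' @param path input image path.
#' @param out_image,out_trace output paths (PNG and CSV); either may be
#'   `NULL` to skip writing.
#' @param gains a [pi_gains()].
#' @param tolerance early-stopping tolerance.
#' @return the [regulate_intensity()] result, invisibly.
#' @export
regulate_image_file <- function(path, out_image = NULL, out_trace = NULL,
                                gains = pi_gains(0.6, 0.05), tolerance = 1e-3) {
  img <- read_gray_image(path)
  res <- regulate_intensity(img, gains, tolerance)
  if (!is.null(out_image)) write_gray_png(res$image, out_image)
  if (!is.null(out_trace)) write.csv(res$trace, out_trace, row.names = FALSE)
  invisible(res)
}

#' Write a gray-level matrix as an 8-bit PNG
#' @param img numeric matrix in \[0, 1\].
#' @param path output path.
#' @export
write_gray_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG images requires the png package")
  }
  png::writePNG(clip01(img), path)
  invisible(path)
}

resize_gray <- function(img, size) {
  if (nrow(img) == size && ncol(img) == size) return(img)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("resizing requires the EBImage package")
  }
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(t(img)), w = size, h = size))
  clip01(t(out))
}

#' Write a labelled image set in folder-per-class PNG layout
#'
#' Produces `<root>/<split>/<class>/imgNNNN.png` plus a JSON-lines metadata
#' file per split — the same layout [load_image_folder()] reads back.
#'
#' @param ds a [labeled_image_set()].
#' @param root output root directory.
#' @param split split name used as the subdirectory (defaults to the set's
#'   role, or "data").
#' @return the split directory, invisibly.
#' @export
write_image_folder <- function(ds, root, split = NULL) {
  stopifnot(inherits(ds, "labeled_image_set"))
  split <- split %||% attr(ds, "role") %||% "data"
  classes <- c("benign", "malignant")
  for (cl in classes) {
    dir.create(file.path(root, split, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(ds$images)) {
    cl <- classes[ds$labels[i] + 1L]
    write_gray_png(ds$images[[i]],
                   file.path(root, split, cl, sprintf("img%04d.png", i)))
  }
  if (!is.null(ds$metadata)) {
    con <- file(file.path(root, split, "metadata.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(ds$metadata))) {
      writeLines(jsonlite::toJSON(as.list(ds$metadata[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(file.path(root, split))
}

#' Load a folder-per-class image directory
#'
#' Expects `<path>/<class>/*.png|jpg`; class folders are read in sorted
#' order (a folder named "benign" maps to label 0 and "malignant" to 1 when
#' present). Images are converted to gray, normalized to \[0, 1\], and
#' resized to `size`; files are read in sorted-name order so the result is
#' deterministic.
#'
#' @param path directory in folder-per-class layout.
#' @param size target square size in pixels.
#' @return a [labeled_image_set()].
#' @export
load_image_folder <- function(path, size = 64L) {
  if (!dir.exists(path)) stop(sprintf("directory '%s' does not exist", path))
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop(sprintf("no class folders found under '%s'", path))
  known <- c(benign = 0L, malignant = 1L)
  images <- list()
  labels <- integer(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl),
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) {
      stop(sprintf("class folder '%s' contains no readable images", file.path(path, cl)))
    }
    lab <- if (cl %in% names(known)) known[[cl]] else match(cl, classes) - 1L
    if (!lab %in% c(0L, 1L)) stop("binary classification expects two classes")
    for (f in files) {
      images[[length(images) + 1L]] <- resize_gray(read_gray_image(f), size)
      labels <- c(labels, lab)
    }
  }
  labeled_image_set(images, labels)
}
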