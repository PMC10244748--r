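#' Read grayscale digit images in IDX format
#'
#' Reads the standard big-endian IDX pair of files used by the
#' handwritten-digit benchmark (magic number 2051 for image files,
#' 2049 for label files).  Pixels are scaled from 0..255 to \[0, 1\]
#' and flattened row-major, so they can be clamped directly as input
#' rates.
#'
#' @param images_path Path to the IDX image file.
#' @param labels_path Path to the IDX label file.
#' @param n_max Optionally read only the first `n_max` images.
#' @param target_hi,target_lo One-hot target levels (defaults
#'   0.95 / 0.05).
#' @return List with `x` (n x (rows*cols) matrix in \[0,1\]), `labels`
#'   (integers 1..10 for digits 0..9), `digits` (the raw 0..9 labels),
#'   `targets` (n x 10 one-hot rate matrix).
#' @export
read_idx_images <- function(images_path, labels_path, n_max = Inf,
                            target_hi = 0.95, target_lo = 0.05) {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) {
    stop(sprintf("bad magic number %d in '%s' (expected 2051 for IDX images)",
                 magic, images_path), call. = FALSE)
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  nr <- readBin(con, "integer", 1, size = 4, endian = "big")
  nc <- readBin(con, "integer", 1, size = 4, endian = "big")
  n_read <- min(n, n_max)
  raw_px <- readBin(con, "integer", n_read * nr * nc, size = 1, signed = FALSE)
  if (length(raw_px) < n_read * nr * nc) {
    stop("truncated IDX image file: ", images_path, call. = FALSE)
  }
  x <- matrix(raw_px / 255, nrow = n_read, ncol = nr * nc, byrow = TRUE)

  con2 <- file(labels_path, "rb")
  on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (!identical(magic2, 2049L)) {
    stop(sprintf("bad magic number %d in '%s' (expected 2049 for IDX labels)",
                 magic2, labels_path), call. = FALSE)
  }
  n_lab <- readBin(con2, "integer", 1, size = 4, endian = "big")
  digits <- readBin(con2, "integer", min(n_lab, n_read), size = 1,
                    signed = FALSE)
  if (length(digits) < n_read) {
    stop("truncated IDX label file: ", labels_path, call. = FALSE)
  }
  labels <- digits + 1L
  targets <- matrix(target_lo, n_read, 10)
  targets[cbind(seq_len(n_read), labels)] <- target_hi
  list(x = x, labels = labels, digits = digits, targets = targets,
       image_dim = c(nr, nc))
}

#' Write images and labels in IDX format
#'
#' Companion writer for [read_idx_images()], used to build small
#' round-trip fixtures and to export subsets.
#'
#' @param pixels Integer matrix (n x rows*cols) with values 0..255.
#' @param digits Integer vector of class digits 0..9.
#' @param image_dim Image dimensions `c(rows, cols)`.
#' @param images_path,labels_path Output paths.
#' @export
write_idx_images <- function(pixels, digits, image_dim, images_path,
                             labels_path) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == prod(image_dim),
            all(pixels >= 0 & pixels <= 255),
            length(digits) == nrow(pixels))
  con <- file(images_path, "wb")
  writeBin(c(2051L, nrow(pixels), as.integer(image_dim)), con, size = 4,
           endian = "big")
  writeBin(as.integer(t(pixels)), con, size = 1)
  close(con)
  con <- file(labels_path, "wb")
  writeBin(c(2049L, length(digits)), con, size = 4, endian = "big")
  writeBin(as.integer(digits), con, size = 1)
  close(con)
  invisible(images_path)
}
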