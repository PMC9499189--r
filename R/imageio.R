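# Raster I/O and the pre-processing chain: resize, RGB -> grayscale,
# denoise, binarize. Images are numeric arrays with intensities in [0, 1]:
# grayscale images are H x W matrices, RGB images H x W x 3 arrays, both
# indexed (row, col) with the origin at the top-left. Files on disk are
# 8-bit PNG/JPEG/BMP.

#' Load a raster image as an RGB array
#'
#' Reads an 8-bit PNG, JPEG or BMP file and returns an `H x W x 3` numeric
#' array with intensities in `[0, 1]`. Grayscale files are promoted to
#' three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg` or `.bmp` file.
#' @return numeric array of dimension `H x W x 3`, values in `[0, 1]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' save_image(matrix(runif(64), 8, 8), f)
#' img <- load_image(f)
#' dim(img)
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stopf("`path` must be a single file path")
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    bmp = read_bmp(path),
    stopf("unsupported image format '.%s' (expected png, jpg or bmp)", ext))
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) == 3L && dim(px)[3] == 2L)  # gray + alpha
    px <- array(rep(px[, , 1L], 3L), dim = c(dim(px)[1:2], 3L))
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stopf("could not interpret %s as an RGB image", path)
  clip01(px)
}

#' Save a grayscale or RGB image to disk
#'
#' Writes an 8-bit PNG, JPEG or BMP depending on the file extension.
#' Values are clipped to `[0, 1]` before quantization.
#'
#' @param img numeric matrix (grayscale) or `H x W x 3` array (RGB).
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  if (!is.numeric(img)) stopf("`img` must be numeric")
  img <- clip01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(img, path, quality = 0.95),
    bmp = write_bmp(img, path),
    stopf("unsupported image format '.%s' (expected png, jpg or bmp)", ext))
  invisible(path)
}

# Minimal uncompressed BMP support (BITMAPINFOHEADER, 8-bit grayscale with
# palette or 24-bit BGR, no compression). BMP rows are stored bottom-up and
# padded to 4-byte boundaries.
read_bmp <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(magic), "BM")) stopf("%s is not a BMP file", path)
  readBin(con, "integer", 1L, 4L)            # file size
  readBin(con, "integer", 2L, 2L)            # reserved
  data_off <- readBin(con, "integer", 1L, 4L)
  hdr_size <- readBin(con, "integer", 1L, 4L)
  if (hdr_size < 40L) stopf("unsupported BMP header in %s", path)
  w <- readBin(con, "integer", 1L, 4L)
  h <- readBin(con, "integer", 1L, 4L)
  readBin(con, "integer", 1L, 2L)            # planes
  bpp <- readBin(con, "integer", 1L, 2L)
  compression <- readBin(con, "integer", 1L, 4L)
  if (compression != 0L) stopf("compressed BMP not supported: %s", path)
  if (!bpp %in% c(8L, 24L)) stopf("only 8- and 24-bit BMP supported (got %d)", bpp)
  seek(con, data_off)
  bytes_per_row <- ((bpp / 8) * w + 3) %/% 4 * 4
  raw_px <- readBin(con, "raw", bytes_per_row * abs(h))
  rows <- matrix(as.integer(raw_px), nrow = bytes_per_row)[, seq_len(abs(h)), drop = FALSE]
  flip <- h > 0
  h <- abs(h)
  if (bpp == 24L) {
    px <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {                        # BGR order on disk
      idx <- seq(from = 4L - ch, by = 3L, length.out = w)
      m <- t(rows[idx, , drop = FALSE])      # h x w
      px[, , ch] <- if (flip) m[h:1, , drop = FALSE] else m
    }
  } else {
    m <- t(rows[seq_len(w), , drop = FALSE])
    if (flip) m <- m[h:1, , drop = FALSE]
    px <- array(rep(m, 3L), dim = c(h, w, 3L))
  }
  px / 255
}

write_bmp <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  h <- dim(img)[1]; w <- dim(img)[2]
  q <- array(as.integer(round(img * 255)), dim = dim(img))
  bytes_per_row <- (3 * w + 3) %/% 4 * 4
  data_size <- bytes_per_row * h
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54L + data_size), con, 4L)
  writeBin(0L, con, 4L)
  writeBin(54L, con, 4L)
  writeBin(40L, con, 4L)
  writeBin(as.integer(w), con, 4L)
  writeBin(as.integer(h), con, 4L)           # positive: bottom-up
  writeBin(1L, con, 2L); writeBin(24L, con, 2L)
  writeBin(0L, con, 4L)                      # no compression
  writeBin(as.integer(data_size), con, 4L)
  writeBin(c(2835L, 2835L, 0L, 0L), con, 4L)
  buf <- raw(data_size)
  for (ch in 1:3) {
    idx_out <- outer(seq(from = 4L - ch, by = 3L, length.out = w),
                     (seq_len(h) - 1L) * bytes_per_row, "+")
    buf[idx_out] <- as.raw(t(q[h:1, , ch]))
  }
  writeBin(buf, con)
  invisible(path)
}

#' Convert an RGB image to grayscale luminance
#'
#' Removes hue and saturation, keeping luminance, using the ITU-R BT.601
#' weights `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img `H x W x 3` numeric array in `[0, 1]`.
#' @return numeric matrix in `[0, 1]`.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stopf("`img` must be an H x W x 3 array")
  img[, , 1] * 0.299 + img[, , 2] * 0.587 + img[, , 3] * 0.114
}

#' Binarize a grayscale image
#'
#' Assigns 1 to every pixel strictly brighter than the threshold and 0 to
#' the rest. `threshold = "otsu"` picks the threshold maximizing the
#' between-class variance of the 256-bin intensity histogram.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param threshold a number in `(0, 1)` or `"otsu"` (default).
#' @return 0/1 integer-valued matrix of the same shape.
#' @export
binarize <- function(img, threshold = "otsu") {
  check_gray(img)
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(img)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stopf("`threshold` must be in (0, 1) or \"otsu\"")
  (img > threshold) * 1
}

# Otsu threshold of the 256-bin intensity histogram on the [0, 1] scale.
otsu_threshold <- function(img) {
  EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
}

#' Median-filter denoising
#'
#' Applies a square median filter of the given odd window size;
#' `window = 1` is the identity. Borders use the nearest-pixel (replicate)
#' extension.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param window odd integer window side length (default 3).
#' @return denoised matrix, same shape.
#' @export
denoise <- function(img, window = 3L) {
  check_gray(img)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L)
    stopf("`window` must be an odd integer >= 1")
  if (window == 1L) return(img)
  r <- (window - 1L) %/% 2L
  out <- EBImage::medianFilter(EBImage::Image(clip01(img)), size = r)
  matrix(as.numeric(EBImage::imageData(out)), nrow(img), ncol(img))
}

#' Resize an image by bilinear resampling
#'
#' Resamples to exactly `out_h x out_w` using bilinear interpolation with
#' corner-aligned sample positions, so resizing to an image's own shape is
#' the identity. Works on grayscale matrices and RGB arrays alike.
#'
#' @param img numeric matrix or `H x W x 3` array in `[0, 1]`.
#' @param out_h,out_w positive integer output dimensions.
#' @return resized image of the same kind as the input, values in `[0, 1]`.
#' @export
resize_image <- function(img, out_h, out_w) {
  out_h <- as.integer(out_h); out_w <- as.integer(out_w)
  if (is.na(out_h) || is.na(out_w) || out_h < 1L || out_w < 1L)
    stopf("output dimensions must be positive integers")
  if (!is.matrix(img)) {
    if (length(dim(img)) != 3L) stopf("`img` must be a matrix or 3-D array")
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- resize_image(img[, , ch], out_h, out_w)
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  ys <- if (out_h == 1L) (h - 1) / 2 else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1)
  xs <- if (out_w == 1L) (w - 1) / 2 else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1)
  grid_x <- rep(xs, each = out_h)
  grid_y <- rep(ys, times = out_w)
  clip01(matrix(bilinear_sample(img, grid_x, grid_y, fill = "nearest"),
                out_h, out_w))
}
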