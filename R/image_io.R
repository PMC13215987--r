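#' Read a grayscale image
#'
#' Reads a TIFF or PNG raster into a plain numeric matrix indexed
#' `[row, col]` (row 1 = top of the image) with intensities on the
#' normalized `[0, 1]` scale. 16-bit input is rescaled to `[0, 1]`;
#' multi-channel (RGB) input is collapsed to luminance with the fixed
#' weights 0.299 R + 0.587 G + 0.114 B and a warning.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix of intensities in `[0, 1]`.
#' @seealso [write_image()], [read_mask()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  arr <- tryCatch(read_raster(path),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      warning("multi-channel image '", path,
              "' collapsed to luminance (0.299R + 0.587G + 0.114B)")
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (!is.matrix(arr) || any(dim(arr) == 0L)) {
    stop("zero-sized or non-2D image: ", path, call. = FALSE)
  }
  if (anyNA(arr) || any(!is.finite(arr))) {
    stop("image contains non-finite values: ", path, call. = FALSE)
  }
  arr
}

# Dispatch on extension; both readers return data in [0,1].
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format '", ext, "' (expected tif/tiff/png)")
  }
}

#' Write a grayscale image
#'
#' Writes a numeric matrix with values in `[0, 1]` as a single-channel
#' TIFF or PNG. 8-bit output is lossless for data quantized to 256 levels.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param bits Bit depth, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  stopifnot(is.matrix(img), bits %in% c(8L, 16L))
  if (min(img) < 0 || max(img) > 1) stop("image values must lie in [0, 1]", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported image format '", ext, "'")
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a two-level raster (TIFF or PNG) and maps the positive level to 1
#' and zero to 0. Rasters with more than two distinct levels are rejected.
#'
#' @param path Path to the mask file.
#' @return An integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  arr <- read_image(path)
  lv <- sort(unique(as.vector(arr)))
  if (length(lv) > 2L) {
    stop("mask '", path, "' has more than two levels: ",
         paste(signif(lv, 4), collapse = ", "), call. = FALSE)
  }
  if (length(lv) == 2L && lv[1] != 0) {
    stop("mask '", path, "' lacks a zero level: ",
         paste(signif(lv, 4), collapse = ", "), call. = FALSE)
  }
  out <- matrix(0L, nrow(arr), ncol(arr))
  out[arr > 0] <- 1L
  out
}

#' Write a binary mask
#'
#' Writes a 0/1 mask as an 8-bit raster with levels 0 and 255, the
#' conventional on-disk encoding. Round-trips through [read_mask()] exactly.
#'
#' @param mask Integer 0/1 matrix.
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  # 0/1 in [0,1] scale encodes as 0/255 in the 8-bit file
  write_image(mask + 0, path)
}
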