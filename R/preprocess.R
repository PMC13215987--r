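#' Preprocessing configuration
#'
#' Parameters for the denoise + contrast-enhancement stage applied before
#' segmentation.
#'
#' @param wiener_window Length-2 `(rows, cols)` local window of the
#'   adaptive Wiener filter; default `c(6, 6)`.
#' @param selem_shape Structuring element shape, `"disc"` or `"square"`.
#' @param selem_radius Structuring element radius in pixels (default 5,
#'   on the order of the SAT-ring thickness at typical export resolution).
#' @param clip_range Output intensity bounds after enhancement.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(wiener_window = c(6L, 6L),
                              selem_shape = c("disc", "square"),
                              selem_radius = 5L,
                              clip_range = c(0, 1)) {
  selem_shape <- match.arg(selem_shape)
  stopifnot(length(wiener_window) == 2, all(wiener_window >= 1),
            selem_radius >= 1, length(clip_range) == 2,
            clip_range[2] > clip_range[1])
  structure(list(wiener_window = as.integer(wiener_window),
                 selem_shape = selem_shape,
                 selem_radius = as.integer(selem_radius),
                 clip_range = as.numeric(clip_range)),
            class = "preprocess_config")
}

make_selem <- function(cfg) {
  EBImage::makeBrush(2L * cfg$selem_radius + 1L,
                     shape = if (cfg$selem_shape == "disc") "disc" else "box")
}

# Local box sums with reflect padding via an integral image. The window of
# size w around pixel i spans offsets -floor((w-1)/2) .. +ceiling((w-1)/2)
# (so an even window extends one pixel further towards larger indices).
local_box_mean <- function(img, window) {
  wr <- window[1]; wc <- window[2]
  br <- floor((wr - 1) / 2); ar <- wr - 1L - br
  bc <- floor((wc - 1) / 2); ac <- wc - 1L - bc
  nr <- nrow(img); nc <- ncol(img)
  if (wr > nr || wc > nc) stop("window larger than image", call. = FALSE)
  ridx <- c(rev(seq_len(br)), seq_len(nr), nr + 1 - seq_len(ar))   # reflect
  cidx <- c(rev(seq_len(bc)), seq_len(nc), nc + 1 - seq_len(ac))
  pad <- img[ridx, cidx, drop = FALSE]
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)   # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  sums <- ii[r1 + wr, c1 + wc, drop = FALSE] - ii[r1, c1 + wc, drop = FALSE] -
    ii[r1 + wr, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  sums / (wr * wc)
}

#' Adaptive Wiener denoising
#'
#' Local adaptive (Lee/Wiener) filter: each output pixel is
#' `m + max(v - nv, 0) / max(v, nv) * (x - m)` where `m` and `v` are the
#' local window mean and variance and `nv` is the noise variance,
#' estimated as the mean of all local variances when not supplied. Flat
#' regions collapse to their local mean; high-variance structure is
#' preserved. Borders are handled by reflect padding.
#'
#' @param img Numeric image matrix.
#' @param window Length-2 `(rows, cols)` local window; default `c(6, 6)`.
#' @param noise_var Optional known noise variance.
#' @return Denoised image matrix of the same shape.
#' @export
wiener_denoise <- function(img, window = c(6L, 6L), noise_var = NULL) {
  stopifnot(is.matrix(img), length(window) == 2, all(window >= 1))
  m <- local_box_mean(img, window)
  v <- pmax(local_box_mean(img * img, window) - m * m, 0)
  nv <- if (is.null(noise_var)) mean(v) else noise_var
  denom <- pmax(v, nv)
  gain <- ifelse(denom > 0, pmax(v - nv, 0) / denom, 0)
  m + gain * (img - m)
}

#' Top-hat and bottom-hat transforms
#'
#' `tophat` is the image minus its grayscale morphological opening
#' (bright detail smaller than the structuring element); `bottomhat` is
#' the closing minus the image (dark detail). Both are non-negative.
#'
#' @param img Numeric image matrix.
#' @param selem Structuring element (binary matrix, e.g.
#'   `EBImage::makeBrush()`); defaults to a disc of radius 5.
#' @return Image matrix of the same shape.
#' @export
tophat <- function(img, selem = EBImage::makeBrush(11L, "disc")) {
  check_selem(img, selem)
  opened <- as_plain_matrix(EBImage::opening(img, selem))
  pmax(img - opened, 0)
}

#' @rdname tophat
#' @export
bottomhat <- function(img, selem = EBImage::makeBrush(11L, "disc")) {
  check_selem(img, selem)
  closed <- as_plain_matrix(EBImage::closing(img, selem))
  pmax(closed - img, 0)
}

check_selem <- function(img, selem) {
  if (nrow(selem) >= nrow(img) || ncol(selem) >= ncol(img)) {
    stop("structuring element must be smaller than the image", call. = FALSE)
  }
  invisible(TRUE)
}

#' Denoise and contrast-enhance a slice
#'
#' The full preprocessing stage: adaptive Wiener denoising followed by
#' combination of the top-hat and bottom-hat responses with the image,
#' `clip(img + tophat - bottomhat, clip_range)`. Adding the top-hat
#' brightens small hyperintense (fat) structure while subtracting the
#' bottom-hat darkens lean/background detail, widening the adipose-lean
#' intensity separation the segmentation backends rely on.
#'
#' @param img Numeric image matrix.
#' @param cfg A [preprocess_config()].
#' @return Preprocessed image matrix within `clip_range`.
#' @export
enhance <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  den <- wiener_denoise(img, cfg$wiener_window)
  selem <- make_selem(cfg)
  out <- den + tophat(den, selem) - bottomhat(den, selem)
  pmin(pmax(out, cfg$clip_range[1]), cfg$clip_range[2])
}
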