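# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a binary mask: integer-valued matrix over {0, 1}.
assert_mask <- function(mask, name = deparse(substitute(mask))) {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0/1 values; found: %s",
                 name, paste(sort(vals[!vals %in% c(0, 1)]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(mask)
}

assert_same_shape <- function(a, b, name_a = "first", name_b = "second") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %s is %s, %s is %s",
                 name_a, paste(dim(a), collapse = "x"),
                 name_b, paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Image center in 1-based (row, col) pixel coordinates.
image_center <- function(img) {
  c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
}

# Coerce an EBImage Image back to a plain matrix.
as_plain_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Pixel coordinate grids (row index and col index matrices).
coord_grids <- function(nr, nc) {
  list(row = matrix(seq_len(nr), nr, nc),
       col = matrix(seq_len(nc), nr, nc, byrow = TRUE))
}
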