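#' Label 8-connected components
#'
#' Labels the foreground of a binary mask into connected components under
#' 8-connectivity (N, S, E, W and the four diagonals). Labels are
#' contiguous integers `1..R` assigned in column-major scan order of each
#' component's first pixel, so labeling is deterministic.
#'
#' @param mask Integer 0/1 matrix.
#' @return An integer matrix of the same shape; 0 = background.
#' @export
label_regions <- function(mask) {
  assert_mask(mask)
  idx <- which(mask == 1)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(out)
  nr <- nrow(mask); nc <- ncol(mask)
  rank <- integer(nr * nc)
  rank[idx] <- seq_along(idx)
  rw <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  # forward offsets: S, E, SE, NE cover all 8-neighbor pairs once
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (i in seq_along(offs)) {
    o <- offs[[i]]
    r2 <- rw + o[1]; c2 <- cl + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    fg <- rank[nb] > 0L
    edges[[i]] <- cbind(rank[idx[ok]][fg], rank[nb][fg])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  # relabel so that component labels follow the scan order of first pixels
  first_seen <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first_seen]] <- seq_len(sum(first_seen))
  out[idx] <- relab[comp]
  out
}

#' Region properties
#'
#' Computes, for each labeled region, the pixel area, the centroid (mean
#' of member pixel `(row, col)` coordinates) and the Euclidean distance
#' from the centroid to the image center. Rows are sorted by area,
#' descending (ties by label).
#'
#' @param labeled Integer label matrix from [label_regions()].
#' @param center Image center `(row, col)`; defaults to
#'   `((rows + 1) / 2, (cols + 1) / 2)`.
#' @return A data.frame with columns `label`, `area_px`, `centroid_row`,
#'   `centroid_col`, `dist_center_px`.
#' @export
region_props <- function(labeled, center = NULL) {
  stopifnot(is.matrix(labeled))
  if (is.null(center)) center <- image_center(labeled)
  idx <- which(labeled > 0)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      dist_center_px = numeric()))
  }
  nr <- nrow(labeled)
  lab <- labeled[idx]
  rw <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  area <- as.vector(rowsum(rep(1L, length(lab)), lab))
  labs <- sort(unique(lab))
  cr <- as.vector(rowsum(as.numeric(rw), lab)) / area
  cc <- as.vector(rowsum(as.numeric(cl), lab)) / area
  d <- sqrt((cr - center[1])^2 + (cc - center[2])^2)
  df <- data.frame(label = labs, area_px = as.integer(area),
                   centroid_row = cr, centroid_col = cc, dist_center_px = d)
  df[order(-df$area_px, df$label), , drop = FALSE]
}

#' Compartment masks (SAT / VAT / TAT)
#'
#' Container for the two adipose compartments; validates that SAT and VAT
#' are disjoint and stores their union as TAT (total adipose tissue).
#'
#' @param sat,vat Integer 0/1 matrices of identical shape.
#' @return An object of class `compartment_masks` with elements `sat`,
#'   `vat`, `tat`.
#' @export
compartment_masks <- function(sat, vat) {
  assert_mask(sat); assert_mask(vat)
  assert_same_shape(sat, vat, "sat", "vat")
  if (any(sat == 1L & vat == 1L)) stop("SAT and VAT masks overlap", call. = FALSE)
  structure(list(sat = sat, vat = vat,
                 tat = mask_int(sat == 1L | vat == 1L)),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat("<compartment_masks>", nrow(x$sat), "x", ncol(x$sat), "px\n")
  cat(sprintf("  SAT %d px, VAT %d px, TAT %d px\n",
              sum(x$sat), sum(x$vat), sum(x$tat)))
  invisible(x)
}

#' Restrict a mask to the abdominal region
#'
#' Pointwise logical AND with the abdominal mask; pixels outside the
#' abdomen (the arms) are forced to 0.
#'
#' @param mask,abdominal Integer 0/1 matrices of identical shape.
#' @return The masked 0/1 matrix.
#' @export
apply_abdominal_mask <- function(mask, abdominal) {
  assert_mask(mask); assert_mask(abdominal)
  assert_same_shape(mask, abdominal, "mask", "abdominal")
  mask_int(mask == 1L & abdominal == 1L)
}

#' Construct an abdominal mask automatically
#'
#' Builds a mask of the abdominal cross-section so that upper-extremity
#' (arm) fat can be excluded before VAT/SAT delineation: threshold the
#' body foreground with Otsu on the raw image, morphologically close with
#' a disc, keep the 8-connected component containing (or nearest to) the
#' image center, and fill interior holes. Supply a manually drawn mask to
#' [apply_abdominal_mask()] instead when the automatic construction fails.
#'
#' @param body_image Numeric raw image matrix.
#' @param closing_radius Disc radius (px) of the morphological closing.
#' @return An integer 0/1 abdominal mask.
#' @export
build_abdominal_mask <- function(body_image, closing_radius = 10L) {
  stopifnot(is.matrix(body_image))
  thr <- otsu_threshold(as.vector(body_image))
  fg <- mask_int(body_image > thr)
  if (sum(fg) == 0) {
    stop("no foreground found; supply a manual abdominal mask", call. = FALSE)
  }
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
  closed <- mask_int(as_plain_matrix(EBImage::closing(fg + 0, brush)) > 0.5)
  # fill holes first: the bright SAT ring encloses the (darker) abdominal
  # interior, so the filled ring component is the body cross-section
  closed <- mask_int(as_plain_matrix(EBImage::fillHull(closed + 0)) > 0.5)
  lab <- label_regions(closed)
  if (max(lab) == 0L) {
    stop("no foreground component survives closing; supply a manual abdominal mask",
         call. = FALSE)
  }
  ctr <- image_center(body_image)
  ctr_px <- c(round(ctr[1]), round(ctr[2]))
  target <- lab[ctr_px[1], ctr_px[2]]
  if (target == 0L) {
    # nearest foreground pixel to the center
    idx <- which(lab > 0)
    nr <- nrow(lab)
    rw <- ((idx - 1L) %% nr) + 1L
    cl <- ((idx - 1L) %/% nr) + 1L
    target <- lab[idx[which.min((rw - ctr[1])^2 + (cl - ctr[2])^2)]]
  }
  mask_int(lab == target)
}

#' Delineate VAT from SAT by centroid-center distance
#'
#' Separates the adipose mask into subcutaneous (SAT) and visceral (VAT)
#' compartments: among the two largest 8-connected adipose regions, the
#' one whose centroid lies farther from the image center becomes SAT (the
#' peripheral ring) and the nearer one VAT (central); every remaining
#' smaller region is assigned to VAT, the fragmented compartment.
#'
#' A single-region mask yields SAT only (with a warning: the usual cause
#' is SAT-VAT bridging). A centroid-distance tie within `1e-9` px is
#' resolved by area (larger region becomes SAT), also with a warning.
#'
#' @param adipose_mask Integer 0/1 adipose mask, arms already removed.
#' @param center Image center `(row, col)`; defaults to
#'   `((rows + 1) / 2, (cols + 1) / 2)`.
#' @return A [compartment_masks()].
#' @export
delineate_vat_sat <- function(adipose_mask, center = NULL) {
  assert_mask(adipose_mask)
  if (is.null(center)) center <- image_center(adipose_mask)
  lab <- label_regions(adipose_mask)
  props <- region_props(lab, center)
  if (nrow(props) == 0L) {
    stop("adipose mask is empty; nothing to delineate", call. = FALSE)
  }
  if (nrow(props) == 1L) {
    warning("only one adipose region found; labeling it SAT with empty VAT ",
            "(possible SAT-VAT bridging)")
    return(compartment_masks(sat = mask_int(lab == props$label[1]),
                             vat = matrix(0L, nrow(lab), ncol(lab))))
  }
  top2 <- props[1:2, ]
  dd <- top2$dist_center_px
  if (abs(dd[1] - dd[2]) < 1e-9) {
    warning("centroid-center distances of the two largest regions tie; ",
            "assigning the larger region to SAT")
    sat_label <- top2$label[1]
  } else {
    sat_label <- top2$label[which.max(dd)]
  }
  compartment_masks(sat = mask_int(lab == sat_label),
                    vat = mask_int(lab > 0L & lab != sat_label))
}
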