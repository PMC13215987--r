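#' Pixel geometry
#'
#' Derives the physical pixel area from the field of view and the pixel
#' grid the masks live on: `pixel_area_cm2 =
#' (fov_row_mm / n_rows) * (fov_col_mm / n_cols) / 100`. Supply the grid
#' of the exported images (the grid the masks are defined on), which may
#' differ from the acquisition matrix when images were interpolated on
#' export; total area is conserved only if the FOV is divided by the grid
#' the pixels are counted on.
#'
#' @param fov_row_mm,fov_col_mm Field of view along image rows/cols, mm.
#' @param n_rows,n_cols Pixel grid dimensions.
#' @return An object of class `pixel_geometry` with `pixel_area_cm2`.
#' @export
pixel_geometry <- function(fov_row_mm, fov_col_mm, n_rows, n_cols) {
  stopifnot(fov_row_mm > 0, fov_col_mm > 0, n_rows >= 1, n_cols >= 1)
  structure(list(fov_row_mm = fov_row_mm, fov_col_mm = fov_col_mm,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_area_cm2 = (fov_row_mm / n_rows) * (fov_col_mm / n_cols) / 100),
            class = "pixel_geometry")
}

#' Surface area of a mask
#'
#' Number of foreground pixels multiplied by the physical pixel area.
#'
#' @param mask Integer 0/1 matrix.
#' @param geom A [pixel_geometry()] whose grid matches the mask.
#' @return Area in cm².
#' @export
surface <- function(mask, geom) {
  assert_mask(mask)
  stopifnot(inherits(geom, "pixel_geometry"))
  if (nrow(mask) != geom$n_rows || ncol(mask) != geom$n_cols) {
    stop(sprintf("mask grid %dx%d does not match geometry grid %dx%d",
                 nrow(mask), ncol(mask), geom$n_rows, geom$n_cols), call. = FALSE)
  }
  sum(mask) * geom$pixel_area_cm2
}

#' Adipose distribution indices
#'
#' Summarizes the compartment areas as total adipose tissue (TAT),
#' the visceral fraction VAT/TAT (%) and the VAT/SAT ratio. Ratios with a
#' zero denominator are carried as `NA`, never as infinity.
#'
#' @param sat_cm2,vat_cm2 Compartment areas in cm², >= 0.
#' @return A list of class `surface_report` with `sat_cm2`, `vat_cm2`,
#'   `tat_cm2`, `vat_tat_pct`, `vat_sat_ratio`.
#' @export
distribution_indices <- function(sat_cm2, vat_cm2) {
  stopifnot(sat_cm2 >= 0, vat_cm2 >= 0)
  tat <- sat_cm2 + vat_cm2
  structure(list(sat_cm2 = sat_cm2, vat_cm2 = vat_cm2, tat_cm2 = tat,
                 vat_tat_pct = if (tat > 0) 100 * vat_cm2 / tat else NA_real_,
                 vat_sat_ratio = if (sat_cm2 > 0) vat_cm2 / sat_cm2 else NA_real_),
            class = "surface_report")
}

#' Multi-slice volume aggregation
#'
#' Aggregates per-slice areas into a volume, `V = (t + h) * sum(A_i)`,
#' where `t` is the slice thickness and `h` the between-slice gap (both
#' cm): each slice's area is extruded over the thickness plus its share
#' of the gap. With `h = 0` this is the contiguous-slab estimate
#' `t * sum(A_i)`.
#'
#' @param areas_cm2 Ordered per-slice areas, cm².
#' @param slice_thickness_cm Slice thickness `t`, > 0.
#' @param gap_cm Between-slice gap `h`, >= 0.
#' @return Volume in cm³.
#' @export
fat_volume <- function(areas_cm2, slice_thickness_cm, gap_cm = 0) {
  if (length(areas_cm2) == 0) stop("at least one slice area is required", call. = FALSE)
  stopifnot(slice_thickness_cm > 0, gap_cm >= 0, all(areas_cm2 >= 0))
  (slice_thickness_cm + gap_cm) * sum(areas_cm2)
}
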