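#' Physical coordinates of pixel centers
#'
#' Returns the in-plane coordinates (mm) of every pixel center of a square
#' image grid, with the origin at the image center.  The same convention is
#' used by the phantom generators, the ROI tools and the strain pipeline, so
#' coordinates are interchangeable across stages.
#'
#' @param grid_size image dimension in pixels (square grid).
#' @param pixel_spacing pixel size, mm.
#' @return list with matrices \code{x} and \code{y} (mm) of dimension
#'   \code{grid_size x grid_size}.
#' @export
pixel_grid <- function(grid_size, pixel_spacing) {
  stopifnot(grid_size >= 2, pixel_spacing > 0)
  coords <- (seq_len(grid_size) - (grid_size + 1) / 2) * pixel_spacing
  list(x = matrix(coords, grid_size, grid_size),
       y = matrix(coords, grid_size, grid_size, byrow = TRUE))
}

# radius of a star-shaped polygon at query angles, by periodic linear
# interpolation of the vertex (angle, radius) profile about `center`
.polygon_radius_at <- function(poly, center, theta_query) {
  ang <- atan2(poly[, 2] - center[2], poly[, 1] - center[1])
  rad <- sqrt((poly[, 1] - center[1])^2 + (poly[, 2] - center[2])^2)
  ord <- order(ang)
  ang <- ang[ord]
  rad <- rad[ord]
  # periodic extension for wrap-around interpolation
  a <- c(ang[length(ang)] - 2 * pi, ang, ang[1] + 2 * pi)
  r <- c(rad[length(rad)], rad, rad[1])
  stats::approx(a, r, xout = theta_query, rule = 2)$y
}

#' Mid-myocardial ROI between eroded endo- and epicardial contours
#'
#' Restricts the myocardial ROI to the mid-wall layer by excluding a
#' wall-thickness fraction at both the endocardial and epicardial borders
#' (to limit partial-volume contamination of T1 from blood and lung).
#' Contours are treated as star-shaped about the endocardial centroid, the
#' usual situation for LV short-axis slices; a pixel belongs to the ROI if
#' its center lies inside the eroded annulus.
#'
#' @param endo,epi polygons (two-column matrices, mm, package grid
#'   coordinates); endo must lie strictly inside epi.
#' @param grid_size,pixel_spacing grid geometry (see
#'   \code{\link{pixel_grid}}).
#' @param erosion_fraction wall-thickness fraction removed at each border,
#'   in \[0, 0.5); default 0.25.
#' @param slice_id identifier used in error messages.
#' @return logical matrix mask.
#' @export
extract_midwall_roi <- function(endo, epi, grid_size, pixel_spacing,
                                erosion_fraction = 0.25, slice_id = "slice") {
  stopifnot(is.matrix(endo), is.matrix(epi), ncol(endo) == 2, ncol(epi) == 2,
            nrow(endo) >= 3, nrow(epi) >= 3,
            erosion_fraction >= 0, erosion_fraction < 0.5)
  center <- colMeans(endo)
  g <- pixel_grid(grid_size, pixel_spacing)
  theta <- atan2(g$y - center[2], g$x - center[1])
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  r_endo <- .polygon_radius_at(endo, center, theta)
  r_epi <- .polygon_radius_at(epi, center, theta)
  if (any(r_endo >= r_epi))
    stop(sprintf("endo contour not strictly inside epi contour (%s)", slice_id))
  w <- r_epi - r_endo
  mask <- r >= r_endo + erosion_fraction * w & r <= r_epi - erosion_fraction * w
  dim(mask) <- dim(r)
  if (!any(mask))
    stop(sprintf("empty mid-wall mask after erosion (%s, fraction %.2f)",
                 slice_id, erosion_fraction))
  mask
}

#' Partition a myocardial mask into standard LV segments
#'
#' Divides the masked myocardium into equal angular sectors anchored at the
#' anterior RV insertion point: 6 sectors of 60 degrees on basal and
#' mid-ventricular slices, 4 sectors of 90 degrees on apical slices,
#' proceeding counterclockwise as viewed from the apex.  Segment numbers
#' follow the standard 16-segment convention: 1-6 basal, 7-12 mid, 13-16
#' apical, with the first segment of each slice starting at the insertion
#' angle (anterior).
#'
#' @param mask logical myocardial mask (non-empty).
#' @param lv_centroid LV center, mm in package grid coordinates (length 2).
#' @param rv_insertion_angle angle of the anterior RV insertion point,
#'   degrees, measured counterclockwise from the +x axis.
#' @param slice_level "basal", "mid" or "apical".
#' @param pixel_spacing pixel size, mm.
#' @return object of class \code{segment_model}: list with \code{labels}
#'   (integer matrix, 0 outside the mask), \code{segment_ids},
#'   \code{slice_level}, \code{rv_insertion_angle}, \code{lv_centroid}.
#' @export
partition_segments <- function(mask, lv_centroid, rv_insertion_angle,
                               slice_level = c("basal", "mid", "apical"),
                               pixel_spacing = 1) {
  slice_level <- match.arg(slice_level)
  stopifnot(is.logical(mask), any(mask), length(lv_centroid) == 2,
            is.finite(rv_insertion_angle))
  n_seg <- if (slice_level == "apical") 4L else 6L
  offset <- switch(slice_level, basal = 0L, mid = 6L, apical = 12L)
  g <- pixel_grid(nrow(mask), pixel_spacing)
  theta <- atan2(g$y - lv_centroid[2], g$x - lv_centroid[1]) * 180 / pi
  rel <- (theta - rv_insertion_angle) %% 360
  sector <- pmin(floor(rel / (360 / n_seg)) + 1L, n_seg)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[mask] <- sector[mask] + offset
  structure(list(labels = labels,
                 segment_ids = offset + seq_len(n_seg),
                 slice_level = slice_level,
                 rv_insertion_angle = rv_insertion_angle,
                 lv_centroid = lv_centroid,
                 pixel_spacing = pixel_spacing),
            class = "segment_model")
}
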