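#' Write an image series as a NIfTI volume with a JSON sidecar
#'
#' Stores a (x, y, frame) array as NIfTI and the acquisition metadata that
#' does not fit the NIfTI header (inversion times, frame interval, encoding
#' frequency, pixel spacing, ...) as a JSON sidecar next to it.
#'
#' @param arr numeric array (x, y, frame).
#' @param prefix file path without extension; writes \code{<prefix>.nii.gz}
#'   and \code{<prefix>.json}.
#' @param sidecar named list of metadata.
#' @return invisibly, the two file paths.
#' @export
write_image_series <- function(arr, prefix, sidecar = list()) {
  stopifnot(is.array(arr), is.list(sidecar))
  nii <- paste0(prefix, ".nii.gz")
  js <- paste0(prefix, ".json")
  RNifti::writeNifti(RNifti::asNifti(arr), nii)
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(nii, js))
}

#' Read an image series written by \code{\link{write_image_series}}
#'
#' @param prefix file path without extension.
#' @return list with \code{data} (array) and \code{sidecar} (list).
#' @export
read_image_series <- function(prefix) {
  nii <- paste0(prefix, ".nii.gz")
  js <- paste0(prefix, ".json")
  stopifnot(file.exists(nii), file.exists(js))
  list(data = as.array(RNifti::readNifti(nii)),
       sidecar = jsonlite::read_json(js, simplifyVector = TRUE))
}

#' Write contours and landmarks as JSON
#'
#' Stores myocardial contours (polygon vertex lists, mm, package grid
#' coordinates) plus the anterior RV insertion landmark.
#'
#' @param contours named list; polygon entries are two-column matrices,
#'   scalars (e.g. \code{rv_insertion_angle}) pass through.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
write_contours_json <- function(contours, path) {
  ser <- lapply(contours, function(x) {
    if (is.matrix(x)) list(x = x[, 1], y = x[, 2]) else x
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read contours written by \code{\link{write_contours_json}}
#' @param path JSON path.
#' @return named list; polygon entries restored as two-column matrices.
#' @export
read_contours_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) {
    if (is.list(x) && all(c("x", "y") %in% names(x))) cbind(x = x$x, y = x$y)
    else x
  })
}

#' Circular contour polygon
#'
#' Vertex matrix of a circle in package grid coordinates (mm), useful as a
#' synthetic endo-/epicardial contour.
#'
#' @param radius circle radius, mm.
#' @param center circle center, mm.
#' @param n number of vertices.
#' @return two-column matrix of vertices.
#' @export
circle_polygon <- function(radius, center = c(0, 0), n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
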