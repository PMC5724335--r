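#' Displacement fields from displacement-encoded phase series
#'
#' Converts wrapped phase images (one series per in-plane encoding axis) into
#' displacement fields.  Each frame is spatially unwrapped with a
#' quality-guided region-growing algorithm (quality = magnitude weighted by
#' local wrapped-phase-gradient coherence), which determines the solution up
#' to one 2-pi multiple per connected component; that multiple is fixed by
#' temporal seeding from the previous frame's solution (the first frame is
#' referenced to zero).  Displacement is then
#' \eqn{u = \phi_{unwrapped} / (2\pi k_e)} per axis.
#'
#' Disconnected mask components are unwrapped independently (with a warning):
#' each component's temporal seeding is resolved separately.
#'
#' @param phase_x,phase_y wrapped phase arrays (x, y, frame), radians.
#' @param magnitude magnitude array, same dimension.
#' @param mask logical matrix (applied to all frames) or logical array
#'   (x, y, frame) of pixels to unwrap; \code{NULL} derives a per-frame mask
#'   by magnitude thresholding at half the frame maximum.
#' @param encoding_frequency cycles/mm, > 0.
#' @param frame_times frame times, ms (strictly increasing); defaults to
#'   frame index.
#' @param pixel_spacing pixel size, mm.
#' @return object of class \code{displacement_field}: list with \code{ux},
#'   \code{uy} (mm, NA outside the mask), \code{valid} (logical array),
#'   \code{frame_times}, \code{encoding_frequency}, \code{pixel_spacing}.
#' @export
phase_to_displacement <- function(phase_x, phase_y, magnitude, mask = NULL,
                                  encoding_frequency, frame_times = NULL,
                                  pixel_spacing = 1) {
  stopifnot(length(dim(phase_x)) == 3L,
            all(dim(phase_x) == dim(phase_y)),
            all(dim(phase_x) == dim(magnitude)),
            encoding_frequency > 0, pixel_spacing > 0)
  nf <- dim(phase_x)[3]
  if (is.null(frame_times)) frame_times <- seq_len(nf) - 1
  stopifnot(length(frame_times) == nf, all(diff(frame_times) > 0))
  dims <- dim(phase_x)[1:2]
  mask_f <- function(f) {
    if (is.null(mask)) magnitude[, , f] > 0.5 * max(magnitude[, , f])
    else if (length(dim(mask)) == 3L) mask[, , f]
    else mask
  }
  m1 <- mask_f(1)
  if (!all(dim(m1) == dims)) stop("mask dimensions do not match the images")

  ux <- uy <- array(NA_real_, dim(phase_x))
  valid <- array(FALSE, dim(phase_x))
  warned_components <- FALSE
  prev <- list(x = NULL, y = NULL)

  for (f in seq_len(nf)) {
    m <- mask_f(f)
    mag <- magnitude[, , f]
    for (axis in c("x", "y")) {
      ph <- if (axis == "x") phase_x[, , f] else phase_y[, , f]
      q <- .phase_quality(ph, mag, m)
      res <- .unwrap2d_cpp(ph, q, m)
      if (res$n_components > 1 && !warned_components) {
        warning(sprintf(
          "mask splits into %d disconnected components; unwrapped independently",
          res$n_components))
        warned_components <- TRUE
      }
      u <- .seed_temporal(res$unwrapped, res$components, prev[[axis]])
      prev[[axis]] <- u
      if (axis == "x") ux[, , f] <- u / (2 * pi * encoding_frequency)
      else uy[, , f] <- u / (2 * pi * encoding_frequency)
    }
    valid[, , f] <- m & is.finite(ux[, , f]) & is.finite(uy[, , f])
  }
  structure(list(ux = ux, uy = uy, valid = valid,
                 frame_times = as.numeric(frame_times),
                 encoding_frequency = encoding_frequency,
                 pixel_spacing = pixel_spacing),
            class = "displacement_field")
}

# quality map: magnitude weighted by coherence of the wrapped phase gradient
.phase_quality <- function(ph, mag, mask) {
  nr <- nrow(ph); nc <- ncol(ph)
  grad2 <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (s in shifts) {
    r_src <- seq_len(nr) + s[1]
    c_src <- seq_len(nc) + s[2]
    okr <- r_src >= 1 & r_src <= nr
    okc <- c_src >= 1 & c_src <= nc
    d <- matrix(NA_real_, nr, nc)
    d[okr, okc] <- ph[r_src[okr], c_src[okc]] - ph[okr, okc]
    msk <- matrix(FALSE, nr, nc)
    msk[okr, okc] <- mask[r_src[okr], c_src[okc]] & mask[okr, okc]
    dw <- wrap_phase(d)
    grad2[msk] <- grad2[msk] + dw[msk]^2
    cnt[msk] <- cnt[msk] + 1
  }
  sdg <- sqrt(grad2 / pmax(cnt, 1))
  mag * exp(-sdg)
}

# fix the per-component 2*pi*k offset using the previous frame's solution
.seed_temporal <- function(u, comp, prev) {
  for (k in seq_len(max(comp))) {
    sel <- comp == k
    if (!any(sel)) next
    if (!is.null(prev)) {
      common <- sel & is.finite(prev) & is.finite(u)
      if (any(common)) {
        off <- 2 * pi * round(stats::median(u[common] - prev[common]) /
                                (2 * pi))
        u[sel] <- u[sel] - off
        next
      }
    }
    # no temporal anchor: reference the component median into (-pi, pi]
    off <- 2 * pi * round(stats::median(u[sel]) / (2 * pi))
    u[sel] <- u[sel] - off
  }
  u
}
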