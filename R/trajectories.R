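#' Material-point trajectories from a displacement field
#'
#' Builds a smoothed position trajectory for every reference-frame myocardial
#' point.  Per frame, the Eulerian displacement field is spatially smoothed
#' (normalized Gaussian convolution over valid pixels, default sigma of one
#' pixel), then each material point's current position is found by fixed-point
#' iteration of \eqn{x = X_0 + u(x)} with bilinear interpolation, warm-started
#' from the previous frame.  Finally each point's displacement history is fit
#' by a least-squares polynomial in time (default order 5, capped at
#' \code{n_frames - 2} so the fit always smooths; an interpolating order is
#' rejected).
#'
#' Points whose position leaves the valid field of view are marked invalid
#' from the first exit frame onward.
#'
#' @param field a \code{\link{phase_to_displacement}} result.
#' @param ref_mask logical matrix of reference-frame points to track.
#' @param sigma_px spatial smoothing SD, pixels; 0 disables smoothing.
#' @param poly_order temporal polynomial order; must be at most
#'   \code{n_frames - 2}.
#' @param max_iter,tol fixed-point iteration controls (pixels).
#' @return object of class \code{trajectories}: \code{X0} (n x 2, mm),
#'   \code{pos} (n x 2 x n_frames, mm), \code{valid} (n x n_frames),
#'   \code{frame_times}, \code{pixel_spacing}, \code{ref_index}.
#' @export
build_trajectories <- function(field, ref_mask, sigma_px = 1, poly_order = 5,
                               max_iter = 20L, tol = 1e-3) {
  stopifnot(inherits(field, "displacement_field"), is.logical(ref_mask))
  nf <- length(field$frame_times)
  if (nf < 3L) stop("at least 3 frames are required")
  if (poly_order >= nf - 1)
    stop(sprintf(
      "poly_order %d with %d frames would interpolate, not smooth (max %d)",
      poly_order, nf, nf - 2))
  order_eff <- min(poly_order, nf - 2)

  np <- nrow(ref_mask)
  sp <- field$pixel_spacing
  g <- pixel_grid(np, sp)
  idx <- which(ref_mask)
  X0 <- cbind(g$x[idx], g$y[idx])
  n_pts <- nrow(X0)

  pos <- array(NA_real_, c(n_pts, 2, nf))
  valid <- matrix(FALSE, n_pts, nf)
  cur <- X0
  for (f in seq_len(nf)) {
    v <- field$valid[, , f]
    sux <- .gauss_smooth2d(field$ux[, , f], v, sigma_px)
    suy <- .gauss_smooth2d(field$uy[, , f], v, sigma_px)
    ok <- rep(TRUE, n_pts)
    for (it in seq_len(max_iter)) {
      px <- cur[, 1] / sp + (np + 1) / 2
      py <- cur[, 2] / sp + (np + 1) / 2
      ix <- .bilinear(sux, px, py)
      iy <- .bilinear(suy, px, py)
      new_x <- X0[, 1] + ix
      new_y <- X0[, 2] + iy
      bad <- !is.finite(new_x) | !is.finite(new_y)
      ok <- ok & !bad
      new_x[bad] <- cur[bad, 1]
      new_y[bad] <- cur[bad, 2]
      shift <- pmax(abs(new_x - cur[, 1]), abs(new_y - cur[, 2])) / sp
      cur <- cbind(new_x, new_y)
      if (max(shift[ok], 0) < tol) break
    }
    pos[, , f] <- cur
    valid[, f] <- ok
  }
  # invalid from first exit frame onward
  for (f in 2:nf) valid[, f] <- valid[, f] & valid[, f - 1]

  # temporal polynomial smoothing of the displacement histories
  tt <- field$frame_times / max(field$frame_times)
  B <- outer(tt, 0:order_eff, `^`)
  patterns <- apply(valid, 1, function(v) paste(as.integer(v), collapse = ""))
  for (pat in unique(patterns)) {
    rows <- which(patterns == pat)
    vf <- which(valid[rows[1], ])
    if (length(vf) < order_eff + 2) next   # too short to smooth; keep raw
    Bv <- B[vf, , drop = FALSE]
    H <- Bv %*% solve(crossprod(Bv), t(Bv))
    for (d in 1:2) {
      D <- pos[rows, d, vf, drop = FALSE]
      dim(D) <- c(length(rows), length(vf))
      disp <- D - X0[rows, d]
      pos[rows, d, vf] <- X0[rows, d] + disp %*% t(H)
    }
  }
  structure(list(X0 = X0, pos = pos, valid = valid,
                 frame_times = field$frame_times,
                 pixel_spacing = sp, ref_index = idx,
                 grid_dim = dim(ref_mask)),
            class = "trajectories")
}

# Gaussian-weighted local-plane smoothing over valid pixels.  Fitting a
# plane (not a weighted mean) keeps linear displacement fields -- rigid
# rotations in particular -- unbiased even where the kernel support is
# clipped by the mask edge.  Falls back to the weighted mean where the
# normal equations are ill-conditioned.
.gauss_smooth2d <- function(mat, valid, sigma) {
  if (sigma <= 0) {
    out <- mat
    out[!valid] <- NA_real_
    return(out)
  }
  rad <- max(1L, ceiling(3 * sigma))
  off <- -rad:rad
  k1 <- exp(-off^2 / (2 * sigma^2))
  nr <- nrow(mat); nc <- ncol(mat)
  m0 <- ifelse(valid, mat, 0)
  v0 <- ifelse(valid, 1, 0)
  acc <- function() matrix(0, nr, nc)
  Sw <- acc(); Sx <- acc(); Sy <- acc(); Sxx <- acc(); Sxy <- acc()
  Syy <- acc(); Su <- acc(); Sxu <- acc(); Syu <- acc()
  for (i in seq_along(off)) {
    for (j in seq_along(off)) {
      kw <- k1[i] * k1[j]
      dx <- off[i]; dy <- off[j]
      rs <- seq_len(nr) + dx
      cs <- seq_len(nc) + dy
      okr <- rs >= 1 & rs <= nr
      okc <- cs >= 1 & cs <= nc
      vv <- v0[rs[okr], cs[okc]]
      uu <- m0[rs[okr], cs[okc]]
      Sw[okr, okc] <- Sw[okr, okc] + kw * vv
      Sx[okr, okc] <- Sx[okr, okc] + kw * dx * vv
      Sy[okr, okc] <- Sy[okr, okc] + kw * dy * vv
      Sxx[okr, okc] <- Sxx[okr, okc] + kw * dx * dx * vv
      Sxy[okr, okc] <- Sxy[okr, okc] + kw * dx * dy * vv
      Syy[okr, okc] <- Syy[okr, okc] + kw * dy * dy * vv
      Su[okr, okc] <- Su[okr, okc] + kw * vv * uu
      Sxu[okr, okc] <- Sxu[okr, okc] + kw * dx * vv * uu
      Syu[okr, okc] <- Syu[okr, okc] + kw * dy * vv * uu
    }
  }
  # Cramer solve of the 3x3 normal equations for the intercept term
  det3 <- Sw * (Sxx * Syy - Sxy^2) - Sx * (Sx * Syy - Sxy * Sy) +
    Sy * (Sx * Sxy - Sxx * Sy)
  d_a <- Su * (Sxx * Syy - Sxy^2) - Sx * (Sxu * Syy - Sxy * Syu) +
    Sy * (Sxu * Sxy - Sxx * Syu)
  out <- d_a / det3
  fallback <- !is.finite(out) | abs(det3) < 1e-8 * pmax(Sw, 1e-12)^3
  out[fallback] <- (Su / Sw)[fallback]
  out[!valid | Sw < 1e-3] <- NA_real_
  out
}

# bilinear interpolation at fractional pixel coordinates; NA when any
# contributing pixel is NA or the query leaves the grid
.bilinear <- function(mat, px, py) {
  nr <- nrow(mat); nc <- ncol(mat)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  out <- rep(NA_real_, length(px))
  ok <- x0 >= 1 & x0 + 1 <= nr & y0 >= 1 & y0 + 1 <= nc &
    is.finite(px) & is.finite(py)
  if (!any(ok)) return(out)
  i00 <- cbind(x0[ok], y0[ok])
  i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1)
  i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  v <- (1 - fx[ok]) * (1 - fy[ok]) * mat[i00] +
    fx[ok] * (1 - fy[ok]) * mat[i10] +
    (1 - fx[ok]) * fy[ok] * mat[i01] +
    fx[ok] * fy[ok] * mat[i11]
  out[ok] <- v
  out
}
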