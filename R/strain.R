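#' Green-Lagrange strain curves from material trajectories
#'
#' For each tracked element (one per reference pixel) and frame, the local
#' deformation gradient F is estimated by least squares over the element's
#' reference neighborhood, and the Green-Lagrange tensor
#' \eqn{E = (F^T F - I)/2} is projected onto the circumferential and radial
#' unit vectors defined at the reference configuration relative to the LV
#' centroid.  Green-Lagrange strain is exactly zero under rigid motion, so
#' translations and rotations do not masquerade as deformation.  Element
#' curves are averaged within angular sectors (anchored at the RV insertion
#' angle, counterclockwise) and over the whole slice.
#'
#' Strains are reported as the tensor projection times 100 (percent): an
#' isotropic scaling \eqn{r = kR} gives \eqn{Ecc = Err = 100 (k^2-1)/2}.
#'
#' @param traj a \code{\link{build_trajectories}} result.
#' @param lv_centroid LV center at reference, mm (length 2).
#' @param rv_insertion_angle sector anchor angle, degrees.
#' @param n_sectors number of angular sectors (6 basal/mid, 4 apical).
#' @param neighborhood_radius_px neighborhood radius for the deformation
#'   gradient, pixels (default 2.5); at least 6 valid neighbors are required
#'   per element and frame, otherwise that element-frame is NA.
#' @return object of class \code{strain_curves}: element-level \code{ecc}
#'   and \code{err} matrices (percent, elements x frames), element
#'   \code{angle} (deg) / \code{radius} / \code{sector}, sector means
#'   \code{ecc_segment}/\code{err_segment} (sectors x frames), slice means
#'   \code{ecc_slice}/\code{err_slice}, \code{frame_times},
#'   \code{n_sectors}, \code{rv_insertion_angle}.
#' @export
compute_strains <- function(traj, lv_centroid = c(0, 0),
                            rv_insertion_angle = 0, n_sectors = 6L,
                            neighborhood_radius_px = 2.5) {
  stopifnot(inherits(traj, "trajectories"), length(lv_centroid) == 2,
            n_sectors >= 1)
  X0 <- traj$X0
  n_el <- nrow(X0)
  nf <- length(traj$frame_times)
  sp <- traj$pixel_spacing

  # neighbor lists on the reference pixel lattice (via stored pixel indices)
  rad <- neighborhood_radius_px
  rc <- arrayInd(traj$ref_index, traj$grid_dim)
  lut <- setNames(seq_len(n_el), paste(rc[, 1], rc[, 2]))
  offs <- expand.grid(dx = -floor(rad):floor(rad), dy = -floor(rad):floor(rad))
  offs <- offs[offs$dx^2 + offs$dy^2 <= rad^2 &
                 !(offs$dx == 0 & offs$dy == 0), ]
  nb <- vector("list", n_el)
  for (k in seq_len(nrow(offs))) {
    nbk <- lut[paste(rc[, 1] + offs$dx[k], rc[, 2] + offs$dy[k])]
    for (i in which(!is.na(nbk))) nb[[i]] <- c(nb[[i]], nbk[i])
  }

  dtheta <- atan2(X0[, 2] - lv_centroid[2], X0[, 1] - lv_centroid[1])
  er <- cbind(cos(dtheta), sin(dtheta))
  ec <- cbind(-sin(dtheta), cos(dtheta))
  angle_deg <- dtheta * 180 / pi
  radius <- sqrt(rowSums((X0 - matrix(lv_centroid, n_el, 2, byrow = TRUE))^2))
  sector <- pmin(floor(((angle_deg - rv_insertion_angle) %% 360) /
                         (360 / n_sectors)) + 1L, n_sectors)

  # only elements tracked over the whole cine enter the strain analysis:
  # trajectories with truncated temporal support carry a different
  # polynomial-fit residual than their neighbors, which would masquerade as
  # strain
  full <- traj$valid[, nf]
  ecc <- err <- matrix(NA_real_, n_el, nf)
  for (f in seq_len(nf)) {
    vf <- traj$valid[, f] & full
    P <- traj$pos[, , f]
    for (i in seq_len(n_el)) {
      if (!vf[i]) next
      ns <- nb[[i]]
      ns <- ns[vf[ns]]
      if (length(ns) < 6L) next
      dX <- X0[ns, , drop = FALSE] -
        matrix(X0[i, ], length(ns), 2, byrow = TRUE)
      dx <- P[ns, , drop = FALSE] -
        matrix(P[i, ], length(ns), 2, byrow = TRUE)
      M <- crossprod(dX)
      if (abs(det(M)) < 1e-9) next
      Fg <- t(solve(M, crossprod(dX, dx)))   # F = (dx' dX)(dX' dX)^-1
      E <- 0.5 * (crossprod(Fg) - diag(2))
      ecc[i, f] <- 100 * drop(ec[i, ] %*% E %*% ec[i, ])
      err[i, f] <- 100 * drop(er[i, ] %*% E %*% er[i, ])
    }
  }

  seg_mean <- function(m) {
    t(sapply(seq_len(n_sectors), function(s) {
      rows <- which(sector == s)
      if (!length(rows)) return(rep(NA_real_, nf))
      colMeans(m[rows, , drop = FALSE], na.rm = TRUE)
    }))
  }
  structure(list(ecc = ecc, err = err, angle = angle_deg, radius = radius,
                 sector = sector,
                 ecc_segment = seg_mean(ecc), err_segment = seg_mean(err),
                 ecc_slice = colMeans(ecc, na.rm = TRUE),
                 err_slice = colMeans(err, na.rm = TRUE),
                 frame_times = traj$frame_times, n_sectors = n_sectors,
                 rv_insertion_angle = rv_insertion_angle),
            class = "strain_curves")
}
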