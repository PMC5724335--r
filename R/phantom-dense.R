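#' Specification for a displacement-encoded (DENSE-style) cine phantom
#'
#' Describes an annular myocardium deforming under a named analytic law,
#' imaged as magnitude plus wrapped-phase series with the phase of each
#' in-plane axis proportional to the displacement component since the
#' reference frame (frame 1, zero deformation).  Activation follows
#' \eqn{s(t) = \sin^2(\pi t / T)} over the cine duration
#' \eqn{T = (n_{frames}-1)\,\Delta t} (contraction peaking at mid-cine),
#' optionally delayed per angular sector with linear angular blending across
#' sector borders so the displacement field stays continuous.
#'
#' Deformation laws (parameters at peak activation):
#' \itemize{
#'   \item \code{translation}: rigid shift by \code{c(dx, dy)} mm.
#'   \item \code{rotation}: rigid rotation by \code{angle} degrees about the
#'     center.
#'   \item \code{uniform-scale}: isotropic scaling \code{r = scale * R}.
#'   \item \code{incompressible-annulus}: area-preserving radial motion
#'     \code{r^2 = R^2 + delta} (delta in mm^2, negative for contraction).
#' }
#' Sector delays require a radial law (scale or incompressible annulus);
#' delayed rigid motions are not invertible sector-wise and are rejected.
#'
#' @param grid_size image size, pixels (square).
#' @param pixel_spacing pixel size, mm.
#' @param annulus_inner_radius,annulus_outer_radius reference annulus radii,
#'   mm.
#' @param n_frames number of cine frames (>= 3); frame i is at
#'   \code{(i-1)*frame_interval} ms.
#' @param frame_interval frame spacing, ms.
#' @param encoding_frequency displacement-encoding frequency, cycles/mm
#'   (> 0).
#' @param deformation_law list with element \code{type} and the law's
#'   parameters (see Details).
#' @param segment_delays activation delays per angular sector, ms (sectors of
#'   equal width anchored at 0 degrees, counterclockwise).
#' @param transition_width angular blending width at sector borders, degrees.
#' @param noise_sd_phase phase noise SD, radians.
#' @param seed integer seed.
#' @return object of class \code{dense_phantom_spec}.
#' @export
dense_phantom_spec <- function(grid_size = 96L, pixel_spacing = 1,
                               annulus_inner_radius = 25,
                               annulus_outer_radius = 35,
                               n_frames = 21L, frame_interval = 30,
                               encoding_frequency = 0.10,
                               deformation_law = list(
                                 type = "incompressible-annulus",
                                 delta = -120),
                               segment_delays = rep(0, 6),
                               transition_width = 10,
                               noise_sd_phase = 0, seed = 1L) {
  if (encoding_frequency <= 0) stop("encoding_frequency must be > 0")
  if (n_frames < 3L) stop("n_frames must be >= 3")
  if (annulus_inner_radius >= annulus_outer_radius)
    stop("annulus_inner_radius must be smaller than annulus_outer_radius")
  if (!all(is.finite(segment_delays))) stop("segment_delays must be finite")
  if (noise_sd_phase < 0) stop("noise_sd_phase must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  types <- c("translation", "rotation", "uniform-scale",
             "incompressible-annulus")
  if (!is.list(deformation_law) || !deformation_law$type %in% types)
    stop("deformation_law$type must be one of: ",
         paste(types, collapse = ", "))
  radial <- deformation_law$type %in% c("uniform-scale",
                                        "incompressible-annulus")
  if (any(segment_delays != 0) && !radial)
    stop("segment_delays require a radial deformation law")
  if (deformation_law$type == "incompressible-annulus" &&
      annulus_inner_radius^2 + min(0, deformation_law$delta) <= 0)
    stop("incompressible-annulus delta collapses the inner radius")
  structure(list(grid_size = as.integer(grid_size),
                 pixel_spacing = pixel_spacing,
                 annulus_inner_radius = annulus_inner_radius,
                 annulus_outer_radius = annulus_outer_radius,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 encoding_frequency = encoding_frequency,
                 deformation_law = deformation_law,
                 segment_delays = segment_delays,
                 transition_width = transition_width,
                 noise_sd_phase = noise_sd_phase,
                 seed = as.integer(seed)),
            class = "dense_phantom_spec")
}

#' Wrap phase into (-pi, pi]
#' @param p phase, radians.
#' @return wrapped phase.
#' @export
wrap_phase <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  # map -pi to +pi for a (-pi, pi] convention
  w[w == -pi] <- pi
  w
}

# activation profile: sin^2 ramp over the cine, 0 outside [0, T]
.activation <- function(t, t_cycle) {
  s <- numeric(length(t))
  inside <- t > 0 & t < t_cycle
  s[inside] <- sin(pi * t[inside] / t_cycle)^2
  s
}

# blended sector-delay profile at angles theta (degrees, any range)
.delay_profile <- function(theta_deg, delays, width) {
  k <- length(delays)
  sw <- 360 / k
  th <- theta_deg %% 360
  j <- floor(th / sw)              # sector index 0..k-1
  u <- th - j * sw                 # position within sector
  d <- delays[j + 1]
  if (width > 0) {
    h <- width / 2
    lo <- u < h                     # blend with previous sector
    if (any(lo)) {
      prev <- delays[(j[lo] - 1) %% k + 1]
      frac <- 0.5 + u[lo] / width
      d[lo] <- prev * (1 - frac) + delays[j[lo] + 1] * frac
    }
    hi <- u > sw - h                # blend with next sector
    if (any(hi)) {
      nxt <- delays[(j[hi] + 1) %% k + 1]
      frac <- (u[hi] - (sw - h)) / width
      d[hi] <- delays[j[hi] + 1] * (1 - frac) + nxt * frac
    }
  }
  d
}

#' Generate a displacement-encoded cine phantom with ground truth
#'
#' Simulates Eulerian magnitude and wrapped-phase series of the deforming
#' annulus described by a \code{\link{dense_phantom_spec}}: at each frame the
#' motion is inverted analytically so the phase at a pixel encodes the
#' displacement of the tissue currently there,
#' \eqn{\phi = \mathrm{wrap}(2\pi k_e u)} per encoded axis.  Ground-truth
#' Lagrangian displacements and closed-form Green-Lagrange radial and
#' circumferential strain curves are returned for every reference-frame
#' myocardial pixel, together with the blended per-element delays.
#'
#' A warning is issued when the deformation moves tissue by more than half an
#' encoding period between consecutive frames or between adjacent pixels,
#' since no unwrapping can traverse such a step.
#'
#' @param spec a \code{\link{dense_phantom_spec}}.
#' @return list with \code{magnitude}, \code{phase_x}, \code{phase_y}
#'   (arrays x, y, frame; phase wrapped), \code{mask_ref} (reference annulus,
#'   logical), \code{frame_times} (ms), \code{lv_center} (mm, c(0,0)),
#'   \code{truth} (list: \code{ux}, \code{uy}, \code{ecc}, \code{err}
#'   element x frame matrices in mm and percent strain; \code{ref_xy} element
#'   reference positions, mm; \code{element_delay} ms;
#'   \code{segment_delays} the injected sector delays), and the \code{spec}.
#' @export
generate_dense_phantom <- function(spec) {
  stopifnot(inherits(spec, "dense_phantom_spec"))
  set.seed(spec$seed)
  n <- spec$grid_size
  g <- pixel_grid(n, spec$pixel_spacing)
  law <- spec$deformation_law
  t_cycle <- (spec$n_frames - 1) * spec$frame_interval
  frame_times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  ke <- spec$encoding_frequency

  r_pix <- sqrt(g$x^2 + g$y^2)
  theta_pix <- atan2(g$y, g$x) * 180 / pi
  mask_ref <- r_pix >= spec$annulus_inner_radius &
    r_pix <= spec$annulus_outer_radius

  has_delays <- any(spec$segment_delays != 0)
  delay_at <- function(th) {
    if (!has_delays) rep(0, length(th))
    else .delay_profile(th, spec$segment_delays, spec$transition_width)
  }

  # inverse motion: reference position X of the tissue at pixel x at time t
  invert <- function(t) {
    s_px <- .activation(t - delay_at(theta_pix), t_cycle)
    switch(law$type,
      "translation" = {
        s <- .activation(t, t_cycle)
        list(X = g$x - law$dx * s, Y = g$y - law$dy * s)
      },
      "rotation" = {
        s <- .activation(t, t_cycle)
        phi <- -law$angle * pi / 180 * s
        list(X = cos(phi) * g$x - sin(phi) * g$y,
             Y = sin(phi) * g$x + cos(phi) * g$y)
      },
      "uniform-scale" = {
        k <- 1 + (law$scale - 1) * s_px
        list(X = g$x / k, Y = g$y / k)
      },
      "incompressible-annulus" = {
        R2 <- pmax(r_pix^2 - law$delta * s_px, 0)
        scale <- ifelse(r_pix > 0, sqrt(R2) / r_pix, 1)
        list(X = g$x * scale, Y = g$y * scale)
      })
  }

  mag <- phx <- phy <- array(0, dim = c(n, n, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    inv <- invert(frame_times[f])
    Rref <- sqrt(inv$X^2 + inv$Y^2)
    tissue <- Rref >= spec$annulus_inner_radius &
      Rref <= spec$annulus_outer_radius
    ux <- g$x - inv$X
    uy <- g$y - inv$Y
    px <- 2 * pi * ke * ux
    py <- 2 * pi * ke * uy
    if (spec$noise_sd_phase > 0) {
      px <- px + rnorm(length(px), sd = spec$noise_sd_phase)
      py <- py + rnorm(length(py), sd = spec$noise_sd_phase)
    }
    px[!tissue] <- runif(sum(!tissue), -pi, pi)
    py[!tissue] <- runif(sum(!tissue), -pi, pi)
    mag[, , f] <- ifelse(tissue, 1, 0.05)
    phx[, , f] <- wrap_phase(px)
    phy[, , f] <- wrap_phase(py)
  }

  # Lagrangian ground truth at reference pixels
  idx <- which(mask_ref)
  R <- r_pix[idx]
  TH <- theta_pix[idx]
  edel <- delay_at(TH)
  n_el <- length(idx)
  ux_t <- uy_t <- ecc_t <- err_t <- matrix(0, n_el, spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    t <- frame_times[f]
    s_el <- .activation(t - edel, t_cycle)
    s0 <- .activation(t, t_cycle)
    res <- switch(law$type,
      "translation" = list(x = g$x[idx] + law$dx * s0,
                           y = g$y[idx] + law$dy * s0,
                           ecc = rep(0, n_el), err = rep(0, n_el)),
      "rotation" = {
        phi <- law$angle * pi / 180 * s0
        list(x = cos(phi) * g$x[idx] - sin(phi) * g$y[idx],
             y = sin(phi) * g$x[idx] + cos(phi) * g$y[idx],
             ecc = rep(0, n_el), err = rep(0, n_el))
      },
      "uniform-scale" = {
        k <- 1 + (law$scale - 1) * s_el
        e <- (k^2 - 1) / 2
        list(x = k * g$x[idx], y = k * g$y[idx], ecc = e, err = e)
      },
      "incompressible-annulus" = {
        r2 <- R^2 + law$delta * s_el
        rr <- sqrt(pmax(r2, 0))
        list(x = g$x[idx] * rr / R, y = g$y[idx] * rr / R,
             ecc = (r2 / R^2 - 1) / 2, err = (R^2 / r2 - 1) / 2)
      })
    ux_t[, f] <- res$x - g$x[idx]
    uy_t[, f] <- res$y - g$y[idx]
    ecc_t[, f] <- 100 * res$ecc
    err_t[, f] <- 100 * res$err
  }

  half_period <- 1 / (2 * ke)
  if (spec$n_frames > 1) {
    step_t <- max(abs(diff(t(ux_t))), abs(diff(t(uy_t))))
    if (step_t > half_period)
      warning(sprintf(
        "unwrapping feasibility: frame-to-frame displacement step %.2f mm exceeds half an encoding period (%.2f mm)",
        step_t, half_period))
  }

  list(magnitude = mag, phase_x = phx, phase_y = phy,
       mask_ref = mask_ref, frame_times = frame_times,
       lv_center = c(0, 0),
       encoding_frequency = ke, pixel_spacing = spec$pixel_spacing,
       truth = list(ux = ux_t, uy = uy_t, ecc = ecc_t, err = err_t,
                    ref_index = idx,
                    ref_xy = cbind(g$x[idx], g$y[idx]),
                    ref_radius = R, ref_angle = TH,
                    element_delay = edel,
                    segment_delays = spec$segment_delays),
       spec = spec)
}
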