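#' Peak strains and circumferential strain rates
#'
#' Peak circumferential strain is the signed minimum of the slice-mean Ecc
#' curve (most negative, percent); peak radial strain is the maximum of the
#' slice-mean Err curve.  The circumferential strain rate is the centered
#' finite difference of the slice-mean Ecc curve in percent per second;
#' systolic strain rate is its signed minimum, diastolic its maximum.
#' Segmental peak strains are also returned (segmental strain rates are
#' deliberately not derived).
#'
#' @param curves a \code{\link{compute_strains}} result.
#' @return list of class \code{mechanics_measures}: \code{peak_ecc},
#'   \code{peak_err} (percent), \code{sr_systolic}, \code{sr_diastolic}
#'   (percent/s), \code{sr_curve}/\code{sr_times} (interior frames),
#'   \code{peak_ecc_segment}, \code{peak_err_segment}.  All-invalid curves
#'   yield NA, never silent zeros.
#' @export
peak_metrics <- function(curves) {
  stopifnot(inherits(curves, "strain_curves"))
  tt <- curves$frame_times
  nf <- length(tt)
  if (nf < 3L) stop("at least 3 frames are required")
  safe_min <- function(x) if (all(!is.finite(x))) NA_real_
  else min(x, na.rm = TRUE)
  safe_max <- function(x) if (all(!is.finite(x))) NA_real_
  else max(x, na.rm = TRUE)

  ecc <- curves$ecc_slice
  err <- curves$err_slice
  i <- 2:(nf - 1)
  sr <- (ecc[i + 1] - ecc[i - 1]) / ((tt[i + 1] - tt[i - 1]) / 1000)
  structure(list(
    peak_ecc = safe_min(ecc), peak_err = safe_max(err),
    sr_systolic = safe_min(sr), sr_diastolic = safe_max(sr),
    sr_curve = sr, sr_times = tt[i],
    peak_ecc_segment = apply(curves$ecc_segment, 1, safe_min),
    peak_err_segment = apply(curves$err_segment, 1, safe_max)),
    class = "mechanics_measures")
}

#' Segmental contraction delays by cross-correlation
#'
#' Compares every element's circumferential strain curve against a
#' subject-level reference curve (the mean Ecc curve over all valid elements
#' across all supplied slices) with a normalized cross-correlation over
#' integer frame lags, refined to sub-frame resolution by parabolic
#' interpolation around the discrete peak.  Curves are mean-removed and
#' amplitude-normalized, so the delay estimate is insensitive to strain
#' magnitude differences.  The per-segment delay is the mean of its element
#' delays.
#'
#' The reference is ventricular: when \code{required_slices} names slices
#' that are absent, delays are still computed for the available slices but
#' the result is flagged incomplete and downstream dyssynchrony indices
#' should not be derived from it.
#'
#' @param slices a single \code{strain_curves} object or a named list of them
#'   (one per slice).
#' @param max_lag_fraction lag search range as a fraction of the cine
#'   duration (default 1/3), in whole-frame steps.
#' @param required_slices character vector of slice names that must be
#'   present for a complete (ventricular) analysis, or \code{NULL}.
#' @return list of class \code{delay_result}: \code{segment_delays} (data
#'   frame: slice, segment, angle, delay_ms, n_elements),
#'   \code{element_delays} (list per slice), \code{reference_curve},
#'   \code{frame_interval}, \code{complete}.
#' @export
segmental_delays <- function(slices, max_lag_fraction = 1 / 3,
                             required_slices = NULL) {
  if (inherits(slices, "strain_curves")) slices <- list(slice = slices)
  stopifnot(length(slices) >= 1,
            all(vapply(slices, inherits, TRUE, "strain_curves")))
  if (is.null(names(slices)))
    names(slices) <- paste0("slice", seq_along(slices))
  complete <- TRUE
  if (!is.null(required_slices) &&
      !all(required_slices %in% names(slices)))
    complete <- FALSE

  tt <- slices[[1]]$frame_times
  nf <- length(tt)
  dt <- tt[2] - tt[1]
  for (s in slices)
    if (!isTRUE(all.equal(s$frame_times, tt)))
      stop("all slices must share common frame times")

  allcurves <- do.call(rbind, lapply(slices, `[[`, "ecc"))
  refc <- colMeans(allcurves, na.rm = TRUE)
  if (all(!is.finite(refc))) stop("no valid element curves for the reference")
  max_lag <- max(1L, round(nf * max_lag_fraction))

  delay_one <- function(x) {
    if (any(!is.finite(x))) return(NA_real_)
    xc <- x - mean(x)
    rc <- refc - mean(refc)
    lags <- -max_lag:max_lag
    cc <- vapply(lags, function(k) {
      ti <- max(1, 1 + k):min(nf, nf + k)
      a <- xc[ti]; b <- rc[ti - k]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den == 0) return(NA_real_)
      sum(a * b) / den
    }, numeric(1))
    if (all(!is.finite(cc))) return(NA_real_)
    kbest <- which.max(cc)
    frac <- 0
    if (kbest > 1 && kbest < length(lags) &&
        all(is.finite(cc[kbest + c(-1, 1)]))) {
      denom <- cc[kbest - 1] - 2 * cc[kbest] + cc[kbest + 1]
      if (denom < 0) frac <- 0.5 * (cc[kbest - 1] - cc[kbest + 1]) / denom
      frac <- max(min(frac, 0.5), -0.5)
    }
    (lags[kbest] + frac) * dt
  }

  element_delays <- lapply(slices, function(s)
    apply(s$ecc, 1, delay_one))
  seg_tabs <- Map(function(nm, s, ed) {
    do.call(rbind, lapply(seq_len(s$n_sectors), function(k) {
      rows <- which(s$sector == k)
      d <- ed[rows]
      data.frame(slice = nm, segment = k,
                 angle = s$rv_insertion_angle +
                   (k - 0.5) * 360 / s$n_sectors,
                 delay_ms = if (any(is.finite(d))) mean(d, na.rm = TRUE)
                 else NA_real_,
                 n_elements = sum(is.finite(d)))
    }))
  }, names(slices), slices, element_delays)
  structure(list(segment_delays = do.call(rbind, c(seg_tabs,
                                                   make.row.names = FALSE)),
                 element_delays = element_delays, reference_curve = refc,
                 frame_interval = dt, complete = complete),
            class = "delay_result")
}

#' Dyssynchrony index from segmental delays
#'
#' Circumferentially smooths the segmental delays of one slice with a
#' periodic cubic spline interpolant over angular position, evaluates it on
#' a dense angular grid, and returns the standard deviation (population
#' form, divisor n) of the smoothed values.  DI is non-negative and
#' invariant to a uniform additive delay.
#'
#' @param delays segmental delays, ms (>= 4 finite values required).
#' @param angles_deg segment center angles, degrees (same length).
#' @param n_grid number of dense angular evaluation points (default 360).
#' @return DI in ms, or NA (with a warning) when fewer than 4 finite
#'   segmental delays are available.
#' @export
dyssynchrony_index <- function(delays, angles_deg, n_grid = 360L) {
  stopifnot(length(delays) == length(angles_deg), n_grid >= 8)
  ok <- is.finite(delays) & is.finite(angles_deg)
  if (sum(ok) < 4L) {
    warning("fewer than 4 segmental delays; DI not computed")
    return(NA_real_)
  }
  d <- delays[ok]
  a <- angles_deg[ok] %% 360
  ord <- order(a)
  a <- a[ord]; d <- d[ord]
  if (anyDuplicated(a)) stop("duplicate segment angles")
  xs <- c(a, a[1] + 360)
  ys <- c(d, d[1])
  grid <- a[1] + (seq_len(n_grid) - 1) * 360 / n_grid
  sm <- spline(xs, ys, method = "periodic", xout = grid)$y
  sqrt(mean((sm - mean(sm))^2))
}

#' Global dyssynchrony index over slices
#'
#' Applies \code{\link{dyssynchrony_index}} per slice of a
#' \code{\link{segmental_delays}} result and averages.  Returns all-NA when
#' the delay analysis is incomplete (a required slice was missing), since the
#' reference curve is then not ventricular.
#'
#' @param delay_result a \code{\link{segmental_delays}} result.
#' @return list with \code{per_slice} (named DI vector, ms) and
#'   \code{global} (mean of slice DIs).
#' @export
dyssynchrony_summary <- function(delay_result) {
  stopifnot(inherits(delay_result, "delay_result"))
  tab <- delay_result$segment_delays
  slices <- unique(tab$slice)
  if (!delay_result$complete) {
    per <- setNames(rep(NA_real_, length(slices)), slices)
    return(list(per_slice = per, global = NA_real_))
  }
  per <- vapply(slices, function(s) {
    rows <- tab[tab$slice == s, ]
    dyssynchrony_index(rows$delay_ms, rows$angle)
  }, numeric(1))
  list(per_slice = per, global = mean(per, na.rm = FALSE))
}
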