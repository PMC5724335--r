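#' Fit the three-parameter magnitude inversion-recovery model
#'
#' Estimates T1 from magnitude inversion-recovery signals
#' \eqn{S(TI) = |A - B e^{-TI/T_1^*}|} with polarity restoration and
#' Look-Locker correction \eqn{T_1 = T_1^* (B/A - 1)}.
#'
#' Polarity is restored by trying candidate null-crossing positions around
#' the minimum-magnitude sample (signs flipped for samples before the
#' crossing) and keeping the lowest-residual fit.  For each candidate the fit
#' is solved by variable projection: \eqn{A} and \eqn{B} are linear in the
#' model for fixed \eqn{T_1^*}, so only \eqn{T_1^*} is searched (coarse
#' log-spaced grid then local refinement), which is robust without starting
#' values.
#'
#' @param signals numeric vector (one pixel/ROI) or matrix with one row per
#'   pixel and one column per inversion time.
#' @param inversion_times strictly increasing inversion times, ms (>= 4).
#' @param mode "pixelwise" fits each row; "roi-pooled" fits the mean signal
#'   across rows.
#' @param t1_range admissible true-T1 range in ms; estimates outside it mark
#'   the pixel invalid rather than raising.
#' @return data frame of class \code{t1_fit_result} with one row per fit:
#'   \code{t1} (corrected, ms), \code{t1_star}, \code{a}, \code{b},
#'   \code{rss} (residual sum of squares), \code{valid}.
#' @export
fit_t1 <- function(signals, inversion_times,
                   mode = c("pixelwise", "roi-pooled"),
                   t1_range = c(1, 5000)) {
  mode <- match.arg(mode)
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  ti <- as.numeric(inversion_times)
  stopifnot(length(ti) >= 4L, all(diff(ti) > 0), ncol(signals) == length(ti),
            all(is.finite(ti)), ti[1] >= 0)
  if (mode == "roi-pooled") signals <- matrix(colMeans(signals), nrow = 1L)

  n <- length(ti)
  npx <- nrow(signals)
  # candidate null-crossing index per pixel: around the minimum-magnitude
  # sample (offsets -1..+1); crossing index j means samples 1..j are negative
  jmin <- max.col(-signals, ties.method = "first")
  cand <- lapply(-1:1, function(o) pmin(pmax(jmin + o, 0L), n))
  cand <- unique(do.call(cbind, cand), MARGIN = 2)

  tau_grid <- exp(seq(log(t1_range[1] + 1), log(t1_range[2] * 2),
                      length.out = 60L))

  # linear subproblem: y ~ a + c * e with e = exp(-ti/tau); returns RSS and
  # coefficients for all pixels at once (y is npx x n)
  lin_rss <- function(y, e) {
    Se <- sum(e); See <- sum(e * e)
    Sy <- rowSums(y); Sey <- as.vector(y %*% e)
    det <- n * See - Se * Se
    chat <- (n * Sey - Se * Sy) / det
    ahat <- (Sy - chat * Se) / n
    rss <- rowSums(y * y) - (ahat * Sy + chat * Sey)
    list(rss = pmax(rss, 0), a = ahat, c = chat)
  }

  ncand <- ncol(cand)
  grid_rss <- array(Inf, c(npx, ncand))
  grid_tau <- array(NA_real_, c(npx, ncand))
  for (ci in seq_len(ncand)) {
    j <- cand[, ci]
    sgn <- outer(j, seq_len(n), function(jj, ii) ifelse(ii <= jj, -1, 1))
    y <- signals * sgn
    for (tau in tau_grid) {
      r <- lin_rss(y, exp(-ti / tau))$rss
      upd <- r < grid_rss[, ci]
      grid_rss[upd, ci] <- r[upd]
      grid_tau[upd, ci] <- tau
    }
  }

  # per-pixel refinement of tau around the grid optimum of every polarity
  # candidate (the lowest-residual candidate may change after refinement)
  t1 <- t1s <- a <- b <- rss <- rep(NA_real_, npx)
  valid <- logical(npx)
  step <- tau_grid[2] / tau_grid[1]
  for (p in seq_len(npx)) {
    best <- list(rss = Inf)
    for (ci in seq_len(ncand)) {
      if (!is.finite(grid_tau[p, ci])) next
      sgn <- ifelse(seq_len(n) <= cand[p, ci], -1, 1)
      y <- matrix(signals[p, ] * sgn, nrow = 1L)
      obj <- function(tau) lin_rss(y, exp(-ti / tau))$rss
      opt <- optimize(obj, c(grid_tau[p, ci] / step, grid_tau[p, ci] * step),
                      tol = 1e-4)
      if (opt$objective < best$rss) {
        fit <- lin_rss(y, exp(-ti / opt$minimum))
        best <- list(rss = fit$rss, tau = opt$minimum, a = fit$a,
                     b = -fit$c)
      }
    }
    if (!is.finite(best$rss)) next
    t1s[p] <- best$tau
    a[p] <- best$a
    b[p] <- best$b
    rss[p] <- best$rss
    if (is.finite(a[p]) && a[p] > 0 && b[p] > 0) {
      t1[p] <- t1s[p] * (b[p] / a[p] - 1)
      valid[p] <- is.finite(t1[p]) && t1[p] > t1_range[1] &&
        t1[p] < t1_range[2]
    }
  }
  structure(data.frame(t1 = t1, t1_star = t1s, a = a, b = b,
                       rss = sqrt(rss), valid = valid),
            class = c("t1_fit_result", "data.frame"))
}

#' Fit a T1 map over masked pixels of an inversion-recovery series
#'
#' Convenience wrapper around \code{\link{fit_t1}} for an image series:
#' fits every pixel inside \code{mask} and returns a T1 map (NA outside the
#' mask and at invalid fits).
#'
#' @param series numeric array (x, y, inversion time).
#' @param inversion_times inversion times, ms.
#' @param mask logical matrix of pixels to fit.
#' @return list with \code{t1} (matrix, ms), \code{valid} (logical matrix),
#'   and \code{fits} (the per-pixel \code{t1_fit_result}).
#' @export
fit_t1_map <- function(series, inversion_times, mask) {
  stopifnot(length(dim(series)) == 3L, is.logical(mask),
            all(dim(mask) == dim(series)[1:2]))
  idx <- which(mask)
  sig <- matrix(series, ncol = dim(series)[3])[idx, , drop = FALSE]
  fits <- fit_t1(sig, inversion_times, mode = "pixelwise")
  t1 <- matrix(NA_real_, nrow(mask), ncol(mask))
  ok <- matrix(FALSE, nrow(mask), ncol(mask))
  t1[idx] <- ifelse(fits$valid, fits$t1, NA_real_)
  ok[idx] <- fits$valid
  list(t1 = t1, valid = ok, fits = fits)
}
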