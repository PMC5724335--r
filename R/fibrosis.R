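#' Gadolinium partition coefficient from pre/post-contrast T1
#'
#' Ratio of the contrast-induced change in myocardial relaxation rate to that
#' in blood:
#' \deqn{\lambda_{Gd} = \frac{1/T_{1,myo}^{post} - 1/T_{1,myo}^{pre}}
#'   {1/T_{1,blood}^{post} - 1/T_{1,blood}^{pre}}.}
#' The ratio is dimensionless and invariant to a common rescaling of all four
#' inputs (ms vs s).
#'
#' @param t1_myo_pre,t1_myo_post,t1_blood_pre,t1_blood_post T1 values, ms
#'   (any common unit), all > 0.
#' @param tol smallest admissible |denominator| in 1/ms; below it the blood
#'   relaxation change is too small to define a partition coefficient.
#' @return lambda_Gd, dimensionless.
#' @export
compute_lambda_gd <- function(t1_myo_pre, t1_myo_post,
                              t1_blood_pre, t1_blood_post, tol = 1e-9) {
  vals <- c(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  denom <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (abs(denom) < tol)
    stop("contrast dynamics error: blood relaxation-rate change below tolerance")
  (1 / t1_myo_post - 1 / t1_myo_pre) / denom
}

#' Default coefficients of the synthetic-hematocrit relationship
#'
#' The linear-in-1/T1 relationship \eqn{Hct = a / T_{1,blood}^{native} + b}
#' estimating hematocrit from native blood T1.  The defaults correspond to a
#' published validation at 1.5 T; they are configuration, not embedded truth,
#' and should be replaced when a site-specific calibration exists.
#'
#' @param a coefficient on 1/T1, ms.
#' @param b intercept, dimensionless.
#' @return named list with elements \code{a} and \code{b}.
#' @export
hematocrit_coefficients <- function(a = 866.0, b = -0.1232) {
  stopifnot(is.finite(a), is.finite(b))
  list(a = a, b = b)
}

#' Synthetic hematocrit from native blood T1
#'
#' Evaluates \eqn{Hct = a/T_1 + b} with configurable coefficients
#' (\code{\link{hematocrit_coefficients}}).  Estimates outside (0.1, 0.65)
#' are physiologically implausible and trigger a warning, but the value is
#' still returned.
#'
#' @param native_blood_t1 native (pre-contrast) blood T1, ms, > 0.
#' @param coefficients list with elements \code{a} (ms) and \code{b}.
#' @return estimated hematocrit fraction.
#' @export
synthetic_hematocrit <- function(native_blood_t1,
                                 coefficients = hematocrit_coefficients()) {
  stopifnot(is.finite(native_blood_t1), native_blood_t1 > 0,
            is.list(coefficients), all(c("a", "b") %in% names(coefficients)))
  hct <- coefficients$a / native_blood_t1 + coefficients$b
  if (hct <= 0.1 || hct >= 0.65)
    warning(sprintf("implausible synthetic hematocrit %.3f (outside (0.1, 0.65))",
                    hct))
  hct
}

#' Extracellular volume fraction
#'
#' \eqn{ECV = \lambda_{Gd} (1 - Hct)}: the gadolinium partition coefficient
#' scaled by the plasma fraction.
#'
#' @param lambda_gd gadolinium partition coefficient.
#' @param hematocrit hematocrit fraction in \[0, 1).
#' @return ECV fraction.
#' @export
compute_ecv <- function(lambda_gd, hematocrit) {
  stopifnot(is.finite(lambda_gd), is.finite(hematocrit),
            hematocrit >= 0, hematocrit < 1)
  lambda_gd * (1 - hematocrit)
}

#' Per-slice and per-segment fibrosis measures from co-registered T1 maps
#'
#' Averages native and post-contrast myocardial T1 within each scope (whole
#' slice and each segment of a \code{\link{partition_segments}} model), takes
#' blood T1 from the blood-pool ROI per slice, and computes lambda_Gd,
#' synthetic hematocrit and ECV from the scope-level mean T1s (ROI-mean
#' convention, not per-pixel lambda averaged).
#'
#' @param t1_pre,t1_post co-registered T1 maps (matrices, ms; NA at invalid
#'   pixels), pre- and post-contrast.
#' @param blood_mask logical matrix selecting the blood pool.
#' @param segments a \code{segment_model} from
#'   \code{\link{partition_segments}}; its labels define the myocardial
#'   scopes.
#' @param hct_coefficients synthetic-hematocrit coefficients
#'   (\code{\link{hematocrit_coefficients}}).
#' @param min_pixels scopes with fewer valid pixels are flagged invalid and
#'   carry NA measures.
#' @return data frame of class \code{fibrosis_measures}: one row per scope
#'   (\code{"slice"} then each segment), with native/post T1 (myocardium and
#'   blood), \code{lambda_gd}, \code{hematocrit}, \code{ecv},
#'   \code{n_pixels}, \code{valid}.  ECV outside \[0, 1\] is kept but flagged
#'   via the \code{ecv_plausible} column.
#' @export
summarize_fibrosis <- function(t1_pre, t1_post, blood_mask, segments,
                               hct_coefficients = hematocrit_coefficients(),
                               min_pixels = 10L) {
  stopifnot(is.matrix(t1_pre), all(dim(t1_pre) == dim(t1_post)),
            is.logical(blood_mask), all(dim(blood_mask) == dim(t1_pre)),
            inherits(segments, "segment_model"))
  labels <- segments$labels
  stopifnot(all(dim(labels) == dim(t1_pre)))

  blood_pre <- mean(t1_pre[blood_mask], na.rm = TRUE)
  blood_post <- mean(t1_post[blood_mask], na.rm = TRUE)
  if (!is.finite(blood_pre) || !is.finite(blood_post))
    stop("blood-pool ROI has no valid T1 pixels")
  hct <- synthetic_hematocrit(blood_pre, hct_coefficients)

  scopes <- c("slice", paste0("segment_", segments$segment_ids))
  masks <- c(list(labels > 0),
             lapply(segments$segment_ids, function(s) labels == s))

  one <- function(scope, m) {
    pre_vals <- t1_pre[m]
    post_vals <- t1_post[m]
    ok <- is.finite(pre_vals) & is.finite(post_vals)
    npx <- sum(ok)
    if (npx < min_pixels) {
      return(data.frame(scope = scope, native_t1_myo = NA_real_,
                        post_t1_myo = NA_real_, native_t1_blood = blood_pre,
                        post_t1_blood = blood_post, lambda_gd = NA_real_,
                        hematocrit = hct, ecv = NA_real_,
                        n_pixels = npx, valid = FALSE, ecv_plausible = NA))
    }
    myo_pre <- mean(pre_vals[ok])
    myo_post <- mean(post_vals[ok])
    lam <- compute_lambda_gd(myo_pre, myo_post, blood_pre, blood_post)
    # an out-of-range hematocrit (already warned about) cannot scale lambda
    # into an ECV; lambda itself is still reported
    ecv <- if (hct >= 0 && hct < 1) compute_ecv(lam, hct) else NA_real_
    data.frame(scope = scope, native_t1_myo = myo_pre,
               post_t1_myo = myo_post, native_t1_blood = blood_pre,
               post_t1_blood = blood_post, lambda_gd = lam,
               hematocrit = hct, ecv = ecv, n_pixels = npx, valid = TRUE,
               ecv_plausible = is.finite(ecv) && ecv >= 0 && ecv <= 1)
  }
  out <- do.call(rbind, Map(one, scopes, masks))
  rownames(out) <- NULL
  class(out) <- c("fibrosis_measures", "data.frame")
  out
}
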