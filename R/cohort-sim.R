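#' Specification for a simulated fibrosis-mechanics cohort
#'
#' Describes a cohort of subjects each measured at multiple levels (three
#' short-axis regions or sixteen segments), with a fibrosis predictor, a
#' mechanics outcome generated from a standardized linear model with
#' within-subject correlated residuals, and age/sex covariates.
#'
#' The generating model (on the analysis scale, after any log transform) is
#' \deqn{y_{ij} = \beta x_{ij} + a\,\mathrm{age}^z_i + s\,(\mathrm{male}_i - p)
#'   + \gamma_j + \epsilon_{ij}}
#' with \eqn{x_{ij}} standard normal (exchangeably correlated within subject),
#' \eqn{\gamma_j} centred level offsets and \eqn{\epsilon_i} multivariate
#' normal with the requested within-subject correlation.  With
#' \code{residual_sd = "auto"} the residual scale is chosen so the marginal
#' outcome variance is 1, so the injected \code{true_beta} is directly the
#' standardized coefficient recovered after sample z-scoring.
#'
#' @param n_subjects number of subjects.
#' @param levels "regional" (3 levels per subject) or "segmental" (16).
#' @param true_beta standardized effect of the predictor on the outcome.
#' @param region_effects centred fixed offsets per level (length 3 or 16);
#'   \code{NULL} for defaults.
#' @param age_effect,sex_effect standardized covariate coefficients.
#' @param within_subject_correlation 3x3 symmetric positive-definite matrix
#'   (regional) or a single exchangeable coefficient with |rho| < 1
#'   (segmental); \code{NULL} for defaults (a heterogeneous AR-like matrix,
#'   or rho = 0.5).
#' @param predictor_correlation exchangeable within-subject correlation of
#'   the predictor (default 0.5).
#' @param residual_sd residual standard deviation, or \code{"auto"} to target
#'   unit marginal outcome variance.
#' @param outcome_transform "identity" or "log"; with "log" the linear model
#'   generates the log outcome and the table stores its exponential.
#' @param age_mean,age_sd,p_male cohort demographics used to realise age in
#'   years and sex.
#' @param seed integer seed; the generator is deterministic given the spec.
#' @return object of class \code{cohort_sim_spec}.
#' @export
cohort_sim_spec <- function(n_subjects = 40L,
                            levels = c("regional", "segmental"),
                            true_beta = 0,
                            region_effects = NULL,
                            age_effect = 0.2,
                            sex_effect = 0.2,
                            within_subject_correlation = NULL,
                            predictor_correlation = 0.5,
                            residual_sd = "auto",
                            outcome_transform = c("identity", "log"),
                            age_mean = 25.5, age_sd = 10.5, p_male = 0.575,
                            seed = 1L) {
  levels <- match.arg(levels)
  outcome_transform <- match.arg(outcome_transform)
  n_levels <- if (levels == "regional") 3L else 16L
  if (is.null(region_effects)) {
    region_effects <- if (levels == "regional") c(-0.3, 0, 0.3)
    else 0.2 * cos(2 * pi * seq_len(16) / 16)
  }
  stopifnot(n_subjects >= 2, length(region_effects) == n_levels,
            all(is.finite(region_effects)),
            is.finite(true_beta), is.finite(age_effect), is.finite(sex_effect),
            predictor_correlation > -1 / (n_levels - 1),
            predictor_correlation < 1,
            p_male > 0, p_male < 1, age_sd > 0)
  region_effects <- region_effects - mean(region_effects)
  if (is.null(within_subject_correlation)) {
    within_subject_correlation <- if (levels == "regional") {
      matrix(c(1, 0.6, 0.45,
               0.6, 1, 0.7,
               0.45, 0.7, 1), 3, 3)
    } else 0.5
  }
  if (levels == "regional") {
    C <- within_subject_correlation
    stopifnot(is.matrix(C), nrow(C) == 3L, ncol(C) == 3L)
    if (max(abs(C - t(C))) > 1e-12)
      stop("within_subject_correlation must be symmetric")
    if (any(eigen(C, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
      stop("within_subject_correlation must be positive-definite")
    if (max(abs(diag(C) - 1)) > 1e-12)
      stop("within_subject_correlation must have unit diagonal")
  } else {
    rho <- within_subject_correlation
    stopifnot(length(rho) == 1L, abs(rho) < 1, rho > -1 / (n_levels - 1))
  }
  if (!identical(residual_sd, "auto"))
    stopifnot(is.numeric(residual_sd), residual_sd >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects), levels = levels,
    n_levels = n_levels, true_beta = true_beta,
    region_effects = region_effects, age_effect = age_effect,
    sex_effect = sex_effect,
    within_subject_correlation = within_subject_correlation,
    predictor_correlation = predictor_correlation,
    residual_sd = residual_sd, outcome_transform = outcome_transform,
    age_mean = age_mean, age_sd = age_sd, p_male = p_male,
    seed = as.integer(seed)), class = "cohort_sim_spec")
}

# residual SD targeting unit marginal outcome variance on the analysis scale
.auto_residual_sd <- function(spec) {
  var_region <- mean(spec$region_effects^2)
  var_fixed <- spec$true_beta^2 + spec$age_effect^2 +
    spec$sex_effect^2 * spec$p_male * (1 - spec$p_male) + var_region
  if (var_fixed >= 1)
    stop("auto residual_sd infeasible: fixed effects already imply variance >= 1")
  sqrt(1 - var_fixed)
}

# exchangeable correlation matrix
.exch_cor <- function(k, rho) {
  C <- matrix(rho, k, k)
  diag(C) <- 1
  C
}

#' Simulate a long-format cohort table with known ground truth
#'
#' Draws a cohort according to a \code{\link{cohort_sim_spec}} and returns a
#' long-format table (one record per subject and level) carrying the ground
#' truth parameters as an attribute.  Output is bit-identical for a fixed
#' spec (including seed).
#'
#' @param spec a \code{\link{cohort_sim_spec}}.
#' @return data frame with columns \code{subject}, \code{level},
#'   \code{predictor}, \code{outcome}, \code{age}, \code{sex};
#'   attribute \code{truth} holds the generating parameters.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  k <- spec$n_levels
  sigma <- if (identical(spec$residual_sd, "auto")) .auto_residual_sd(spec)
  else spec$residual_sd

  Cx <- .exch_cor(k, spec$predictor_correlation)
  Ce <- if (spec$levels == "regional") spec$within_subject_correlation
  else .exch_cor(k, spec$within_subject_correlation)
  Lx <- chol(Cx)
  Le <- chol(Ce)

  age_z <- rnorm(n)
  male <- as.integer(runif(n) < spec$p_male)
  x <- matrix(rnorm(n * k), n, k) %*% Lx          # subjects x levels
  eps <- (matrix(rnorm(n * k), n, k) %*% Le) * sigma

  eta <- spec$true_beta * x +
    matrix(spec$age_effect * age_z, n, k) +
    matrix(spec$sex_effect * (male - spec$p_male), n, k) +
    matrix(spec$region_effects, n, k, byrow = TRUE)
  y <- eta + eps
  if (spec$outcome_transform == "log") y <- exp(y)

  level_names <- if (spec$levels == "regional") c("basal", "mid", "apical")
  else paste0("seg", seq_len(16))
  out <- data.frame(
    subject = rep(sprintf("S%03d", seq_len(n)), each = k),
    level = factor(rep(level_names, n), levels = level_names),
    predictor = as.vector(t(x)),
    outcome = as.vector(t(y)),
    age = spec$age_mean + spec$age_sd * rep(age_z, each = k),
    sex = factor(ifelse(rep(male, each = k) == 1L, "male", "female"),
                 levels = c("female", "male")),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(
    true_beta = spec$true_beta, residual_sd = sigma,
    age_effect = spec$age_effect, sex_effect = spec$sex_effect,
    region_effects = spec$region_effects,
    within_subject_correlation = Ce,
    outcome_transform = spec$outcome_transform)
  out
}
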