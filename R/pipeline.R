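#' Default pipeline configuration
#'
#' Full set of tunables for \code{\link{run_pipeline}}, each at its
#' documented default.  \code{\link{validate_config}} merges a user config
#' over these values.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = file.path(tempdir(), "fibromech-run"),
    stages = c("simulate", "t1", "strain", "associate"),
    simulate = list(
      n_subjects = 6L,
      missing_slice_subjects = 1L,   # subjects with one DENSE slice dropped
      ecv_mean = 0.245, ecv_sd = 0.05,
      delay_base = 10, delay_slope = 8,  # ms; segment delay amplitude vs ECV
      molli = list(grid_size = 48L, pixel_spacing = 2.5, noise_sd = 1),
      dense = list(grid_size = 64L, pixel_spacing = 1.5, n_frames = 11L,
                   frame_interval = 30, encoding_frequency = 0.10,
                   delta = -120, noise_sd_phase = 0.05)),
    t1 = list(erosion_fraction = 0.25,
              hematocrit_a = 866.0, hematocrit_b = -0.1232,
              min_pixels = 10L),
    strain = list(sigma_px = 1, poly_order = 5,
                  neighborhood_radius_px = 2.5, max_lag_fraction = 1 / 3),
    associate = list(alpha = 0.05))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or \code{NULL} (defaults only,
#' simulation mode).  Unknown keys produce a warning (forward
#' compatibility); out-of-range tunables are collected and reported together
#' as one error.  Defaults are injected for everything unspecified.
#'
#' @param config path to a YAML config file, a nested list, or \code{NULL}.
#' @return normalized configuration of class \code{run_config}.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- default_config()

  warn_unknown <- function(user, def, prefix = "") {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      warning(sprintf("ignoring unknown config key(s): %s",
                      paste0(prefix, unknown, collapse = ", ")),
              call. = FALSE)
    for (nm in intersect(names(user), names(def)))
      if (is.list(def[[nm]]) && is.list(user[[nm]]))
        warn_unknown(user[[nm]], def[[nm]], paste0(prefix, nm, "."))
  }
  warn_unknown(config, defaults)
  merge_rec <- function(def, user) {
    for (nm in intersect(names(user), names(def))) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(user[[nm]]))
        merge_rec(def[[nm]], user[[nm]]) else user[[nm]]
    }
    def
  }
  cfg <- merge_rec(defaults, config)

  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$t1$erosion_fraction >= 0 && cfg$t1$erosion_fraction < 0.5,
      "t1.erosion_fraction must be in [0, 0.5)")
  chk(cfg$associate$alpha > 0 && cfg$associate$alpha < 1,
      "associate.alpha must be in (0, 1)")
  chk(cfg$simulate$n_subjects >= 2, "simulate.n_subjects must be >= 2")
  chk(cfg$simulate$missing_slice_subjects >= 0 &&
        cfg$simulate$missing_slice_subjects <= cfg$simulate$n_subjects,
      "simulate.missing_slice_subjects out of range")
  chk(cfg$simulate$dense$encoding_frequency > 0,
      "simulate.dense.encoding_frequency must be > 0")
  chk(cfg$simulate$dense$n_frames >= 3, "simulate.dense.n_frames must be >= 3")
  chk(cfg$simulate$molli$noise_sd >= 0,
      "simulate.molli.noise_sd must be >= 0")
  chk(cfg$strain$poly_order >= 1 &&
        cfg$strain$poly_order <= cfg$simulate$dense$n_frames - 2,
      "strain.poly_order must smooth (at most n_frames - 2)")
  chk(all(cfg$stages %in% c("simulate", "t1", "strain", "associate")),
      "stages must be a subset of simulate/t1/strain/associate")
  if (length(errs))
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"))
  class(cfg) <- "run_config"
  cfg
}

#' Run the fibrosis-mechanics pipeline end to end
#'
#' Simulates a synthetic study cohort (paired MOLLI-style and
#' displacement-encoded phantoms at three short-axis slices per subject,
#' with the subject's extracellular volume fraction driving both the
#' post-contrast T1 phantom and the injected dyssynchrony), then runs the T1
#' chain, the mechanics chain and the statistical association stage, writing
#' CSV tables and an exclusion log to \code{config$outdir}.
#'
#' Subjects with a dropped DENSE slice remain in the strain tables for their
#' available slices but receive no dyssynchrony index (the reference curve
#' is ventricular), and the exclusion is logged.  A subject failing a stage
#' is excluded from downstream tables with a logged reason; the run itself
#' continues.  Given a fixed config (including seed) the outputs are
#' deterministic.
#'
#' @param config a \code{run_config}, a YAML path, a list, or \code{NULL}
#'   (defaults; see \code{\link{validate_config}}).
#' @return list with the result tables (\code{fibrosis}, \code{mechanics},
#'   \code{models}, \code{exclusions}), the paths of the written CSVs, and
#'   the \code{log} lines.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
  }
  say("pipeline start: %d subjects, stages: %s", cfg$simulate$n_subjects,
      paste(cfg$stages, collapse = ","))
  for (nm in c("erosion_fraction", "hematocrit_a", "hematocrit_b"))
    say("tunable t1.%s = %s", nm, format(cfg$t1[[nm]]))
  for (nm in c("sigma_px", "poly_order", "max_lag_fraction"))
    say("tunable strain.%s = %s", nm, format(cfg$strain[[nm]]))

  slices <- c("basal", "mid", "apical")
  n <- cfg$simulate$n_subjects
  hctc <- hematocrit_coefficients(cfg$t1$hematocrit_a, cfg$t1$hematocrit_b)

  # --- simulate: subject-level ground truth -------------------------------
  zs <- rnorm(n)
  ecv_true <- pmin(pmax(cfg$simulate$ecv_mean + cfg$simulate$ecv_sd * zs,
                        0.12), 0.45)
  delay_amp <- pmax(cfg$simulate$delay_base + cfg$simulate$delay_slope * zs, 0)
  subj_seed <- sample.int(1e6, n)
  drop_slice <- rep(NA_character_, n)
  if (cfg$simulate$missing_slice_subjects > 0)
    drop_slice[seq_len(cfg$simulate$missing_slice_subjects)] <- "apical"

  blood_pre <- 1550; blood_post <- 300; myo_pre <- 950
  hct <- synthetic_hematocrit(blood_pre, hctc)
  lam_true <- ecv_true / (1 - hct)
  myo_post <- 1 / (lam_true * (1 / blood_post - 1 / blood_pre) + 1 / myo_pre)

  fibrosis <- mechanics <- exclusions <- NULL
  mol <- cfg$simulate$molli
  den <- cfg$simulate$dense

  for (s in seq_len(n)) {
    sid <- sprintf("S%03d", s)
    res <- tryCatch({
      fib_rows <- mech_rows <- NULL
      slice_curves <- list()
      for (sl in slices) {
        lev_jit <- c(basal = 0.98, mid = 1, apical = 1.02)[[sl]]
        if ("t1" %in% cfg$stages || "associate" %in% cfg$stages) {
          msp <- molli_phantom_spec(
            grid_size = mol$grid_size, pixel_spacing = mol$pixel_spacing,
            t1_myocardium = c(pre = myo_pre, post = myo_post[s] * lev_jit),
            t1_blood = c(pre = blood_pre, post = blood_post),
            noise_sd = mol$noise_sd, seed = subj_seed[s] + match(sl, slices))
          mph <- generate_molli_phantom(msp)
          endo <- circle_polygon(msp$annulus_inner_radius)
          epi <- circle_polygon(msp$annulus_outer_radius)
          roi <- extract_midwall_roi(endo, epi, msp$grid_size,
                                     msp$pixel_spacing,
                                     cfg$t1$erosion_fraction,
                                     slice_id = paste(sid, sl))
          segm <- partition_segments(roi, c(0, 0), 0, slice_level = sl,
                                     pixel_spacing = msp$pixel_spacing)
          fit_mask <- roi | mph$mask == 2L   # mid-wall plus blood pool
          pre_map <- fit_t1_map(mph$pre, mph$inversion_times, fit_mask)
          post_map <- fit_t1_map(mph$post, mph$inversion_times, fit_mask)
          fm <- summarize_fibrosis(pre_map$t1, post_map$t1,
                                   mph$mask == 2L, segm,
                                   hct_coefficients = hctc,
                                   min_pixels = cfg$t1$min_pixels)
          fib_rows <- rbind(fib_rows,
                            cbind(subject = sid, slice = sl, fm))
        }
        if (("strain" %in% cfg$stages || "associate" %in% cfg$stages) &&
            !identical(drop_slice[s], sl)) {
          n_sect <- if (sl == "apical") 4L else 6L
          dsp <- dense_phantom_spec(
            grid_size = den$grid_size, pixel_spacing = den$pixel_spacing,
            annulus_inner_radius = 20, annulus_outer_radius = 28,
            n_frames = den$n_frames, frame_interval = den$frame_interval,
            encoding_frequency = den$encoding_frequency,
            deformation_law = list(type = "incompressible-annulus",
                                   delta = den$delta * lev_jit),
            segment_delays = delay_amp[s] *
              (seq_len(n_sect) > n_sect / 2),
            noise_sd_phase = den$noise_sd_phase,
            seed = subj_seed[s] + 10L + match(sl, slices))
          dph <- generate_dense_phantom(dsp)
          fld <- phase_to_displacement(dph$phase_x, dph$phase_y,
                                       dph$magnitude,
                                       encoding_frequency =
                                         dph$encoding_frequency,
                                       frame_times = dph$frame_times,
                                       pixel_spacing = dph$pixel_spacing)
          tr <- build_trajectories(fld, dph$mask_ref,
                                   sigma_px = cfg$strain$sigma_px,
                                   poly_order = cfg$strain$poly_order)
          sc <- compute_strains(tr, dph$lv_center,
                                n_sectors = n_sect,
                                neighborhood_radius_px =
                                  cfg$strain$neighborhood_radius_px)
          slice_curves[[sl]] <- sc
          pm <- peak_metrics(sc)
          mech_rows <- rbind(mech_rows, data.frame(
            subject = sid, slice = sl, peak_ecc = pm$peak_ecc,
            peak_err = pm$peak_err, sr_systolic = pm$sr_systolic,
            sr_diastolic = pm$sr_diastolic, di = NA_real_))
        }
      }
      if (length(slice_curves)) {
        dl <- segmental_delays(slice_curves,
                               max_lag_fraction = cfg$strain$max_lag_fraction,
                               required_slices = slices)
        ds <- dyssynchrony_summary(dl)
        for (sl in names(ds$per_slice))
          mech_rows$di[mech_rows$slice == sl] <- ds$per_slice[[sl]]
        if (!dl$complete) {
          say("%s: missing slice (%s); dyssynchrony index not computed",
              sid, drop_slice[s])
          exclusions <- rbind(exclusions, data.frame(
            subject = sid, stage = "dyssynchrony",
            reason = sprintf("missing %s slice", drop_slice[s])))
        }
      }
      list(fib = fib_rows, mech = mech_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      say("%s: excluded (%s)", sid, conditionMessage(res))
      exclusions <- rbind(exclusions, data.frame(
        subject = sid, stage = "processing",
        reason = conditionMessage(res)))
    } else {
      fibrosis <- rbind(fibrosis, res$fib)
      mechanics <- rbind(mechanics, res$mech)
    }
  }

  # --- associate ----------------------------------------------------------
  models <- NULL
  if ("associate" %in% cfg$stages && !is.null(fibrosis) &&
      !is.null(mechanics)) {
    fib_slice <- fibrosis[fibrosis$scope == "slice", ]
    merged <- merge(fib_slice[, c("subject", "slice", "ecv")],
                    mechanics, by = c("subject", "slice"))
    demo <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                       age = 25.5 + 10.5 * rnorm(n),
                       sex = sample(c("male", "female"), n, replace = TRUE))
    merged <- merge(merged, demo, by = "subject")
    pairs <- list(list(outcome = "di", log = TRUE),
                  list(outcome = "peak_err", log = FALSE))
    for (pr in pairs) {
      tab <- data.frame(subject = merged$subject,
                        level = factor(merged$slice,
                                       levels = c("basal", "mid", "apical")),
                        predictor = merged$ecv,
                        outcome = merged[[pr$outcome]],
                        age = merged$age, sex = merged$sex)
      tab <- tab[is.finite(tab$outcome) & tab$outcome != 0 | !pr$log, ]
      tab <- tab[is.finite(tab$outcome), ]
      mr <- tryCatch(fit_mixed_model(tab, "regional", log_outcome = pr$log),
                     error = function(e) e)
      if (inherits(mr, "error")) {
        say("model %s ~ ecv failed: %s", pr$outcome, conditionMessage(mr))
        models <- rbind(models, data.frame(
          outcome = pr$outcome, predictor = "ecv", beta = NA_real_,
          p = NA_real_, structure = NA_character_, significant = NA))
      } else {
        models <- rbind(models, data.frame(
          outcome = pr$outcome, predictor = "ecv", beta = mr$beta,
          p = mr$p, structure = mr$structure, significant = NA))
      }
    }
    if (!is.null(models) && any(is.finite(models$p)))
      models$significant[is.finite(models$p)] <-
      bh_adjust(models$p[is.finite(models$p)], cfg$associate$alpha)
  }

  if (is.null(exclusions))
    exclusions <- data.frame(subject = character(), stage = character(),
                             reason = character())
  paths <- character()
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(cfg$outdir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(fibrosis, "fibrosis.csv")
  wr(mechanics, "mechanics.csv")
  wr(models, "models.csv")
  wr(exclusions, "exclusions.csv")
  writeLines(log_lines, file.path(cfg$outdir, "run.log"))
  say("pipeline complete")
  list(fibrosis = fibrosis, mechanics = mechanics, models = models,
       exclusions = exclusions, paths = paths, log = log_lines,
       config = cfg)
}
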