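#' Study configuration
#'
#' The reference experiment is 24 subjects x 5 trials x 3 speeds, models
#' trained at cutoffs 2/10/25 Hz with 10 subject-wise folds and the
#' reference LSTM (2 x 512, 100 epochs).  `desk_scale = TRUE` switches to a
#' smaller profile (12 subjects x 3 trials x 3 speeds, LSTM 2 x 64 and 30
#' epochs, 3 folds) that preserves every qualitative contrast while running
#' on a laptop-class single core.
#'
#' @param n_subjects cohort size.
#' @param trials_per_speed walking trials per subject and speed class.
#' @param speeds speed classes to simulate.
#' @param cutoffs IMU low-pass cutoffs (Hz), each below the 50 Hz Nyquist.
#' @param models estimators to run ("ffann", "lstm").
#' @param n_folds subject-wise folds.
#' @param master_seed integer; all randomness derives from it.
#' @param scale_mode "paper" (min/max over the whole matrix) or
#'   "train_only".
#' @param desk_scale logical; apply the reduced profile defaults.
#' @param lstm,ffann optional explicit model specs overriding the profile.
#' @param noise a [noise_spec()] (its seed is re-derived per trial).
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = if (desk_scale) 12L else 24L,
                         trials_per_speed = if (desk_scale) 3L else 5L,
                         speeds = c("slow", "normal", "fast"),
                         cutoffs = c(2, 10, 25),
                         models = c("ffann", "lstm"),
                         n_folds = if (desk_scale) 3L else 10L,
                         master_seed = 1L,
                         scale_mode = c("paper", "train_only"),
                         desk_scale = TRUE,
                         lstm = NULL, ffann = NULL,
                         noise = noise_spec()) {
  scale_mode <- match.arg(scale_mode)
  if (any(cutoffs >= 50)) fail("cutoffs must be below the 50 Hz IMU Nyquist")
  if (n_subjects < 1L || trials_per_speed < 1L || n_folds < 1L)
    fail("all counts must be >= 1")
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(lstm))
    lstm <- if (desk_scale) lstm_spec(cells = 64L, epochs = 30L)
    else lstm_spec(cells = 512L, epochs = 100L)
  if (is.null(ffann)) ffann <- ffann_spec()
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_speed = as.integer(trials_per_speed),
                 speeds = speeds, cutoffs = cutoffs, models = models,
                 n_folds = as.integer(n_folds),
                 master_seed = as.integer(master_seed),
                 scale_mode = scale_mode, desk_scale = desk_scale,
                 lstm = lstm, ffann = ffann, noise = noise),
            class = "study_config")
}

#' Simulate a cohort of walking trials
#'
#' @param config a [study_config()].
#' @return list with `subjects` (list of [subject_params()]) and `trials`
#'   (list of `trial_recording`).
#' @export
simulate_cohort <- function(config) {
  ms <- config$master_seed
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    sample_subject(derive_seed(ms, "cohort", i)))
  trials <- list()
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    for (sp in config$speeds) {
      for (tr in seq_len(config$trials_per_speed)) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(
          subjects[[i]], sp,
          seed = derive_seed(ms, paste("trial", i, sp), tr),
          noise = config$noise, trial_id = tr)
      }
    }
  }
  list(subjects = subjects, trials = trials)
}

# internal: ground-truth cycles + windows for every trial
cohort_ground_truth <- function(trials, model = anthropometric_model()) {
  lapply(trials, function(tr) {
    gt <- trial_inclination_angles(tr, model)
    list(trial = tr, ia = gt$ia, window = gt$window)
  })
}

# internal: per-cutoff dataset matrices from trials + ground truth
build_matrices <- function(gt, cutoff, scale_mode = "paper",
                           train_subjects = NULL) {
  fs <- filter_spec(cutoff = cutoff)
  cycles <- lapply(gt, function(g) {
    imu <- g$trial$imu
    filt <- imu
    for (ch in c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz"))
      filt[[ch]] <- butterworth_lowpass(imu[[ch]], g$trial$imu_rate, fs)
    list(subject = g$trial$subject_id,
         trial = g$trial$meta$trial_id,
         speed = g$trial$speed_class,
         X = resample_to_cycle(filt, g$window),
         Y = as.matrix(g$ia[, c("sagittal", "frontal")]))
  })
  assemble_matrices(cycles, scaling = scale_mode,
                    train_subjects = train_subjects)
}

#' Run the full study end-to-end
#'
#' Simulates the cohort, computes ground-truth inclination angles, builds
#' the learning matrices for every cutoff, trains every requested model on
#' every subject-wise fold, and aggregates correlation, RMSE, rRMSE and
#' ANOVA summaries.  Fully reproducible from `master_seed`.
#'
#' @param config a [study_config()].
#' @param verbose print progress lines.
#' @return object of class `study_result`: list with `results` (long
#'   data.frame: plane, model, cutoff, fold_id, r, rmse, rrmse), `summary`
#'   (see [summarize_study()]), `folds`, `config` and a `manifest` of
#'   derived seeds.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d subjects x %d trials x %d speeds",
      config$n_subjects, config$trials_per_speed, length(config$speeds))
  cohort <- simulate_cohort(config)
  gt <- cohort_ground_truth(cohort$trials)
  subject_ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  folds <- make_folds(subject_ids, config$n_folds,
                      derive_seed(config$master_seed, "folds"))
  results <- NULL
  for (cutoff in config$cutoffs) {
    say("cutoff %g Hz: assembling matrices", cutoff)
    mat <- build_matrices(gt, cutoff, config$scale_mode,
                          train_subjects = if (config$scale_mode == "train_only")
                            folds[[1]]$train_subjects else NULL)
    for (kind in config$models) {
      for (fold in folds) {
        spec0 <- if (kind == "ffann") config$ffann else config$lstm
        spec0$seed <- derive_seed(config$master_seed,
                                  paste("init", kind, cutoff), fold$fold_id)
        say("  %s fold %d", kind, fold$fold_id)
        ev <- evaluate_fold(mat, fold, kind, spec0)
        met <- ev$metrics
        met$cutoff <- cutoff
        results <- rbind(results, met)
      }
    }
  }
  structure(list(results = results, summary = summarize_study(results),
                 folds = folds, config = config,
                 manifest = list(master_seed = config$master_seed,
                                 cohort_seeds = vapply(
                                   seq_len(config$n_subjects), function(i)
                                     derive_seed(config$master_seed, "cohort", i),
                                   integer(1)),
                                 fold_seed = derive_seed(config$master_seed,
                                                         "folds"))),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d metric rows (%s; cutoffs %s; %d folds)\n",
              nrow(x$results), paste(x$config$models, collapse = "+"),
              paste(x$config$cutoffs, collapse = "/"), x$config$n_folds))
  bm <- x$summary$rrmse_by_model
  for (i in seq_len(nrow(bm)))
    cat(sprintf("  %s %-6s rRMSE %.1f (%.1f)%%\n", bm$plane[i], bm$model[i],
                bm$rrmse[i, "mean"], bm$rrmse[i, "sd"]))
  invisible(x)
}
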