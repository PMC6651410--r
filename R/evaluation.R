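#' Subject-wise cross-validation splits
#'
#' Builds `n_folds` seeded random subject-wise splits with sizes preserving
#' the 75/12.5/12.5 learning/validation/test ratio (18/3/3 for 24 subjects).
#' Because ten disjoint 3-subject test sets cannot partition 24 subjects,
#' folds are repeated random subsamples (each fold an independent seeded
#' shuffle), matching "randomly selected subjects".
#'
#' @param subjects vector of >= 8 subject ids.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the same seed reproduces the same folds.
#' @return list of `fold_split` objects with fields fold_id, train_subjects,
#'   val_subjects, test_subjects.
#' @export
make_folds <- function(subjects, n_folds = 10L, seed = 1L) {
  subjects <- unique(subjects)
  n <- length(subjects)
  if (n < 8L) fail("need at least 8 subjects to keep the 75/12.5/12.5 ratio, got %d", n)
  n_tr <- round(0.75 * n)
  n_va <- round(0.125 * n)
  n_te <- n - n_tr - n_va
  if (min(n_tr, n_va, n_te) < 1L) fail("cannot split %d subjects into 75/12.5/12.5", n)
  with_seed(seed, {
    lapply(seq_len(n_folds), function(k) {
      perm <- sample(subjects)
      structure(list(fold_id = k,
                     train_subjects = sort(perm[seq_len(n_tr)]),
                     val_subjects = sort(perm[n_tr + seq_len(n_va)]),
                     test_subjects = sort(perm[n_tr + n_va + seq_len(n_te)]),
                     seed = seed),
                class = "fold_split")
    })
  })
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d: train %d / val %d / test %d subjects (test: %s)\n",
              x$fold_id, length(x$train_subjects), length(x$val_subjects),
              length(x$test_subjects), paste(x$test_subjects, collapse = ",")))
  invisible(x)
}

#' Agreement metrics between measured and predicted angles
#'
#' Pearson correlation r, RMSE (degrees), and relative RMSE defined as
#' 100 x RMSE / (max(y_true) - min(y_true)) — RMSE as a percentage of the
#' measured signal's range.
#'
#' @param y_true,y_pred numeric series (degrees), equal length >= 2.
#' @return one-row data.frame with r, rmse, rrmse.  A constant `y_true`
#'   yields `r = NA` (with a warning) and `rrmse = NA`.
#' @export
ia_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    fail("series must have equal length >= 2")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  rng <- diff(range(y_true))
  if (rng == 0) {
    warning("constant y_true: r and rRMSE undefined")
    return(data.frame(r = NA_real_, rmse = rmse, rrmse = NA_real_))
  }
  data.frame(r = cor(y_true, y_pred), rmse = rmse, rrmse = 100 * rmse / rng)
}

#' Classical one-way ANOVA
#'
#' F statistic with (k - 1, N - k) degrees of freedom and the p-value from
#' the F distribution, computed through `stats::oneway.test` with equal
#' variances (the textbook one-way ANOVA).
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 observations.
#' @return object of class `anova_result`: list(F, df_between, df_within, p).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) fail("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) fail("every group needs >= 2 observations (got %s)",
                            paste(sizes, collapse = ","))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  structure(list(F = unname(ft$statistic),
                 df_between = unname(ft$parameter[1]),
                 df_within = unname(ft$parameter[2]),
                 p = unname(ft$p.value)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F[%d, %d] = %.3g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Train and test one model on one fold
#'
#' Trains the requested estimator on the fold's training subjects (with the
#' fold's validation subjects for early stopping / monitoring), predicts the
#' concatenated test-subject cycles, and returns per-plane metrics in
#' degrees.  A provenance audit asserts that no test-subject rows enter
#' training.
#'
#' @param mat a `dataset_matrices`.
#' @param fold a `fold_split`.
#' @param kind "ffann" or "lstm".
#' @param spec matching model spec; defaults to the spec constructor.
#' @return list with `metrics` (2-row data.frame: plane, r, rmse, rrmse),
#'   `model`, and `predictions` (degrees).
#' @export
evaluate_fold <- function(mat, fold, kind = c("ffann", "lstm"), spec = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(mat, "dataset_matrices"), inherits(fold, "fold_split"))
  if (length(intersect(fold$train_subjects, fold$test_subjects)) ||
      length(intersect(fold$val_subjects, fold$test_subjects)))
    fail("fold partitions overlap: test subjects leak into training")
  model <- if (kind == "ffann") {
    sp <- if (is.null(spec)) ffann_spec() else spec
    tr <- subject_rows(mat, fold$train_subjects)
    va <- subject_rows(mat, fold$val_subjects)
    stopifnot(length(intersect(tr, subject_rows(mat, fold$test_subjects))) == 0L)
    train_ffann(mat$X[tr, , drop = FALSE], mat$Y[tr, , drop = FALSE],
                mat$X[va, , drop = FALSE], mat$Y[va, , drop = FALSE],
                sp, scale_params = mat$scale_params)
  } else {
    sp <- if (is.null(spec)) lstm_spec() else spec
    train_lstm(cycle_blocks(mat, fold$train_subjects),
               cycle_blocks(mat, fold$val_subjects),
               sp, scale_params = mat$scale_params, n_frames = mat$n_frames)
  }
  te_cycles <- cycle_blocks(mat, fold$test_subjects)
  pred <- if (kind == "ffann") {
    predict(model, do.call(rbind, lapply(te_cycles, `[[`, "X")))
  } else {
    predict(model, lapply(te_cycles, `[[`, "X"))
  }
  truth_scaled <- do.call(rbind, lapply(te_cycles, `[[`, "Y"))
  truth <- truth_scaled
  sp2 <- mat$scale_params
  for (j in 1:2) truth[, j] <- minmax_inverse(truth_scaled[, j],
                                              sp2$y_lo[j], sp2$y_hi[j])
  met <- rbind(cbind(plane = "sagittal", ia_metrics(truth[, 1], pred[, 1])),
               cbind(plane = "frontal", ia_metrics(truth[, 2], pred[, 2])))
  met$fold_id <- fold$fold_id
  met$model <- kind
  list(metrics = met, model = model,
       predictions = list(pred = pred, truth = truth))
}

#' Summarize evaluation results
#'
#' Aggregates per-fold metrics into the study's reporting shapes: a
#' plane x cutoff x model grid of mean r and mean (SD) RMSE; rRMSE
#' mean (SD) per model (pooled over cutoffs) and per model x cutoff; and
#' one-way ANOVA contrasts — model within each plane (pooled cutoffs) and
#' cutoff within each model and plane.
#'
#' @param results data.frame with columns plane, model, cutoff, fold_id, r,
#'   rmse, rrmse (one row per fold x plane x model x cutoff).
#' @return list with `table1`, `rrmse_by_model`, `rrmse_by_cutoff`, `anova`.
#' @export
summarize_study <- function(results) {
  if (!nrow(results)) fail("no results to summarize")
  t1 <- aggregate(cbind(r, rmse) ~ plane + cutoff + model, data = results,
                  FUN = mean)
  t1$rmse_sd <- aggregate(rmse ~ plane + cutoff + model, data = results,
                          FUN = sd)$rmse
  by_model <- aggregate(rrmse ~ plane + model, data = results,
                        FUN = function(v) c(mean = mean(v), sd = sd(v)))
  by_cut <- aggregate(rrmse ~ plane + model + cutoff, data = results,
                      FUN = function(v) c(mean = mean(v), sd = sd(v)))
  anova_rows <- NULL
  for (pl in unique(results$plane)) {
    sub <- results[results$plane == pl, ]
    if (length(unique(sub$model)) >= 2L) {
      a <- one_way_anova(split(sub$rrmse, sub$model))
      anova_rows <- rbind(anova_rows,
                          data.frame(contrast = "model", plane = pl,
                                     model = NA, F = a$F,
                                     df_between = a$df_between,
                                     df_within = a$df_within, p = a$p))
    }
    for (md in unique(sub$model)) {
      s2 <- sub[sub$model == md, ]
      if (length(unique(s2$cutoff)) >= 2L) {
        a <- one_way_anova(split(s2$rrmse, s2$cutoff))
        anova_rows <- rbind(anova_rows,
                            data.frame(contrast = "cutoff", plane = pl,
                                       model = md, F = a$F,
                                       df_between = a$df_between,
                                       df_within = a$df_within, p = a$p))
      }
    }
  }
  list(table1 = t1, rrmse_by_model = by_model, rrmse_by_cutoff = by_cut,
       anova = anova_rows)
}
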