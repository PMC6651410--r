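test_that("subject-wise folds keep the 75/12.5/12.5 ratio and are disjoint", {
  subjects <- sprintf("S%02d", 1:24)
  folds <- make_folds(subjects, 10, seed = 1)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f$train_subjects, 18)
    expect_length(f$val_subjects, 3)
    expect_length(f$test_subjects, 3)
    expect_length(intersect(f$train_subjects, f$val_subjects), 0)
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_length(intersect(f$val_subjects, f$test_subjects), 0)
    expect_setequal(c(f$train_subjects, f$val_subjects, f$test_subjects),
                    subjects)
  }
  expect_identical(make_folds(subjects, 10, seed = 1), folds)
  # proportional sizes for other cohort sizes
  f12 <- make_folds(sprintf("S%02d", 1:12), 3, seed = 2)[[1]]
  expect_identical(lengths(f12[c("train_subjects", "val_subjects",
                                 "test_subjects")]),
                   c(train_subjects = 9L, val_subjects = 2L,
                     test_subjects = 1L))
  expect_error(make_folds(letters[1:7], 3, 1), "at least 8")
})

test_that("agreement metrics match hand computations", {
  y <- c(0, 10)
  m <- ia_metrics(y, c(1, 9))
  expect_equal(m$rmse, 1)
  expect_equal(m$rrmse, 10)
  exact <- ia_metrics(c(1, 3, 7), c(1, 3, 7))
  expect_equal(c(exact$r, exact$rmse, exact$rrmse), c(1, 0, 0))
  z <- c(-2, 0, 2)
  expect_equal(ia_metrics(z, -z)$r, -1)
  expect_warning(mc <- ia_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(mc$r) && is.na(mc$rrmse))
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  a <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$F, 13.5, tolerance = 1e-12)
  expect_identical(c(a$df_between, a$df_within), c(1, 4))
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # two-group F equals the squared equal-variance t statistic
  withr::with_seed(8, { g1 <- rnorm(12); g2 <- rnorm(15, 0.5) })
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  a2 <- one_way_anova(list(g1, g2))
  expect_lt(abs(a2$F - tt$statistic^2), 1e-9)
  expect_lt(abs(a2$p - tt$p.value), 1e-12)
  expect_error(one_way_anova(list(1:3, 5)), ">= 2 observations")
})

test_that("study summaries aggregate fold metrics correctly", {
  one <- data.frame(plane = "sagittal", model = "lstm", cutoff = 10,
                    fold_id = 1, r = 0.93, rmse = 1.8, rrmse = 9.5)
  s1 <- summarize_study(one)
  expect_equal(s1$table1$r, 0.93)
  expect_equal(s1$table1$rmse, 1.8)
  ten <- do.call(rbind, replicate(10, one, simplify = FALSE))
  ten$fold_id <- 1:10
  s10 <- summarize_study(ten)
  expect_equal(unname(s10$rrmse_by_model$rrmse[1, "mean"]), 9.5)
  expect_equal(unname(s10$rrmse_by_model$rrmse[1, "sd"]), 0)
  # independent aggregation oracle on a 3-fold two-model toy
  toy <- expand.grid(plane = c("sagittal", "frontal"),
                     model = c("ffann", "lstm"), cutoff = c(2, 10),
                     fold_id = 1:3, stringsAsFactors = FALSE)
  toy$r <- withr::with_seed(3, runif(nrow(toy), 0.7, 1))
  toy$rmse <- withr::with_seed(4, runif(nrow(toy), 0.5, 4))
  toy$rrmse <- withr::with_seed(5, runif(nrow(toy), 5, 20))
  s <- summarize_study(toy)
  want <- mean(toy$rmse[toy$plane == "frontal" & toy$model == "lstm" &
                          toy$cutoff == 10])
  got <- s$table1$rmse[s$table1$plane == "frontal" & s$table1$model == "lstm" &
                         s$table1$cutoff == 10]
  expect_equal(got, want)
  onek <- one_way_anova(split(toy$rrmse[toy$plane == "sagittal"],
                              toy$model[toy$plane == "sagittal"]))
  expect_equal(s$anova$F[s$anova$contrast == "model" &
                           s$anova$plane == "sagittal"], onek$F)
})

test_that("fold evaluation audits subject-wise separation", {
  f <- structure(list(fold_id = 1, train_subjects = c("A", "B"),
                      val_subjects = "A", test_subjects = "C", seed = 1),
                 class = "fold_split")
  mat <- structure(list(X = matrix(0, 10, 9), Y = matrix(0, 10, 2),
                        row_meta = data.frame(subject = rep("A", 10),
                                              trial = 1, speed = "slow",
                                              frame = 1:10),
                        scale_params = NULL, scaling = "paper",
                        n_frames = 10),
                   class = "dataset_matrices")
  f_bad <- f; f_bad$test_subjects <- "B"
  expect_error(evaluate_fold(mat, f_bad, "ffann"), "leak")
})
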