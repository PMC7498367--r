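test_that("the RBF kernel follows the sigma-times-squared-distance convention", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 0.5), 1)
  # closed form: distance^2 = ln(2)/sigma gives similarity one half
  y <- x + sqrt(log(2) / 0.3) * c(1, 0, 0)
  expect_equal(rbf_kernel(x, y, 0.3), 0.5, tolerance = 1e-12)
  expect_gt(rbf_kernel(c(0, 0), c(10, 10), 1e-9), 0.999)
  expect_error(rbf_kernel(1:3, 1:4, 1), "dimension")
  expect_error(rbf_kernel(x, x, 0), "sigma")
})

test_that("tuning recovers a separable problem and respects a singleton grid", {
  sep <- separable_matrix(n_per_class = 4)
  cfg <- svm_config(inner_folds = 2L, inner_repeats = 1L, seed = 1)
  tuned <- tune_svm(sep$x, sep$y, cfg)
  expect_equal(tuned$accuracy, 100)

  cfg1 <- svm_config(C_grid = 10, sigma_grid = 0.02,
                     inner_folds = 2L, inner_repeats = 1L)
  t1 <- tune_svm(sep$x, sep$y, cfg1)
  expect_equal(t1$C, 10)
  expect_equal(t1$sigma, 0.02)

  expect_error(tune_svm(sep$x, rep("A", nrow(sep$x)), cfg), "single class")
})

test_that("tie-breaking prefers the smallest cost, then the smallest bandwidth", {
  sep <- separable_matrix(n_per_class = 4)
  cfg <- svm_config(inner_folds = 2L, inner_repeats = 1L, seed = 1)
  tuned <- tune_svm(sep$x, sep$y, cfg)
  g <- tuned$grid
  best <- g[g$accuracy == max(g$accuracy), ]
  expect_equal(tuned$C, min(best$C))
  expect_equal(tuned$sigma, min(best$sigma[best$C == tuned$C]))
})

test_that("hyperparameter selection agrees with exhaustive grid evaluation", {
  # independent oracle: re-evaluate every grid point with the same folds and
  # a plain loop, then pick the best with the stated tie-break
  set.seed(5)
  sep <- separable_matrix(n_per_class = 4, n_noise = 10)
  x <- sep$x + matrix(rnorm(length(sep$x), sd = 1.2), nrow(sep$x))
  y <- factor(sep$y)
  cfg <- svm_config(C_grid = c(1, 100), sigma_grid = c(1e-3, 1e-1),
                    inner_folds = 3L, inner_repeats = 2L, seed = 7)
  tuned <- tune_svm(x, y, cfg, seed = 42)
  grid <- expand.grid(sigma = cfg$sigma_grid, C = cfg$C_grid)
  correct <- rep(0, nrow(grid)); total <- 0
  for (rep_i in seq_len(cfg$inner_repeats)) {
    fold <- digiwest:::make_folds(y, cfg$inner_folds,
                                  digiwest:::substream_seed(42, "inner", rep_i))
    for (f in seq_len(cfg$inner_folds)) {
      tr <- fold != f
      prep <- digiwest:::fit_preprocess(x[tr, , drop = FALSE], TRUE, NULL)
      xtr <- digiwest:::apply_preprocess(x[tr, , drop = FALSE], prep)
      xva <- digiwest:::apply_preprocess(x[!tr, , drop = FALSE], prep)
      for (g in seq_len(nrow(grid))) {
        m <- e1071::svm(xtr, droplevels(y[tr]), type = "C-classification",
                        kernel = "radial", gamma = grid$sigma[g],
                        cost = grid$C[g], scale = FALSE)
        correct[g] <- correct[g] + sum(predict(m, xva) == y[!tr])
      }
      total <- total + sum(!tr)
    }
  }
  acc <- 100 * correct / total
  best <- which.max(acc)
  expect_equal(tuned$C, grid$C[best])
  expect_equal(tuned$sigma, grid$sigma[best])
  expect_equal(tuned$accuracy, acc[best], tolerance = 1e-9)
  # the study's published optimum is a member of the default grids
  dflt <- svm_config()
  expect_true(100 %in% dflt$C_grid)
  expect_true(any(abs(dflt$sigma_grid - 1e-4) < 1e-12))
})

test_that("nested cross-validation is perfect on separable data and conserves counts", {
  sep <- separable_matrix(n_per_class = 5)
  cfg <- svm_config(outer_folds = 5L, outer_repeats = 2L,
                    inner_folds = 2L, inner_repeats = 1L, seed = 3)
  rep_ <- nested_cv(sep$x, sep$y, cfg)
  expect_equal(rep_$accuracy_mean, 100)
  expect_equal(rep_$accuracy_sd, 0)
  # every row of the mean matrix sums to its class size
  expect_equal(unname(rowSums(rep_$matrix)), rep(5, 5), tolerance = 1e-9)
  expect_equal(unname(rep_$per_class), rep(100, 5))
})

test_that("label permutation drives nested-CV accuracy to chance", {
  sep <- separable_matrix(n_per_class = 5, seed = 2)
  set.seed(99)
  y_perm <- sample(sep$y)
  cfg <- svm_config(outer_folds = 5L, outer_repeats = 2L,
                    inner_folds = 2L, inner_repeats = 1L, seed = 11,
                    C_grid = c(1, 100), sigma_grid = c(1e-3, 1e-1))
  rep_ <- nested_cv(sep$x, y_perm, cfg)
  expect_gte(rep_$accuracy_mean, 0)
  expect_lte(rep_$accuracy_mean, 45)  # chance is 20% for five classes
})

test_that("tuning and preprocessing never touch held-out outer-fold samples", {
  sep <- separable_matrix(n_per_class = 4, n_noise = 3)
  cfg <- svm_config(outer_folds = 4L, outer_repeats = 2L,
                    inner_folds = 2L, inner_repeats = 1L, seed = 5,
                    C_grid = c(1, 100), sigma_grid = c(1e-3, 1e-1))
  audit <- new.env()
  audit$log <- list()
  nested_cv(sep$x, sep$y, cfg, instrument = audit)
  fits <- Filter(function(e) e$what == "outer_fit", audit$log)
  tunes <- Filter(function(e) e$what == "tune", audit$log)
  expect_equal(length(fits), 4 * 2)
  expect_equal(length(tunes), 4 * 2)
  for (e in fits) {
    expect_length(intersect(e$indices, e$held_out), 0)
    expect_setequal(c(e$indices, e$held_out), seq_len(nrow(sep$x)))
  }
  # each tune call saw exactly the training indices of its outer fold
  for (i in seq_along(tunes))
    expect_identical(sort(tunes[[i]]$indices), sort(fits[[i]]$indices))
})

test_that("class merging redistributes within-group confusions into the diagonal", {
  cm <- matrix(c(4.9, 0, 0.1, 0, 0,
                 0, 5, 0, 0, 0,
                 0.5, 0, 2.6, 2.0, 0,
                 0, 0, 0.9, 2.9, 1.2,
                 0, 0, 0, 0, 5), 5, 5, byrow = TRUE,
               dimnames = list(c("HNSC", "PAAD", "LUSC", "LUAD", "COAD"),
                               c("HNSC", "PAAD", "LUSC", "LUAD", "COAD")))
  rep_ <- digiwest:::new_contingency(cm, 100 * sum(diag(cm)) / sum(cm),
                                     n_per_class = rep(5, 5), repeats = 10)
  ident <- merge_class_report(rep_, setNames(rownames(cm), rownames(cm)))
  expect_equal(ident$matrix, rep_$matrix)
  expect_equal(ident$accuracy_mean, rep_$accuracy_mean)

  merged <- merge_class_report(
    rep_, c(HNSC = "HNSC", PAAD = "PAAD", LUSC = "LUNG", LUAD = "LUNG",
            COAD = "COAD"))
  expect_equal(dim(merged$matrix), c(4L, 4L))
  expect_gte(merged$accuracy_mean, rep_$accuracy_mean)
  expect_equal(sum(merged$matrix), sum(cm))

  # a 2x2 toy where every error is between the merged classes
  toy <- matrix(c(3, 2, 2, 3), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  toy_rep <- digiwest:::new_contingency(toy, 60, n_per_class = c(5, 5),
                                        repeats = 1)
  m2 <- merge_class_report(toy_rep, c(a = "ab", b = "ab"))
  expect_equal(unname(m2$per_class), 100)
  expect_equal(m2$accuracy_mean, 100)

  expect_error(merge_class_report(rep_, c(HNSC = "x")), "cover all classes")
})

test_that("the final model memorizes separable training data and is deterministic", {
  sep <- separable_matrix(n_per_class = 4)
  cfg <- svm_config(outer_folds = 2L, outer_repeats = 1L, seed = 21,
                    C_grid = c(1, 100), sigma_grid = c(1e-3, 1e-1))
  m1 <- train_final(sep$x, sep$y, cfg)
  m2 <- train_final(sep$x, sep$y, cfg)
  expect_equal(m1$C, m2$C)
  expect_equal(m1$sigma, m2$sigma)
  preds <- predict_cohort(m1, sep$x)
  expect_equal(preds$predicted, sep$y)
  expect_gte(100 * mean(preds$predicted == sep$y), m1$cv_accuracy)
})

test_that("cohort prediction yields proper probability vectors and guards features", {
  sep <- separable_matrix(n_per_class = 4)
  cfg <- svm_config(outer_folds = 2L, outer_repeats = 1L, seed = 2,
                    C_grid = 100, sigma_grid = 0.01)
  model <- train_final(sep$x, sep$y, cfg)
  preds <- predict_cohort(model, sep$x)
  pcols <- grep("^prob\\.", names(preds))
  expect_equal(unname(rowSums(preds[, pcols])), rep(1, nrow(preds)),
               tolerance = 1e-9)
  expect_setequal(sub("^prob\\.", "", names(preds)[pcols]), unique(sep$y))

  x_bad <- sep$x[, -1]
  expect_error(predict_cohort(model, x_bad), "feature mismatch")
  x_extra <- cbind(sep$x, EXTRA = 1)
  expect_error(predict_cohort(model, x_extra), "feature mismatch")

  # missing entries are imputed by the frozen policy, not rejected
  x_na <- sep$x
  x_na[1, 1] <- NA
  expect_silent(predict_cohort(model, x_na))
})

test_that("correct-class probability comparison by grade matches a pooled t-test", {
  rec <- data.frame(sample_id = sprintf("V%02d", 1:8),
                    predicted = "A", true_type = "A",
                    grade = rep(c("G2", "G3"), each = 4),
                    prob.A = c(0.8, 0.7, 0.75, 0.85, 0.5, 0.45, 0.6, 0.4),
                    prob.B = 0)
  out <- probability_by_grade(rec)
  expect_equal(unname(out$means["G2"]), mean(c(0.8, 0.7, 0.75, 0.85)))
  a <- rec$prob.A[1:4]; b <- rec$prob.A[5:8]
  expect_equal(out$p, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  # identical distributions: p = 1
  rec2 <- rec
  rec2$prob.A <- rep(c(0.6, 0.7), 4)
  expect_equal(probability_by_grade(rec2)$p, 1, tolerance = 1e-12)

  # degenerate zero-variance case: p defined as 1
  rec3 <- rec
  rec3$prob.A <- 1
  expect_equal(probability_by_grade(rec3)$p, 1)

  # too small a group: p missing
  out4 <- probability_by_grade(rec[c(1, 5:8), ])
  expect_true(is.na(out4$p))
  expect_error(probability_by_grade(rec[, -3]), "true_type")
})
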