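#' Radial-basis-function kernel
#'
#' `exp(-sigma * ||x - y||^2)` — the convention in which `sigma` multiplies
#' the squared Euclidean distance, so small bandwidth parameters
#' (e.g. 1e-4) correspond to wide kernels over high-dimensional profiles.
#' This matches libsvm's `gamma`, the engine used for fitting.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param sigma bandwidth, > 0.
#' @return similarity in (0, 1].
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (length(x) != length(y))
    stopf("dimension mismatch: %d vs %d", length(x), length(y))
  assert_number(sigma, "sigma", lower = .Machine$double.xmin)
  exp(-sigma * sum((x - y)^2))
}

#' SVM tuning and cross-validation configuration
#'
#' Defaults follow the study design this pipeline reproduces: cost grid
#' `10^(0:3)`, bandwidth grid `0.01 * 10^(-3:3)`, five outer folds repeated
#' ten times, four inner folds repeated five times.
#'
#' @param C_grid cost grid.
#' @param sigma_grid RBF bandwidth grid.
#' @param outer_folds,outer_repeats outer cross-validation design.
#' @param inner_folds,inner_repeats inner (tuning) design.
#' @param seed integer seed for fold shuffling.
#' @param scale standardize features using training-fitted statistics.
#' @param impute_value log2 value imputed for missing signals; `NULL` means
#'   "training minimum minus 1", computed on the training portion only.
#' @return list of class `dw_svm_config`.
#' @export
svm_config <- function(C_grid = 10^(0:3),
                       sigma_grid = 0.01 * 10^(-3:3),
                       outer_folds = 5L, outer_repeats = 10L,
                       inner_folds = 4L, inner_repeats = 5L,
                       seed = 1L, scale = TRUE, impute_value = NULL) {
  if (length(C_grid) < 1L || any(C_grid <= 0)) stopf("C_grid must be positive")
  if (length(sigma_grid) < 1L || any(sigma_grid <= 0))
    stopf("sigma_grid must be positive")
  if (outer_folds < 2L || inner_folds < 2L) stopf("folds must be >= 2")
  structure(list(C_grid = sort(C_grid), sigma_grid = sort(sigma_grid),
                 outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_folds = as.integer(inner_folds),
                 inner_repeats = as.integer(inner_repeats),
                 seed = as.integer(seed), scale = isTRUE(scale),
                 impute_value = impute_value),
            class = "dw_svm_config")
}

# stratified fold assignment: within each class, shuffled round-robin
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(sample(seq_len(k)), length.out = length(idx))
    }
  })
  fold
}

fit_preprocess <- function(x, scale = TRUE, impute_value = NULL) {
  if (is.null(impute_value)) {
    mn <- suppressWarnings(min(x, na.rm = TRUE))
    impute_value <- if (is.finite(mn)) mn - 1 else 0
  }
  xi <- x
  xi[is.na(xi)] <- impute_value
  ctr <- if (scale) colMeans(xi) else rep(0, ncol(x))
  scl <- if (scale) apply(xi, 2, stats::sd) else rep(1, ncol(x))
  scl[!is.finite(scl) | scl == 0] <- 1
  list(impute_value = impute_value, center = ctr, scale = scl,
       features = colnames(x))
}

apply_preprocess <- function(x, prep) {
  x[is.na(x)] <- prep$impute_value
  sweep(sweep(x, 2, prep$center, "-"), 2, prep$scale, "/")
}

fit_svm <- function(x, y, C, sigma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = sigma, cost = C, scale = FALSE)
}

# Platt sigmoid P(class i | i or j) = 1 / (1 + exp(A * f + B)) fitted by
# regularized maximum likelihood on training decision values; deterministic
# (no internal cross-validation), with Platt's soft targets guarding the
# perfectly separated case.
fit_platt <- function(f, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  t <- ifelse(is_pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(ab) {
    fApB <- ab[1] * f + ab[2]
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  init <- c(A = 0, B = log((n_neg + 1) / (n_pos + 1)))
  stats::optim(init, nll, method = "BFGS")$par
}

platt_prob <- function(f, ab) {
  fApB <- ab[1] * f + ab[2]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# pairwise coupling of binary class probabilities into a multiclass vector
# (Wu, Lin & Weng's second method, the one libsvm uses)
couple_probabilities <- function(r, max_iter = 200, eps = 1e-12) {
  k <- nrow(r)
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
  }
  p <- rep(1 / k, k)
  for (iter in seq_len(max_iter)) {
    Qp <- as.vector(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

# decision-value matrix with libsvm's "i/j" pair columns
decision_values <- function(model, x) {
  attr(predict(model, x, decision.values = TRUE), "decision.values")
}

fit_pairwise_calibration <- function(model, x, y) {
  dv <- decision_values(model, x)
  calib <- list()
  for (pair in colnames(dv)) {
    cls <- strsplit(pair, "/", fixed = TRUE)[[1]]
    sel <- y %in% cls
    calib[[pair]] <- fit_platt(dv[sel, pair], y[sel] == cls[1])
  }
  calib
}

predict_probabilities <- function(model, calib, levels, x) {
  dv <- decision_values(model, x)
  k <- length(levels)
  probs <- matrix(0, nrow(x), k, dimnames = list(rownames(x), levels))
  for (s in seq_len(nrow(x))) {
    r <- matrix(0.5, k, k)
    for (pair in colnames(dv)) {
      cls <- strsplit(pair, "/", fixed = TRUE)[[1]]
      i <- match(cls[1], levels)
      j <- match(cls[2], levels)
      pij <- min(max(platt_prob(dv[s, pair], calib[[pair]]), 1e-7), 1 - 1e-7)
      r[i, j] <- pij
      r[j, i] <- 1 - pij
    }
    probs[s, ] <- couple_probabilities(r)
  }
  probs
}

#' Grid-search hyperparameters by repeated stratified cross-validation
#'
#' Evaluates every (C, sigma) pair of the grids by `inner_folds`-fold
#' cross-validation repeated `inner_repeats` times; imputation and
#' standardization are fitted inside each training split only. Score is the
#' mean accuracy over repeats; ties go to the smallest C, then the smallest
#' sigma.
#'
#' @param x samples x features numeric matrix (NAs allowed).
#' @param y class labels (factor or character), at least two classes.
#' @param config a `dw_svm_config`.
#' @param seed fold-shuffling seed (defaults to `config$seed`).
#' @param instrument optional environment; when supplied, the row indices
#'   this call touches (`indices`) are appended to `instrument$log` for
#'   leakage auditing.
#' @param indices global row indices of `x` (for the audit log only).
#' @return list: `C`, `sigma`, `accuracy` (selected mean inner accuracy, %),
#'   `grid` (per-combination accuracies).
#' @export
tune_svm <- function(x, y, config = svm_config(), seed = config$seed,
                     instrument = NULL, indices = seq_len(nrow(x))) {
  y <- factor(y)
  if (nlevels(y) < 2L) stopf("training data contains a single class")
  if (!is.null(instrument))
    instrument$log <- c(instrument$log,
                        list(list(what = "tune", indices = indices)))
  grid <- expand.grid(sigma = config$sigma_grid, C = config$C_grid)
  correct <- rep(0, nrow(grid))
  total <- 0L
  for (rep_i in seq_len(config$inner_repeats)) {
    fold <- make_folds(y, config$inner_folds,
                       substream_seed(seed, "inner", rep_i))
    for (f in seq_len(config$inner_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2L || sum(!tr) == 0L) next
      prep <- fit_preprocess(x[tr, , drop = FALSE], config$scale,
                             config$impute_value)
      xtr <- apply_preprocess(x[tr, , drop = FALSE], prep)
      xva <- apply_preprocess(x[!tr, , drop = FALSE], prep)
      ytr <- droplevels(y[tr])
      for (g in seq_len(nrow(grid))) {
        m <- fit_svm(xtr, ytr, grid$C[g], grid$sigma[g])
        pred <- predict(m, xva)
        correct[g] <- correct[g] + sum(as.character(pred) ==
                                         as.character(y[!tr]))
      }
      total <- total + sum(!tr)
    }
  }
  acc <- 100 * correct / total
  best <- which.max(acc)  # grid ordered C slow, sigma fast -> smallest C wins
  list(C = grid$C[best], sigma = grid$sigma[best], accuracy = acc[best],
       grid = cbind(grid, accuracy = acc))
}

#' Repeated nested cross-validation of the RBF-SVM classifier
#'
#' For each outer repeat: a stratified `outer_folds`-fold partition; per
#' fold, hyperparameters are tuned on the outer-training portion only
#' (inner cross-validation per `config`), the model is refit on that portion
#' and predicts the held-out fold. Contingency matrices are accumulated per
#' repeat and averaged, so each cell reports how many samples of a true
#' class land in each predicted class on average per repeat; overall
#' accuracy is reported as mean and standard deviation across the outer
#' repeats.
#'
#' @param x samples x features matrix (NAs allowed).
#' @param y class labels.
#' @param config a `dw_svm_config`.
#' @param instrument optional environment for the leakage audit log; each
#'   tuning/fitting event records the held-out and touched row indices.
#' @return list of class `dw_contingency`: `matrix` (true x predicted, mean
#'   samples per repeat), `accuracy_mean`, `accuracy_sd` (percent),
#'   `per_class` (percent), `n_per_class`, `repeats`.
#' @export
nested_cv <- function(x, y, config = svm_config(), instrument = NULL) {
  y <- factor(y)
  lv <- levels(y)
  if (nrow(x) < config$outer_folds) stopf("fewer samples than outer folds")
  if (any(table(y) < config$outer_folds))
    warnf("some classes have fewer samples than outer folds; folds will hold at most one such sample")
  cmat <- matrix(0, nlevels(y), nlevels(y), dimnames = list(lv, lv))
  accs <- numeric(config$outer_repeats)
  for (rep_i in seq_len(config$outer_repeats)) {
    fold <- make_folds(y, config$outer_folds,
                       substream_seed(config$seed, "outer", rep_i))
    pred <- character(length(y))
    for (f in seq_len(config$outer_folds)) {
      tr_idx <- which(fold != f)
      va_idx <- which(fold == f)
      if (length(va_idx) == 0L) next
      tuned <- tune_svm(x[tr_idx, , drop = FALSE], y[tr_idx], config,
                        seed = substream_seed(config$seed, "tune", rep_i, f),
                        instrument = instrument, indices = tr_idx)
      if (!is.null(instrument))
        instrument$log <- c(instrument$log,
                            list(list(what = "outer_fit", repeat_i = rep_i,
                                      fold = f, indices = tr_idx,
                                      held_out = va_idx)))
      prep <- fit_preprocess(x[tr_idx, , drop = FALSE], config$scale,
                             config$impute_value)
      m <- fit_svm(apply_preprocess(x[tr_idx, , drop = FALSE], prep),
                   droplevels(y[tr_idx]), tuned$C, tuned$sigma)
      pred[va_idx] <- as.character(
        predict(m, apply_preprocess(x[va_idx, , drop = FALSE], prep)))
    }
    cmat <- cmat + table(factor(as.character(y), lv), factor(pred, lv))
    accs[rep_i] <- 100 * mean(pred == as.character(y))
  }
  new_contingency(cmat / config$outer_repeats, accs,
                  n_per_class = table(y), repeats = config$outer_repeats)
}

new_contingency <- function(mat, accs, n_per_class, repeats) {
  n_per_class <- as.numeric(n_per_class)[seq_len(nrow(mat))]
  if (is.null(names(n_per_class)) || all(names(n_per_class) == ""))
    names(n_per_class) <- rownames(mat)
  structure(list(
    matrix = mat,
    accuracy_mean = mean(accs),
    accuracy_sd = stats::sd(accs),
    accuracy_per_repeat = accs,
    per_class = 100 * diag(mat) / rowSums(mat),
    n_per_class = n_per_class,
    repeats = repeats), class = "dw_contingency")
}

#' @export
print.dw_contingency <- function(x, ...) {
  cat(sprintf("<dw_contingency> overall accuracy %.1f%% (sd %.1f%%) over %d repeats\n",
              x$accuracy_mean, x$accuracy_sd, x$repeats))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Re-score a contingency report after merging classes
#'
#' Sums rows and columns of the averaged contingency matrix by superclass
#' (e.g. treating squamous and adenocarcinoma of the lung as one lung class)
#' and recomputes per-class accuracies and the sample-weighted overall
#' accuracy. Misclassifications between members of one superclass become
#' correct calls, so merging can only raise the overall accuracy when all
#' affected cells lie within merged groups.
#'
#' @param report a `dw_contingency`.
#' @param merge named character vector mapping every class of the report to
#'   its superclass (identity entries allowed).
#' @return a `dw_contingency` over the superclasses. Repeat-wise accuracies
#'   are not carried over (set to the merged overall accuracy), since
#'   per-repeat matrices are not retained.
#' @export
merge_class_report <- function(report, merge) {
  classes <- rownames(report$matrix)
  if (!all(classes %in% names(merge)))
    stopf("merge map must cover all classes; missing: %s",
          paste(setdiff(classes, names(merge)), collapse = ", "))
  sup <- merge[classes]
  lv <- unique(unname(sup))
  agg <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in classes) for (j in classes)
    agg[sup[i], sup[j]] <- agg[sup[i], sup[j]] + report$matrix[i, j]
  overall <- 100 * sum(diag(agg)) / sum(agg)
  n_per <- tapply(as.numeric(report$n_per_class),
                  sup[names(report$n_per_class)], sum)[lv]
  new_contingency(agg, overall, n_per_class = n_per, repeats = report$repeats)
}

#' Train the final classifier on a full training set
#'
#' Hyperparameters are selected by cross-validation on the whole training
#' set (five folds, ten repeats by default, same grid), the model is then
#' refit on every training sample with pairwise-coupled Platt probability
#' calibration, and the preprocessing statistics are frozen from the
#' training data.
#'
#' @param x samples x features matrix (NAs allowed).
#' @param y class labels.
#' @param config a `dw_svm_config`; its `outer_folds`/`outer_repeats` define
#'   the selection cross-validation here.
#' @return list of class `dw_svm_model`: `model`, `prep`, `C`, `sigma`,
#'   `cv_accuracy` (%), `levels`, `features`.
#' @export
train_final <- function(x, y, config = svm_config()) {
  y <- factor(y)
  sel_cfg <- config
  sel_cfg$inner_folds <- config$outer_folds
  sel_cfg$inner_repeats <- config$outer_repeats
  tuned <- tune_svm(x, y, sel_cfg, seed = substream_seed(config$seed, "final"))
  prep <- fit_preprocess(x, config$scale, config$impute_value)
  xp <- apply_preprocess(x, prep)
  m <- fit_svm(xp, y, tuned$C, tuned$sigma)
  calib <- fit_pairwise_calibration(m, xp, as.character(y))
  structure(list(model = m, calibration = calib,
                 prep = prep, C = tuned$C, sigma = tuned$sigma,
                 cv_accuracy = tuned$accuracy, levels = levels(y),
                 features = colnames(x), config = config),
            class = "dw_svm_model")
}

#' @export
print.dw_svm_model <- function(x, ...) {
  cat(sprintf("<dw_svm_model> C = %g, sigma = %g, %d features, %d classes (CV accuracy %.1f%%)\n",
              x$C, x$sigma, length(x$features), length(x$levels),
              x$cv_accuracy))
  invisible(x)
}

#' Predict a cohort with class probabilities
#'
#' Applies the frozen training preprocessing (imputation, standardization)
#' and returns the argmax class plus the pairwise-coupled per-class
#' probability vector for every sample.
#'
#' @param model a `dw_svm_model`.
#' @param x samples x features matrix with exactly the training features
#'   (NAs allowed), or a `dw_signal_matrix` (signals x samples, transposed
#'   internally).
#' @param metadata optional sample metadata; `tumor_type` and `grade` are
#'   joined in when present.
#' @return data.frame: `sample_id`, `predicted`, one `prob.<class>` column
#'   per class, and `true_type`/`grade` when metadata is given.
#' @export
predict_cohort <- function(model, x, metadata = NULL) {
  if (inherits(x, "dw_signal_matrix")) x <- t(x$values)
  missing_feat <- setdiff(model$features, colnames(x))
  extra_feat <- setdiff(colnames(x), model$features)
  if (length(missing_feat) || length(extra_feat))
    stopf("feature mismatch with the training panel (missing: %s; unseen: %s)",
          paste(utils::head(missing_feat, 3), collapse = ", "),
          paste(utils::head(extra_feat, 3), collapse = ", "))
  x <- x[, model$features, drop = FALSE]
  xp <- apply_preprocess(x, model$prep)
  # class labels come from the SVM vote; the coupled Platt probabilities are
  # reported alongside (their argmax can differ when the calibration data
  # held few or no within-class errors)
  lab <- predict(model$model, xp)
  probs <- predict_probabilities(model$model, model$calibration,
                                 model$levels, xp)
  stopifnot(max(abs(rowSums(probs) - 1)) < 1e-6)
  out <- data.frame(sample_id = rownames(x), predicted = as.character(lab))
  colnames(probs) <- paste0("prob.", colnames(probs))
  out <- cbind(out, probs)
  if (!is.null(metadata)) {
    i <- match(out$sample_id, metadata$sample_id)
    out$true_type <- metadata$tumor_type[i]
    out$grade <- metadata$grade[i]
  }
  rownames(out) <- NULL
  out
}

#' Compare correct-class probability between histological grades
#'
#' Computes the mean probability assigned to the true class per grade group
#' and a pooled-sd two-sided t-test between two grade groups (moderately,
#' G2, vs poorly, G3, differentiated by default). When both groups are
#' constant the p-value is defined as 1.
#'
#' @param records output of [predict_cohort()] with `true_type` and `grade`.
#' @param group_a,group_b grade labels to compare.
#' @return list: `means` (named per-group), `n`, `p`.
#' @export
probability_by_grade <- function(records, group_a = "G2", group_b = "G3") {
  if (is.null(records$true_type) || is.null(records$grade))
    stopf("records must carry true_type and grade")
  pc <- vapply(seq_len(nrow(records)), function(i) {
    col <- paste0("prob.", records$true_type[i])
    if (!col %in% names(records)) return(NA_real_)
    records[[col]][i]
  }, 1)
  a <- pc[records$grade == group_a & !is.na(pc)]
  b <- pc[records$grade == group_b & !is.na(pc)]
  means <- stats::setNames(c(mean(a), mean(b)), c(group_a, group_b))
  p <- NA_real_
  if (length(a) >= 2L && length(b) >= 2L) {
    p <- if (stats::sd(c(a - mean(a), b - mean(b))) == 0) 1
         else stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  list(means = means, n = c(length(a), length(b)), p = p)
}
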