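#' RBF-SVM hyperparameters
#'
#' The classifier is a C-support vector machine with a radial basis function
#' kernel at the canonical libsvm defaults: cost C = 1 and gamma = 1 /
#' (number of features). Features are z-scored with training-set statistics
#' by default; nodal degrees range over 0..C-1 and the RBF kernel is
#' scale-sensitive, so standardization is on unless a literal unscaled run is
#' wanted (`standardize = FALSE`).
#'
#' @param cost Positive misclassification cost (default 1).
#' @param gamma RBF width, or `NULL` for 1 / feature count (default).
#' @param standardize Z-score features with training-fold statistics
#'   (default TRUE).
#' @return An `svm_params` list.
#' @export
svm_params <- function(cost = 1, gamma = NULL, standardize = TRUE) {
  if (cost <= 0) abort("`cost` must be positive.")
  if (!is.null(gamma) && gamma <= 0) abort("`gamma` must be positive.")
  structure(list(cost = cost, gamma = gamma, standardize = standardize),
            class = "svm_params")
}

#' Train an RBF-SVM on a labelled feature matrix
#'
#' @param x Numeric subjects x features matrix (training rows only).
#' @param y Integer labels, +1 = patient, -1 = control; both classes must be
#'   present.
#' @param params An [svm_params()] object.
#' @return An `fnirs_svm` model (libsvm fit plus the training-fold
#'   standardization statistics).
#' @export
train_svm <- function(x, y, params = svm_params()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) abort("Label length must match row count.")
  if (length(unique(y)) < 2) {
    abort("Training set contains a single class; cannot fit an SVM.")
  }
  if (!all(y %in% c(1L, -1L))) abort("Labels must be +1 or -1.")
  center <- if (params$standardize) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (params$standardize) apply(x, 2, sd) else rep(1, ncol(x))
  scale_[scale_ == 0] <- 1 # constant feature: centre only
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fit <- e1071::svm(
    x = xs, y = factor(y, levels = c(1L, -1L)),
    kernel = "radial",
    cost = params$cost,
    gamma = params$gamma %||% (1 / ncol(x)),
    scale = FALSE
  )
  structure(
    list(fit = fit, center = center, scale = scale_, n_features = ncol(x),
         params = params),
    class = "fnirs_svm"
  )
}

#' Predict class labels with a trained RBF-SVM
#'
#' Decision values are oriented so that positive means the patient class;
#' a decision value of exactly zero is assigned to +1 (deterministic
#' tie-break).
#'
#' @param object An `fnirs_svm` model.
#' @param newdata Numeric matrix with the same feature count as training.
#' @param ... Unused.
#' @return Integer vector of +1/-1 labels with attribute
#'   `"decision_values"`.
#' @export
predict.fnirs_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(structure(integer(0), decision_values = numeric(0)))
  }
  if (ncol(newdata) != object$n_features) {
    abort(sprintf("Feature dimension mismatch: model has %d, data has %d.",
                  object$n_features, ncol(newdata)))
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  pred <- predict(object$fit, xs, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # e1071 orients the decision value toward the first factor level (+1)
  if (!identical(colnames(attr(pred, "decision.values")), "1/-1")) {
    dv <- -dv
  }
  structure(ifelse(dv >= 0, 1L, -1L), decision_values = as.numeric(dv))
}

#' Confusion counts of a binary prediction
#'
#' Patients (+1) are the positive class: TP / FN count patients predicted
#' correctly / incorrectly, TN / FP count controls.
#'
#' @param truth,predicted Integer vectors of +1/-1 labels.
#' @return Named integer vector `c(TP, FN, FP, TN)`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(TP = sum(truth == 1L & predicted == 1L),
    FN = sum(truth == 1L & predicted == -1L),
    FP = sum(truth == -1L & predicted == 1L),
    TN = sum(truth == -1L & predicted == -1L))
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' ACC = (TP + TN) / (TP + FP + TN + FN) is the overall accuracy, SS =
#' TP / (TP + FN) the sensitivity (patient recall) and TNR = TN / (TN + FP)
#' the specificity (control recall). Values are proportions in \[0, 1\];
#' the print method shows percentages to one decimal.
#'
#' @param confusion Named vector or list with elements TP, FN, FP, TN.
#' @return A tibble of class `fnirs_performance` with columns `accuracy`,
#'   `sensitivity`, `specificity`, `TP`, `FN`, `FP`, `TN`.
#' @export
#' @examples
#' performance_metrics(c(TP = 39, FN = 3, FP = 8, TN = 26))
performance_metrics <- function(confusion) {
  cm <- unlist(confusion)[c("TP", "FN", "FP", "TN")]
  if (anyNA(cm) || any(cm < 0)) {
    abort("Confusion needs nonnegative counts TP, FN, FP, TN.")
  }
  if (cm[["TP"]] + cm[["FN"]] == 0) {
    abort("Sensitivity undefined: no positive-class (patient) subjects.")
  }
  if (cm[["TN"]] + cm[["FP"]] == 0) {
    abort("Specificity undefined: no negative-class (control) subjects.")
  }
  out <- tibble::tibble(
    accuracy = (cm[["TP"]] + cm[["TN"]]) / sum(cm),
    sensitivity = cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
    specificity = cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]),
    TP = cm[["TP"]], FN = cm[["FN"]], FP = cm[["FP"]], TN = cm[["TN"]]
  )
  class(out) <- c("fnirs_performance", class(out))
  out
}

#' @export
print.fnirs_performance <- function(x, ...) {
  cat(sprintf(
    "<fnirs_performance> ACC %.1f%% | sensitivity %.1f%% | specificity %.1f%% (TP %d, FN %d, FP %d, TN %d)\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    x$TP, x$FN, x$FP, x$TN
  ))
  invisible(x)
}

new_loocv_result <- function(folds, confusion, selection) {
  perf <- performance_metrics(confusion)
  structure(
    list(
      folds = folds,
      confusion = confusion,
      accuracy = perf$accuracy,
      sensitivity = perf$sensitivity,
      specificity = perf$specificity,
      selection = selection
    ),
    class = "fnirs_loocv"
  )
}

#' Leave-one-out cross-validated SVM classification
#'
#' Each of the n subjects serves once as the test sample while the remaining
#' n - 1 train the SVM, for n rounds in total. Two selection modes control
#' where the (metric, sparsity) feature choice comes from:
#'
#' * `"fixed"` — classify the supplied `features` slice as-is (used both for
#'   a forced choice such as degree at sparsity 0.21, and for a
#'   whole-sample pre-selection, in which case the selection leaks test
#'   labels into the choice — statistically optimistic, but an explicitly
#'   available mode).
#' * `"fold"` — rerun [group_difference_scan()] on the training subjects of
#'   every fold and classify the slice that fold chose (leakage-free
#'   default for pipelines).
#'
#' @param features An `fnirs_features` slice (required for
#'   `selection = "fixed"`).
#' @param params [svm_params()].
#' @param selection `"fixed"` or `"fold"`.
#' @param tensor An `fnirs_tensor`; required when `selection = "fold"`.
#' @param alpha Scan significance level for fold-wise selection.
#' @return An `fnirs_loocv` object: per-fold predictions (`$folds` tibble),
#'   confusion counts, `accuracy`, `sensitivity`, `specificity` and a
#'   `selection` record. `tidy()` returns the folds, `glance()` the
#'   one-row performance summary.
#' @export
loocv_svm <- function(features = NULL, params = svm_params(),
                      selection = c("fixed", "fold"), tensor = NULL,
                      alpha = 0.05) {
  selection <- match.arg(selection)
  if (selection == "fold") {
    if (is.null(tensor)) abort("Fold-wise selection needs the feature tensor.")
    tm <- tensor_matrix(tensor)
    subjects <- tm$subjects
  } else {
    if (is.null(features)) abort("Fixed selection needs a feature slice.")
    subjects <- tibble::tibble(subject_id = features$subject_id,
                               group = features_labels(features))
    x_all <- features_matrix(features)
  }
  n <- nrow(subjects)
  if (n < 3) abort("LOOCV needs at least 3 subjects.")
  if (length(unique(subjects$group)) < 2) {
    abort("Both classes must be present for LOOCV.")
  }
  folds <- purrr::map_dfr(seq_len(n), function(i) {
    train_groups <- subjects$group[-i]
    if (length(unique(train_groups)) < 2) {
      abort(sprintf(
        "Training set is single-class when subject %s is held out.",
        subjects$subject_id[i]
      ))
    }
    if (selection == "fold") {
      sub_tm <- list(
        x = tm$x[-i, , drop = FALSE], index = tm$index,
        subjects = subjects[-i, ]
      )
      scan <- scan_matrix(sub_tm, alpha, quiet = TRUE)
      keep <- tm$index$metric == scan$chosen_metric &
        abs(tm$index$sparsity - scan$chosen_sparsity) < 1e-9
      x_train <- tm$x[-i, keep, drop = FALSE]
      x_test <- tm$x[i, keep, drop = FALSE]
      sel_metric <- scan$chosen_metric
      sel_sparsity <- scan$chosen_sparsity
    } else {
      x_train <- x_all[-i, , drop = FALSE]
      x_test <- x_all[i, , drop = FALSE]
      sel_metric <- attr(features, "metric") %||% NA_character_
      sel_sparsity <- attr(features, "sparsity") %||% NA_real_
    }
    model <- train_svm(x_train, subjects$group[-i], params)
    pred <- predict(model, x_test)
    tibble::tibble(
      subject_id = subjects$subject_id[i],
      truth = subjects$group[i],
      predicted = as.integer(pred),
      decision_value = attr(pred, "decision_values"),
      chosen_metric = sel_metric,
      chosen_sparsity = sel_sparsity
    )
  })
  sel <- list(
    mode = selection,
    metric = if (selection == "fold") unique(folds$chosen_metric) else
      folds$chosen_metric[1],
    sparsity = if (selection == "fold") unique(folds$chosen_sparsity) else
      folds$chosen_sparsity[1]
  )
  new_loocv_result(folds, confusion_counts(folds$truth, folds$predicted), sel)
}

#' @export
print.fnirs_loocv <- function(x, ...) {
  cat(sprintf(
    "<fnirs_loocv> %d folds | ACC %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
    nrow(x$folds), 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity
  ))
  cat(sprintf("  confusion: TP %d, FN %d, FP %d, TN %d\n",
              x$confusion[["TP"]], x$confusion[["FN"]],
              x$confusion[["FP"]], x$confusion[["TN"]]))
  invisible(x)
}

#' @method tidy fnirs_loocv
#' @export
tidy.fnirs_loocv <- function(x, ...) x$folds

#' @method glance fnirs_loocv
#' @export
glance.fnirs_loocv <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$folds),
    accuracy = x$accuracy,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    TP = x$confusion[["TP"]], FN = x$confusion[["FN"]],
    FP = x$confusion[["FP"]], TN = x$confusion[["TN"]]
  )
}

#' @method autoplot fnirs_loocv
#' @export
autoplot.fnirs_loocv <- function(object, ...) {
  df <- object$folds
  df$truth_lab <- factor(ifelse(df$truth == 1, "patient", "control"))
  ggplot2::ggplot(df, ggplot2::aes(.data$truth_lab, .data$decision_value,
                                   colour = .data$predicted == .data$truth)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "SVM decision value", colour = "correct",
                  title = "Leave-one-out decision values")
}
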