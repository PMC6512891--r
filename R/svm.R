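#' One-vs-all linear SVM for multiclass affect prediction
#'
#' Trains one binary linear SVM (LIBSVM via \pkg{e1071}) per class against
#' the rest and stores each scorer as an explicit linear function
#' `score_k(x) = w_k' x_std + b_k` on the standardized feature space. A test
#' sample is assigned to the class whose scorer gives the highest response,
#' ties broken toward the lowest class index in the fixed class order.
#'
#' Classes absent from the training labels receive a constant most-negative
#' scorer (`w = 0`, `b = -1e6`) so leave-one-out folds that lose a rare class
#' remain well defined. If only one class is observed at all, the model is
#' flagged degenerate and always predicts that class.
#'
#' @param x Feature matrix, one row per patient.
#' @param y Labels; a factor fixes the class order, otherwise levels are taken
#'   in order of first appearance.
#' @param C Soft-margin cost of the linear SVM. Default 100: on standardized
#'   mid-level features the within-class spread is small relative to the
#'   class separation, and a near-hard margin keeps the low-dimensional
#'   one-vs-all scorers informative (C = 1 over-regularizes the
#'   one-dimensional motion descriptor). Exposed for tuning.
#' @param standardize Standardize features to zero mean / unit variance using
#'   training statistics only (zero-variance features get scale 1).
#'   Default `TRUE`; mixed-scale concatenations (e.g. motion with a transition
#'   count) are otherwise dominated by one component.
#' @return An object of class `ova_model` with elements `classes`, `W`
#'   (classes x features weight matrix), `b`, `center`, `scale`, `C`,
#'   `degenerate`.
#' @export
train_ova <- function(x, y, C = 100, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y, levels = unique(as.character(y)))
  if (nrow(x) != length(y)) stop_input("x and y lengths differ")
  classes <- levels(y)
  observed <- unique(as.character(y))
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    scale <- ifelse(is.na(s) | s < 1e-12, 1, s)
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  W <- matrix(0, length(classes), ncol(x),
              dimnames = list(classes, colnames(x)))
  b <- stats::setNames(rep(-1e6, length(classes)), classes)
  degenerate <- length(observed) < 2L
  if (degenerate) {
    b[observed] <- 0  # constant scorer; the single class always wins
  } else {
    for (cl in classes) {
      if (!(cl %in% observed)) next
      ybin <- factor(ifelse(as.character(y) == cl, "pos", "neg"),
                     levels = c("pos", "neg"))
      fit <- e1071::svm(xs, ybin, kernel = "linear", cost = C, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      bias <- -fit$rho
      # libsvm orients decision values toward the first label seen in the
      # data; flip when that label is "neg"
      if (fit$labels[1] != 1L) { w <- -w; bias <- -bias }
      W[cl, ] <- w
      b[cl] <- bias
    }
  }
  structure(list(classes = classes, W = W, b = b, center = center,
                 scale = scale, C = C, standardize = standardize,
                 degenerate = degenerate,
                 degenerate_class = if (degenerate) observed else NULL),
            class = "ova_model")
}

#' @rdname train_ova
#' @param model An `ova_model`.
#' @return `ova_scores()` returns the matrix of per-class linear responses
#'   (one row per sample).
#' @export
ova_scores <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$W))
    stop_input("feature length ", ncol(x), " does not match model (",
               ncol(model$W), ")")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- xs %*% t(model$W)
  sweep(scores, 2, model$b, "+")
}

#' @rdname train_ova
#' @return `predict_ova()` returns the predicted label(s) as a factor over the
#'   model's class order.
#' @export
predict_ova <- function(model, x) {
  s <- ova_scores(model, x)
  idx <- apply(s, 1, which_max_first)
  factor(model$classes[idx], levels = model$classes)
}

# leave-one-out folds: fold i trains on everything except sample i
loo_folds <- function(n) {
  lapply(seq_len(n), function(i) list(train = setdiff(seq_len(n), i), test = i))
}

#' Leave-one-out evaluation of one rater's affect labels
#'
#' Each patient provides the test sample once; the one-vs-all SVM is trained
#' on all other patients and predicts the held-out label. Reports accuracy,
#' the most-common-label baseline, and the improvement coefficient
#' (accuracy / baseline).
#'
#' @inheritParams train_ova
#' @param rater_id,domain,feature_kind Optional provenance recorded in the
#'   report.
#' @return An object of class `loo_report`: list with `accuracy`, `baseline`,
#'   `improvement`, `n`, `predictions` (data.frame of true and predicted
#'   labels per patient), `degenerate` (TRUE when any fold, or the full label
#'   set, had a single class).
#' @export
loo_evaluate <- function(x, y, C = 100, standardize = TRUE,
                         rater_id = NA_character_, domain = NA_character_,
                         feature_kind = NA_character_) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y, levels = unique(as.character(y)))
  n <- nrow(x)
  if (n < 3L) stop_input("leave-one-out needs at least 3 patients")
  if (length(y) != n) stop_input("x and y lengths differ")
  preds <- character(n)
  degenerate <- FALSE
  for (fold in loo_folds(n)) {
    m <- train_ova(x[fold$train, , drop = FALSE], droplevels(y[fold$train]),
                   C = C, standardize = standardize)
    if (m$degenerate) degenerate <- TRUE
    preds[fold$test] <- as.character(predict_ova(m, x[fold$test, , drop = FALSE]))
  }
  accuracy <- mean(preds == as.character(y))
  tab <- table(y)
  baseline <- max(tab) / n
  structure(list(
    rater_id = rater_id, domain = domain, feature_kind = feature_kind,
    accuracy = accuracy, baseline = baseline,
    improvement = improvement_coefficient(accuracy, tab),
    n = n, degenerate = degenerate,
    predictions = data.frame(index = seq_len(n), true = as.character(y),
                             predicted = preds, stringsAsFactors = FALSE)
  ), class = "loo_report")
}

#' Improvement over the most-common-label baseline
#'
#' The ratio between an obtained accuracy and the accuracy of always guessing
#' the rater's most common label; both arguments must share a scale (fractions
#' or percents).
#'
#' @param accuracy Obtained accuracy.
#' @param distribution Label frequencies (counts, fractions or percents); only
#'   the maximum relative frequency is used.
#' @return The ratio `accuracy / max frequency`.
#' @export
improvement_coefficient <- function(accuracy, distribution) {
  if (length(distribution) == 0) stop_input("empty label distribution")
  distribution <- as.numeric(distribution)
  top <- max(distribution)
  if (!(top > 0)) stop_input("most common label has zero frequency")
  # raw counts are normalized to fractions; fractions (sum ~ 1) and percents
  # (sum ~ 100, possibly off by table rounding) are used as given
  s <- sum(distribution)
  if (s > 1.5 && abs(s - 100) > 0.5) top <- top / s
  accuracy / top
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("Leave-one-out report (%s / %s / %s): accuracy %.3f, baseline %.3f, improvement %.2f%s\n",
              x$rater_id, x$domain, x$feature_kind, x$accuracy, x$baseline,
              x$improvement, if (x$degenerate) " [degenerate folds]" else ""))
  invisible(x)
}
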