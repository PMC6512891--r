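#' Train the 7-class facial-expression scorer
#'
#' Fits seven one-vs-all linear scorers (norm, anger, disgust, fear,
#' happiness, sadness, surprise), each mapping a per-frame cell-intensity
#' vector to a real score. Classes absent from the training labels get a
#' constant most-negative scorer.
#'
#' @param x Matrix of per-frame cell-intensity vectors (one row per frame).
#' @param labels Expression labels; must contain at least 2 distinct classes
#'   drawn from [expression_classes()].
#' @param C Linear SVM cost. Default 100 (see [train_ova()]).
#' @param seed Stored as training metadata (the fit itself is deterministic).
#' @return An object of class `expression_model` wrapping an [train_ova()]
#'   model over the fixed 7-class order.
#' @export
train_expression_model <- function(x, labels, C = 100, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), expression_classes())
  if (length(bad))
    stop_input("unknown expression labels: ", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop_input("need at least 2 distinct expression classes to train")
  y <- factor(labels, levels = expression_classes())
  ova <- train_ova(x, y, C = C, standardize = TRUE)
  structure(list(ova = ova, n_cells = ncol(x), C = C, seed = seed),
            class = "expression_model")
}

#' @rdname train_expression_model
#' @param ts An `expression_trainingset` (see
#'   [generate_expression_trainingset()]).
#' @param grid Cell grid used to turn frames into cell-intensity vectors.
#' @return `trainingset_cell_features()` returns `list(x, labels)` ready for
#'   [train_expression_model()].
#' @export
trainingset_cell_features <- function(ts, grid = c(8, 8)) {
  x <- t(vapply(ts$frames, frame_cell_means, numeric(prod(grid)), grid = grid))
  list(x = x, labels = ts$labels)
}

#' @rdname train_expression_model
#' @param model An `expression_model`.
#' @return `expression_scores()` returns the 7 per-class scores (vector for a
#'   single frame vector, matrix for a stack of frames), in the fixed class
#'   order.
#' @export
expression_scores <- function(x, model) {
  s <- ova_scores(model$ova, x)
  if (nrow(s) == 1L) drop(s) else s
}

#' @rdname train_expression_model
#' @return `dominant_expression()` returns the argmax class per frame, ties
#'   broken toward the lowest class index (so an all-zero scorer yields
#'   "norm").
#' @export
dominant_expression <- function(x, model) {
  s <- ova_scores(model$ova, x)
  idx <- apply(s, 1, which_max_first)
  factor(expression_classes()[idx], levels = expression_classes())
}

# internal constructor for a per-video descriptor
midlevel_feature <- function(kind, values, patient_id = NA_character_,
                             part = "whole_face") {
  kind <- match.arg(kind, c("expression", "label", "motion",
                            "motion_label", "motion_expression"))
  expected <- c(expression = 7L, label = 1L, motion = 1L,
                motion_label = 2L, motion_expression = 8L)[kind]
  if (length(values) != expected)
    stop_input(kind, " feature must have length ", expected)
  structure(list(kind = kind, values = as.numeric(values),
                 patient_id = patient_id, part = part),
            class = "midlevel_feature")
}

#' Mid-level per-video features
#'
#' The three per-video descriptors used to summarize a face video, and their
#' two concatenations:
#' \describe{
#'   \item{expression}{the per-frame 7-class expression scores averaged
#'     arithmetically over frames (length 7);}
#'   \item{label}{the number of transitions of the dominating expression
#'     label along the video (length 1);}
#'   \item{motion}{the population standard deviation of the per-frame mean
#'     gray level over the selected cells (length 1);}
#'   \item{motion_label / motion_expression}{concatenations with motion
#'     first (lengths 2 and 8).}
#' }
#' All three are invariant to video length; `expression` is additionally
#' invariant to frame order while `label` is not.
#'
#' @param series A `cell_series` (see [cell_intensity_series()]).
#' @param model An `expression_model`.
#' @return A `midlevel_feature` of the corresponding kind.
#' @export
expression_feature <- function(series, model) {
  X <- series$X
  if (ncol(X) < 2L) stop_input("need at least 2 frames")
  s <- ova_scores(model$ova, t(X))
  midlevel_feature("expression", colMeans(s),
                   patient_id = series$patient_id, part = "whole_face")
}

#' @rdname expression_feature
#' @export
label_feature <- function(series, model) {
  X <- series$X
  if (ncol(X) < 2L) stop_input("need at least 2 frames")
  lab <- as.integer(dominant_expression(t(X), model))
  midlevel_feature("label", sum(diff(lab) != 0),
                   patient_id = series$patient_id, part = "whole_face")
}

#' @rdname expression_feature
#' @param cells 1-based cell indices (rows of `series$X`) to average over;
#'   `NULL` means the whole face.
#' @param part Provenance tag for the cell subset (a [face_regions()] name or
#'   `"whole_face"`).
#' @export
motion_feature <- function(series, cells = NULL, part = "whole_face") {
  X <- series$X
  if (ncol(X) < 2L) stop_input("need at least 2 frames")
  if (is.null(cells)) cells <- seq_len(nrow(X))
  if (length(cells) == 0L) stop_input("empty cell subset")
  m <- colMeans(X[cells, , drop = FALSE])
  midlevel_feature("motion", sd_pop(m),
                   patient_id = series$patient_id, part = part)
}

#' @rdname expression_feature
#' @param kind `"motion_label"` or `"motion_expression"`.
#' @param motion,other Constituent `midlevel_feature`s of kinds `motion` and
#'   `label`/`expression`, with matching provenance.
#' @export
combined_feature <- function(kind = c("motion_label", "motion_expression"),
                             motion, other) {
  kind <- match.arg(kind)
  if (!inherits(motion, "midlevel_feature") || motion$kind != "motion")
    stop_input("first constituent must be a motion feature")
  need <- if (kind == "motion_label") "label" else "expression"
  if (!inherits(other, "midlevel_feature") || other$kind != need)
    stop_input("second constituent must be a ", need, " feature")
  if (!identical(motion$patient_id, other$patient_id) ||
      !identical(motion$part, other$part))
    stop_input("constituent features have mismatched provenance")
  midlevel_feature(kind, c(motion$values, other$values),
                   patient_id = motion$patient_id, part = motion$part)
}

#' Per-patient feature matrix for one feature kind
#'
#' Convenience builder: computes one mid-level feature per patient and stacks
#' the values into a matrix (rows = patients).
#'
#' @param series_list Named list of `cell_series`, one per patient.
#' @param kind One of the five feature kinds.
#' @param model An `expression_model` (required for all kinds except
#'   `motion`).
#' @param cells Optional cell subset (motion-based kinds only).
#' @param part Provenance tag for `cells`.
#' @return Numeric matrix with one row per patient (rownames = patient ids).
#' @export
feature_matrix <- function(series_list,
                           kind = c("expression", "label", "motion",
                                    "motion_label", "motion_expression"),
                           model = NULL, cells = NULL, part = "whole_face") {
  kind <- match.arg(kind)
  one <- function(cs) {
    switch(kind,
      expression = expression_feature(cs, model)$values,
      label = label_feature(cs, model)$values,
      motion = motion_feature(cs, cells, part)$values,
      motion_label = combined_feature("motion_label",
        motion_feature(cs, cells, part),
        { f <- label_feature(cs, model); f$part <- part; f })$values,
      motion_expression = combined_feature("motion_expression",
        motion_feature(cs, cells, part),
        { f <- expression_feature(cs, model); f$part <- part; f })$values
    )
  }
  len <- c(expression = 7, label = 1, motion = 1,
           motion_label = 2, motion_expression = 8)[[kind]]
  out <- vapply(series_list, one, numeric(len))
  out <- if (len == 1L) matrix(out, ncol = 1) else t(out)
  rownames(out) <- names(series_list) %||%
    vapply(series_list, function(cs) cs$patient_id, character(1))
  colnames(out) <- switch(kind,
    expression = expression_classes(),
    label = "label_transitions",
    motion = "motion_sd",
    motion_label = c("motion_sd", "label_transitions"),
    motion_expression = c("motion_sd", expression_classes()))
  out
}
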