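# shared fixtures: desk-sized cohorts and hand-built linear models

tiny_config <- function(seed = 1, ...) {
  cohort_config(n_patients = 4, n_frames = 20, frame_size = 48, seed = seed,
                ...)
}

tiny_latent <- function(quality = "euthymic", range = "blunt",
                        subtype = "unknown") {
  list(quality = quality, range = range, subtype = subtype)
}

# an affect_effect with every oscillation amplitude forced to zero
zero_effect <- function() {
  eff <- default_affect_effect()
  eff$range <- c(full = 0, restricted = 0, blunt = 0, flat = 0)
  eff$nonsignal <- 0
  eff
}

# a hand-built OVA model: explicit weights/bias, no standardization
manual_ova <- function(W, b, classes = rownames(W)) {
  structure(list(classes = classes, W = W,
                 b = stats::setNames(b, classes),
                 center = rep(0, ncol(W)), scale = rep(1, ncol(W)),
                 C = NA_real_, standardize = FALSE, degenerate = FALSE,
                 degenerate_class = NULL),
            class = "ova_model")
}

# a hand-built expression model over all 7 classes
manual_expression_model <- function(W, b) {
  stopifnot(nrow(W) == 7)
  structure(list(ova = manual_ova(W, b, classes = expression_classes()),
                 n_cells = ncol(W), C = NA_real_, seed = NA_integer_),
            class = "expression_model")
}

# a cell_series built directly from an X matrix (cells x frames)
manual_series <- function(X, patient_id = "patient_001") {
  structure(list(X = X, grid = c(1, nrow(X)), out_size = c(1, nrow(X)),
                 cells = NULL, patient_id = patient_id),
            class = "cell_series")
}

# annotation table from a wide matrix (patients x raters) for one domain
annotations_from_matrix <- function(m, domain) {
  do.call(rbind, lapply(seq_len(ncol(m)), function(j) data.frame(
    patient_id = rownames(m) %||% sprintf("patient_%03d", seq_len(nrow(m))),
    rater_id = colnames(m)[j], domain = domain, label = m[, j],
    stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
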