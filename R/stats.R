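#' Pairwise inter-rater percent agreement
#'
#' For each pair of raters, the number of patients annotated identically
#' divided by the number of patients, times 100.
#'
#' @param table Annotation data.frame with columns `patient_id`, `rater_id`,
#'   `domain`, `label`.
#' @param domain One of [affect_domains()].
#' @return An `agreement_matrix`: symmetric rater-by-rater percent matrix with
#'   a 100 diagonal; attributes `domain` and `n_patients`.
#' @export
pairwise_agreement <- function(table, domain) {
  domain <- match.arg(domain, affect_domains())
  tb <- table[table$domain == domain, , drop = FALSE]
  raters <- sort(unique(table$rater_id))
  patients <- sort(unique(table$patient_id))
  key <- paste(tb$patient_id, tb$rater_id)
  need <- expand.grid(patient_id = patients, rater_id = raters,
                      stringsAsFactors = FALSE)
  missing <- !(paste(need$patient_id, need$rater_id) %in% key)
  if (any(missing)) {
    miss <- need[missing, , drop = FALSE]
    stop_input("missing ", domain, " annotations for: ",
               paste(paste0("(", miss$patient_id, ", ", miss$rater_id, ")"),
                     collapse = ", "))
  }
  wide <- matrix(tb$label[match(paste(rep(patients, length(raters)),
                                      rep(raters, each = length(patients))),
                                key)],
                 nrow = length(patients),
                 dimnames = list(patients, raters))
  M <- matrix(100, length(raters), length(raters),
              dimnames = list(raters, raters))
  for (i in seq_along(raters)) for (j in seq_along(raters)) {
    if (i < j) M[i, j] <- M[j, i] <- 100 * mean(wide[, i] == wide[, j])
  }
  structure(M, domain = domain, n_patients = length(patients),
            class = c("agreement_matrix", "matrix"))
}

#' Mean and SD of inter-rater agreement
#'
#' Summarizes an agreement matrix over its unique off-diagonal rater pairs:
#' arithmetic mean and sample standard deviation (denominator `n_pairs - 1`),
#' reported at full precision alongside the nearest-integer percent values.
#'
#' @param matrix An [pairwise_agreement()] matrix, or any square symmetric
#'   percent matrix.
#' @return List with `mean`, `sd`, `mean_rounded`, `sd_rounded`, `n_pairs`.
#' @export
agreement_summary <- function(matrix) {
  if (nrow(matrix) < 2L) stop_input("need at least 2 raters")
  vals <- matrix[upper.tri(matrix)]
  list(mean = mean(vals), sd = stats::sd(vals),
       mean_rounded = round(mean(vals)), sd_rounded = round(stats::sd(vals)),
       n_pairs = length(vals))
}

#' Label distribution of one rater in one domain
#'
#' Percentages per label (summing to 100 before rounding) over the domain's
#' fixed vocabulary, plus the most common label and its frequency — the
#' chance-level baseline used by [improvement_coefficient()]. Ties for the
#' most common label are broken by the fixed vocabulary order.
#'
#' @inheritParams pairwise_agreement
#' @param rater A rater id present in the table.
#' @return List with `freq` (named percent vector over the vocabulary),
#'   `counts`, `most_common`, `most_common_pct`, `n`.
#' @export
label_distribution <- function(table, rater, domain) {
  domain <- match.arg(domain, affect_domains())
  labs <- affect_labels(domain)
  tb <- table[table$domain == domain & table$rater_id == rater, , drop = FALSE]
  if (nrow(tb) == 0L)
    stop_input("rater ", rater, " has no annotations in domain ", domain)
  counts <- table(factor(tb$label, levels = labs))
  freq <- 100 * as.numeric(counts) / sum(counts)
  names(freq) <- labs
  top <- which_max_first(freq)
  list(freq = freq, counts = stats::setNames(as.integer(counts), labs),
       most_common = labs[top], most_common_pct = freq[[top]], n = nrow(tb))
}

#' Multinomial logistic regression likelihood-ratio test
#'
#' Fits a multinomial logit of the labels on the feature columns (intercepts
#' plus predictors) and compares it against the intercepts-only baseline with
#' a likelihood-ratio test: `LR = 2 (ll_full - ll_null)`, referenced to a
#' chi-square with `(K - 1) * p` degrees of freedom for K observed classes
#' and p retained predictors. The baseline log-likelihood is computed in
#' closed form from the label counts.
#'
#' Zero-variance predictors are dropped with a warning (with none left the
#' model equals the baseline: LR = 0, p = 1). The fit is skipped with an
#' explanatory reason when fewer than 2 classes are observed or when the
#' sample is smaller than the number of fitted parameters. Non-converged fits
#' (e.g. quasi-separation under the bounded iteration limit) are flagged, not
#' hidden.
#'
#' @param X Feature matrix or vector (one row/value per patient).
#' @param y Labels (character or factor); unused classes are dropped.
#' @param maxit,reltol Optimizer controls passed to [nnet::multinom()].
#' @return An object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`, `n`, `k_classes`, `n_predictors`, `converged`,
#'   `skipped_reason` (`NA` unless the fit was skipped).
#' @export
multinomial_lrt <- function(X, y, maxit = 500, reltol = 1e-12) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  n <- length(y)
  if (nrow(X) != n) stop_input("X and y lengths differ")
  skipped <- function(reason) structure(
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
         n = n, k_classes = nlevels(y), n_predictors = ncol(X),
         converged = NA, skipped_reason = reason),
    class = "lrt_result")
  K <- nlevels(y)
  if (K < 2L) return(skipped("single observed class"))
  keep <- apply(X, 2, function(col) stats::sd(col) > 1e-12)
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance predictor(s)",
            call. = FALSE)
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  tab <- table(y)
  ll_null <- sum(tab * log(tab / n))
  if (p == 0L) {
    return(structure(list(statistic = 0, df = 0L, p_value = 1, n = n,
                          k_classes = K, n_predictors = 0L, converged = TRUE,
                          skipped_reason = NA_character_),
                     class = "lrt_result"))
  }
  n_params <- (K - 1L) * (p + 1L)
  if (n <= n_params) return(skipped("insufficient n"))
  colnames(X) <- paste0("x", seq_len(p))
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = maxit,
                        reltol = reltol, MaxNWts = 100000)
  ll_full <- -fit$deviance / 2
  lr <- max(0, 2 * (ll_full - ll_null))
  df <- (K - 1L) * p
  structure(list(statistic = lr, df = df,
                 p_value = stats::pchisq(lr, df, lower.tail = FALSE),
                 n = n, k_classes = K, n_predictors = p,
                 converged = fit$convergence == 0,
                 skipped_reason = NA_character_),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  if (!is.na(x$skipped_reason))
    cat("Multinomial LRT skipped:", x$skipped_reason, "\n")
  else
    cat(sprintf("Multinomial LRT: LR = %.3f, df = %d, p = %.4g%s\n",
                x$statistic, x$df, x$p_value,
                if (isFALSE(x$converged)) " [not converged]" else ""))
  invisible(x)
}

#' Region-wise motion regression grid
#'
#' For every rater, affect domain and facial region (the four composite
#' groups followed by the six single parts), computes the motion feature over
#' the region's cells and tests its association with the rater's labels by
#' [multinomial_lrt()]. Only the motion descriptor is used per region: the
#' other descriptors require expression classification, which is based on the
#' entire face.
#'
#' @param series_list Named list of `cell_series`, one per patient.
#' @param partition A [partition_faceparts()] result.
#' @param table Annotation data.frame (`patient_id`, `rater_id`, `domain`,
#'   `label`).
#' @param domains Domains to analyze; default all three.
#' @return A `regression_report` data.frame with one row per rater x domain x
#'   region: `rater_id`, `domain`, `region`, `statistic`, `df`, `p_value`,
#'   `converged`, `skipped_reason`.
#' @export
facepart_analysis <- function(series_list, partition, table,
                              domains = affect_domains()) {
  patients <- names(series_list)
  raters <- sort(unique(table$rater_id))
  regions <- face_regions()
  motion <- sapply(regions, function(rg) {
    cells <- region_cells(partition, rg)
    vapply(series_list, function(cs)
      if (length(cells)) motion_feature(cs, cells, rg)$values else NA_real_,
      numeric(1))
  })
  rows <- list()
  for (d in domains) for (r in raters) {
    tb <- table[table$domain == d & table$rater_id == r, , drop = FALSE]
    y <- tb$label[match(patients, tb$patient_id)]
    for (rg in regions) {
      cells <- region_cells(partition, rg)
      if (length(cells) == 0L) {
        res <- list(statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, converged = NA,
                    skipped_reason = "empty region")
      } else {
        res <- suppressWarnings(multinomial_lrt(motion[, rg], y))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = r, domain = d, region = rg,
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        converged = isTRUE(res$converged),
        skipped_reason = res$skipped_reason %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("regression_report", "data.frame")
  out
}

#' Feature-kind regression grid
#'
#' For every rater, affect domain and mid-level feature kind, tests the
#' association between the whole-face feature and the rater's labels by
#' [multinomial_lrt()].
#'
#' @param features Named list of per-kind feature matrices (as returned by
#'   [feature_matrix()]), rows = patients.
#' @inheritParams facepart_analysis
#' @return A `regression_report` data.frame with columns `rater_id`, `domain`,
#'   `feature_kind`, `statistic`, `df`, `p_value`, `converged`,
#'   `skipped_reason`.
#' @export
feature_kind_analysis <- function(features, table,
                                  domains = affect_domains()) {
  raters <- sort(unique(table$rater_id))
  rows <- list()
  for (d in domains) for (r in raters) {
    tb <- table[table$domain == d & table$rater_id == r, , drop = FALSE]
    for (kind in names(features)) {
      Xk <- features[[kind]]
      y <- tb$label[match(rownames(Xk), tb$patient_id)]
      res <- suppressWarnings(multinomial_lrt(Xk, y))
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = r, domain = d, feature_kind = kind,
        statistic = res$statistic, df = res$df, p_value = res$p_value,
        converged = isTRUE(res$converged),
        skipped_reason = res$skipped_reason %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("regression_report", "data.frame")
  out
}
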