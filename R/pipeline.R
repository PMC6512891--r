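#' Run the full affect-annotation study end to end
#'
#' Orchestrates the complete analysis on a synthetic (or pre-rendered)
#' cohort: cohort generation, landmark-based normalization, grid-cell
#' intensity extraction, the five mid-level features, inter-rater agreement
#' statistics, multinomial-regression grids (per feature kind and per facial
#' region), and per-rater leave-one-out SVM prediction with the improvement
#' coefficient. The report layout mirrors the result tables of a multi-rater
#' affect-annotation study: agreement matrices and summaries, label
#' distributions, two regression grids, and a prediction grid.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built `synthetic_cohort` with rendered videos
#'   (e.g. read from disk).
#' @param grid Cell grid `c(g_r, g_c)`; the normalized face side must be
#'   divisible by both. Default 8 x 8.
#' @param out_size Normalized face side in pixels. Default 96.
#' @param C Linear SVM cost. Default 100 (see [train_ova()]).
#' @param expression_n_per_class Training frames per expression class for the
#'   expression scorer. Default 50.
#' @param out_dir Optional output directory; when given, writes `report.json`,
#'   `tables/*.csv` and `provenance.json`.
#' @param verbose Log stage progress with [message()].
#' @return An object of class `study_report`: list with sections `agreement`,
#'   `distributions`, `regressions` (feature-kind and face-part grids),
#'   `prediction` (the LOO grid and a best-kind summary), and `provenance`.
#' @export
run_study <- function(config = cohort_config(), cohort = NULL,
                      grid = c(8, 8), out_size = 96, C = 100,
                      expression_n_per_class = 50,
                      out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  if (is.null(cohort)) {
    say("stage cohort: generating ", config$n_patients, " patients (seed ",
        config$seed, ")")
    cohort <- generate_cohort(config)
  } else {
    config <- cohort$config %||% config
  }
  if (is.null(cohort$videos)) stop_input("stage cohort: no rendered videos")
  tick("cohort")

  seeds <- derive_seeds(config$seed, 2L)
  say("stage expression_model: training 7-class scorer")
  ts <- generate_expression_trainingset(expression_n_per_class,
                                        frame_size = out_size,
                                        seed = seeds[1])
  tf <- trainingset_cell_features(ts, grid)
  model <- train_expression_model(tf$x, tf$labels, C = C, seed = seeds[1])
  tick("expression_model")

  say("stage extract: normalizing videos and recording cell intensities")
  template <- canonical_landmarks(out_size)
  series_list <- lapply(cohort$videos, function(v) {
    cell_intensity_series(normalize_video(v, template, out_size), grid)
  })
  names(series_list) <- names(cohort$videos)
  partition <- partition_faceparts(grid)
  tick("extract")

  say("stage features: five mid-level feature kinds")
  kinds <- c("expression", "label", "motion", "motion_label",
             "motion_expression")
  features <- stats::setNames(
    lapply(kinds, function(k) feature_matrix(series_list, k, model)), kinds)
  tick("features")

  say("stage stats: agreement, distributions, regressions")
  ann <- cohort$annotations
  raters <- sort(unique(ann$rater_id))
  agreement <- lapply(stats::setNames(nm = affect_domains()), function(d) {
    m <- pairwise_agreement(ann, d)
    list(matrix = m, summary = agreement_summary(m))
  })
  distributions <- lapply(stats::setNames(nm = affect_domains()), function(d) {
    lapply(stats::setNames(nm = raters), function(r)
      label_distribution(ann, r, d))
  })
  reg_kinds <- feature_kind_analysis(features, ann)
  reg_parts <- facepart_analysis(series_list, partition, ann)
  tick("stats")

  say("stage predict: leave-one-out SVM per rater, domain and feature kind")
  loo_rows <- list()
  for (d in affect_domains()) for (r in raters) {
    tb <- ann[ann$domain == d & ann$rater_id == r, , drop = FALSE]
    for (k in kinds) {
      Xk <- features[[k]]
      y <- factor(tb$label[match(rownames(Xk), tb$patient_id)],
                  levels = affect_labels(d))
      if (length(unique(as.character(y))) < 2L) {
        loo_rows[[length(loo_rows) + 1L]] <- data.frame(
          rater_id = r, domain = d, feature_kind = k,
          accuracy = NA_real_, baseline = NA_real_, improvement = NA_real_,
          n = length(y), degenerate = TRUE,
          skipped_reason = "no label variability", stringsAsFactors = FALSE)
        next
      }
      rep_ <- loo_evaluate(Xk, droplevels(y), C = C,
                           rater_id = r, domain = d, feature_kind = k)
      loo_rows[[length(loo_rows) + 1L]] <- data.frame(
        rater_id = r, domain = d, feature_kind = k,
        accuracy = rep_$accuracy, baseline = rep_$baseline,
        improvement = rep_$improvement, n = rep_$n,
        degenerate = rep_$degenerate, skipped_reason = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  loo_grid <- do.call(rbind, loo_rows)
  ok <- !is.na(loo_grid$accuracy)
  best <- do.call(rbind, lapply(split(loo_grid[ok, ],
                                      loo_grid[ok, c("rater_id", "domain")],
                                      drop = TRUE), function(g)
    g[which_max_first(g$accuracy), ]))
  rownames(best) <- NULL
  tick("predict")

  provenance <- list(
    seed = config$seed,
    n_patients = config$n_patients, n_raters = config$n_raters,
    n_frames = config$n_frames, frame_size = config$frame_size,
    grid = grid, out_size = out_size, svm_cost = C,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("affectfar")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  report <- structure(list(
    agreement = agreement, distributions = distributions,
    regressions = list(feature_kinds = reg_kinds, face_parts = reg_parts),
    prediction = list(loo = loo_grid, best_by_rater = best),
    provenance = provenance
  ), class = "study_report")
  attr(report, "timings") <- timings

  if (!is.null(out_dir)) {
    say("stage write: ", out_dir)
    write_study_report(report, out_dir)
  }
  report
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  slim <- config[setdiff(names(config), "rater_confusions")]
  slim$rater_confusions <- lapply(config$rater_confusions,
                                  function(rr) lapply(rr, as.vector))
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @rdname run_study
#' @param report A `study_report`.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  for (d in names(report$agreement)) {
    utils::write.csv(as.data.frame(unclass(report$agreement[[d]]$matrix)),
                     file.path(out_dir, "tables",
                               paste0("agreement_", d, ".csv")))
    dist <- do.call(rbind, lapply(names(report$distributions[[d]]), function(r)
      data.frame(rater_id = r, label = names(report$distributions[[d]][[r]]$freq),
                 percent = unname(report$distributions[[d]][[r]]$freq))))
    utils::write.csv(dist, file.path(out_dir, "tables",
                                     paste0("distribution_", d, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$regressions$feature_kinds,
                   file.path(out_dir, "tables", "regression_feature_kinds.csv"),
                   row.names = FALSE)
  utils::write.csv(report$regressions$face_parts,
                   file.path(out_dir, "tables", "regression_face_parts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$prediction$loo,
                   file.path(out_dir, "tables", "prediction_loo.csv"),
                   row.names = FALSE)
  json <- list(
    agreement = lapply(report$agreement, function(a) list(
      matrix = as.data.frame(unclass(a$matrix)), summary = a$summary)),
    distributions = report$distributions,
    regressions = report$regressions,
    prediction = report$prediction,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Affect annotation study report\n")
  for (d in names(x$agreement)) {
    s <- x$agreement[[d]]$summary
    cat(sprintf("  %s agreement: %d%% +/- %d (mean +/- SD over %d rater pairs)\n",
                d, s$mean_rounded, s$sd_rounded, s$n_pairs))
  }
  ok <- !is.na(x$prediction$loo$accuracy)
  if (any(ok)) {
    cat(sprintf("  LOO prediction: mean accuracy %.2f, mean improvement %.2f over %d rater/domain/kind cells\n",
                mean(x$prediction$loo$accuracy[ok]),
                mean(x$prediction$loo$improvement[ok]), sum(ok)))
  }
  sig <- x$regressions$face_parts
  sig <- sig[!is.na(sig$p_value), ]
  if (nrow(sig)) {
    hits <- tapply(sig$p_value < 0.05, sig$region, sum)
    cat("  face-part regressions with p < 0.05:",
        paste(names(hits), hits, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
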