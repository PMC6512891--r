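#' Write and read cohorts on disk
#'
#' On-disk layout: one directory per patient holding zero-padded numbered
#' grayscale PNG frames (`frames/000000.png`, 0-based) and a `landmarks.csv`
#' (columns `frame_index`, `landmark_name`, `x`, `y`; 0-based pixel
#' coordinates, origin top-left, x rightward, y downward); plus cohort-level
#' `annotations.csv` (columns `patient_id`, `rater_id`, `domain`, `label`),
#' `latents.csv`, and `config.yaml`.
#'
#' @param cohort A `synthetic_cohort` with rendered videos.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$videos)) stop_input("cohort has no rendered videos")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$videos)) {
    v <- cohort$videos[[id]]
    pdir <- file.path(dir, id, "frames")
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (n in seq_along(v$frames)) {
      png::writePNG(v$frames[[n]] / 255,
                    file.path(pdir, sprintf("%06d.png", n - 1L)))
    }
    utils::write.csv(v$landmarks, file.path(dir, id, "landmarks.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$latents, file.path(dir, "latents.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(
    n_patients = cfg$n_patients, n_raters = cfg$n_raters,
    n_frames = cfg$n_frames, frame_size = cfg$frame_size, seed = cfg$seed,
    noise_sd = cfg$noise_sd, fps = cfg$fps,
    signal_regions = cfg$signal_regions,
    affect_effect = lapply(cfg$affect_effect, as.list)
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_video()` returns a `face_video`-shaped list (`frames`,
#'   `landmarks`, `patient_id`) read from one patient directory.
#' @param patient_dir Directory holding `frames/` and `landmarks.csv`.
#' @export
read_video <- function(patient_dir) {
  files <- sort(list.files(file.path(patient_dir, "frames"),
                           pattern = "^\\d{6}\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop_input("no PNG frames under ", patient_dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    round(to_gray(img) * 255)
  })
  landmarks <- utils::read.csv(file.path(patient_dir, "landmarks.csv"),
                               stringsAsFactors = FALSE)
  structure(list(frames = frames, landmarks = landmarks,
                 frame_size = nrow(frames[[1]]),
                 patient_id = basename(patient_dir)),
            class = "face_video")
}

#' @rdname write_cohort
#' @return `read_annotations()` returns the annotation data.frame.
#' @param path Path to an annotations CSV.
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cell-intensity series as CSV plus JSON sidecar
#'
#' CSV rows are cells (row-major, top-left first), columns are frames; the
#' sidecar records the grid shape and, optionally, the facial partition.
#'
#' @param series A `cell_series`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param partition Optional `face_partition` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cell_series <- function(series, path, partition = NULL) {
  utils::write.csv(as.data.frame(series$X), path, row.names = TRUE)
  side <- list(grid = series$grid, out_size = series$out_size,
               patient_id = series$patient_id)
  if (!is.null(partition))
    side$partition <- lapply(partition$parts, as.integer)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Validate a cohort directory
#'
#' Checks frame-directory completeness (contiguous 0-based numbering),
#' landmark coverage per frame, annotation-table completeness and label
#' vocabulary conformance. Issues are reported, not thrown.
#'
#' @param dir A cohort directory in the [write_cohort()] layout.
#' @return data.frame with columns `type`, `where`, `detail`; zero rows when
#'   the cohort is clean.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  add <- function(type, where, detail)
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, where = where, detail = detail, stringsAsFactors = FALSE)
  pdirs <- list.dirs(dir, recursive = FALSE)
  pdirs <- pdirs[dir.exists(file.path(pdirs, "frames"))]
  for (pd in pdirs) {
    files <- list.files(file.path(pd, "frames"), pattern = "\\.png$")
    nums <- suppressWarnings(as.integer(sub("\\.png$", "", files)))
    expected <- sprintf("%06d.png", seq(0, max(c(nums, -1L))))
    miss <- setdiff(expected, files)
    for (m in miss)
      add("missing_frame", basename(pd), paste0("missing frame ", m))
    lm_path <- file.path(pd, "landmarks.csv")
    if (!file.exists(lm_path)) {
      add("missing_landmarks", basename(pd), "landmarks.csv not found")
    } else {
      lm <- utils::read.csv(lm_path, stringsAsFactors = FALSE)
      covered <- unique(lm$frame_index)
      for (n in setdiff(seq(0, max(c(nums, -1L))), covered))
        add("missing_landmarks", basename(pd),
            paste0("no landmarks for frame ", n))
    }
  }
  ann_path <- file.path(dir, "annotations.csv")
  if (!file.exists(ann_path)) {
    add("missing_annotations", dir, "annotations.csv not found")
  } else {
    ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ann))) {
      d <- ann$domain[i]
      if (!(d %in% affect_domains())) {
        add("vocabulary", "annotations.csv",
            paste0("row ", i, ": unknown domain '", d, "'"))
      } else if (!(ann$label[i] %in% affect_labels(d))) {
        add("vocabulary", "annotations.csv",
            paste0("row ", i, ": label '", ann$label[i],
                   "' not in the ", d, " vocabulary"))
      }
    }
    if (length(pdirs)) {
      ids <- basename(pdirs)
      raters <- unique(ann$rater_id)
      for (d in unique(ann$domain)) for (id in ids) for (r in raters) {
        if (!any(ann$patient_id == id & ann$rater_id == r & ann$domain == d))
          add("missing_annotation", "annotations.csv",
              paste0("no ", d, " label for (", id, ", ", r, ")"))
      }
    }
  }
  if (length(issues) == 0L)
    return(data.frame(type = character(), where = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
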