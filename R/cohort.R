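#' Configuration for a synthetic interview cohort
#'
#' Defines the conditions of a simulated affect-annotation study: a cohort of
#' patients, each contributing one short face video, rated independently by
#' several psychiatrists in three affect domains (quality, range, subtype).
#' Defaults mirror the pilot-study setting the package targets: 25 male
#' schizophrenia inpatients and 5 senior raters, with video length scaled down
#' to desk size (all mid-level features are length-invariant).
#'
#' @param n_patients Number of patients (>= 2). Default 25.
#' @param n_raters Number of raters. Default 5.
#' @param n_frames Frames per video (>= 2). Default 300.
#' @param frame_size Square frame side in pixels. Default 96.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param affect_effect Effect sizes linking latent affect to facial dynamics;
#'   see [default_affect_effect()].
#' @param rater_confusions Per-rater, per-domain row-stochastic confusion
#'   matrices over the domain's labels. Default: built from
#'   `rater_reliability` by [make_confusion()].
#' @param rater_reliability Scalar or per-rater vector in \[0, 1\]; probability
#'   mass a rater keeps on the latent label before uniform spreading.
#'   Default 0.9, chosen so that label recovery from video features is
#'   well-posed at the default cohort size (n = 25); lower it to around 0.5
#'   to emulate the weaker agreement typical of expert affect annotation.
#' @param signal_regions Facial regions whose oscillation amplitude carries the
#'   latent range signal. Default: all six parts.
#' @param latent_priors Named list of class priors per domain.
#' @param noise_sd Intensity noise scale (gray levels): static per-pixel facial
#'   texture with this SD plus per-region per-frame jitter with SD
#'   `noise_sd / 2`. Default 2.
#' @param fps Nominal frames per second used for oscillation phase. Default 30.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 25, n_raters = 5, n_frames = 300,
                          frame_size = 96, seed = 1,
                          affect_effect = default_affect_effect(),
                          rater_confusions = NULL,
                          rater_reliability = 0.9,
                          signal_regions = face_parts(),
                          latent_priors = default_latent_priors(),
                          noise_sd = 2, fps = 30) {
  if (n_patients < 2) stop_input("n_patients must be >= 2")
  if (n_raters < 1) stop_input("n_raters must be >= 1")
  if (n_frames < 2) stop_input("n_frames must be >= 2")
  if (!all(unlist(affect_effect) >= 0))
    stop_input("all affect_effect scalars must be >= 0")
  signal_regions <- match.arg(signal_regions, face_parts(), several.ok = TRUE)
  if (is.null(rater_confusions)) {
    rel <- rep_len(rater_reliability, n_raters)
    rater_confusions <- lapply(seq_len(n_raters), function(r) {
      stats::setNames(lapply(affect_domains(), function(d)
        make_confusion(affect_labels(d), rel[r])), affect_domains())
    })
  }
  validate_confusions(rater_confusions, n_raters)
  for (d in affect_domains()) {
    pr <- latent_priors[[d]]
    if (is.null(pr) || length(pr) != length(affect_labels(d)) ||
        abs(sum(pr) - 1) > 1e-9 || any(pr < 0))
      stop_input("latent_priors$", d, " must be a probability vector over ",
                 length(affect_labels(d)), " labels")
  }
  structure(
    list(n_patients = as.integer(n_patients), n_raters = as.integer(n_raters),
         n_frames = as.integer(n_frames), frame_size = as.integer(frame_size),
         seed = as.integer(seed), affect_effect = affect_effect,
         rater_confusions = rater_confusions,
         signal_regions = signal_regions, latent_priors = latent_priors,
         noise_sd = noise_sd, fps = fps),
    class = "cohort_config"
  )
}

validate_confusions <- function(conf, n_raters) {
  if (length(conf) != n_raters)
    stop_input("rater_confusions must have one entry per rater")
  for (r in seq_len(n_raters)) for (d in affect_domains()) {
    C <- conf[[r]][[d]]
    labs <- affect_labels(d)
    if (is.null(C) || !is.matrix(C) || any(dim(C) != length(labs)))
      stop_input("rater ", r, " ", d, " confusion matrix has wrong shape")
    if (any(abs(rowSums(C) - 1) > 1e-9))
      stop_input("rater ", r, " ", d,
                 " confusion matrix rows must sum to 1 (within 1e-9)")
    if (any(C < 0)) stop_input("confusion probabilities must be >= 0")
  }
  invisible(TRUE)
}

#' @rdname cohort_config
#' @param labels Label vocabulary.
#' @param reliability Probability kept on the true label before uniform
#'   spreading over all labels.
#' @return `make_confusion()` returns a row-stochastic K x K matrix
#'   `reliability * I + (1 - reliability) / K`.
#' @export
make_confusion <- function(labels, reliability) {
  K <- length(labels)
  stopifnot(reliability >= 0, reliability <= 1)
  C <- matrix((1 - reliability) / K, K, K, dimnames = list(labels, labels))
  diag(C) <- diag(C) + reliability
  C
}

#' @rdname cohort_config
#' @return `default_affect_effect()` returns the default effect sizes:
#'   `range` — oscillation-amplitude multipliers per range class
#'   (flat 1 < blunt 4 < restricted 8 < full 14); `quality` — gray-level scale
#'   of the expression-mixture offsets (25); `subtype` — gray-level scale of
#'   the per-subtype static template (6); `nonsignal` — amplitude multiplier
#'   for regions outside `signal_regions` (4).
#' @export
default_affect_effect <- function() {
  list(
    quality = 25,
    range = c(full = 14, restricted = 8, blunt = 4, flat = 1),
    subtype = 6,
    nonsignal = 4
  )
}

#' @rdname cohort_config
#' @export
default_latent_priors <- function() {
  list(
    quality = c(dysphoric = 0.20, euthymic = 0.65, manic = 0.15),
    range   = c(full = 0.12, restricted = 0.28, blunt = 0.38, flat = 0.22),
    subtype = c(unknown = 0.38, stupid = 0.20, euphoria = 0.05,
                empathetic = 0.04, self_contempt = 0.01, anxious = 0.10,
                suspicious = 0.03, hopeless = 0.02, frightened = 0.03,
                irritable = 0.05, vacancy = 0.08, sense_of_guilt = 0.01)
  )
}

# ---- parametric face model -------------------------------------------------

# Region rectangles in unit face coordinates [0,1]^2 (x rightward, y downward),
# chosen so each rendered region falls inside the matching default partition
# part (see default_part_layout()).
face_model <- function() {
  rect <- function(x0, x1, y0, y1) c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
  list(
    head = list(center = c(0.5, 0.52), semi = c(0.38, 0.46), base = 180),
    regions = list(
      left_eye    = rect(0.22, 0.40, 0.28, 0.44),
      right_eye   = rect(0.60, 0.78, 0.28, 0.44),
      left_cheek  = rect(0.14, 0.34, 0.52, 0.70),
      right_cheek = rect(0.66, 0.86, 0.52, 0.70),
      mouth       = rect(0.34, 0.66, 0.78, 0.92),
      nose        = rect(0.44, 0.56, 0.52, 0.70)
    ),
    base = c(left_eye = 90, right_eye = 90, left_cheek = 150,
             right_cheek = 150, mouth = 70, nose = 140),
    # oscillation frequency (Hz) and unit amplitude per region
    freq = c(left_eye = 0.9, right_eye = 0.9, left_cheek = 0.45,
             right_cheek = 0.45, mouth = 0.6, nose = 0.3),
    base_amp = c(left_eye = 1.0, right_eye = 1.0, left_cheek = 0.5,
                 right_cheek = 0.5, mouth = 0.8, nose = 0.4),
    landmarks = rbind(
      left_eye    = c(0.31, 0.36),
      right_eye   = c(0.69, 0.36),
      nose_tip    = c(0.50, 0.66),
      mouth_left  = c(0.34, 0.85),
      mouth_right = c(0.66, 0.85),
      chin        = c(0.50, 0.95)
    )
  )
}

# quality -> unit region-intensity offsets (expression mixture per quality)
quality_templates <- function() {
  m <- rbind(
    dysphoric = c(left_eye = -0.4, right_eye = -0.4, left_cheek = -0.2,
                  right_cheek = -0.2, mouth = -1.0, nose = 0),
    euthymic  = c(0, 0, 0, 0, 0, 0),
    manic     = c(left_eye = 0.3, right_eye = 0.3, left_cheek = 0.8,
                  right_cheek = 0.8, mouth = 1.0, nose = 0)
  )
  colnames(m) <- face_parts()
  m
}

# subtype -> unit region offsets; a fixed, seeded template matrix
subtype_templates <- function() {
  vals <- withr::with_seed(104729L,
    stats::runif(length(affect_labels("subtype")) * 6, -1, 1))
  matrix(round(vals, 3), nrow = length(affect_labels("subtype")),
         dimnames = list(affect_labels("subtype"), face_parts()))
}

# expression class -> unit region offsets for the expression training set.
# The seven template points are affinely independent (mild left/right
# asymmetry; "norm" displaced off the centroid) so every class is a vertex of
# their convex hull and each one-vs-rest problem is linearly separable.
expression_templates <- function() {
  m <- rbind(
    norm      = c(-0.2, -0.2, -0.5, -0.5, 0.3, -0.6),
    anger     = c(-1, -0.8, 0, 0, -0.5, 0.6),
    disgust   = c(0, 0, 0.5, 0.7, -0.8, 1),
    fear      = c(1, 0.8, 0, 0, 0.5, -0.2),
    happiness = c(0, 0.2, 0.8, 0.6, 1, 0),
    sadness   = c(-0.5, -0.4, -0.2, 0, -1, 0),
    surprise  = c(0.9, 1, -0.5, -0.4, 1, -0.6)
  )
  colnames(m) <- face_parts()
  m
}

# pose: similarity jitter in pixel space; identity when NULL
identity_pose <- function() list(dx = 0, dy = 0, scale = 1, rot_deg = 0)

pose_forward <- function(pose, xy, frame_size) {
  ctr <- (frame_size - 1) / 2
  th <- pose$rot_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(pose$scale * (sweep(xy, 2, c(ctr, ctr)) %*% t(R)), 2,
        c(ctr + pose$dx, ctr + pose$dy), `+`)
}

pose_inverse <- function(pose, xy, frame_size) {
  ctr <- (frame_size - 1) / 2
  th <- -pose$rot_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep((sweep(xy, 2, c(ctr + pose$dx, ctr + pose$dy)) %*% t(R)) / pose$scale,
        2, c(ctr, ctr), `+`)
}

# canonical unit coords of every output pixel center under a pose
pixel_unit_coords <- function(frame_size, pose) {
  xy <- cbind(rep(0:(frame_size - 1), each = frame_size),  # x = column
              rep(0:(frame_size - 1), frame_size))          # y = row (fast)
  can <- pose_inverse(pose, xy, frame_size)
  (can + 0.5) / frame_size
}

in_rect <- function(u, rect) {
  u[, 1] >= rect["x0"] & u[, 1] < rect["x1"] &
    u[, 2] >= rect["y0"] & u[, 2] < rect["y1"]
}

#' Render a synthetic face video for one latent affect state
#'
#' Draws a parametric grayscale face (elliptical head, eyes, nose, mouth,
#' cheeks at known canonical coordinates) whose region intensities oscillate
#' sinusoidally. The latent range class scales the oscillation amplitudes
#' (flat < blunt < restricted < full), the latent quality class shifts the
#' region intensity mixture, and the subtype adds a class-specific static
#' template. Landmarks are the generator's true coordinates, so no face
#' detector is needed downstream.
#'
#' @param latent A list or one-row data.frame with `quality`, `range`,
#'   `subtype` labels (and optionally `patient_id`).
#' @param n_frames Number of frames (>= 2).
#' @param frame_size Square frame side in pixels.
#' @param seed Integer seed.
#' @param pose Optional similarity jitter `list(dx, dy, scale, rot_deg)`
#'   applied to the canonical face; default identity.
#' @inheritParams cohort_config
#' @return An object of class `face_video`: list with `frames` (list of
#'   integer matrices in \[0, 255\]) and `landmarks` (data.frame with columns
#'   `frame_index` (0-based), `landmark_name`, `x`, `y`; 0-based pixel
#'   coordinates, origin top-left, x rightward, y downward).
#' @export
render_face_video <- function(latent, n_frames = 300, frame_size = 96,
                              seed = 1, pose = NULL,
                              affect_effect = default_affect_effect(),
                              signal_regions = face_parts(),
                              noise_sd = 2, fps = 30) {
  if (n_frames < 2) stop_input("n_frames must be >= 2 (motion SD undefined)")
  latent <- as.list(latent)
  pose <- pose %||% identity_pose()
  fm <- face_model()
  regions <- names(fm$regions)
  qual_off <- quality_templates()[latent$quality, ] * affect_effect$quality
  sub_off <- subtype_templates()[latent$subtype, ] * affect_effect$subtype
  mult <- ifelse(regions %in% signal_regions,
                 affect_effect$range[[latent$range]],
                 affect_effect$nonsignal %||% 0)
  amp <- fm$base_amp[regions] * mult

  u <- pixel_unit_coords(frame_size, pose)
  hc <- fm$head$center; hs <- fm$head$semi
  head_idx <- which(((u[, 1] - hc[1]) / hs[1])^2 +
                    ((u[, 2] - hc[2]) / hs[2])^2 <= 1)
  # regions are clipped to the head ellipse so nothing oscillates on background
  region_idx <- lapply(fm$regions,
                       function(r) intersect(which(in_rect(u, r)), head_idx))

  withr::with_seed(as.integer(seed), {
    phases <- stats::runif(length(regions), 0, 2 * pi)
    texture <- stats::rnorm(length(head_idx), 0, noise_sd)
    jitter <- matrix(stats::rnorm(length(regions) * n_frames, 0, noise_sd / 2),
                     nrow = length(regions))
  })
  names(phases) <- regions

  canvas <- numeric(frame_size^2)
  canvas[head_idx] <- fm$head$base + texture
  for (r in regions)
    canvas[region_idx[[r]]] <- fm$base[r] + qual_off[r] + sub_off[r] +
      texture[match(region_idx[[r]], head_idx)]

  tt <- (seq_len(n_frames) - 1) / fps
  # pixels x frames; column-major pixel order matches matrix(row = y, col = x)
  P <- matrix(canvas, frame_size^2, n_frames)
  for (k in seq_along(regions)) {
    r <- regions[k]
    idx <- region_idx[[k]]
    if (length(idx) == 0L) next
    delta <- amp[r] * sin(2 * pi * fm$freq[r] * tt + phases[r]) + jitter[k, ]
    P[idx, ] <- P[idx, ] + rep(delta, each = length(idx))
  }
  P <- round(pmin(pmax(P, 0), 255))
  frames <- lapply(seq_len(n_frames), function(n)
    matrix(as.integer(P[, n]), frame_size, frame_size))

  lm_can <- fm$landmarks * frame_size - 0.5  # unit -> 0-based pixel coords
  lm_px <- pose_forward(pose, lm_can, frame_size)
  landmarks <- data.frame(
    frame_index = rep(0:(n_frames - 1), each = nrow(lm_can)),
    landmark_name = rep(rownames(lm_can), n_frames),
    x = rep(lm_px[, 1], n_frames),
    y = rep(lm_px[, 2], n_frames),
    stringsAsFactors = FALSE
  )
  structure(list(frames = frames, landmarks = landmarks,
                 frame_size = frame_size, fps = fps,
                 latent = latent, pose = pose),
            class = "face_video")
}

#' Apply the rater annotation model to latent affect states
#'
#' Each rater annotates each patient and domain independently by drawing a
#' label from the row of their confusion matrix indexed by the latent label.
#' With identity confusion matrices the annotations equal the latent labels;
#' the expected agreement between two raters sharing confusion matrix C under
#' latent prior pi is `sum_j pi_j * sum_k C[j,k]^2`, which makes inter-rater
#' agreement an analytically controllable target.
#'
#' @param latents data.frame with columns `patient_id`, `quality`, `range`,
#'   `subtype`.
#' @param confusions Per-rater list of per-domain confusion matrices.
#' @param seed Integer seed.
#' @param rater_ids Optional rater identifiers; default `rater_1`, ...
#' @return data.frame with columns `patient_id`, `rater_id`, `domain`, `label`.
#' @export
annotate_cohort <- function(latents, confusions, seed = 1, rater_ids = NULL) {
  n_raters <- length(confusions)
  rater_ids <- rater_ids %||% paste0("rater_", seq_len(n_raters))
  validate_confusions(confusions, n_raters)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (r in seq_len(n_raters)) for (d in affect_domains()) {
      labs <- affect_labels(d)
      C <- confusions[[r]][[d]]
      lab <- vapply(latents[[d]], function(true_lab) {
        sample(labs, 1L, prob = C[match(true_lab, labs), ])
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = latents$patient_id, rater_id = rater_ids[r],
        domain = d, label = lab, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic cohort of face videos and multi-rater annotations
#'
#' Draws a latent affect state per patient from the configured priors, renders
#' one face video per patient (with a small per-patient similarity pose jitter
#' so landmark-based normalization is exercised), and produces the five-rater
#' annotation table through the confusion-matrix rater model. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param render If `FALSE`, skip video rendering (latents and annotations
#'   only); useful for large-n calibration of the rater model.
#' @return An object of class `synthetic_cohort`: list with `config`,
#'   `latents` (data.frame), `poses`, `annotations` (data.frame), and `videos`
#'   (list of `face_video`, or `NULL` when `render = FALSE`).
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ids <- sprintf("patient_%03d", seq_len(n))
  seeds <- derive_seeds(config$seed, n + 3L)
  latents <- withr::with_seed(seeds[1], {
    data.frame(
      patient_id = ids,
      quality = sample(affect_labels("quality"), n, TRUE,
                       config$latent_priors$quality),
      range = sample(affect_labels("range"), n, TRUE,
                     config$latent_priors$range),
      subtype = sample(affect_labels("subtype"), n, TRUE,
                       config$latent_priors$subtype),
      stringsAsFactors = FALSE
    )
  })
  poses <- withr::with_seed(seeds[2], {
    lapply(seq_len(n), function(i) list(
      dx = stats::runif(1, -0.05, 0.05) * config$frame_size,
      dy = stats::runif(1, -0.05, 0.05) * config$frame_size,
      scale = stats::runif(1, 0.92, 1.08),
      rot_deg = stats::runif(1, -7, 7)
    ))
  })
  annotations <- annotate_cohort(latents, config$rater_confusions,
                                 seed = seeds[3])
  videos <- NULL
  if (render) {
    videos <- lapply(seq_len(n), function(i) {
      v <- render_face_video(
        latents[i, ], n_frames = config$n_frames,
        frame_size = config$frame_size, seed = seeds[i + 3L],
        pose = poses[[i]], affect_effect = config$affect_effect,
        signal_regions = config$signal_regions,
        noise_sd = config$noise_sd, fps = config$fps)
      v$patient_id <- ids[i]
      v
    })
    names(videos) <- ids
  }
  structure(list(config = config, latents = latents, poses = poses,
                 annotations = annotations, videos = videos),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic affect-annotation cohort\n")
  cat("  patients:", x$config$n_patients,
      " raters:", x$config$n_raters,
      " frames/video:", x$config$n_frames,
      " frame size:", x$config$frame_size, "px\n")
  cat("  videos rendered:", !is.null(x$videos), "\n")
  invisible(x)
}

#' Generate a labeled training set for the 7-class expression scorer
#'
#' Renders static canonical-pose faces for each of the seven expression
#' classes (norm, anger, disgust, fear, happiness, sadness, surprise) using
#' class-specific region-intensity templates plus per-pixel Gaussian noise.
#'
#' @param n_per_class Frames per class (>= 1).
#' @param frame_size Square frame side in pixels.
#' @param seed Integer seed.
#' @param noise_sd Per-pixel noise SD in gray levels; 0 gives identical frames
#'   within a class.
#' @param template_scale Gray-level scale of the class templates. Default 30.
#' @return An object of class `expression_trainingset`: list with `frames`
#'   (list of integer matrices) and `labels` (factor over the seven classes).
#' @export
generate_expression_trainingset <- function(n_per_class = 50, frame_size = 96,
                                            seed = 1, noise_sd = 2,
                                            template_scale = 30) {
  if (n_per_class < 1) stop_input("n_per_class must be >= 1")
  fm <- face_model()
  tmpl <- expression_templates() * template_scale
  u <- pixel_unit_coords(frame_size, identity_pose())
  hc <- fm$head$center; hs <- fm$head$semi
  head_idx <- which(((u[, 1] - hc[1]) / hs[1])^2 +
                    ((u[, 2] - hc[2]) / hs[2])^2 <= 1)
  region_idx <- lapply(fm$regions, function(r) which(in_rect(u, r)))
  classes <- expression_classes()
  frames <- vector("list", length(classes) * n_per_class)
  labels <- character(length(frames))
  withr::with_seed(as.integer(seed), {
    k <- 0L
    for (cl in classes) {
      canvas <- numeric(frame_size^2)
      canvas[head_idx] <- fm$head$base
      for (r in names(region_idx))
        canvas[region_idx[[r]]] <- fm$base[r] + tmpl[cl, r]
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        px <- canvas + stats::rnorm(length(canvas), 0, noise_sd)
        frames[[k]] <- matrix(as.integer(round(pmin(pmax(px, 0), 255))),
                              frame_size, frame_size)
        labels[k] <- cl
      }
    }
  })
  structure(list(frames = frames,
                 labels = factor(labels, levels = classes),
                 frame_size = frame_size),
            class = "expression_trainingset")
}
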