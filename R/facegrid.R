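#' Canonical landmark template
#'
#' Fixed canonical positions (0-based pixel coordinates on an
#' `out_size x out_size` canvas) of the six named landmarks used for
#' landmark-based face alignment: eye centers in the upper third, nose tip
#' central, mouth corners in the lower third, chin at the bottom.
#'
#' @param out_size Side of the normalized face canvas in pixels.
#' @return data.frame with columns `landmark_name`, `x`, `y`.
#' @export
canonical_landmarks <- function(out_size = 96) {
  lm <- face_model()$landmarks
  data.frame(landmark_name = rownames(lm),
             x = lm[, 1] * out_size - 0.5,
             y = lm[, 2] * out_size - 0.5,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize a face frame by landmark alignment
#'
#' Computes the least-squares similarity transform (rotation, isotropic
#' scale, translation) mapping the frame's landmarks onto the canonical
#' template, and resamples the frame onto the `out_size x out_size`
#' normalized canvas with bilinear interpolation. Samples falling outside the
#' source frame are filled with 0.
#'
#' @param frame Grayscale image matrix (values in \[0, 255\]); a 3-channel
#'   array is converted to gray as 0.299 R + 0.587 G + 0.114 B.
#' @param landmarks data.frame with columns `landmark_name`, `x`, `y` (0-based
#'   pixel coordinates) for this frame.
#' @param template Canonical landmark positions; default
#'   [canonical_landmarks()] at `out_size`.
#' @param out_size Side of the normalized output in pixels.
#' @return Numeric `out_size x out_size` matrix.
#' @export
normalize_face <- function(frame, landmarks, template = NULL, out_size = 96) {
  frame <- to_gray(frame)
  template <- template %||% canonical_landmarks(out_size)
  common <- intersect(landmarks$landmark_name, template$landmark_name)
  if (length(common) < 2L)
    stop_input("need at least 2 landmarks shared with the template")
  src <- as.matrix(landmarks[match(common, landmarks$landmark_name), c("x", "y")])
  dst <- as.matrix(template[match(common, template$landmark_name), c("x", "y")])
  if (any(!is.finite(src))) stop_input("landmark coordinates must be finite")
  tr <- fit_similarity(src, dst)
  plan <- warp_plan(tr, out_size, nrow(frame), ncol(frame))
  matrix(bilinear_apply(plan, frame), out_size, out_size)
}

# plan for sampling source pixels at the inverse-transformed positions of
# every output pixel center
warp_plan <- function(tr, out_size, src_nr, src_nc) {
  out_xy <- cbind(rep(0:(out_size - 1), each = out_size),
                  rep(0:(out_size - 1), out_size))
  src_xy <- tr$inverse(out_xy)
  bilinear_plan(src_xy[, 1], src_xy[, 2], src_nr, src_nc)
}

to_gray <- function(frame) {
  if (length(dim(frame)) == 3L) {
    if (dim(frame)[3] >= 3)
      frame <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    else frame <- frame[, , 1]
  }
  frame
}

#' Normalize every frame of a face video
#'
#' Applies [normalize_face()] per frame. When the landmarks are identical
#' across frames (a fixed head pose), the resampling plan is computed once and
#' reused.
#'
#' @param video A `face_video` (see [render_face_video()]) or a list with
#'   `frames` and `landmarks` in the same layout.
#' @param template,out_size As in [normalize_face()].
#' @return An object of class `normalized_face_sequence`: list with `frames`
#'   (list of numeric matrices), `out_size`, `patient_id`, `fps`.
#' @export
normalize_video <- function(video, template = NULL, out_size = 96) {
  template <- template %||% canonical_landmarks(out_size)
  lms <- split(video$landmarks, video$landmarks$frame_index)
  n_frames <- length(video$frames)
  if (length(lms) != n_frames)
    stop_input("landmarks must cover every frame (",
               n_frames, " frames, ", length(lms), " landmark frames)")
  lms <- lms[order(as.integer(names(lms)))]
  static_pose <- n_frames > 1 &&
    all(vapply(lms[-1], function(l)
      isTRUE(all.equal(l[c("landmark_name", "x", "y")],
                       lms[[1]][c("landmark_name", "x", "y")],
                       check.attributes = FALSE)), logical(1)))
  frames <- vector("list", n_frames)
  if (static_pose) {
    l1 <- lms[[1]]
    common <- intersect(l1$landmark_name, template$landmark_name)
    if (length(common) < 2L)
      stop_input("need at least 2 landmarks shared with the template")
    src <- as.matrix(l1[match(common, l1$landmark_name), c("x", "y")])
    dst <- as.matrix(template[match(common, template$landmark_name), c("x", "y")])
    tr <- fit_similarity(src, dst)
    plan <- warp_plan(tr, out_size, nrow(video$frames[[1]]),
                      ncol(video$frames[[1]]))
    npx <- length(video$frames[[1]])
    M <- vapply(video$frames, function(f) as.numeric(to_gray(f)), numeric(npx))
    out <- plan$w[, 1] * M[plan$idx[, 1], , drop = FALSE] +
           plan$w[, 2] * M[plan$idx[, 2], , drop = FALSE] +
           plan$w[, 3] * M[plan$idx[, 3], , drop = FALSE] +
           plan$w[, 4] * M[plan$idx[, 4], , drop = FALSE]
    for (n in seq_len(n_frames))
      frames[[n]] <- matrix(out[, n], out_size, out_size)
  } else {
    for (n in seq_len(n_frames))
      frames[[n]] <- normalize_face(video$frames[[n]], lms[[n]],
                                    template, out_size)
  }
  structure(list(frames = frames, out_size = out_size,
                 patient_id = video$patient_id %||% NA_character_,
                 fps = video$fps %||% NA_real_),
            class = "normalized_face_sequence")
}

# row-major cell id (0-based, top-left cell 0) of every pixel of an nr x nc
# frame in column-major pixel order
pixel_cell_ids <- function(nr, nc, g_r, g_c) {
  if (nr %% g_r != 0 || nc %% g_c != 0)
    stop_input("frame size (", nr, "x", nc,
               ") must be divisible by the grid (", g_r, "x", g_c, ")")
  ch <- nr / g_r; cw <- nc / g_c
  row <- rep(0:(nr - 1), nc); col <- rep(0:(nc - 1), each = nr)
  (row %/% ch) * g_c + col %/% cw
}

# mean gray level of each grid cell of a single frame (row-major cell order,
# cell 0 = top-left)
frame_cell_means <- function(frame, grid = c(8, 8)) {
  ids <- pixel_cell_ids(nrow(frame), ncol(frame), grid[1], grid[2])
  as.vector(rowsum(as.numeric(frame), ids)) / tabulate(ids + 1L)
}

#' Mean gray-level intensity series per grid cell
#'
#' Divides each normalized frame into a `g_r x g_c` grid of equally sized
#' cells and records the mean gray level of cell r at frame n, the canonical
#' per-frame descriptor. Cells are indexed row-major with the top-left cell
#' first.
#'
#' @param seq A `normalized_face_sequence`, or any list of equally sized
#'   grayscale matrices.
#' @param grid Integer vector `c(g_r, g_c)`; the frame side must be divisible
#'   by both so cells are exactly equally sized.
#' @return An object of class `cell_series`: list with `X` (matrix, rows =
#'   cells in row-major order, columns = frames), `grid`, `out_size`,
#'   `cells` (data.frame mapping each cell to its pixel rectangle),
#'   `patient_id`.
#' @export
cell_intensity_series <- function(seq, grid = c(8, 8)) {
  frames <- if (is.list(seq) && !is.null(seq$frames)) seq$frames else seq
  if (length(frames) < 2L) stop_input("need at least 2 frames")
  g_r <- as.integer(grid[1]); g_c <- as.integer(grid[2])
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  ids <- pixel_cell_ids(nr, nc, g_r, g_c)
  M <- vapply(frames, as.numeric, numeric(nr * nc))
  X <- rowsum(M, ids) / tabulate(ids + 1L)
  X <- matrix(X, nrow = g_r * g_c)
  rownames(X) <- paste0("cell_", seq_len(g_r * g_c) - 1L)
  ch <- nr / g_r; cw <- nc / g_c
  k <- seq_len(g_r * g_c) - 1L
  cells <- data.frame(
    cell = k, grid_row = k %/% g_c, grid_col = k %% g_c,
    y0 = (k %/% g_c) * ch, y1 = (k %/% g_c + 1) * ch,
    x0 = (k %% g_c) * cw, x1 = (k %% g_c + 1) * cw
  )
  structure(list(X = X, grid = c(g_r, g_c), out_size = c(nr, nc),
                 cells = cells,
                 patient_id = (if (is.list(seq)) seq$patient_id else NULL) %||%
                   NA_character_),
            class = "cell_series")
}

#' Default facial part layout
#'
#' Part rectangles in normalized \[0, 1\]^2 face coordinates (half-open),
#' qualitatively matching the six-part division of the normalized face: eyes
#' in the upper half, cheeks lateral, nose central, mouth in the lower part.
#'
#' @return Named list of rectangles `c(x0, x1, y0, y1)`.
#' @export
default_part_layout <- function() {
  rect <- function(x0, x1, y0, y1) c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
  list(
    left_eye    = rect(0.125, 0.500, 0.25, 0.50),
    right_eye   = rect(0.500, 0.875, 0.25, 0.50),
    left_cheek  = rect(0.000, 0.375, 0.50, 0.75),
    right_cheek = rect(0.625, 1.000, 0.50, 0.75),
    nose        = rect(0.375, 0.625, 0.50, 0.75),
    mouth       = rect(0.250, 0.750, 0.75, 1.00)
  )
}

#' Partition the cell grid into six facial parts
#'
#' Assigns each grid cell to a facial part iff the cell's center lies inside
#' that part's rectangle, and assembles the composite groups used for
#' region-wise analysis: `eyes`, `mouth_and_nose`, `cheeks`, `all_parts`.
#'
#' @param grid Integer vector `c(g_r, g_c)`.
#' @param layout Named list of part rectangles in \[0, 1\]^2 (half-open);
#'   rectangles must not overlap. Default [default_part_layout()].
#' @return An object of class `face_partition`: list with `parts` (named list
#'   of 1-based cell row indices into the `X` matrix; the first row is cell 0,
#'   the top-left cell), `groups`, `grid`, `layout`.
#' @export
partition_faceparts <- function(grid = c(8, 8), layout = default_part_layout()) {
  if (!all(face_parts() %in% names(layout)))
    stop_input("layout must define all six parts: ",
               paste(face_parts(), collapse = ", "))
  nm <- names(layout)
  for (i in seq_along(layout)) for (j in seq_along(layout)) {
    if (i >= j) next
    a <- layout[[i]]; b <- layout[[j]]
    if (a["x0"] < b["x1"] && b["x0"] < a["x1"] &&
        a["y0"] < b["y1"] && b["y0"] < a["y1"])
      stop_input("part rectangles overlap: ", nm[i], " and ", nm[j])
  }
  g_r <- grid[1]; g_c <- grid[2]
  k <- seq_len(g_r * g_c) - 1L
  cx <- (k %% g_c + 0.5) / g_c
  cy <- (k %/% g_c + 0.5) / g_r
  parts <- lapply(layout, function(r)
    which(cx >= r["x0"] & cx < r["x1"] & cy >= r["y0"] & cy < r["y1"]))
  parts <- parts[face_parts()]
  groups <- list(
    eyes = sort(c(parts$left_eye, parts$right_eye)),
    mouth_and_nose = sort(c(parts$mouth, parts$nose)),
    cheeks = sort(c(parts$left_cheek, parts$right_cheek)),
    all_parts = sort(unique(unlist(parts)))
  )
  structure(list(parts = parts, groups = groups, grid = grid, layout = layout),
            class = "face_partition")
}

#' @rdname partition_faceparts
#' @param partition A `face_partition`.
#' @param region One of [face_regions()].
#' @return `region_cells()` returns the 1-based cell indices of a part or
#'   composite group.
#' @export
region_cells <- function(partition, region) {
  region <- match.arg(region, face_regions())
  if (region %in% names(partition$groups)) partition$groups[[region]]
  else partition$parts[[region]]
}
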