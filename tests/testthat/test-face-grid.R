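canonical_face_frame <- function(out_size = 48, seed = 5) {
  v <- render_face_video(tiny_latent(), n_frames = 2, frame_size = out_size,
                         seed = seed)
  v$frames[[1]]
}

test_that("normalization is the identity when landmarks already match the template", {
  frame <- canonical_face_frame(48)
  tmpl <- canonical_landmarks(48)
  out <- normalize_face(frame, tmpl, template = tmpl, out_size = 48)
  expect_lt(max(abs(out - frame)), 1e-9)
})

test_that("a pure translation is undone up to interpolation tolerance", {
  ref <- canonical_face_frame(48)
  tmpl <- canonical_landmarks(48)
  shifted <- matrix(0, 56, 56)
  shifted[6:53, 6:53] <- ref  # content moved by (+5, +5) pixels
  lm <- tmpl
  lm$x <- lm$x + 5
  lm$y <- lm$y + 5
  out <- normalize_face(shifted, lm, template = tmpl, out_size = 48)
  expect_lte(max(abs(out - ref)), 1)
})

test_that("coincident landmarks are a degenerate alignment problem", {
  frame <- canonical_face_frame(48)
  lm <- canonical_landmarks(48)
  lm$x <- 10
  lm$y <- 10
  expect_error(normalize_face(frame, lm, out_size = 48), "degenerate")
})

test_that("normalization is idempotent on already-normalized frames", {
  frame <- canonical_face_frame(96)
  tmpl <- canonical_landmarks(96)
  once <- normalize_face(frame, tmpl, template = tmpl, out_size = 96)
  twice <- normalize_face(once, tmpl, template = tmpl, out_size = 96)
  expect_lte(max(abs(twice - once)), 1)
})

test_that("cell means reproduce hand-computed values", {
  # constant image: every cell mean equals the constant
  const <- list(matrix(100, 48, 48), matrix(100, 48, 48))
  cs <- cell_intensity_series(const, grid = c(8, 8))
  expect_true(all(cs$X == 100))
  # one pixel per cell: values in row-major order
  f <- matrix(c(0, 20, 10, 30), 2, 2)  # [[0,10],[20,30]] as an image
  cs2 <- cell_intensity_series(list(f, f), grid = c(2, 2))
  expect_equal(unname(cs2$X[, 1]), c(0, 10, 20, 30))
  expect_equal(unname(cs2$X[, 2]), c(0, 10, 20, 30))
})

test_that("cell means equal brute-force block averages", {
  set.seed(42)
  f <- matrix(runif(16, 0, 255), 4, 4)
  cs <- cell_intensity_series(list(f, f + 1), grid = c(2, 2))
  brute <- function(img, i, j)  # grid row i, col j (0-based), 2x2 blocks
    mean(img[(i * 2 + 1):(i * 2 + 2), (j * 2 + 1):(j * 2 + 2)])
  for (i in 0:1) for (j in 0:1) {
    expect_equal(unname(cs$X[i * 2 + j + 1, 1]), brute(f, i, j),
                 tolerance = 1e-12)
    expect_equal(unname(cs$X[i * 2 + j + 1, 2]), brute(f + 1, i, j),
                 tolerance = 1e-12)
  }
})

test_that("cell means conserve the frame mean and refine consistently", {
  set.seed(7)
  frames <- list(matrix(runif(48^2, 0, 255), 48, 48),
                 matrix(runif(48^2, 0, 255), 48, 48))
  coarse <- cell_intensity_series(frames, grid = c(2, 2))
  fine <- cell_intensity_series(frames, grid = c(4, 4))
  for (n in 1:2) {
    expect_equal(mean(coarse$X[, n]), mean(frames[[n]]), tolerance = 1e-9)
    # each 2x2 parent equals the mean of its four 4x4 children
    for (i in 0:1) for (j in 0:1) {
      children <- c((2 * i) * 4 + 2 * j, (2 * i) * 4 + 2 * j + 1,
                    (2 * i + 1) * 4 + 2 * j, (2 * i + 1) * 4 + 2 * j + 1) + 1
      expect_equal(unname(coarse$X[i * 2 + j + 1, n]),
                   mean(fine$X[children, n]),
                   tolerance = 1e-9)
    }
  }
})

test_that("invalid grids and too-short sequences are rejected", {
  f <- matrix(0, 48, 48)
  expect_error(cell_intensity_series(list(f, f), grid = c(7, 8)), "divisible")
  expect_error(cell_intensity_series(list(f), grid = c(8, 8)), "2 frames")
})

test_that("the default partition places eye cells in the upper half-quadrants", {
  part <- partition_faceparts(grid = c(8, 8))
  # cells are row-major, 0-based; left_eye must sit in rows 0-3, cols 0-3
  rows <- (part$parts$left_eye - 1) %/% 8
  cols <- (part$parts$left_eye - 1) %% 8
  expect_true(all(rows <= 3))
  expect_true(all(cols <= 3))
})

test_that("parts are disjoint and composite groups are exact unions", {
  part <- partition_faceparts(grid = c(8, 8))
  all_cells <- unlist(part$parts)
  expect_equal(anyDuplicated(all_cells), 0L)
  expect_identical(part$groups$eyes,
                   sort(c(part$parts$left_eye, part$parts$right_eye)))
  expect_identical(part$groups$mouth_and_nose,
                   sort(c(part$parts$mouth, part$parts$nose)))
  expect_identical(part$groups$cheeks,
                   sort(c(part$parts$left_cheek, part$parts$right_cheek)))
  expect_identical(part$groups$all_parts, sort(unique(all_cells)))
})

test_that("quadrant-sized eye rectangles on a 2x2 grid catch one cell each", {
  layout <- default_part_layout()
  layout$left_eye <- c(x0 = 0, x1 = 0.5, y0 = 0, y1 = 0.5)
  layout$right_eye <- c(x0 = 0.5, x1 = 1, y0 = 0, y1 = 0.5)
  layout$left_cheek <- c(x0 = 0, x1 = 0.5, y0 = 0.5, y1 = 1)
  layout$right_cheek <- c(x0 = 0.5, x1 = 1, y0 = 0.5, y1 = 1)
  layout$nose <- c(x0 = 0, x1 = 0, y0 = 0, y1 = 0)
  layout$mouth <- c(x0 = 1, x1 = 1, y0 = 1, y1 = 1)
  part <- partition_faceparts(grid = c(2, 2), layout = layout)
  expect_length(part$parts$left_eye, 1)
  expect_length(part$parts$right_eye, 1)
})

test_that("overlapping part rectangles are a configuration error", {
  layout <- default_part_layout()
  layout$nose <- c(x0 = 0.3, x1 = 0.7, y0 = 0.4, y1 = 0.8)  # hits cheeks
  expect_error(partition_faceparts(grid = c(8, 8), layout = layout),
               "overlap")
})
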