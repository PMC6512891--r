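# internal helpers: seeded evaluation, similarity fit, bilinear sampling

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Derive k reproducible sub-seeds (< 2^31) from one seed without disturbing
# the caller's RNG state.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, k))
}

#' Least-squares similarity transform between landmark sets
#'
#' Fits the similarity transform (rotation, isotropic scale, translation,
#' no reflection) mapping source points onto destination points by least
#' squares, using the complex-number closed form.
#'
#' @param src,dst Two-column matrices (x, y) of corresponding points.
#' @return A list with the complex coefficient `a`, centroids `p0`, `q0`, and
#'   functions `forward(xy)` / `inverse(xy)` mapping two-column matrices.
#' @keywords internal
fit_similarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2L || nrow(src) != nrow(dst))
    stop_input("need at least 2 corresponding landmarks")
  p <- complex(real = src[, 1], imaginary = src[, 2])
  q <- complex(real = dst[, 1], imaginary = dst[, 2])
  p0 <- mean(p); q0 <- mean(q)
  denom <- sum(Mod(p - p0)^2)
  if (denom < 1e-12)
    stop_input("degenerate landmarks: all source points coincide")
  a <- sum((q - q0) * Conj(p - p0)) / denom
  if (Mod(a) < 1e-12)
    stop_input("degenerate landmarks: transform has zero scale")
  to_xy <- function(z) cbind(Re(z), Im(z))
  list(
    a = a, p0 = p0, q0 = q0, scale = Mod(a),
    forward = function(xy) {
      z <- complex(real = xy[, 1], imaginary = xy[, 2])
      to_xy(a * (z - p0) + q0)
    },
    inverse = function(xy) {
      z <- complex(real = xy[, 1], imaginary = xy[, 2])
      to_xy((z - q0) / a + p0)
    }
  )
}

# Precompute bilinear interpolation indices/weights for sampling an
# nr x nc image at 0-based pixel coordinates (x = column, y = row).
# Out-of-source samples get weight 0 (fill value 0).
bilinear_plan <- function(x, y, nr, nc) {
  j0 <- floor(x); i0 <- floor(y)
  fx <- x - j0; fy <- y - i0
  # clamp index helper: returns linear index or NA when outside
  lin <- function(i, j) {
    ok <- i >= 0 & i <= (nr - 1) & j >= 0 & j <= (nc - 1)
    ifelse(ok, i + j * nr + 1, NA_integer_)
  }
  idx <- cbind(lin(i0, j0), lin(i0, j0 + 1), lin(i0 + 1, j0), lin(i0 + 1, j0 + 1))
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  w[is.na(idx)] <- 0
  idx[is.na(idx)] <- 1L
  list(idx = idx, w = w)
}

bilinear_apply <- function(plan, img) {
  v <- as.numeric(img)
  plan$w[, 1] * v[plan$idx[, 1]] + plan$w[, 2] * v[plan$idx[, 2]] +
    plan$w[, 3] * v[plan$idx[, 3]] + plan$w[, 4] * v[plan$idx[, 4]]
}

# population standard deviation (denominator n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# argmax with ties broken toward the lowest index
which_max_first <- function(x) which(x == max(x))[1L]
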