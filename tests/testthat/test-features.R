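# a model whose scorers read the first cell: class 1 ("norm") likes positive
# values, class 2 ("anger") negative; the rest never win
sign_model <- function(n_cells = 4) {
  W <- matrix(0, 7, n_cells)
  W[1, 1] <- 1
  W[2, 1] <- -1
  b <- c(0, 0, rep(-1e6, 5))
  manual_expression_model(W, b)
}

test_that("two separable expression classes train to perfect accuracy", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 5), 20), matrix(rnorm(40, -5), 20))
  labels <- rep(c("happiness", "sadness"), each = 20)
  m <- train_expression_model(x, labels, seed = 1)
  pred <- dominant_expression(x, m)
  expect_equal(mean(pred == labels), 1)
  # a frame equal to a training exemplar keeps its class
  expect_equal(as.character(dominant_expression(x[1, , drop = FALSE], m)),
               "happiness")
  # absent classes never win
  expect_true(all(as.character(pred) %in% c("happiness", "sadness")))
})

test_that("expression training is deterministic", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 3), 20), matrix(rnorm(40, -3), 20))
  labels <- rep(c("fear", "surprise"), each = 20)
  m1 <- train_expression_model(x, labels, seed = 9)
  m2 <- train_expression_model(x, labels, seed = 9)
  expect_identical(m1$ova$W, m2$ova$W)
  expect_identical(m1$ova$b, m2$ova$b)
})

test_that("single-class or unknown-label training input is rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(train_expression_model(x, rep("norm", 10)), "2 distinct")
  expect_error(train_expression_model(x, rep(c("norm", "smirk"), 5)),
               "unknown expression")
})

test_that("score vectors have length 7 and mismatched input errors", {
  m <- sign_model(4)
  s <- expression_scores(c(1, 0, 0, 0), m)
  expect_length(s, 7)
  expect_true(all(is.finite(s[1:2])))
  expect_error(expression_scores(c(1, 0), m), "does not match")
})

test_that("an all-zero scorer resolves ties to the first class, norm", {
  m <- manual_expression_model(matrix(0, 7, 4), rep(0, 7))
  s <- expression_scores(c(1, 2, 3, 4), m)
  expect_equal(unname(s), rep(0, 7))
  expect_equal(as.character(dominant_expression(matrix(1:4, 1), m)), "norm")
})

test_that("the expression feature is the frame mean of score vectors", {
  m <- sign_model(2)
  # all frames identical -> feature equals that frame's scores
  X1 <- matrix(c(3, 1, 3, 1, 3, 1), nrow = 2)
  f1 <- expression_feature(manual_series(X1), m)
  expect_equal(f1$values, unname(expression_scores(c(3, 1), m)))
  # two frames -> midpoint
  X2 <- cbind(c(4, 0), c(-2, 0))
  f2 <- expression_feature(manual_series(X2), m)
  s <- (expression_scores(c(4, 0), m) + expression_scores(c(-2, 0), m)) / 2
  expect_equal(f2$values, unname(s))
})

test_that("the expression feature matches a brute-force frame loop", {
  set.seed(3)
  tr <- trainingset_cell_features(generate_expression_trainingset(5, 48, seed = 4))
  model <- train_expression_model(tr$x, tr$labels)
  X <- matrix(runif(64 * 100, 0, 255), 64, 100)  # 64 cells, 100 frames
  feat <- expression_feature(manual_series(X), model)
  # independent loop: standardize and score each frame by hand
  acc <- numeric(7)
  for (n in 1:100) {
    z <- (X[, n] - model$ova$center) / model$ova$scale
    acc <- acc + drop(model$ova$W %*% z) + model$ova$b
  }
  expect_equal(feat$values, unname(acc / 100), tolerance = 1e-9)
})

test_that("label transitions are counted along the dominating-label sequence", {
  m <- sign_model(1)
  # signs + + - - +  ->  labels A A B B A -> 2 transitions
  X <- matrix(c(1, 1, -1, -1, 1), nrow = 1)
  expect_equal(label_feature(manual_series(X), m)$values, 2)
  # constant -> 0
  expect_equal(label_feature(manual_series(matrix(1, 1, 5)), m)$values, 0)
  # strictly alternating over N frames -> N - 1
  N <- 11
  Xa <- matrix(rep(c(1, -1), length.out = N), nrow = 1)
  expect_equal(label_feature(manual_series(Xa), m)$values, N - 1)
})

test_that("motion is the population SD of per-frame means", {
  expect_equal(motion_feature(manual_series(matrix(c(0, 10), 1)))$values, 5)
  expect_equal(motion_feature(manual_series(matrix(1:5, 1)))$values, sqrt(2),
               tolerance = 1e-9)
  expect_equal(motion_feature(manual_series(matrix(7, 1, 4)))$values, 0)
  expect_error(motion_feature(manual_series(matrix(1:4, 2)), cells = integer(0)),
               "empty")
})

test_that("combined features concatenate motion first with guarded provenance", {
  mo <- motion_feature(manual_series(matrix(c(0, 1), 1), "p1"))
  la <- label_feature(manual_series(matrix(c(1, -1), 1), "p1"), sign_model(1))
  ml <- combined_feature("motion_label", mo, la)
  expect_equal(ml$values, c(0.5, 1))
  ex <- expression_feature(manual_series(matrix(c(1, 1), 1), "p1"), sign_model(1))
  me <- combined_feature("motion_expression", mo, ex)
  expect_length(me$values, 8)
  expect_equal(me$values[1], 0.5)
  other <- motion_feature(manual_series(matrix(c(0, 1), 1), "p2"))
  expect_error(combined_feature("motion_label", other, la), "provenance")
  expect_error(combined_feature("motion_label", la, la), "motion feature")
})

test_that("intensity scaling scales motion exactly and preserves labels", {
  set.seed(5)
  X <- matrix(runif(4 * 30, 50, 200), 4, 30)
  k <- 3.7
  m0 <- motion_feature(manual_series(X))$values
  mk <- motion_feature(manual_series(k * X))$values
  expect_equal(mk, k * m0, tolerance = 1e-12)
  hom <- sign_model(4)  # zero-bias scorers are homogeneous
  expect_equal(label_feature(manual_series(k * X), hom)$values,
               label_feature(manual_series(X), hom)$values)
})

test_that("expression feature ignores frame order; label feature does not", {
  m <- sign_model(2)
  X <- rbind(c(1, 1, -1, -1), c(0, 0, 0, 0))
  perm <- c(1, 3, 2, 4)  # A B A B after permutation
  f1 <- expression_feature(manual_series(X), m)$values
  f2 <- expression_feature(manual_series(X[, perm]), m)$values
  expect_equal(f1, f2, tolerance = 1e-12)
  l1 <- label_feature(manual_series(X), m)$values        # A A B B -> 1
  l2 <- label_feature(manual_series(X[, perm]), m)$values # A B A B -> 3
  expect_false(l1 == l2)
})

test_that("motion over a composite group equals motion over the explicit union", {
  part <- partition_faceparts(grid = c(8, 8))
  set.seed(6)
  X <- matrix(runif(64 * 20, 0, 255), 64, 20)
  cs <- manual_series(X)
  via_group <- motion_feature(cs, region_cells(part, "eyes"), "eyes")$values
  via_union <- motion_feature(
    cs, sort(c(part$parts$left_eye, part$parts$right_eye)), "eyes")$values
  expect_equal(via_group, via_union, tolerance = 1e-12)
})
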