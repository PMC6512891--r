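test_that("pairwise agreement matches hand counts", {
  m <- cbind(rater_1 = c("full", "full", "blunt", "flat"),
             rater_2 = c("full", "restricted", "blunt", "full"))
  rownames(m) <- sprintf("patient_%03d", 1:4)
  tb <- annotations_from_matrix(m, "range")
  ag <- pairwise_agreement(tb, "range")
  expect_equal(ag["rater_1", "rater_2"], 50)
  expect_equal(unname(diag(ag)), c(100, 100))
  # identical annotations agree fully
  m2 <- cbind(rater_1 = m[, 1], rater_2 = m[, 1])
  rownames(m2) <- rownames(m)
  expect_equal(pairwise_agreement(annotations_from_matrix(m2, "range"),
                                  "range")["rater_1", "rater_2"], 100)
})

test_that("missing annotations are reported with the offending pairs", {
  m <- cbind(rater_1 = c("full", "blunt"), rater_2 = c("full", "flat"))
  rownames(m) <- c("patient_001", "patient_002")
  tb <- annotations_from_matrix(m, "range")
  tb <- tb[-2, ]  # drop (patient_002, rater_1)
  expect_error(pairwise_agreement(tb, "range"), "patient_002, rater_1")
})

test_that("pairwise agreement equals a brute-force comparison loop", {
  set.seed(8)
  for (rep in 1:10) {
    n_pat <- sample(3:20, 1)
    n_rat <- sample(2:6, 1)
    labs <- affect_labels("quality")
    m <- matrix(sample(labs, n_pat * n_rat, TRUE), n_pat, n_rat,
                dimnames = list(sprintf("patient_%03d", 1:n_pat),
                                paste0("rater_", 1:n_rat)))
    ag <- pairwise_agreement(annotations_from_matrix(m, "quality"), "quality")
    for (i in 1:n_rat) for (j in 1:n_rat) {
      hits <- 0
      for (p in 1:n_pat) if (m[p, i] == m[p, j]) hits <- hits + 1
      expect_equal(ag[i, j], 100 * hits / n_pat)
    }
  }
})

test_that("agreement summaries reproduce the published range and subtype values", {
  path <- system.file("extdata", "pilot_agreement_range.csv",
                      package = "affectfar")
  m <- as.matrix(read.csv(path, row.names = 1))
  s <- agreement_summary(m)
  expect_equal(s$mean_rounded, 43)
  expect_equal(s$sd_rounded, 16)
  path2 <- system.file("extdata", "pilot_agreement_subtype.csv",
                       package = "affectfar")
  s2 <- agreement_summary(as.matrix(read.csv(path2, row.names = 1)))
  expect_equal(s2$mean_rounded, 25)
  expect_equal(s2$sd_rounded, 13)
})

test_that("agreement summary handles edge cases and rater reordering", {
  all100 <- matrix(100, 3, 3)
  s <- agreement_summary(all100)
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  expect_error(agreement_summary(matrix(100, 1, 1)), "2 raters")
  path <- system.file("extdata", "pilot_agreement_range.csv",
                      package = "affectfar")
  m <- as.matrix(read.csv(path, row.names = 1))
  perm <- c(4, 1, 5, 3, 2)
  s1 <- agreement_summary(m)
  s2 <- agreement_summary(m[perm, perm])
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
})

test_that("label distributions are percentages with a fixed-order tie rule", {
  labels <- c(rep("blunt", 12), rep("full", 6), rep("flat", 6))
  tb <- data.frame(patient_id = sprintf("patient_%03d", 1:24),
                   rater_id = "rater_1", domain = "range", label = labels)
  d <- label_distribution(tb, "rater_1", "range")
  expect_equal(unname(d$freq["blunt"]), 50)
  expect_equal(sum(d$freq), 100, tolerance = 1e-9)
  expect_equal(d$most_common, "blunt")
  # exact three-way tie resolves by vocabulary order (full before the rest)
  tie <- data.frame(patient_id = sprintf("patient_%03d", 1:24),
                    rater_id = "rater_1", domain = "range",
                    label = rep(c("full", "blunt", "flat"), 8))
  dt <- label_distribution(tie, "rater_1", "range")
  expect_equal(dt$most_common, "full")
  expect_equal(unname(dt$freq["full"]), 100 / 3, tolerance = 1e-9)
  expect_error(label_distribution(tb, "rater_9", "range"), "no annotations")
})

test_that("a constant predictor reduces the model to its baseline", {
  y <- rep(c("a", "b", "c"), 10)
  expect_warning(res <- multinomial_lrt(rep(1, 30), y), "zero-variance")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a strong class separation is detected with high confidence", {
  set.seed(10)
  n <- 100
  y <- sample(c("a", "b", "c"), n, TRUE)
  x <- c(a = -3, b = 0, c = 3)[y] + rnorm(n)
  res <- multinomial_lrt(x, y)
  expect_lt(res$p_value, 0.001)
  expect_true(res$converged)
  expect_equal(res$df, 2L)
})

test_that("degenerate label sets are skipped with a reason", {
  expect_equal(multinomial_lrt(rnorm(10), rep("a", 10))$skipped_reason,
               "single observed class")
  # 12-class subtype logit with 7 predictors at n = 25 cannot be fit
  set.seed(11)
  y <- sample(affect_labels("subtype")[1:6], 25, TRUE)
  res <- multinomial_lrt(matrix(rnorm(25 * 7), 25), y)
  expect_equal(res$skipped_reason, "insufficient n")
})

test_that("the LR statistic is nonnegative and scale-invariant", {
  set.seed(12)
  y <- sample(c("a", "b", "c"), 80, TRUE)
  x <- rnorm(80) + (y == "b")
  r1 <- multinomial_lrt(x, y)
  r2 <- multinomial_lrt(1000 * x + 52, y)
  expect_gte(r1$statistic, 0)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
})

test_that("the face-part grid covers every rater, domain and region", {
  cfg <- tiny_config(seed = 21, n_raters = 3)
  co <- generate_cohort(cfg)
  sl <- lapply(co$videos, function(v)
    cell_intensity_series(normalize_video(v, out_size = 48), c(8, 8)))
  part <- partition_faceparts(c(8, 8))
  rep_ <- facepart_analysis(sl, part, co$annotations)
  expect_s3_class(rep_, "data.frame")
  expect_equal(nrow(rep_), 3 * 3 * 10)  # raters x domains x regions
  expect_setequal(unique(rep_$region), face_regions())
  # p-values, where present, are probabilities
  p <- rep_$p_value[!is.na(rep_$p_value)]
  expect_true(all(p >= 0 & p <= 1))
})
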