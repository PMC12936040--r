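test_that("keypoint matching counts recognized truth points", {
  truth <- tibble::tibble(
    slice_id = c("s1", "s1", "s2"), class = "buccal_dehiscence",
    role = c("ARC", "CEJ", "ARC"), x = c(10, 10, 30), y = c(5, 25, 5),
    pixel_pitch_mm = 0.25)
  pred <- truth
  pred$x <- pred$x + c(1, 1.5, 11)   # 0.25, 0.375, 2.75 mm errors
  m <- match_keypoints(pred, truth, tolerance_mm = 2)
  expect_equal(m$rate, 2 / 3)
  expect_equal(sort(m$distances$dist_mm), c(0.25, 0.375))

  none <- match_keypoints(pred[0, ], truth, 2)
  expect_equal(none$rate, 0)
  expect_equal(nrow(none$distances), 0)

  perfect <- match_keypoints(truth, truth, 2)
  expect_equal(perfect$rate, 1)
  expect_true(all(perfect$distances$dist_mm == 0))
})

test_that("keypoint statistics match the interpolation oracle", {
  s <- keypoint_stats(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$Q1, 1.75)
  expect_equal(s$Q3, 3.25)
  expect_equal(s$AED, 2.5)
  expect_equal(s$SD, sd(1:4))

  expect_message(s1 <- keypoint_stats(5), "single")
  expect_equal(s1$AED, 5); expect_equal(s1$SD, 0)

  eq <- keypoint_stats(rep(2.2, 9))
  expect_equal(eq$SD, 0)
  expect_equal(eq$Q1, eq$Q3)

  expect_error(keypoint_stats(numeric(0)), "no distances")

  set.seed(3)
  for (i in 1:20) {
    x <- runif(sample(2:30, 1))
    s <- keypoint_stats(x)
    expect_lte(s$Q1, s$median); expect_lte(s$median, s$Q3)
    expect_equal(c(s$Q1, s$median, s$Q3),
                 unname(quantile(x, c(.25, .5, .75), type = 7)))
  }
})

test_that("length statistics follow their closed forms", {
  y <- c(1, 2, 3, 4.5)
  s0 <- length_stats(y, y)
  expect_equal(unlist(s0[, c("MAE", "RMSE", "MRE")]), c(MAE = 0, RMSE = 0,
                                                        MRE = 0))
  expect_equal(s0$PCC, 1)

  s1 <- length_stats(y + 0.5, y)
  expect_equal(s1$MAE, 0.5); expect_equal(s1$RMSE, 0.5)
  expect_equal(s1$PCC, 1)
  expect_equal(s1$MRE, mean(0.5 / y))

  s2 <- length_stats(c(2, 1), c(1, 2))
  expect_equal(s2$PCC, -1); expect_equal(s2$MAE, 1)

  expect_warning(length_stats(2, 1), "PCC")

  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    yt <- runif(n, 0.5, 6); yp <- yt + rnorm(n)
    s <- length_stats(yp, yt)
    expect_gte(s$RMSE, s$MAE)   # power-mean inequality
  }
})

test_that("Bland-Altman bias and limits follow the closed forms", {
  y <- c(1, 2, 3)
  expect_equal(unlist(bland_altman(y, y)[, c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))

  b <- bland_altman(y + 1, y)
  expect_equal(b$bias, 1)
  expect_equal(b$loa_low, 1); expect_equal(b$loa_high, 1)

  b2 <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(b2$bias, 0)
  expect_equal(b2$loa_high, 1.96 * sd(c(-1, 1)))
  expect_equal(b2$loa_low, -1.96 * sd(c(-1, 1)))

  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("classification statistics equal brute-force evaluation on random counts", {
  s <- classification_stats(confusion_counts(3, 5, 1, 1))
  expect_equal(s$accuracy, 0.8)
  expect_equal(s$recall, 0.75)
  expect_equal(s$precision, 0.75)
  expect_equal(s$specificity, 5 / 6, tolerance = 1e-4)
  expect_equal(s$F1, 0.75)

  perfect <- classification_stats(confusion_counts(4, 6, 0, 0))
  expect_true(all(unlist(perfect[, c("accuracy", "recall", "precision",
                                     "specificity", "F1")]) == 1))

  zero_tp <- classification_stats(confusion_counts(0, 5, 2, 3))
  expect_equal(zero_tp$recall, 0)
  expect_equal(zero_tp$F1, 0)

  expect_error(classification_stats(confusion_counts(0, 0, 0, 0)), "zero")

  set.seed(11)
  for (i in 1:400) {
    v <- rpois(4, 5)
    if (sum(v) == 0) v[1] <- 1
    s <- classification_stats(confusion_counts(v[1], v[2], v[3], v[4]))
    expect_equal(s$accuracy, (v[1] + v[2]) / sum(v))
    rec <- if (v[1] + v[4] == 0) NA_real_ else v[1] / (v[1] + v[4])
    prec <- if (v[1] + v[3] == 0) NA_real_ else v[1] / (v[1] + v[3])
    expect_equal(s$recall, rec)
    expect_equal(s$precision, prec)
    expect_equal(s$specificity,
                 if (v[2] + v[3] == 0) NA_real_ else v[2] / (v[2] + v[3]))
    if (!is.na(rec) && !is.na(prec) && (rec + prec) > 0) {
      expect_equal(s$F1, 2 * prec * rec / (prec + rec), tolerance = 1e-12)
      # F1 is the harmonic mean of precision and recall
      if (prec > 0 && rec > 0) {
        expect_equal(s$F1, 2 / (1 / prec + 1 / rec), tolerance = 1e-12)
      }
    }
  }
})

test_that("trapezoidal AUC equals exhaustive pairwise concordance", {
  concordance <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (p in pos) for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
    tot / (length(pos) * length(neg))
  }

  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 10), c(F, F, T, T))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 8), c(F, T, F, T, T, F, T, F))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both label classes")

  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.125), n, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auc, concordance(scores, labels),
                 tolerance = 1e-12, label = sprintf("case %d", i))
  }
})

test_that("Cohen's kappa behaves at the anchor points", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  set.seed(9)
  a <- sample(c(0, 1), 2000, replace = TRUE)
  b <- sample(c(0, 1), 2000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.1)
})
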