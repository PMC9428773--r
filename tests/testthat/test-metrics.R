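test_that("confusion matrix counts match a hand tally", {
  y_true <- c("exhalation", "exhalation", "inhalation", "inhalation",
              "nonbreathing", "nonbreathing", "exhalation", "nonbreathing",
              "inhalation")
  y_pred <- c("exhalation", "inhalation", "inhalation", "inhalation",
              "nonbreathing", "exhalation", "exhalation", "nonbreathing",
              "nonbreathing")
  cm <- confusion(y_true, y_pred)
  expect_equal(unname(cm), matrix(c(2, 1, 0,
                                    0, 2, 1,
                                    1, 0, 2), nrow = 3, byrow = TRUE))
  expect_equal(unname(rowSums(cm)), c(3, 3, 3))
  expect_equal(sum(cm), 9)
  # perfect predictions give a diagonal matrix
  expect_equal(sum(confusion(y_true, y_true)) ,
               sum(diag(confusion(y_true, y_true))))
  expect_error(confusion(y_true, y_pred[-1]), "length mismatch")
})

test_that("per-class metrics satisfy the published identities", {
  cm <- confusion(seeded(26, sample(phases, 200, replace = TRUE)),
                  seeded(27, sample(phases, 200, replace = TRUE)))
  rep <- per_class_metrics(cm)
  per <- rep[rep$class %in% phases, ]
  # balanced accuracy identity on every class
  expect_equal(per$balanced_accuracy, (per$recall + per$specificity) / 2)
  # F1 is the harmonic mean of precision and recall
  expect_equal(per$f1, 2 * per$precision * per$recall /
                 (per$precision + per$recall))
  # macro rows equal the column means
  macro <- rep[rep$class == "macro", ]
  expect_equal(macro$recall, mean(per$recall))
  expect_equal(multiclass_balanced_accuracy(rep, "kelleher"), macro$recall)
  expect_equal(multiclass_balanced_accuracy(rep, "urbanowicz"),
               macro$balanced_accuracy)
})

test_that("published worked examples reproduce to printed precision", {
  expect_equal(round(balanced_accuracy(0.71, 0.97), 2), 0.84)
  expect_equal(round(f1_score(0.84, 0.66), 2), 0.74)
  expect_equal(round(mean(c(0.59, 0.40, 0.96)), 2), 0.65)
  expect_equal(round(mean(balanced_accuracy(c(0.59, 0.40, 0.96),
                                            c(0.93, 0.95, 0.63))), 2), 0.74)
})

test_that("zero-denominator metrics surface as NaN with a warning", {
  cm <- matrix(0L, 3, 3, dimnames = list(true = phases, predicted = phases))
  cm[2, 2] <- 5L; cm[3, 3] <- 5L; cm[2, 1] <- 2L # exhalation absent from truth
  expect_warning(rep <- per_class_metrics(cm), "zero denominator")
  expect_true(is.nan(rep$recall[rep$class == "exhalation"]))
  expect_error(suppressWarnings(
    multiclass_balanced_accuracy(per_class_metrics(cm), "kelleher")),
    "exhalation")
  expect_error(per_class_metrics(matrix(0L, 3, 3)), "empty")
})

test_that("AUC equals the rank-statistic oracle and flips with labels", {
  scores <- seeded(28, runif(200))
  labels <- seeded(29, runif(200) < 0.35)
  roc <- roc_auc(scores, labels)
  # Mann-Whitney U / (n1 n2), tie-corrected
  pos <- scores[labels]; neg <- scores[!labels]
  u <- sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))
  expect_equal(roc$auc, u / (length(pos) * length(neg)), tolerance = 1e-9)
  # inverted labels mirror the AUC
  expect_equal(roc_auc(scores, !labels)$auc, 1 - roc$auc, tolerance = 1e-9)
  # endpoints
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE))$auc, 1)
  expect_error(roc_auc(scores, rep(TRUE, 200)), "both classes")
})

test_that("Bland-Altman limits match hand-computed values", {
  x <- c(10, 12, 9, 11, 13)
  y <- c(9, 13, 9, 10, 11)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$lower_limit, mean(d) - 1.96 * sd(d))
  expect_equal(ba$upper_limit, mean(d) + 1.96 * sd(d))
  # identical pairs: zero-width limits
  expect_equal(unlist(bland_altman(x, x)[c("mean_diff", "lower_limit",
                                           "upper_limit")]),
               c(mean_diff = 0, lower_limit = 0, upper_limit = 0))
  # constant offset: mean -c, sd 0
  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$mean_diff, -2)
  expect_equal(ba2$sd_diff, 0)
  expect_error(bland_altman(1, 2), "at least 2")
})
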