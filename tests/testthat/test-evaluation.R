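# build binary vectors realizing a given confusion matrix
cm_vectors <- function(tp, fp, tn, fn) {
  list(y = c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn)),
       pred = c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn)))
}

test_that("confusion-matrix metrics recover the counts and definitions", {
  v <- cm_vectors(tp = 53, fp = 6, tn = 40, fn = 13)
  m <- confusion_and_metrics(v$y, v$pred)
  expect_equal(unname(m$confusion), c(53, 6, 40, 13))
  expect_equal(unname(m$overall["precision"]), 53 / 59)
  expect_equal(unname(m$overall["recall"]), 53 / 66)
  expect_equal(unname(m$overall["specificity"]), 40 / 46)
  expect_equal(unname(m$overall["accuracy"]), 93 / 112)
  perfect <- confusion_and_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_true(all(unlist(perfect$overall) == 1))
  expect_true(all(perfect$per_class[, c("precision", "recall", "f1")] == 1))
  expect_error(confusion_and_metrics(numeric(0), numeric(0)), "empty")
})

test_that("undefined ratios are reported as missing, never silent NaN", {
  m <- confusion_and_metrics(c(1, 1, 0), c(0, 0, 0))  # no positive predictions
  expect_true(is.na(m$overall["precision"]))
  expect_false(any(is.nan(unlist(m$overall))))
})

test_that("per-class recall of the negative class equals overall specificity", {
  for (s in 1:10) {
    y <- withr::with_seed(s, rbinom(60, 1, 0.5))
    p <- withr::with_seed(s + 100, rbinom(60, 1, 0.5))
    if (length(unique(y)) < 2) next
    m <- confusion_and_metrics(y, p)
    expect_equal(m$per_class$recall[m$per_class$class == "remained_MDD"],
                 unname(m$overall["specificity"]))
  }
})

test_that("F1 is the harmonic mean with its fixed points", {
  expect_equal(f1_consistency(0.5, 0.5), 0.5)
  expect_equal(f1_consistency(0.8, 0.8), 0.8)
  expect_true(is.na(f1_consistency(0, 0)))
  p <- c(0.3, 0.6, 0.9); r <- c(0.7, 0.5, 0.2)
  expect_equal(f1_consistency(p, r), 2 * p * r / (p + r))
})

test_that("AUC equals the normalized Mann-Whitney U statistic, ties included", {
  for (s in 1:20) {
    y <- withr::with_seed(s, rbinom(30, 1, 0.5))
    if (length(unique(y)) < 2) next
    score <- withr::with_seed(s + 50, sample(1:8, 30, replace = TRUE))  # heavy ties
    expect_equal(adprogress:::roc_auc(y, score), auc_u_oracle(y, score),
                 tolerance = 1e-12)
  }
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(adprogress:::roc_auc(y, y), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  y <- withr::with_seed(3, rbinom(80, 1, 0.5))
  s <- withr::with_seed(4, rnorm(80))
  a <- adprogress:::roc_auc(y, s)
  expect_equal(adprogress:::roc_auc(y, exp(s)), a)
  expect_equal(adprogress:::roc_auc(y, 5 * s - 2), a)
  expect_equal(adprogress:::roc_auc(y, rank(s)), a)
})

test_that("independent scores give a null AUC near one half", {
  y <- withr::with_seed(5, rbinom(2000, 1, 0.5))
  s <- withr::with_seed(6, rnorm(2000))
  n1 <- sum(y); n0 <- sum(1 - y)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(adprogress:::roc_auc(y, s) - 0.5), 3 * se)
})

test_that("ROC curves run from (0,0) to (1,1) and never decrease", {
  y <- withr::with_seed(7, rbinom(100, 1, 0.5))
  s <- withr::with_seed(8, rnorm(100))
  a <- auc_with_ci(y, s, boot_n = 50, seed = 1)
  r <- a$roc
  expect_equal(unlist(r[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("bootstrap intervals contain the point AUC and narrow with sample size", {
  y_big <- withr::with_seed(9, rbinom(800, 1, 0.5))
  s_big <- withr::with_seed(10, rnorm(800) + y_big)
  small <- 1:100
  a_small <- auc_with_ci(y_big[small], s_big[small], boot_n = 400, seed = 2)
  a_big <- auc_with_ci(y_big, s_big, boot_n = 400, seed = 2)
  expect_true(a_small$ci_lower <= a_small$auc && a_small$auc <= a_small$ci_upper)
  expect_lt(a_big$ci_upper - a_big$ci_lower,
            a_small$ci_upper - a_small$ci_lower)
  # seeded bootstrap is reproducible
  expect_identical(auc_with_ci(y_big[small], s_big[small], boot_n = 100, seed = 3),
                   auc_with_ci(y_big[small], s_big[small], boot_n = 100, seed = 3))
  expect_error(auc_with_ci(rep(1, 10), rnorm(10)), "both outcome classes")
})

test_that("model comparison flags the clinical-relevance line and guards test sets", {
  y <- withr::with_seed(11, rbinom(120, 1, 0.5))
  s <- withr::with_seed(12, rnorm(120))
  r1 <- evaluate_classifier(y, plogis(s + 3 * y), boot_n = 50, seed = 1)
  r2 <- evaluate_classifier(y, plogis(s + 0.5 * y), boot_n = 50, seed = 1)
  cmp <- compare_models(list(strong = r1, weak = r2))
  expect_equal(cmp$auc$clinically_relevant, cmp$auc$auc > 0.80)
  expect_gt(r1$auc$auc, 0.80)  # the strong model crosses the line
  expect_lt(r2$auc$auc, 0.80)
  # identical reports differ nowhere
  cmp2 <- compare_models(list(a = r1, b = r1))
  tab <- cmp2$table
  expect_equal(tab[tab$model == "a", -1], tab[tab$model == "b", -1],
               ignore_attr = TRUE)
  # a report from a different test set is rejected
  r3 <- evaluate_classifier(rev(y), plogis(s), boot_n = 50, seed = 1)
  expect_error(compare_models(list(a = r1, b = r3)), "identical test set")
})
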