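test_that("one-vs-rest confusion counts match hand and brute-force oracles", {
  y <- c("T", "T", "O", "O")
  p <- c("T", "O", "T", "O")
  cm <- ovr_confusion(y, p, "T")
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))

  all_t <- ovr_confusion(rep("T", 5), rep("T", 5), "T")
  expect_equal(all_t$fn + all_t$fp, 0)

  set.seed(40)
  yt <- sample(0:2, 500, replace = TRUE)
  yp <- sample(0:2, 500, replace = TRUE)
  for (target in 0:2) {
    cm <- ovr_confusion(yt, yp, target)
    tp <- fn <- fp <- tn <- 0L
    for (i in 1:500) {
      if (yt[i] == target && yp[i] == target) tp <- tp + 1L
      else if (yt[i] == target) fn <- fn + 1L
      else if (yp[i] == target) fp <- fp + 1L
      else tn <- tn + 1L
    }
    expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
                 c(tp = tp, fn = fn, fp = fp, tn = tn))
    expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 500L)
  }
  expect_error(ovr_confusion(1:3, 1:4, 1), "mismatch")
})

test_that("metrics handle perfect and degenerate matrices by convention", {
  perfect <- metrics_from_confusion(confusion_2x2(10, 0, 0, 25))
  expect_true(all(unlist(perfect) == 1))
  expect_message(m <- metrics_from_confusion(confusion_2x2(0, 0, 0, 10)),
                 "zero denominator")
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$g, 0)
})

test_that("the G-metric is the geometric mean of Se and Sp", {
  expect_equal(g_metric(1, 1), 1)
  expect_equal(g_metric(0.5, 0.5), 0.5)
  expect_equal(g_metric(96.76, 95.97), sqrt(96.76 * 95.97))
})

test_that("weighted summaries reduce correctly and match the naive oracle", {
  m1 <- metrics_from_confusion(confusion_2x2(8, 2, 1, 9))
  expect_equal(weighted_summary(list(m1), 10)[["f1"]], m1$f1)

  m2 <- metrics_from_confusion(confusion_2x2(5, 5, 3, 7))
  eq <- weighted_summary(list(m1, m2), c(4, 4))
  expect_equal(eq[["precision"]], (m1$precision + m2$precision) / 2)

  set.seed(41)
  mets <- lapply(1:3, function(i) {
    metrics_from_confusion(confusion_2x2(sample(50, 1), sample(50, 1),
                                         sample(50, 1), sample(50, 1)))
  })
  sup <- sample(10:100, 3)
  got <- weighted_summary(mets, sup)
  naive <- sum(vapply(mets, `[[`, 0, "recall") * sup) / sum(sup)
  expect_equal(got[["recall"]], naive)
  expect_error(weighted_summary(list(), numeric(0)), "empty")
  expect_error(weighted_summary(mets, c(1, 2, 0)), "positive")
})

test_that("ROC AUC equals exhaustive Mann-Whitney pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(42)
  for (i in 1:10) {
    n <- 200
    y <- rbinom(n, 1, 0.4)
    s <- round(rnorm(n, mean = 0.5 * y), 1)   # rounding forces ties
    r <- roc_auc(s, y)
    expect_equal(r$auc, paircount_auc(s, y), tolerance = 1e-12)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("LOSO folds are subject-disjoint and cover every subject once", {
  d <- gaussian_intensity_data(n_per_class = 30)
  subj <- rep(sprintf("S%02d", 1:3), length.out = length(d$y))
  rep_ <- loso_bhc(d$X, d$y, subj, bhc_spec(select = FALSE))
  expect_equal(rep_$folds, 3)
  expect_equal(nrow(rep_$predictions), length(d$y))
  expect_setequal(unique(rep_$predictions$subject), unique(subj))
  # every row predicted exactly once, in original order
  expect_identical(rep_$predictions$truth, d$y)
  # pooled per-class matrices share one total
  totals <- vapply(rep_$confusion, function(cm) cm$tp + cm$fn + cm$fp + cm$tn, 0)
  expect_true(all(totals == length(d$y)))
  expect_error(loso_bhc(d$X, d$y, rep("S01", length(d$y))), "2 subjects")
})

test_that("a two-subject LOSO run yields two folds", {
  d <- gaussian_intensity_data(n_per_class = 30)
  subj <- rep(c("A", "B"), length.out = length(d$y))
  rep_ <- loso_bhc(d$X, d$y, subj, bhc_spec(select = FALSE))
  expect_equal(rep_$folds, 2)
  expect_true(all(c("phi1", "phi2") %in% names(rep_$auc)))
})

test_that("report serialisation writes the per-class table", {
  d <- gaussian_intensity_data(n_per_class = 30)
  subj <- rep(c("A", "B"), length.out = length(d$y))
  rep_ <- loso_bhc(d$X, d$y, subj, bhc_spec(select = FALSE))
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  write_loso_report(rep_, json_path = jf, csv_path = cf)
  tab <- read.csv(cf)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("tp", "fn", "fp", "tn", "precision", "recall",
                    "accuracy", "f1") %in% names(tab)))
  js <- jsonlite::read_json(jf)
  expect_equal(js$folds, 2)
})
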