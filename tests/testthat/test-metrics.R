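test_that("confusion matrices tally true x predicted counts", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(cm$counts["A", "A"], 1L, ignore_attr = TRUE)
  expect_equal(cm$counts["A", "B"], 1L, ignore_attr = TRUE)
  expect_equal(cm$counts["B", "B"], 1L, ignore_attr = TRUE)
  expect_equal(cm$counts["B", "A"], 0L, ignore_attr = TRUE)

  # row sums are the true-class supports
  expect_equal(unname(rowSums(cm$counts)), c(2, 1))

  perfect <- confusion(c("x", "y", "x"), c("x", "y", "x"))
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  expect_true(all(perfect$counts[lower.tri(perfect$counts)] == 0))

  expect_error(confusion("A", "Z", label_order = "A"), "label 'Z'")
})

test_that("precision/recall/F1 match brute-force counting on random inputs", {
  labs <- c("A", "B", "C", "D")
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    truth <- sample(labs, n, replace = TRUE)
    pred <- sample(labs, n, replace = TRUE)
    cm <- confusion(truth, pred, labs)
    for (lab in labs) {
      got <- class_prf(cm, lab)
      want <- oracle_prf(truth, pred, lab)
      expect_equal(got$precision, want$precision, tolerance = 1e-12)
      expect_equal(got$recall, want$recall, tolerance = 1e-12)
      expect_equal(got$f1, want$f1, tolerance = 1e-12)
    }
  }
})

test_that("known prf values and degenerate conventions hold", {
  # TP=3, FP=1, FN=2 -> precision .75, recall .6, F1 = 0.9/1.35
  truth <- c(rep("A", 5), rep("B", 4))
  pred <- c("A", "A", "A", "B", "B", "A", "B", "B", "B")
  got <- class_prf(confusion(truth, pred, c("A", "B")), "A")
  expect_equal(got$precision, 0.75)
  expect_equal(got$recall, 0.6)
  expect_equal(got$f1, 0.9 / 1.35)

  # class never predicted and never present -> all zeros by convention
  cm <- confusion(c("A", "A"), c("A", "A"), c("A", "ghost"))
  expect_equal(class_prf(cm, "ghost"),
               list(precision = 0, recall = 0, f1 = 0, support = 0),
               ignore_attr = TRUE)

  # all correct for a class -> all ones
  got <- class_prf(confusion(c("A", "B"), c("A", "B")), "A")
  expect_equal(got[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
})

test_that("reports compute accuracy, macro F1 and the self-consistency identity", {
  x <- sample(c("a", "b", "c"), 30, replace = TRUE)
  expect_equal(metrics_report(confusion(x, x))$top1_accuracy, 1)
  expect_equal(metrics_report(confusion(x, x))$macro_f1, 1)

  expect_error(metrics_report(confusion(character(0), character(0), "a")), "empty")

  # micro-averaged F1 is exactly top-1 accuracy in single-label multiclass
  set.seed(7)
  truth <- sample(c("a", "b", "c", "d"), 200, replace = TRUE)
  pred <- sample(c("a", "b", "c", "d"), 200, replace = TRUE)
  cm <- confusion(truth, pred)
  rep_ <- metrics_report(cm)
  tp <- sum(diag(cm$counts))
  fp <- sum(cm$counts) - tp
  micro_f1 <- 2 * tp / (2 * tp + fp + fp)
  expect_equal(micro_f1, rep_$top1_accuracy, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rep_$macro_f1, rep_$top1_accuracy)))
})

test_that("uniform random prediction converges to the 1/K baseline", {
  k <- 5
  labs <- letters[1:k]
  set.seed(31)
  n <- 20000
  truth <- sample(labs, n, replace = TRUE)
  pred <- sample(labs, n, replace = TRUE)
  acc <- metrics_report(confusion(truth, pred, labs))$top1_accuracy
  p <- 1 / k
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))

  # the 55-class analytic baseline, 1.81...% at printed precision
  expect_equal(random_chance_accuracy(55) * 100, 100 / 55)
  expect_lt(abs(random_chance_accuracy(55) * 100 - 1.81), 0.01)
})

test_that("per-class recall tables agree with class_prf and round-trip to CSV", {
  set.seed(12)
  labs <- c("Elk", "Wolf", "Marten")
  truth <- sample(labs, 50, replace = TRUE)
  pred <- sample(labs, 50, replace = TRUE)
  cm <- confusion(truth, pred, labs)
  tr_counts <- c(Elk = 120, Wolf = 45, Marten = 8)
  tbl <- per_class_recall_table(cm, tr_counts, model_name = "ref")
  for (i in seq_len(nrow(tbl))) {
    expect_equal(tbl$ref[i], class_prf(cm, tbl$class_label[i])$recall)
    expect_equal(tbl$n_test[i], sum(truth == tbl$class_label[i]))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  save_recall_table(tbl, path)
  back <- load_recall_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_equal(attr(back, "models"), "ref")

  # empty test class: zero recall at zero support
  cm2 <- confusion(c("Elk", "Elk"), c("Elk", "Elk"), labs)
  tbl2 <- per_class_recall_table(cm2, tr_counts)
  expect_equal(tbl2$model[tbl2$class_label == "Wolf"], 0)
  expect_equal(tbl2$n_test[tbl2$class_label == "Wolf"], 0)
})
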