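test_that("confusion matrices follow the truth-rows convention", {
  cls <- c("a", "b", "c")
  truth <- rep(cls, times = c(3, 3, 4))
  perfect <- confusion_matrix(truth, truth, cls)
  expect_equal(diag(perfect), c(a = 3L, b = 3L, c = 4L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  # predictions rotated one class forward: empty diagonal (hand-counted)
  rot <- cls[match(truth, cls) %% 3 + 1]
  cm <- confusion_matrix(truth, rot, cls)
  expect_equal(unname(diag(cm)), c(0L, 0L, 0L))
  expect_equal(cm["a", "b"], 3L)
  expect_equal(cm["c", "a"], 4L)

  expect_error(confusion_matrix(c("a", "b"), "a", cls), "different lengths")
})

test_that("one-vs-rest counts satisfy the marginal identities", {
  set.seed(10)
  cls <- c("w", "x", "y", "z")
  truth <- sample(cls, 200, TRUE)
  pred <- sample(cls, 200, TRUE)
  cm <- confusion_matrix(truth, pred, cls)
  cnt <- ovr_counts(cm)
  expect_equal(sum(cm), 200)
  expect_equal(cnt$TP, unname(diag(cm)))
  expect_equal(cnt$FP, unname(colSums(cm)) - cnt$TP)
  expect_equal(cnt$FN, unname(rowSums(cm)) - cnt$TP)
  expect_true(all(cnt$TP + cnt$FP + cnt$FN + cnt$TN == 200))
})

test_that("the five metrics match direct substitution", {
  s <- score_counts(list(TP = 90, FN = 10, FP = 0, TN = 100))
  expect_equal(unname(s["recall"]), 0.9)
  expect_equal(unname(s["precision"]), 1)
  expect_equal(unname(s["specificity"]), 1)
  expect_equal(unname(s["accuracy"]), 0.95)
  expect_equal(unname(s["f1"]), 18 / 19)

  perfect <- score_counts(list(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_equal(unname(perfect), rep(1, 5))

  miss <- suppressWarnings(score_counts(list(TP = 0, FN = 7, FP = 0, TN = 3)))
  expect_equal(unname(miss["recall"]), 0)
  expect_equal(unname(miss["f1"]), 0)
})

test_that("all-positive binary predictions give the degenerate counts", {
  truth <- rep(c("pos", "neg"), each = 5)
  pred <- rep("pos", 10)
  cnt <- ovr_counts(confusion_matrix(truth, pred, c("pos", "neg")))
  pos <- cnt[cnt$class == "pos", ]
  expect_equal(c(pos$TP, pos$FP, pos$TN, pos$FN), c(5, 5, 0, 0))
})

test_that("zero denominators yield 0 with a warning, not NaN", {
  w <- capture_warnings(s <- score_counts(list(TP = 0, FN = 0, FP = 0,
                                               TN = 10)))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(unname(s["recall"]), 0)
  expect_equal(unname(s["precision"]), 0)
})

test_that("aggregates behave: constant average, macro mean, micro identity", {
  truth <- c("a", "a", "b", "b")
  rep_perfect <- classification_report(truth, truth, c("a", "b"))
  expect_equal(unname(rep_perfect$macro), rep(1, 5))

  # recalls 1.0 and 0.0 -> macro recall 0.5
  r <- classification_report(c("a", "a", "b"), c("a", "a", "a"), c("a", "b"))
  expect_equal(unname(r$macro["recall"]), 0.5)

  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    cls <- letters[1:k]
    truth <- sample(cls, 300, TRUE)
    pred <- sample(cls, 300, TRUE)
    rp <- suppressWarnings(classification_report(truth, pred, cls))
    acc <- mean(truth == pred)
    expect_equal(unname(rp$micro["precision"]), acc, tolerance = 1e-12)
    expect_equal(unname(rp$micro["recall"]), acc, tolerance = 1e-12)
    # one-vs-rest accuracy dominates plain accuracy when K > 2
    if (k > 2 && acc < 1)
      expect_gte(unname(rp$macro["accuracy"]), acc)
  }
})
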