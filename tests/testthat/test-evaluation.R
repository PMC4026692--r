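test_that("Mann-Whitney AUC handles separation, ties and transforms", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_mann_whitney(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(auc_mann_whitney(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  set.seed(2)
  s <- rnorm(50); y <- rep(c(TRUE, FALSE), 25)
  expect_equal(auc_mann_whitney(s, y), auc_mann_whitney(exp(s), y))
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("weighted multi-class AUC uses test-set class-size weights", {
  truth <- rep(c("NC", "AD", "FTD"), times = c(8, 9, 4))
  n <- length(truth)
  sc <- matrix(0.1, n, 3, dimnames = list(NULL, c("NC", "AD", "FTD")))
  sc[cbind(seq_len(n), match(truth, colnames(sc)))] <- 0.8
  r <- weighted_multiclass_auc(sc, truth)
  expect_equal(unname(r$per_class_auc), c(1, 1, 1))
  expect_equal(unname(r$weights[c("NC", "AD", "FTD")]), c(8, 9, 4) / 21)
  expect_equal(r$weighted_auc, 1)

  # absent class is dropped with renormalised weights
  expect_warning(r2 <- weighted_multiclass_auc(sc[truth != "FTD", ],
                                               truth[truth != "FTD"]),
                 "renormalised")
  expect_equal(sum(r2$weights), 1)

  # weighted equals macro average for balanced classes
  truthb <- rep(c("A", "B", "C"), each = 5)
  set.seed(9)
  scb <- matrix(runif(45), 15, 3, dimnames = list(NULL, c("A", "B", "C")))
  rb <- weighted_multiclass_auc(scb, truthb)
  expect_equal(rb$weighted_auc, mean(rb$per_class_auc), tolerance = 1e-12)
})

test_that("random scores give chance-level weighted AUC", {
  set.seed(31)
  truth <- sample(c("A", "B", "C"), 200, replace = TRUE)
  sc <- matrix(runif(600), 200, 3, dimnames = list(NULL, c("A", "B", "C")))
  sc <- sc / rowSums(sc)
  r <- weighted_multiclass_auc(sc, truth)
  expect_lt(abs(r$weighted_auc - 0.5), 0.07)
})

test_that("a three-class confusion matrix yields exactly six cobweb axes", {
  truth <- rep(c("NC", "AD", "FTD"), each = 4)
  cc <- confusion_and_cobweb(truth, truth)
  expect_length(cc$axes, 6)
  expect_true(all(cc$axes == 0))

  # hand-built counts [[4,1,0],[0,5,1],[2,0,2]]
  tr <- rep(c("A", "B", "C"), times = c(5, 6, 4))
  pr <- c(rep("A", 4), "B",
          rep("B", 5), "C",
          "A", "A", "C", "C")
  cc2 <- confusion_and_cobweb(pr, tr, classes = c("A", "B", "C"))
  expect_equal(unname(cc2$confusion),
               rbind(c(4, 1, 0), c(0, 5, 1), c(2, 0, 2)), ignore_attr = TRUE)
  expect_equal(unname(cc2$axes[c("A -> B", "A -> C", "B -> A", "B -> C",
                                 "C -> A", "C -> B")]),
               c(1 / 5, 0, 0, 1 / 6, 2 / 4, 0))
  # each row: diagonal rate plus its misclassification axes sums to 1
  for (cl in c("A", "B", "C")) {
    others <- setdiff(c("A", "B", "C"), cl)
    expect_equal(cc2$rates[cl, cl] +
                   sum(cc2$axes[paste(cl, "->", others)]), 1,
                 tolerance = 1e-12)
  }
  expect_error(confusion_and_cobweb(c("A", "Z"), c("A", "B"),
                                    classes = c("A", "B")), "unseen")
})

test_that("binary metrics follow their definitions at the argmax rule", {
  truth <- rep(c("P", "N"), times = c(10, 10))
  scores <- c(rep(0.9, 9), 0.1, rep(0.8, 3), rep(0.2, 7))
  m <- binary_metrics(scores, truth, positive = "P")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.7)

  perf <- binary_metrics(c(rep(0.9, 10), rep(0.1, 10)), truth, "P")
  expect_equal(unlist(perf), c(auc = 1, sensitivity = 1, specificity = 1))

  allpos <- binary_metrics(rep(0.9, 20), truth, "P")
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_error(binary_metrics(1:3 / 4, rep("P", 3), "P"), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60, mean = y)
  expect_equal(auc_mann_whitney(s, y == 1),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("cobweb rendering writes a figure and validates its inputs", {
  axes <- c("A -> B" = 0.2, "A -> C" = 0, "B -> A" = 0.1,
            "B -> C" = 0.4, "C -> A" = 0, "C -> B" = 0.3)
  path <- tempfile(fileext = ".png")
  render_cobweb(list(inv = axes, disp = axes / 2), path)
  expect_true(file.exists(path) && file.size(path) > 0)

  zero <- tempfile(fileext = ".png")
  render_cobweb(axes * 0, zero)
  expect_true(file.exists(zero))

  expect_warning(render_cobweb(c(a = 1.2, b = 0.5, c = -0.1),
                               tempfile(fileext = ".png")), "clipped")
  expect_error(render_cobweb(c(a = 1, b = 0), tempfile(fileext = ".png")),
               "3 axes")
})

test_that("full evaluation reports are internally consistent", {
  set.seed(77)
  truth <- rep(c("NC", "AD", "FTD"), times = c(7, 9, 6))
  sc <- matrix(runif(66), 22, 3, dimnames = list(NULL, c("NC", "AD", "FTD")))
  sc <- sc / rowSums(sc)
  rep_ <- evaluate_multiclass(sc, truth)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(sum(rep_$weights), 1)
  expect_equal(sum(rep_$confusion), 22)
  expect_equal(unname(rowSums(rep_$confusion)), c(7, 9, 6))  # NC, AD, FTD
  expect_true(all(rep_$axes >= 0 & rep_$axes <= 1))
})
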