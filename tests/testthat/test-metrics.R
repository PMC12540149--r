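test_that("perfect predictions give unit metrics and a diagonal confusion", {
  y <- rep(nbi_classes(), each = 5)
  post <- diag(4)[rep(1:4, each = 5), ]
  m <- compute_metrics(y, y, post)
  expect_equal(unname(diag(unclass(m$confusion))), rep(5L, 4))
  expect_equal(sum(m$confusion), 20L)
  expect_equal(unname(m$macro), rep(1, 5))
  expect_equal(m$per_class$f1, rep(1, 4))
})

test_that("one-vs-rest counts reproduce the binary fixture", {
  # class Hbv: TP = 3, FP = 1, FN = 1, TN = 5 in a 10-sample problem
  y_true <- c(rep("Hbv", 4), rep("He", 2), rep("IPCL", 2), rep("Le", 2))
  y_pred <- c("Hbv", "Hbv", "Hbv", "He",      # 3 TP, 1 FN
              "Hbv", "He",                    # 1 FP
              "IPCL", "IPCL", "Le", "Le")
  m <- compute_metrics(y_true, y_pred)
  hbv <- m$per_class[m$per_class$class == "Hbv", ]
  expect_equal(hbv$precision, 0.75)
  expect_equal(hbv$recall, 0.75)
  expect_equal(hbv$f1, 0.75)
  expect_equal(hbv$accuracy, 0.8)
})

test_that("a constant predictor on balanced data has macro recall 0.25", {
  y_true <- rep(nbi_classes(), each = 6)
  y_pred <- rep("Hbv", 24)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(unname(m$macro["recall"]), 0.25)
  expect_equal(unname(m$macro["accuracy"]), mean(c(0.25, rep(0.75, 3))))
})

test_that("metrics agree with a brute-force tally on random data", {
  set.seed(55)
  for (rep in 1:4) {
    n <- 250
    y_true <- sample(nbi_classes(), n, replace = TRUE)
    y_pred <- sample(nbi_classes(), n, replace = TRUE)
    m <- compute_metrics(y_true, y_pred)
    for (cl in nbi_classes()) {
      tp <- sum(y_true == cl & y_pred == cl)
      fp <- sum(y_true != cl & y_pred == cl)
      fn <- sum(y_true == cl & y_pred != cl)
      tn <- n - tp - fp - fn
      row <- m$per_class[m$per_class$class == cl, ]
      expect_equal(row$accuracy, (tp + tn) / n)
      expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(row$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
      expect_equal(unclass(m$confusion)[cl, cl], tp)
    }
    # row sums equal class supports; total mass equals n
    expect_equal(unname(rowSums(unclass(m$confusion))),
                 unname(as.vector(table(factor(y_true,
                                               levels = nbi_classes())))))
    expect_equal(sum(m$confusion), n)
    # macro = arithmetic mean of the per-class columns
    expect_equal(unname(m$macro["precision"]), mean(m$per_class$precision))
  }
})

test_that("rank-based AUC matches pROC", {
  library(pROC)
  set.seed(8)
  n <- 120
  y_true <- sample(nbi_classes(), n, replace = TRUE)
  post <- matrix(runif(n * 4), n, 4)
  post <- post / rowSums(post)
  colnames(post) <- nbi_classes()
  m <- compute_metrics(y_true, sample(nbi_classes(), n, TRUE), post)
  for (k in 1:4) {
    ref <- as.numeric(pROC::auc(
      pROC::roc(response = factor(y_true == nbi_classes()[k],
                                  levels = c(FALSE, TRUE)),
                predictor = post[, k], quiet = TRUE,
                direction = "<")))
    expect_equal(m$per_class$auc[k], ref, tolerance = 1e-12)
  }
})

test_that("a class absent from the truth yields NA AUC with a warning", {
  y_true <- rep(c("Hbv", "He", "IPCL"), each = 4)
  y_pred <- y_true
  post <- matrix(0.25, 12, 4, dimnames = list(NULL, nbi_classes()))
  expect_warning(m <- compute_metrics(y_true, y_pred, post),
                 "absent")
  expect_true(is.na(m$per_class$auc[4]))
  expect_false(is.na(m$macro["auc"]))
  expect_error(compute_metrics(c("Hbv", "X"), c("Hbv", "Hbv")),
               class = "nbi_bad_label")
  expect_error(compute_metrics("Hbv", c("Hbv", "He")),
               class = "nbi_shape_error")
})
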