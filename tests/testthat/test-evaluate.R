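# brute-force oracle: recount TP/TN/FP/FN from the raw label vectors for
# every class and apply the metric definitions directly.
brute_metrics <- function(y_true, y_pred, classes) {
  t(vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    f1 <- if (sen + ppv > 0) 2 * ppv * sen / (ppv + sen) else 0
    c(acc = 100 * (tp + tn) / length(y_true), sen = sen, ppv = ppv, f1 = f1)
  }, numeric(4)))
}

test_that("confusion matrices count correctly", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), classes = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))),
               ignore_attr = "class")
  perfect <- confusion_matrix(rep(c("a", "b"), 5), rep(c("a", "b"), 5),
                              c("a", "b"))
  expect_true(all(perfect == diag(c(5L, 5L))))
  empty <- confusion_matrix(character(0), character(0), c("a", "b"))
  expect_true(all(empty == 0L))
  expect_equal(sum(cm), 3)
  expect_error(confusion_matrix(c(0, 3), c(0, 1), c("a", "b")), "out of range")
  expect_error(confusion_matrix(0, c(0, 1), c("a", "b")), "length")
})

test_that("per-class metrics match the brute-force recount on random data", {
  set.seed(8)
  for (rep_i in 1:5) {
    classes <- letters[1:4]
    y_true <- sample(classes, 50, replace = TRUE)
    y_pred <- sample(classes, 50, replace = TRUE)
    rp <- per_class_metrics(confusion_matrix(y_true, y_pred, classes))
    oracle <- brute_metrics(y_true, y_pred, classes)
    expect_equal(as.matrix(rp$per_class[, c("acc", "sen", "ppv", "f1")]),
                 oracle, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(rp$macro_f1, mean(oracle[, "f1"]), tolerance = 1e-12)
    expect_equal(rp$macro_sen, mean(oracle[, "sen"]), tolerance = 1e-12)
    # structural identities
    cm <- rp$confusion
    expect_equal(sum(diag(cm)), sum(y_true == y_pred))
    expect_equal(rowSums(cm), as.numeric(table(factor(y_true, classes))),
                 ignore_attr = TRUE)
  }
})

test_that("degenerate matrices are handled deterministically", {
  cm <- confusion_matrix(c("a", "a"), c("b", "b"), c("a", "b", "c"))
  rp <- per_class_metrics(cm)
  expect_true(rp$zero_division)
  expect_equal(rp$per_class$f1[rp$per_class$class == "c"], 0)
  perfect <- per_class_metrics(confusion_matrix(c("a", "b"), c("a", "b"),
                                                c("a", "b")))
  expect_equal(perfect$overall_acc, 100)
  expect_true(all(perfect$per_class$f1 == 100))
  expect_error(per_class_metrics(matrix(0L, 2, 2)), "empty")
})

test_that("macro scores are arithmetic means, stable for single classes", {
  tab <- data.frame(sen = c(10, 20, 60), ppv = c(30, 40, 50),
                    f1 = c(15, 25, 55))
  expect_equal(unname(macro_scores(tab)), c(30, 40, 95 / 3))
  one <- data.frame(sen = 42, ppv = 61, f1 = 50)
  expect_equal(unname(macro_scores(one)), c(42, 61, 50))
})

test_that("the ablation report tabulates all four model variants", {
  set.seed(12)
  n <- 10
  mk <- function(h, w, n) array(rnorm(h * w * n), c(h, w, n))
  labs <- rep(c("a", "b"), n / 2)
  train <- list(x_single = mk(6, 8, n), x_three = mk(6, 12, n), labels = labs)
  test <- list(x_single = mk(6, 8, 6), x_three = mk(6, 12, 6),
               labels = rep(c("a", "b"), 3))
  tab <- ablation_report(train, test, c("a", "b"),
                         epochs = 1, batch_size = 5, learning_rate = 1e-3,
                         filters = c(2, 4, 8, 16), fc_hidden = 4)
  expect_identical(tab$variant, c("single", "three", "no_se", "full"))
  expect_true(all(is.finite(as.matrix(tab[-1]))))
  expect_true(all(tab$overall_acc >= 0 & tab$overall_acc <= 100))
  # identical seed and data reproduce the table
  tab2 <- ablation_report(train, test, c("a", "b"),
                          epochs = 1, batch_size = 5, learning_rate = 1e-3,
                          filters = c(2, 4, 8, 16), fc_hidden = 4)
  expect_identical(tab, tab2)
})
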