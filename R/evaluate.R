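#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors (character/factor or
#'   0-based integers).
#' @param classes Ordered class list; labels outside it are an error.
#' @return An `L x L` integer matrix of class `confusion_matrix`, rows =
#'   true class, columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, classes) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  to_idx <- function(y) {
    if (is.numeric(y)) {
      if (any(y < 0 | y >= length(classes))) stop("label out of range")
      as.integer(y) + 1L
    } else {
      i <- match(as.character(y), classes)
      if (anyNA(i)) stop("label outside the class list")
      i
    }
  }
  ti <- to_idx(y_true)
  pi_ <- to_idx(y_pred)
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  for (k in seq_along(ti)) cm[ti[k], pi_[k]] <- cm[ti[k], pi_[k]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class and macro classification metrics
#'
#' One-vs-rest accuracy, sensitivity (recall), positive predictive value
#' (precision) and F1 per class, plus their unweighted macro averages and
#' the overall accuracy, all as percentages:
#' `Acc = (TP+TN)/(TN+FP+TP+FN)`, `Sen = TP/(TP+FN)`, `PPV = TP/(TP+FP)`,
#' `F1 = 2*PPV*Sen/(PPV+Sen)`, `Macro-F1 = mean(F1_i)`. Zero denominators
#' yield 0 and set the `zero_division` flag.
#'
#' @param cm A [confusion_matrix()] (or plain square count matrix with
#'   class dimnames).
#' @return An object of class `eval_report`: list with `per_class` (a
#'   data.frame of percentages), `overall_acc`, `macro_sen`, `macro_ppv`,
#'   `macro_f1`, and `zero_division`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  L <- nrow(cm)
  zero_flag <- FALSE
  pct <- function(num, den) {
    if (den == 0) {
      zero_flag <<- TRUE
      0
    } else {
      100 * num / den
    }
  }
  rows <- lapply(seq_len(L), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sen <- pct(tp, tp + fn)
    ppv <- pct(tp, tp + fp)
    f1 <- if (sen + ppv == 0) {
      zero_flag <<- TRUE
      0
    } else {
      2 * ppv * sen / (ppv + sen)
    }
    data.frame(class = classes[i], acc = pct(tp + tn, total),
               sen = sen, ppv = ppv, f1 = f1)
  })
  per_class <- do.call(rbind, rows)
  structure(list(per_class = per_class,
                 overall_acc = 100 * sum(diag(cm)) / total,
                 macro_sen = mean(per_class$sen),
                 macro_ppv = mean(per_class$ppv),
                 macro_f1 = mean(per_class$f1),
                 zero_division = zero_flag,
                 confusion = cm),
            class = "eval_report")
}

#' Macro averages of per-class metrics
#'
#' Unweighted arithmetic means across classes of the sensitivity, PPV and
#' F1 columns (percentages in, percentages out).
#'
#' @param report An `eval_report` or a data.frame with `sen`, `ppv`, `f1`
#'   columns.
#' @return Named numeric vector `macro_sen`, `macro_ppv`, `macro_f1`.
#' @export
macro_scores <- function(report) {
  tab <- if (inherits(report, "eval_report")) report$per_class else report
  c(macro_sen = mean(tab$sen), macro_ppv = mean(tab$ppv),
    macro_f1 = mean(tab$f1))
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat("Classification report (percent)\n")
  tab <- x$per_class
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall Acc %.2f | Macro Sen %.2f | Macro PPV %.2f | Macro-F1 %.2f\n",
              x$overall_acc, x$macro_sen, x$macro_ppv, x$macro_f1))
  if (x$zero_division) cat("note: zero-denominator metrics reported as 0\n")
  invisible(x)
}

#' Ablation comparison of model variants
#'
#' Trains the listed architecture variants on one fixed split and seed and
#' tabulates overall accuracy, macro sensitivity, macro PPV and Macro-F1
#' for each: the full SE model, the multi-input model without SE, and the
#' two single-input branches.
#'
#' @param train,test Lists with `x_single`, `x_three` (spectrogram arrays)
#'   and `labels`.
#' @param classes Ordered class list.
#' @param variants Subset of `c("single", "three", "no_se", "full")`.
#' @param seed Shared training seed.
#' @param ... Further arguments passed to [se_micnn()] (epochs,
#'   batch_size, ...).
#' @return Data frame, one row per variant, percentages.
#' @export
ablation_report <- function(train, test, classes,
                            variants = c("single", "three", "no_se", "full"),
                            seed = 1L, ...) {
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- lapply(variants, function(v) {
    fit <- switch(v,
      single = se_micnn(train$x_single, NULL, train$labels, classes,
                        branches = "single", seed = seed, ...),
      three = se_micnn(NULL, train$x_three, train$labels, classes,
                       branches = "three", seed = seed, ...),
      no_se = se_micnn(train$x_single, train$x_three, train$labels, classes,
                       use_se = FALSE, seed = seed, ...),
      full = se_micnn(train$x_single, train$x_three, train$labels, classes,
                      seed = seed, ...))
    pred <- predict(fit, test$x_single, test$x_three, type = "class")
    rep_ <- per_class_metrics(confusion_matrix(test$labels, pred, classes))
    data.frame(variant = v, overall_acc = rep_$overall_acc,
               macro_sen = rep_$macro_sen, macro_ppv = rep_$macro_ppv,
               macro_f1 = rep_$macro_f1)
  })
  do.call(rbind, rows)
}
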