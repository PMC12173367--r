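#' Stratified beat-wise train/test split
#'
#' Splits a list of samples per class so that each class contributes
#' `round(n_c * test_fraction)` beats (within one sample) to the test
#' side, with seeded membership. Augmentation is applied downstream to the
#' training side only.
#'
#' @param samples List of [dual_sample()] objects.
#' @param test_fraction Test share in `(0, 1)` (default 0.1).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample lists.
#' @export
stratified_split <- function(samples, test_fraction = 0.1, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)")
  }
  labels <- vapply(samples, `[[`, character(1), "label")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("singleton class cannot be split: ",
         paste(names(counts)[counts < 2], collapse = " "))
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in names(counts)) {
      members <- which(labels == cls)
      n_test <- max(1L, min(length(members) - 1L,
                            round_half_up(length(members) * test_fraction)))
      test_idx <- c(test_idx, sample(members, n_test))
    }
  })
  list(train = samples[-test_idx], test = samples[test_idx])
}

#' Convert dual-scale samples to paired spectrogram arrays
#'
#' Computes the Kaiser-window STFT of every segment at both scales and
#' stacks the magnitudes into `(H, W, N)` arrays ready for [se_micnn()].
#' Soft labels from Mixup samples are preserved; hard labels become one-hot
#' rows.
#'
#' @param samples List of [dual_sample()] objects.
#' @param sampling_rate Rate used for window/hop conversion (the native
#'   rate in fixed mode; the nominal 500 Hz for adaptive-resized segments).
#' @param classes Ordered class list.
#' @param cfg An [stft_config()].
#' @return List with `x_single`, `x_three`, `labels` (character vector),
#'   `y` (N x L soft-label matrix) and `augmented` (logical).
#' @export
samples_to_spectrograms <- function(samples, sampling_rate, classes,
                                    cfg = stft_config()) {
  if (length(samples) == 0) stop("no samples")
  sp1 <- stft_spectrogram(samples[[1]]$single_cycle, sampling_rate, cfg)
  sp3 <- stft_spectrogram(samples[[1]]$three_cycle, sampling_rate, cfg)
  n <- length(samples)
  x_single <- array(NA_real_, c(dim(sp1), n))
  x_three <- array(NA_real_, c(dim(sp3), n))
  y <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  labels <- character(n)
  augmented <- logical(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    x_single[, , i] <- stft_spectrogram(s$single_cycle, sampling_rate, cfg)
    x_three[, , i] <- stft_spectrogram(s$three_cycle, sampling_rate, cfg)
    labels[i] <- s$label
    augmented[i] <- isTRUE(attr(s, "augmented"))
    y[i, ] <- if (!is.null(s$soft_label)) {
      s$soft_label[classes]
    } else {
      as.numeric(classes == s$label)
    }
  }
  list(x_single = x_single, x_three = x_three, labels = labels, y = y,
       augmented = augmented)
}

#' Experiment configuration
#'
#' Bundles every stage of the end-to-end pipeline: data source (an on-disk
#' [dataset_spec()] or the synthetic generator), denoising, segmentation
#' layout, STFT, split, Mixup and model settings.
#'
#' @param dataset A [dataset_spec()], or `NULL` to use the generator.
#' @param synth A [synth_config()] for synthetic data.
#' @param n_records Number of synthetic records.
#' @param layout `"mitbih"` (fixed 288/864 cropping at the native rate) or
#'   `"sph"` (adaptive cropping, bicubic resize to 400/1200, nominal
#'   500 Hz spectrograms).
#' @param denoise A [denoise_config()], or `NULL` to skip filtering.
#' @param use_annotations Use annotated R-peaks when present; otherwise
#'   the detector runs.
#' @param stft An [stft_config()].
#' @param test_fraction Test share (0.1 for the beat-wise layout, 0.2
#'   conventionally for the adaptive one).
#' @param mixup A [mixup_config()], or `NULL` to skip augmentation.
#' @param model Named list of [se_micnn()] arguments (epochs, batch_size,
#'   learning_rate, branches, use_se, ...).
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param seed Global seed; stage seeds are derived from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset = NULL, synth = NULL, n_records = 8,
                              layout = c("mitbih", "sph"),
                              denoise = denoise_config(),
                              use_annotations = TRUE,
                              stft = stft_config(), test_fraction = 0.1,
                              mixup = mixup_config(),
                              model = list(epochs = 30, batch_size = 256,
                                           learning_rate = 0.001),
                              out_dir = NULL, seed = 1L) {
  layout <- match.arg(layout)
  if (is.null(dataset) && is.null(synth)) synth <- synth_config()
  structure(list(dataset = dataset, synth = synth, n_records = n_records,
                 layout = layout, denoise = denoise,
                 use_annotations = use_annotations, stft = stft,
                 test_fraction = test_fraction, mixup = mixup,
                 model = model, out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the end-to-end experiment
#'
#' Load or synthesize records, denoise, locate R-peaks, build paired
#' dual-scale samples, split, augment the training side, compute
#' spectrograms, train the SE-multi-input CNN, and evaluate on the held
#' out beats. Artifacts (manifest, metrics, confusion matrix, history and
#' checkpoint) are written under `out_dir` when set.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print stage progress.
#' @return The test-set `eval_report`, with the fitted model in the `fit`
#'   attribute and the split sizes in the `sizes` attribute.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  records <- stage("load", {
    if (!is.null(cfg$dataset)) {
      iter_dataset(cfg$dataset)
    } else {
      synth <- cfg$synth
      synth$seed <- cfg$seed
      generate_dataset(synth, cfg$n_records)
    }
  })
  say("loaded %d records", length(records))
  mode <- if (cfg$layout == "mitbih") "fixed" else "adaptive"
  spec_fs <- if (cfg$layout == "mitbih") records[[1]]$sampling_rate else 500
  samples <- stage("segment", {
    out <- list()
    for (rec in records) {
      x <- rec$samples
      if (!is.null(cfg$denoise)) {
        x <- wavelet_denoise(x, cfg$denoise)
        x <- remove_baseline(x, rec$sampling_rate, cfg$denoise)
      }
      rec$samples <- x
      if (is.null(rec$r_peaks) || !cfg$use_annotations) {
        rec$r_peaks <- detect_r_peaks(x, rec$sampling_rate)
        rec$beat_labels <- NULL   # labels must come from rhythm attribute
      }
      out <- c(out, build_samples(rec, mode))
    }
    out
  })
  if (length(samples) == 0) stop("[segment] no usable beats")
  classes <- if (!is.null(cfg$dataset)) {
    cfg$dataset$label_map$classes
  } else {
    sort(unique(vapply(samples, `[[`, character(1), "label")))
  }
  classes <- intersect(classes,
                       vapply(samples, `[[`, character(1), "label"))
  say("built %d paired samples, %d classes", length(samples), length(classes))
  split <- stage("split", stratified_split(samples, cfg$test_fraction,
                                           seed = cfg$seed + 1L))
  train_samples <- split$train
  if (!is.null(cfg$mixup)) {
    mx <- cfg$mixup
    mx$seed <- cfg$seed + 2L
    train_samples <- stage("augment",
                           augment_training_set(train_samples, mx, classes))
  }
  say("training on %d samples (%d augmented), testing on %d",
      length(train_samples),
      sum(vapply(train_samples, function(s) isTRUE(attr(s, "augmented")),
                 logical(1))),
      length(split$test))
  train <- stage("spectrogram",
                 samples_to_spectrograms(train_samples, spec_fs, classes,
                                         cfg$stft))
  test <- stage("spectrogram",
                samples_to_spectrograms(split$test, spec_fs, classes,
                                        cfg$stft))
  fit <- stage("train", {
    args <- c(list(x_single = train$x_single, x_three = train$x_three,
                   labels = train$y, classes = classes,
                   seed = cfg$seed + 3L, verbose = verbose),
              cfg$model)
    do.call(se_micnn, args)
  })
  pred <- stage("evaluate", predict(fit, test$x_single, test$x_three))
  report <- per_class_metrics(confusion_matrix(test$labels, pred, classes))
  if (!is.null(cfg$out_dir)) {
    stage("write", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      manifest <- list(
        seed = cfg$seed, layout = cfg$layout, classes = classes,
        n_records = length(records), n_train = length(train_samples),
        n_test = length(split$test),
        class_counts = as.list(table(train$labels)),
        model = cfg$model,
        mixup = if (is.null(cfg$mixup)) NULL else cfg$mixup$class_ratios)
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      jsonlite::write_json(
        list(overall_acc = report$overall_acc, macro_sen = report$macro_sen,
             macro_ppv = report$macro_ppv, macro_f1 = report$macro_f1,
             per_class = report$per_class),
        file.path(cfg$out_dir, "metrics.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write.csv(as.data.frame(unclass(report$confusion)),
                file.path(cfg$out_dir, "confusion.csv"))
      write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
                row.names = FALSE)
      save_checkpoint(fit, file.path(cfg$out_dir, "checkpoint.rds"))
    })
  }
  attr(report, "fit") <- fit
  attr(report, "sizes") <- c(train = length(train_samples),
                             test = length(split$test))
  report
}
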