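#' Mixup configuration
#'
#' @param beta_a,beta_b Beta-distribution parameters for the mixing
#'   coefficient epsilon (default `Beta(1, 1)`, i.e. uniform on `[0, 1]`).
#' @param class_ratios Named generation ratios: for class `c` with `n_c`
#'   training samples, `round(r_c * n_c)` new samples are generated
#'   (round-half-up). Defaults to the minority-class scheme S:1, V:0.5,
#'   F:2, all other classes 0.
#' @param inter_class Allow parents from different classes (off by
#'   default; per-class generated counts are only well defined for
#'   same-class parents).
#' @param seed Integer seed for parent sampling and epsilon draws.
#' @return An object of class `mixup_config`.
#' @export
mixup_config <- function(beta_a = 1, beta_b = 1,
                         class_ratios = c(S = 1, V = 0.5, F = 2),
                         inter_class = FALSE, seed = 1L) {
  if (beta_a <= 0 || beta_b <= 0) stop("beta parameters must be positive")
  if (any(class_ratios < 0)) stop("generation ratios must be >= 0")
  structure(list(beta_a = beta_a, beta_b = beta_b,
                 class_ratios = class_ratios, inter_class = inter_class,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mixup_config")
}

# central window of a three-cycle segment: the middle third, which in
# fixed mode (864 -> 288) is exactly the single-cycle window.
central_third <- function(three) {
  len <- length(three) %/% 3
  start <- len + 1
  three[start:(start + len - 1)]
}

#' Mix two dual-scale samples
#'
#' Convex combination of the parents' three-cycle signals,
#' `epsilon * a + (1 - epsilon) * b`; the mixed single-cycle signal is the
#' central cycle extracted from the mixed three-cycle signal, and the soft
#' label is the same convex combination of the parents' one-hot labels.
#'
#' @param a,b [dual_sample()] parents with equal segment lengths.
#' @param epsilon Mixing coefficient in `[0, 1]`.
#' @param classes Ordered class list defining the one-hot encoding.
#' @return A [dual_sample()] whose `soft_label` is the mixed probability
#'   vector and whose `epsilon` attribute records the coefficient.
#' @export
mixup_pair <- function(a, b, epsilon, classes) {
  if (length(a$three_cycle) != length(b$three_cycle)) {
    stop("parents have mismatched segment lengths")
  }
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  three <- epsilon * a$three_cycle + (1 - epsilon) * b$three_cycle
  onehot <- function(lab) as.numeric(classes == lab)
  soft <- epsilon * onehot(a$label) + (1 - epsilon) * onehot(b$label)
  names(soft) <- classes
  lab <- classes[which.max(soft)]
  out <- dual_sample(central_third(three), three,
                     center_r = NA_integer_, label = lab, soft_label = soft)
  attr(out, "epsilon") <- epsilon
  attr(out, "augmented") <- TRUE
  out
}

#' Mixup oversampling of minority classes
#'
#' For every class `c` with generation ratio `r_c > 0`, appends
#' `round(r_c * n_c)` new samples (round-half-up), each mixing two distinct
#' same-class parents drawn with a seeded sampler. Original samples are
#' returned untouched ahead of the generated ones; generated samples carry
#' an `augmented` attribute. With same-class parents the soft label stays
#' one-hot.
#'
#' @param samples List of [dual_sample()] (a training split).
#' @param cfg A [mixup_config()].
#' @param classes Ordered class list for the one-hot encoding; defaults to
#'   the sorted labels present.
#' @return Augmented list of samples.
#' @export
augment_training_set <- function(samples, cfg = mixup_config(),
                                 classes = NULL) {
  labels <- vapply(samples, `[[`, character(1), "label")
  if (is.null(classes)) classes <- sort(unique(labels))
  ratios <- cfg$class_ratios[intersect(names(cfg$class_ratios), classes)]
  ratios <- ratios[ratios > 0]
  new_samples <- list()
  with_seed(cfg$seed, {
    for (cls in names(ratios)) {
      members <- which(labels == cls)
      n_new <- round_half_up(ratios[[cls]] * length(members))
      if (n_new == 0) next
      if (length(members) < 2) {
        stop("class '", cls, "' has fewer than 2 members; cannot mix")
      }
      for (k in seq_len(n_new)) {
        pool <- if (cfg$inter_class) seq_along(samples) else members
        pair <- sample(pool, 2, replace = FALSE)
        eps <- rbeta(1, cfg$beta_a, cfg$beta_b)
        new_samples[[length(new_samples) + 1L]] <-
          mixup_pair(samples[[pair[1]]], samples[[pair[2]]], eps, classes)
      }
    }
  })
  c(samples, new_samples)
}

#' Post-augmentation class counts
#'
#' The counting law behind minority oversampling:
#' `n_c + round(r_c * n_c)` per class (round-half-up).
#'
#' @param class_counts Named integer vector of pre-augmentation counts.
#' @param class_ratios Named generation ratios (classes absent get 0).
#' @return Named integer vector of post-augmentation counts.
#' @export
augmented_counts <- function(class_counts, class_ratios) {
  r <- class_ratios[names(class_counts)]
  r[is.na(r)] <- 0
  out <- as.integer(class_counts + round_half_up(r * class_counts))
  names(out) <- names(class_counts)
  out
}
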