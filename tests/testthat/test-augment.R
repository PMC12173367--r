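make_parents <- function(labels, len3 = 864) {
  lapply(seq_along(labels), function(i) {
    three <- rnorm(len3)
    dual_sample(three[(len3 / 3 + 1):(2 * len3 / 3)], three, i, labels[i])
  })
}

test_that("mixing is a convex combination with matching soft label", {
  classes <- c("N", "S", "V")
  ps <- make_parents(c("S", "V"))
  a <- ps[[1]]; b <- ps[[2]]
  m1 <- mixup_pair(a, b, 1, classes)
  expect_equal(m1$three_cycle, a$three_cycle)
  expect_equal(unname(m1$soft_label), c(0, 1, 0))
  m0 <- mixup_pair(a, b, 0, classes)
  expect_equal(m0$three_cycle, b$three_cycle)
  expect_equal(unname(m0$soft_label), c(0, 0, 1))
  neg <- dual_sample(-a$single_cycle, -a$three_cycle, 2, "V")
  mz <- mixup_pair(a, neg, 0.5, classes)
  expect_equal(max(abs(mz$three_cycle)), 0)
  # every mixed value lies within the parents' envelope
  m <- mixup_pair(a, b, 0.37, classes)
  expect_true(all(m$three_cycle >= pmin(a$three_cycle, b$three_cycle) - 1e-12))
  expect_true(all(m$three_cycle <= pmax(a$three_cycle, b$three_cycle) + 1e-12))
  # the mixed single-cycle is the epsilon-mix of the parents' single-cycles
  expect_equal(m$single_cycle, 0.37 * a$single_cycle + 0.63 * b$single_cycle)
  expect_error(mixup_pair(a, dual_sample(rnorm(10), rnorm(30), 1, "V"), 0.5,
                          classes), "mismatch")
})

test_that("the counting law reproduces the minority-class table", {
  counts <- c(N = 79519, S = 2486, V = 6459, F = 718, Q = 3496)
  after <- augmented_counts(counts, c(S = 1, V = 0.5, F = 2))
  expect_identical(unname(after),
                   c(79519L, 4972L, 9689L, 2154L, 3496L))
})

test_that("augmentation appends round(r*n) same-class mixes and keeps originals", {
  labels <- c(rep("N", 9), rep("S", 5), rep("V", 4), rep("F", 2))
  ps <- make_parents(labels, len3 = 90)
  out <- augment_training_set(ps, mixup_config(seed = 3), classes = c("F", "N", "S", "V"))
  expect_identical(out[seq_along(ps)], ps)
  new <- out[-seq_along(ps)]
  new_labs <- vapply(new, `[[`, character(1), "label")
  expect_equal(sum(new_labs == "S"), 5)   # round(1 * 5)
  expect_equal(sum(new_labs == "V"), 2)   # round(0.5 * 4)
  expect_equal(sum(new_labs == "F"), 4)   # round(2 * 2)
  expect_true(all(vapply(new, function(s) isTRUE(attr(s, "augmented")), logical(1))))
  # intra-class mixing keeps one-hot labels
  softs <- vapply(new, function(s) max(s$soft_label), numeric(1))
  expect_true(all(softs == 1))
  # ratio 1 on a 2-member class gives 2 new, 4 total
  two <- make_parents(c("S", "S"), len3 = 30)
  expect_length(augment_training_set(two, mixup_config(class_ratios = c(S = 1), seed = 1),
                                     classes = c("N", "S")), 4)
  # all-zero ratios: identity
  expect_identical(augment_training_set(ps, mixup_config(class_ratios = c(S = 0)),
                                        classes = c("F", "N", "S", "V")), ps)
  # too-small class errors
  expect_error(augment_training_set(make_parents(c("F", "N"), len3 = 30),
                                    mixup_config(class_ratios = c(F = 1)),
                                    classes = c("F", "N")), "fewer than 2")
})

test_that("augmentation is seed-reproducible", {
  ps <- make_parents(rep(c("S", "V"), each = 4), len3 = 60)
  cfg <- mixup_config(seed = 42)
  expect_identical(augment_training_set(ps, cfg, c("S", "V")),
                   augment_training_set(ps, cfg, c("S", "V")))
})

test_that("the mixing coefficient is uniform on [0, 1]", {
  ps <- make_parents(rep("S", 40), len3 = 30)
  cfg <- mixup_config(class_ratios = c(S = 250), seed = 11)
  out <- augment_training_set(ps, cfg, classes = c("N", "S"))
  eps <- vapply(out[-seq_along(ps)], function(s) attr(s, "epsilon"), numeric(1))
  expect_length(eps, 10000)
  ks <- suppressWarnings(stats::ks.test(eps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
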