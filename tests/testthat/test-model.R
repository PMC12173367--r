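test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(42)
  n <- 2
  xa <- array(rnorm(6 * 8 * 1 * n), c(6, 8, 1, n))
  xb <- array(rnorm(6 * 12 * 1 * n), c(6, 12, 1, n))
  y <- matrix(0, 3, n); y[1, 1] <- 0.7; y[2, 1] <- 0.3; y[3, 2] <- 1
  eps <- 1e-6
  for (v in list(list(br = "both", se = TRUE), list(br = "single", se = TRUE),
                 list(br = "three", se = TRUE), list(br = "both", se = FALSE))) {
    meta <- tiny_meta(v$br, v$se)
    params <- ecgbeatnet:::micnn_init_params(meta)
    # jitter away from the zero-bias init: with biases exactly 0, dead
    # ReLU regions put pre-activations exactly on the kink, where the
    # subgradient and the central difference legitimately disagree
    params <- lapply(params, function(p) p + rnorm(length(p), 0, 0.05))
    lg <- ecgbeatnet:::micnn_loss_grad(params, meta, xa, xb, y)
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (ecgbeatnet:::micnn_loss_grad(pp, meta, xa, xb, y)$loss -
                ecgbeatnet:::micnn_loss_grad(pm, meta, xa, xb, y)$loss) / (2 * eps)
        ana <- lg$grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("the SE block matches a hand-computed squeeze/excite/scale", {
  a <- array(c(1, 3, 2, 4, 0, -1, 1, 2), c(2, 2, 2, 1))
  par <- list(W1 = matrix(c(0.5, -1), 1, 2), b1 = matrix(0.2, 1, 1),
              W2 = matrix(c(1, -0.5), 2, 1), b2 = matrix(c(0, 0.1), 2, 1))
  got <- ecgbeatnet:::se_fw(a, par)
  s <- c(mean(a[, , 1, 1]), mean(a[, , 2, 1]))          # 2.5, 0.5
  h <- max(0, 0.5 * s[1] - 1 * s[2] + 0.2)              # 0.95
  z <- 1 / (1 + exp(-c(1 * h + 0, -0.5 * h + 0.1)))
  expect_equal(as.numeric(got$s), s)
  expect_equal(as.numeric(got$h), h)
  expect_equal(as.numeric(got$z), z)
  expect_equal(got$out[, , 1, 1], a[, , 1, 1] * z[1])
  expect_equal(got$out[, , 2, 1], a[, , 2, 1] * z[2])
  # zero weights force a gate of exactly 0.5
  par0 <- list(W1 = matrix(0, 1, 2), b1 = matrix(0, 1, 1),
               W2 = matrix(0, 2, 1), b2 = matrix(0, 2, 1))
  expect_equal(ecgbeatnet:::se_fw(a, par0)$out, a * 0.5)
  # the sigmoid gate never increases channel magnitude
  set.seed(1)
  big <- array(rnorm(4 * 5 * 2 * 3), c(4, 5, 2, 3))
  parr <- list(W1 = matrix(rnorm(2), 1, 2), b1 = matrix(rnorm(1)),
               W2 = matrix(rnorm(2), 2, 1), b2 = matrix(rnorm(2)))
  out <- ecgbeatnet:::se_fw(big, parr)$out
  expect_true(all(abs(out) <= abs(big)))
})

test_that("branch and fusion shapes meet the contract for both layouts", {
  for (dims in list(list(a = c(72, 55), b = c(72, 199), flat = 126720),
                    list(a = c(100, 61), b = c(100, 221), flat = 195200))) {
    meta <- ecgbeatnet:::micnn_meta(dims$a, dims$b, 4, c(4, 8, 16, 32),
                                    c(3, 5), 2, 64, "both", TRUE)
    expect_equal(meta$flat_dim, dims$flat)
    set.seed(2)
    params <- ecgbeatnet:::micnn_init_params(meta)
    xa <- array(rnorm(prod(dims$a)), c(dims$a, 1, 1))
    xb <- array(rnorm(prod(dims$b)), c(dims$b, 1, 1))
    cache <- ecgbeatnet:::micnn_forward(params, meta, xa, xb)
    expect_equal(dim(cache$A$out), c(dims$a, 32, 1))
    expect_equal(dim(cache$B$out), c(dims$b, 32, 1))
    expect_equal(dim(cache$probs), c(4, 1))
    expect_equal(colSums(cache$probs), 1, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("feature-map fusion resize preserves constants and identity", {
  Rr <- ecgbeatnet:::cubic_resize_matrix(6, 6)
  expect_equal(Rr, diag(6), tolerance = 1e-12)
  Rc <- ecgbeatnet:::cubic_resize_matrix(20, 7)
  fb <- array(0, c(6, 20, 3, 2))
  for (c_ in 1:3) fb[, , c_, ] <- c_ * 1.5
  out <- ecgbeatnet:::resize_maps(fb, Rr, Rc)
  expect_equal(dim(out), c(6, 7, 3, 2))
  for (c_ in 1:3) expect_true(all(abs(out[, , c_, ] - c_ * 1.5) < 1e-12))
  # identity resize: fused equals plain element-wise sum
  fa <- array(rnorm(6 * 20 * 3 * 2), c(6, 20, 3, 2))
  same <- ecgbeatnet:::resize_maps(fa, diag(6), diag(20))
  expect_equal(same, fa, ignore_attr = TRUE)
})

test_that("training is seed-deterministic and a zero learning rate is a null update", {
  d <- list(xa = array(rnorm(6 * 8 * 6), c(6, 8, 6)),
            xb = array(rnorm(6 * 12 * 6), c(6, 12, 6)),
            lab = rep(c("a", "b", "c"), 2))
  fit_args <- list(x_single = d$xa, x_three = d$xb, labels = d$lab,
                   classes = c("a", "b", "c"), filters = c(2, 4, 8, 16),
                   fc_hidden = 5, batch_size = 4, seed = 9)
  f1 <- do.call(se_micnn, c(fit_args, epochs = 1, learning_rate = 0))
  f2 <- do.call(se_micnn, c(fit_args, epochs = 3, learning_rate = 0))
  expect_identical(f1$params, f2$params)
  f3 <- do.call(se_micnn, c(fit_args, epochs = 1, learning_rate = 1e-3))
  expect_false(identical(f1$params, f3$params))
  f4 <- do.call(se_micnn, c(fit_args, epochs = 1, learning_rate = 1e-3))
  expect_identical(f3$params, f4$params)
  # prediction is a pure function of the parameters
  p1 <- predict(f3, d$xa, d$xb, type = "prob")
  p2 <- predict(f3, d$xa, d$xb, type = "prob")
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-6)
})

test_that("soft labels, history bookkeeping and checkpoints behave", {
  set.seed(3)
  n <- 6
  y <- matrix(runif(n * 3), n, 3)
  y <- y / rowSums(y)
  colnames(y) <- c("a", "b", "c")
  fit <- se_micnn(array(rnorm(6 * 8 * n), c(6, 8, n)),
                  array(rnorm(6 * 12 * n), c(6, 12, n)), y,
                  filters = c(2, 4, 8, 16), fc_hidden = 5,
                  epochs = 2, batch_size = 4, seed = 1)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$loss)))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  xa <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  xb <- array(rnorm(6 * 12 * 2), c(6, 12, 2))
  expect_identical(predict(fit, xa, xb, type = "prob"),
                   predict(back, xa, xb, type = "prob"))
})

test_that("the network has the capacity to fit a small labelled subset", {
  rec <- generate_record(synth_config(n_beats = 16, seed = 6))
  samples <- build_samples(rec, "fixed")
  d <- samples_to_spectrograms(samples, 360, c("F", "N", "Q", "S", "V"))
  fit <- se_micnn(d$x_single, d$x_three, d$labels,
                  c("F", "N", "Q", "S", "V"), epochs = 8, batch_size = 4,
                  learning_rate = 1e-3, precision = "single", seed = 2)
  pred <- predict(fit, d$x_single, d$x_three)
  expect_equal(mean(pred == d$labels), 1)
  # loss decreases over training
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("per-epoch validation metrics are tracked when requested", {
  set.seed(4)
  mk <- function(n) list(x_single = array(rnorm(6 * 8 * n), c(6, 8, n)),
                         x_three = array(rnorm(6 * 12 * n), c(6, 12, n)),
                         labels = rep(c("a", "b"), n / 2))
  tr <- mk(6); va <- mk(4)
  fit <- se_micnn(tr$x_single, tr$x_three, tr$labels, c("a", "b"),
                  epochs = 2, batch_size = 3, learning_rate = 1e-3,
                  filters = c(2, 4, 8, 16), fc_hidden = 4,
                  validation = va, seed = 1)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(fit$history$val_acc >= 0 & fit$history$val_acc <= 1))
})
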