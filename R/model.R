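# The SE-multi-input CNN: two parallel convolutional branches over the
# single-cycle and three-cycle spectrograms (3x3 and 5x5 kernels; filter
# counts 4, 8, 16, 32; same padding, stride 1, no pooling), SE channel
# attention after conv layers 3 and 4 of each branch (FC widths C/2 and C,
# i.e. 8/16 and 16/32 at the defaults), bicubic resize of the three-cycle
# branch's feature maps to the single-cycle spatial size followed by
# element-wise summation, per-channel feature normalization, then a
# 64-unit fully connected layer and a softmax head.

micnn_meta <- function(dim_a, dim_b, n_classes, filters, kernel_sizes,
                       se_reduction, fc_hidden, branches, use_se,
                       precision = "double") {
  if (length(filters) != 4 || any(diff(filters) <= 0)) {
    stop("filters must be four strictly increasing counts")
  }
  if (use_se && any(filters[3:4] %% se_reduction != 0)) {
    stop("SE reduction must divide the channel counts at layers 3 and 4")
  }
  out_dim <- switch(branches, three = dim_b, dim_a)
  meta <- list(dim_a = dim_a, dim_b = dim_b, n_classes = n_classes,
               filters = filters, kernel_sizes = kernel_sizes,
               se_reduction = se_reduction, fc_hidden = fc_hidden,
               branches = branches, use_se = use_se,
               single = identical(precision, "single"),
               out_dim = out_dim,
               flat_dim = prod(out_dim) * filters[4])
  if (branches == "both") {
    meta$Rr <- cubic_resize_matrix(dim_b[1], dim_a[1])
    meta$Rc <- cubic_resize_matrix(dim_b[2], dim_a[2])
  }
  meta
}

micnn_init_params <- function(meta) {
  params <- list()
  add_branch <- function(prefix, kh) {
    cin <- c(1, meta$filters[1:3])
    for (i in 1:4) {
      K <- kh * kh * cin[i]
      params[[paste0(prefix, ".c", i, ".w")]] <<-
        he_mat(K, meta$filters[i], K)
      params[[paste0(prefix, ".c", i, ".b")]] <<-
        matrix(0, meta$filters[i], 1)
    }
    # SE parameters are always drawn (and dropped when the variant does
    # not use them) so that SE and no-SE models share identical
    # initializations of the common layers under one seed: ablation
    # comparisons are then paired.
    for (lay in c(3, 4)) {
      C <- meta$filters[lay]
      r <- C %/% meta$se_reduction
      params[[paste0(prefix, ".se", lay, ".W1")]] <<- he_mat(r, C, C)
      params[[paste0(prefix, ".se", lay, ".b1")]] <<- matrix(0, r, 1)
      params[[paste0(prefix, ".se", lay, ".W2")]] <<- he_mat(C, r, r)
      params[[paste0(prefix, ".se", lay, ".b2")]] <<- matrix(0, C, 1)
    }
  }
  if (meta$branches %in% c("both", "single")) add_branch("A", meta$kernel_sizes[1])
  if (meta$branches %in% c("both", "three")) add_branch("B", meta$kernel_sizes[2])
  params$fuse.gamma <- rep(1, meta$filters[4])
  params$fuse.beta <- rep(0, meta$filters[4])
  params$head.W1 <- he_mat(meta$fc_hidden, meta$flat_dim, meta$flat_dim)
  params$head.b1 <- matrix(0, meta$fc_hidden, 1)
  params$head.W2 <- he_mat(meta$n_classes, meta$fc_hidden, meta$fc_hidden)
  params$head.b2 <- matrix(0, meta$n_classes, 1)
  if (!meta$use_se) params <- params[!grepl("\\.se[34]\\.", names(params))]
  params
}

se_pars <- function(params, prefix, lay) {
  list(W1 = params[[paste0(prefix, ".se", lay, ".W1")]],
       b1 = params[[paste0(prefix, ".se", lay, ".b1")]],
       W2 = params[[paste0(prefix, ".se", lay, ".W2")]],
       b2 = params[[paste0(prefix, ".se", lay, ".b2")]])
}

branch_fw <- function(params, meta, prefix, x, kh) {
  cache <- list(x = x)
  cur <- x
  for (i in 1:4) {
    a <- conv_fw(cur, params[[paste0(prefix, ".c", i, ".w")]],
                 params[[paste0(prefix, ".c", i, ".b")]], kh, kh,
                 relu = TRUE, single = isTRUE(meta$single))
    cache[[paste0("a", i)]] <- a
    if (meta$use_se && i >= 3) {
      se <- se_fw(a, se_pars(params, prefix, i))
      cache[[paste0("se", i)]] <- se[c("s", "h", "z")]
      cur <- se$out
      cache[[paste0("s", i)]] <- cur
    } else {
      cur <- a
    }
  }
  cache$out <- cur
  cache
}

branch_bw <- function(params, meta, prefix, cache, dout, kh) {
  grads <- list()
  dcur <- dout
  for (i in 4:1) {
    if (meta$use_se && i >= 3) {
      sb <- se_bw(dcur, cache[[paste0("a", i)]], cache[[paste0("se", i)]],
                  se_pars(params, prefix, i))
      grads[[paste0(prefix, ".se", i, ".W1")]] <- sb$dW1
      grads[[paste0(prefix, ".se", i, ".b1")]] <- sb$db1
      grads[[paste0(prefix, ".se", i, ".W2")]] <- sb$dW2
      grads[[paste0(prefix, ".se", i, ".b2")]] <- sb$db2
      dcur <- sb$dx
    }
    dcur <- cpp_relu_backward(dcur, cache[[paste0("a", i)]])
    below <- if (i == 1) {
      cache$x
    } else if (meta$use_se && i - 1 >= 3) {
      cache[[paste0("s", i - 1)]]
    } else {
      cache[[paste0("a", i - 1)]]
    }
    cb <- conv_bw(below, params[[paste0(prefix, ".c", i, ".w")]], dcur, kh, kh,
                  single = isTRUE(meta$single))
    grads[[paste0(prefix, ".c", i, ".w")]] <- cb$dw
    grads[[paste0(prefix, ".c", i, ".b")]] <- matrix(cb$db)
    dcur <- cb$dx
  }
  list(grads = grads, dx = dcur)
}

micnn_forward <- function(params, meta, xa, xb) {
  cache <- list()
  if (meta$branches %in% c("both", "single")) {
    cache$A <- branch_fw(params, meta, "A", xa, meta$kernel_sizes[1])
  }
  if (meta$branches %in% c("both", "three")) {
    cache$B <- branch_fw(params, meta, "B", xb, meta$kernel_sizes[2])
  }
  fused <- switch(meta$branches,
    both = cache$A$out + resize_maps(cache$B$out, meta$Rr, meta$Rc),
    single = cache$A$out,
    three = cache$B$out)
  inz <- inorm_fw(fused, params$fuse.gamma, params$fuse.beta)
  cache$fused_dim <- dim(fused)
  cache$inorm <- inz[c("xhat", "sd")]
  n <- dim(inz$out)[4]
  flat <- matrix(inz$out, meta$flat_dim, n)
  cache$flat <- flat
  z1 <- params$head.W1 %*% flat + params$head.b1[, rep(1, n), drop = FALSE]
  a1 <- relu(z1)
  cache$a1 <- a1
  logits <- params$head.W2 %*% a1 + params$head.b2[, rep(1, n), drop = FALSE]
  cache$probs <- softmax_cols(logits)
  cache
}

# Cross-entropy against soft targets; returns loss, full gradient list and
# class probabilities for the batch.
micnn_loss_grad <- function(params, meta, xa, xb, y) {
  cache <- micnn_forward(params, meta, xa, xb)
  p <- cache$probs
  n <- ncol(p)
  loss <- -sum(y * log(pmax(p, 1e-12))) / n
  dlogits <- (p - y) / n
  grads <- list()
  grads$head.W2 <- dlogits %*% t(cache$a1)
  grads$head.b2 <- matrix(rowSums(dlogits))
  da1 <- t(params$head.W2) %*% dlogits
  dz1 <- da1 * (cache$a1 > 0)
  grads$head.W1 <- dz1 %*% t(cache$flat)
  grads$head.b1 <- matrix(rowSums(dz1))
  dflat <- t(params$head.W1) %*% dz1
  dnorm <- array(dflat, cache$fused_dim)
  ib <- inorm_bw(dnorm, cache$inorm, params$fuse.gamma, cache$fused_dim)
  grads$fuse.gamma <- ib$dgamma
  grads$fuse.beta <- ib$dbeta
  dfused <- ib$dx
  if (meta$branches %in% c("both", "single")) {
    ba <- branch_bw(params, meta, "A", cache$A, dfused, meta$kernel_sizes[1])
    grads <- c(grads, ba$grads)
  }
  if (meta$branches %in% c("both", "three")) {
    db_out <- if (meta$branches == "both") {
      resize_maps(dfused, t(meta$Rr), t(meta$Rc))
    } else {
      dfused
    }
    bb <- branch_bw(params, meta, "B", cache$B, db_out, meta$kernel_sizes[2])
    grads <- c(grads, bb$grads)
  }
  list(loss = loss, grads = grads, probs = p)
}

# z-score each spectrogram: (H, W, N) -> same, per-sample standardization.
standardize_specs <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  sd_ <- sqrt(pmax(colMeans(m^2) - mu^2, 0)) + 1e-8
  array((m - rep(mu, each = d[1] * d[2])) / rep(sd_, each = d[1] * d[2]), d)
}

labels_to_soft <- function(labels, classes) {
  if (is.matrix(labels)) {
    if (ncol(labels) != length(classes)) {
      stop("soft-label matrix must have one column per class")
    }
    t(labels)
  } else {
    y <- matrix(0, length(classes), length(labels))
    idx <- match(as.character(labels), classes)
    if (anyNA(idx)) stop("labels outside the class list")
    y[cbind(idx, seq_along(labels))] <- 1
    y
  }
}

#' Fit the SE-multi-input CNN heartbeat classifier
#'
#' Trains the two-branch convolutional network on paired single-cycle and
#' three-cycle magnitude spectrograms with soft-label cross-entropy and the
#' Adam optimizer. Each branch has four same-padding stride-1
#' convolutional layers (3x3 kernels for the single-cycle branch, 5x5 for
#' the three-cycle branch; 4, 8, 16, 32 filters) with ReLU activations and
#' squeeze-and-excitation blocks after layers 3 and 4; the three-cycle
#' branch's feature maps are bicubically resized to the single-cycle
#' spatial size and fused by element-wise summation, normalized per
#' channel, flattened, and classified through a 64-unit hidden layer and a
#' softmax output.
#'
#' @param x_single Array `(H, W, N)` of single-cycle spectrograms (e.g.
#'   72 x 55 x N for the 360 Hz layout, 100 x 61 x N for the adaptive
#'   layout).
#' @param x_three Array `(H, W, N)` of the paired three-cycle spectrograms
#'   (72 x 199 or 100 x 221).
#' @param labels Character/factor vector of beat classes, or an `N x L`
#'   matrix of soft labels (rows on the probability simplex) as produced by
#'   Mixup.
#' @param classes Ordered class list; defaults to the sorted distinct
#'   labels (required when `labels` is a matrix without column names).
#' @param epochs,batch_size,learning_rate Training schedule; defaults 30,
#'   256 and 0.001.
#' @param filters Filter counts of the four convolutional layers.
#' @param kernel_sizes Kernel sizes of the single-cycle and three-cycle
#'   branches.
#' @param se_reduction Channel reduction inside the SE bottleneck (2 gives
#'   the FC widths 8/16 and 16/32 at the default filters).
#' @param fc_hidden Width of the first fully connected layer.
#' @param branches `"both"` (the full model), `"single"` or `"three"`
#'   (single-input ablations).
#' @param use_se Include the SE blocks (disable for the plain multi-input
#'   ablation).
#' @param clip_norm Global gradient L2-norm ceiling per step (stabilises
#'   early Adam updates on small batches; `Inf` disables).
#' @param precision `"double"` (reference; used by the gradient checks) or
#'   `"single"` for float32 convolution arithmetic, roughly twice as fast
#'   with gradient noise far below the stochastic-gradient noise floor.
#' @param validation Optional list with `x_single`, `x_three`, `labels`
#'   evaluated once per epoch.
#' @param standardize Z-score each spectrogram before input (recommended;
#'   also applied at prediction time).
#' @param seed Integer seed for initialization and epoch shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `se_micnn` with elements `params`, `meta`,
#'   `classes`, `history` (per-epoch loss/accuracy) and `config`.
#' @export
se_micnn <- function(x_single, x_three, labels, classes = NULL,
                     epochs = 30, batch_size = 256, learning_rate = 0.001,
                     filters = c(4, 8, 16, 32), kernel_sizes = c(3, 5),
                     se_reduction = 2, fc_hidden = 64,
                     branches = c("both", "single", "three"), use_se = TRUE,
                     clip_norm = 5, precision = c("double", "single"),
                     validation = NULL, standardize = TRUE,
                     seed = 1L, verbose = FALSE) {
  branches <- match.arg(branches)
  if (is.null(classes)) {
    classes <- if (is.matrix(labels)) {
      if (is.null(colnames(labels))) stop("supply `classes` for soft labels")
      colnames(labels)
    } else {
      sort(unique(as.character(labels)))
    }
  }
  if (length(classes) < 2) stop("need at least two classes")
  n <- if (is.matrix(labels)) nrow(labels) else length(labels)
  if (n == 0) stop("empty training set")
  if (!is.null(x_single) && dim(x_single)[3] != n ||
      !is.null(x_three) && dim(x_three)[3] != n) {
    stop("spectrogram count does not match label count")
  }
  if (standardize) {
    if (!is.null(x_single)) x_single <- standardize_specs(x_single)
    if (!is.null(x_three)) x_three <- standardize_specs(x_three)
  }
  if (any(!is.finite(x_single)) || (!is.null(x_three) && any(!is.finite(x_three)))) {
    stop("non-finite spectrogram values")
  }
  dim_a <- if (is.null(x_single)) NULL else dim(x_single)[1:2]
  dim_b <- if (is.null(x_three)) NULL else dim(x_three)[1:2]
  precision <- match.arg(precision)
  meta <- micnn_meta(dim_a, dim_b, length(classes), filters, kernel_sizes,
                     se_reduction, fc_hidden, branches, use_se, precision)
  y <- labels_to_soft(labels, classes)
  xa <- if (!is.null(x_single)) array(x_single, c(dim_a, 1, n))
  xb <- if (!is.null(x_three)) array(x_three, c(dim_b, 1, n))
  hist_rows <- vector("list", epochs)
  params <- NULL
  with_seed(seed, {
    params <- micnn_init_params(meta)
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      idx <- sample(n)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1, n)]
        lg <- micnn_loss_grad(params, meta,
                              if (!is.null(xa)) xa[, , , bi, drop = FALSE],
                              if (!is.null(xb)) xb[, , , bi, drop = FALSE],
                              y[, bi, drop = FALSE])
        st <- adam_step(params, clip_gradients(lg$grads, clip_norm), state,
                        learning_rate)
        params <- st$params
        state <- st$state
        ep_loss <- ep_loss + lg$loss * length(bi)
        pred <- max.col(t(lg$probs))
        truth <- max.col(t(y[, bi, drop = FALSE]))
        ep_correct <- ep_correct + sum(pred == truth)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n, acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(validation)) {
        fitted <- list(params = params, meta = meta, classes = classes,
                       config = list(standardize = standardize))
        class(fitted) <- "se_micnn"
        vp <- predict(fitted, validation$x_single, validation$x_three,
                      type = "prob")
        vy <- labels_to_soft(validation$labels, classes)
        row$val_loss <- -sum(t(vy) * log(pmax(vp, 1e-12))) / ncol(vy)
        row$val_acc <- mean(max.col(vp) == max.col(t(vy)))
      }
      hist_rows[[ep]] <- row
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  acc %.3f%s", ep, epochs,
                        row$loss, row$acc,
                        if (is.na(row$val_acc)) "" else
                          sprintf("  val_acc %.3f", row$val_acc)))
      }
    }
  })
  structure(list(params = params, meta = meta, classes = classes,
                 history = do.call(rbind, hist_rows),
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate, seed = seed,
                               standardize = standardize),
                 call = match.call()),
            class = "se_micnn")
}

#' Predict classes or class probabilities from a fitted SE-multi-input CNN
#'
#' @param object A fitted [se_micnn()] model.
#' @param x_single,x_three Spectrogram arrays `(H, W, N)` matching the
#'   training layout (either may be omitted for single-branch models).
#' @param type `"class"` or `"prob"`.
#' @param batch_size Evaluation batch size (memory bound).
#' @param ... Unused.
#' @return Character vector of classes, or an `N x L` probability matrix.
#' @export
predict.se_micnn <- function(object, x_single = NULL, x_three = NULL,
                             type = c("class", "prob"), batch_size = 64,
                             ...) {
  type <- match.arg(type)
  meta <- object$meta
  if (meta$branches %in% c("both", "single") && is.null(x_single)) {
    stop("model needs single-cycle spectrograms")
  }
  if (meta$branches %in% c("both", "three") && is.null(x_three)) {
    stop("model needs three-cycle spectrograms")
  }
  if (isTRUE(object$config$standardize)) {
    if (!is.null(x_single)) x_single <- standardize_specs(x_single)
    if (!is.null(x_three)) x_three <- standardize_specs(x_three)
  }
  n <- if (!is.null(x_single)) dim(x_single)[3] else dim(x_three)[3]
  probs <- matrix(NA_real_, n, meta$n_classes,
                  dimnames = list(NULL, object$classes))
  for (start in seq(1, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1, n)
    xa <- if (!is.null(x_single)) {
      array(x_single[, , bi, drop = FALSE], c(meta$dim_a, 1, length(bi)))
    }
    xb <- if (!is.null(x_three)) {
      array(x_three[, , bi, drop = FALSE], c(meta$dim_b, 1, length(bi)))
    }
    cache <- micnn_forward(object$params, meta, xa, xb)
    probs[bi, ] <- t(cache$probs)
  }
  if (type == "prob") probs else object$classes[max.col(probs)]
}

#' @export
print.se_micnn <- function(x, ...) {
  cat("SE-multi-input CNN heartbeat classifier\n")
  cat(sprintf("  branches: %s%s | filters %s | kernels %s\n",
              x$meta$branches, if (x$meta$use_se) " + SE" else "",
              paste(x$meta$filters, collapse = "/"),
              paste(x$meta$kernel_sizes, collapse = "/")))
  cat(sprintf("  classes (%d): %s\n", length(x$classes),
              paste(x$classes, collapse = " ")))
  np <- sum(vapply(x$params, length, numeric(1)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  %d parameters | %d epochs | final train acc %.3f\n",
              np, nrow(x$history), last$acc))
  invisible(x)
}

#' @export
summary.se_micnn <- function(object, ...) {
  cat("SE-multi-input CNN\n")
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.se_micnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "Training loss", ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' @export
coef.se_micnn <- function(object, ...) object$params

#' Save / load a fitted model checkpoint
#'
#' The checkpoint stores weights, architecture metadata, class list and the
#' training configuration (including the seed), so a reloaded model
#' reproduces predictions exactly.
#'
#' @param object A fitted [se_micnn()] model.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `se_micnn` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "se_micnn"))
  saveRDS(unclass(object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  class(obj) <- "se_micnn"
  obj
}
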