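#' @title Array classifier (CNN meta-predictor) and MLP baseline
#' @description A small convolutional network trained on the 200-slot
#'   meta-predictor arrays: conv (3x3, same padding, ReLU) -> max-pool ->
#'   flatten -> dense(ReLU) -> dense(2, softmax), optimized with Adam
#'   (learning rate 0.01, batch size 32, at most 100 epochs) under
#'   early stopping on validation loss with best-weight restore, plus an
#'   equal-depth multilayer perceptron baseline. Implemented directly on
#'   base R linear algebra (im2col convolution); no external deep-learning
#'   backend is required, and training is bit-reproducible from the seed.
#'
#'   Because the canonical flat slot order is refilled row-major into
#'   every array layout, the flat 200-vector is identical to the
#'   row-major flattening of each shape; the shape only changes the
#'   convolution's spatial interpretation (for 3D shapes the leading
#'   axis is treated as input channels).
#' @name array_classifier
NULL

shape_chw <- function(shape) {
  dims <- parse_shape(shape)
  if (is.null(dims)) stop("network input needs a non-flat shape")
  if (length(dims) == 2) c(1L, dims) else
    if (length(dims) == 3) dims else
      stop("unsupported shape rank: ", shape)
}

#' CNN configuration
#'
#' @param input_shape One of `"50x4"`, `"40x5"`, `"5x10x4"`,
#'   `"10x5x4"` (3D shapes: leading axis = channels).
#' @param filters Convolution filters per block (default 32).
#' @param kernel Kernel height/width (default `c(3, 3)`, same padding).
#' @param pool Pool height/width; `NULL` picks 2x2 where both spatial
#'   dims allow, else 2x1. Window remainders are dropped.
#' @param blocks Number of conv+pool blocks (default 1).
#' @param dense_width Width of the hidden dense layer (default 64).
#' @param max_epochs,batch_size,learning_rate Training hyperparameters
#'   (defaults 100, 32, 0.01 with the Adam optimizer).
#' @param patience Early-stopping patience on validation loss (default
#'   10); best weights are restored.
#' @param val_fraction Fraction of the training data held out for the
#'   early-stopping monitor (default 0.2, stratified).
#' @param seed Integer seed (weight init, batch order, monitor split).
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = "50x4", filters = 32,
                       kernel = c(3, 3), pool = NULL, blocks = 1,
                       dense_width = 64, max_epochs = 100,
                       batch_size = 32, learning_rate = 0.01,
                       patience = 10, val_fraction = 0.2, seed = 1) {
  shape_chw(input_shape)  # validates
  structure(list(input_shape = input_shape, filters = filters,
                 kernel = kernel, pool = pool, blocks = blocks,
                 dense_width = dense_width, max_epochs = max_epochs,
                 batch_size = batch_size,
                 learning_rate = learning_rate, patience = patience,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "cnn_config")
}

## ---- layer constructors (dims computed at build time) -----------------

conv_plan <- function(chw, kernel) {
  C <- chw[1]; H <- chw[2]; W <- chw[3]
  kh <- kernel[1]; kw <- kernel[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2   # same padding
  # IDX[q, r]: input feature index feeding kernel cell r at output pos q
  idx <- matrix(NA_integer_, H * W, C * kh * kw)
  for (c in seq_len(C)) for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
    r <- ((c - 1) * kh + (dh - 1)) * kw + dw
    for (oh in seq_len(H)) {
      ih <- oh + dh - 1 - ph
      if (ih < 1 || ih > H) next
      for (ow in seq_len(W)) {
        iw <- ow + dw - 1 - pw
        if (iw < 1 || iw > W) next
        q <- (oh - 1) * W + ow
        idx[q, r] <- ((c - 1) * H + (ih - 1)) * W + iw
      }
    }
  }
  list(idx = idx, n_pos = H * W, patch_len = C * kh * kw,
       out_chw = c(NA, H, W))
}

im2col <- function(xmat, plan) {
  n <- nrow(xmat)
  pad <- cbind(xmat, 0)
  flat_idx <- plan$idx
  flat_idx[is.na(flat_idx)] <- ncol(pad)
  p <- pad[, as.vector(flat_idx), drop = FALSE]
  matrix(p, n * plan$n_pos, plan$patch_len)
}

pool_plan <- function(chw, pool) {
  C <- chw[1]; H <- chw[2]; W <- chw[3]
  ph <- pool[1]; pw <- pool[2]
  oh <- H %/% ph; ow <- W %/% pw
  if (oh < 1 || ow < 1)
    stop("configuration error in pooling layer: ", ph, "x", pw,
         " window does not fit ", H, "x", W, " input")
  widx <- matrix(NA_integer_, C * oh * ow, ph * pw)
  for (c in seq_len(C)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    o <- ((c - 1) * oh + (i - 1)) * ow + j
    k <- 0
    for (dh in seq_len(ph)) for (dw in seq_len(pw)) {
      k <- k + 1
      ih <- (i - 1) * ph + dh; iw <- (j - 1) * pw + dw
      widx[o, k] <- ((c - 1) * H + (ih - 1)) * W + iw
    }
  }
  list(widx = widx, out_chw = c(C, oh, ow))
}

init_dense <- function(n_in, n_out, act = c("relu", "linear")) {
  act <- match.arg(act)
  sd <- if (act == "relu") sqrt(2 / n_in) else sqrt(1 / n_in)
  list(type = "dense", W = matrix(stats::rnorm(n_in * n_out, 0, sd),
                                  n_in, n_out),
       b = rep(0, n_out), act = act)
}

#' Build the CNN meta-classifier
#'
#' Validates layer/shape compatibility and initializes weights
#' (seeded). The forward pass maps a batch of flat 200-vectors to
#' two-class softmax probabilities.
#'
#' @param config A [cnn_config()].
#' @return Object of class `nn_model`.
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  chw <- shape_chw(config$input_shape)
  layers <- list()
  with_seed(config$seed, {
    for (b in seq_len(config$blocks)) {
      if (any(config$kernel > chw[2:3] + (config$kernel - 1)))
        stop("configuration error in conv block ", b,
             ": kernel larger than padded input")
      cp <- conv_plan(chw, config$kernel)
      n_in <- cp$patch_len
      layers[[length(layers) + 1L]] <- list(
        type = "conv", plan = cp,
        W = matrix(stats::rnorm(n_in * config$filters, 0,
                                sqrt(2 / n_in)),
                   n_in, config$filters),
        b = rep(0, config$filters))
      chw <- c(config$filters, chw[2], chw[3])
      pool <- config$pool
      if (is.null(pool)) pool <- c(2, if (chw[3] >= 2) 2 else 1)
      pp <- pool_plan(chw, pool)   # errors if window does not fit
      layers[[length(layers) + 1L]] <- list(type = "pool", plan = pp)
      chw <- pp$out_chw
    }
    n_flat <- prod(chw)
    layers[[length(layers) + 1L]] <- init_dense(n_flat,
                                                config$dense_width,
                                                "relu")
    layers[[length(layers) + 1L]] <- init_dense(config$dense_width, 2,
                                                "linear")
  })
  structure(list(layers = layers, config = config, kind = "CNN"),
            class = "nn_model")
}

#' Build the equal-depth MLP baseline
#'
#' A dense network on the flat 200-vector with the same number of
#' trainable layers as the CNN of the same configuration (each conv
#' block replaced by a dense hidden layer), trained under the identical
#' protocol.
#'
#' @param config A [cnn_config()].
#' @param hidden_width Width of the layers standing in for the conv
#'   blocks (default 128).
#' @return Object of class `nn_model`.
#' @export
build_mlp_baseline <- function(config, hidden_width = 128) {
  stopifnot(inherits(config, "cnn_config"))
  n_in <- N_SLOTS
  layers <- list()
  with_seed(config$seed, {
    for (b in seq_len(config$blocks)) {
      layers[[length(layers) + 1L]] <- init_dense(n_in, hidden_width,
                                                  "relu")
      n_in <- hidden_width
    }
    layers[[length(layers) + 1L]] <- init_dense(n_in,
                                                config$dense_width,
                                                "relu")
    layers[[length(layers) + 1L]] <- init_dense(config$dense_width, 2,
                                                "linear")
  })
  structure(list(layers = layers, config = config, kind = "MLP"),
            class = "nn_model")
}

#' Count of trainable layers (conv + dense)
#' @param model An `nn_model`.
#' @return Integer.
#' @export
n_trainable_layers <- function(model)
  sum(vapply(model$layers, function(l) l$type %in% c("conv", "dense"),
             logical(1)))

## ---- forward / backward ----------------------------------------------

nn_forward <- function(model, xmat, keep_cache = FALSE) {
  caches <- list()
  a <- xmat
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      m <- im2col(a, l$plan)
      z <- sweep(m %*% l$W, 2, l$b, "+")
      act <- matrix(pmax(z, 0), nrow(a))
      if (keep_cache) caches[[li]] <- list(m = m, z = z, n = nrow(a))
      a <- act
    } else if (l$type == "pool") {
      widx <- l$plan$widx
      n <- nrow(a)
      out <- a[, widx[, 1], drop = FALSE]
      arg <- matrix(1L, n, nrow(widx))
      if (ncol(widx) > 1) for (k in 2:ncol(widx)) {
        cand <- a[, widx[, k], drop = FALSE]
        better <- cand > out
        better[is.na(better)] <- TRUE   # propagate non-finite values
        out[better] <- cand[better]
        arg[better] <- k
      }
      if (keep_cache) caches[[li]] <- list(arg = arg, in_cols = ncol(a))
      a <- out
    } else {  # dense
      z <- sweep(a %*% l$W, 2, l$b, "+")
      if (keep_cache) caches[[li]] <- list(a_in = a, z = z)
      a <- if (l$act == "relu") pmax(z, 0) else z
    }
  }
  # softmax over the two output logits
  zmax <- pmax(a[, 1], a[, 2])
  e <- exp(a - zmax)
  probs <- e / rowSums(e)
  list(probs = probs, caches = caches)
}

nn_backward <- function(model, fw, y01) {
  n <- length(y01)
  grads <- vector("list", length(model$layers))
  onehot <- cbind(1 - y01, y01)
  delta <- (fw$probs - onehot) / n   # d loss / d logits
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (l$type == "dense") {
      if (l$act == "relu") delta <- delta * (cache$z > 0)
      grads[[li]] <- list(W = crossprod(cache$a_in, delta),
                          b = colSums(delta))
      delta <- delta %*% t(l$W)
    } else if (l$type == "pool") {
      widx <- l$plan$widx
      dx <- matrix(0, nrow(delta), cache$in_cols)
      for (k in seq_len(ncol(widx))) {
        mask <- cache$arg == k
        contrib <- delta * mask
        # scatter-add into source columns (columns are distinct per k)
        dx[, widx[, k]] <- dx[, widx[, k]] + contrib
      }
      delta <- dx
    } else {  # conv
      nq <- l$plan$n_pos
      dz <- matrix(delta, cache$n * nq, ncol(l$W)) * (cache$z > 0)
      grads[[li]] <- list(W = crossprod(cache$m, dz),
                          b = colSums(dz))
      dm <- dz %*% t(l$W)                      # (n*nq) x patch_len
      dmw <- matrix(dm, cache$n, nq * ncol(dm))
      dx <- matrix(0, cache$n, max(l$plan$idx, na.rm = TRUE))
      flat_idx <- as.vector(l$plan$idx)
      for (j in seq_along(flat_idx)) {
        v <- flat_idx[j]
        if (!is.na(v)) dx[, v] <- dx[, v] + dmw[, j]
      }
      delta <- dx
    }
  }
  grads
}

adam_init <- function(model) {
  lapply(model$layers, function(l)
    if (l$type %in% c("conv", "dense"))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL)
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    s <- state[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW <- s$mW / (1 - beta1^t); vW <- s$vW / (1 - beta2^t)
    mb <- s$mb / (1 - beta1^t); vb <- s$vb / (1 - beta2^t)
    model$layers[[li]]$W <- model$layers[[li]]$W -
      lr * mW / (sqrt(vW) + eps)
    model$layers[[li]]$b <- model$layers[[li]]$b -
      lr * mb / (sqrt(vb) + eps)
    state[[li]] <- s
  }
  list(model = model, state = state)
}

dataset_xy <- function(data) {
  list(x = data$values, y = as.integer(data$class_labels == "CWA"))
}

batch_loss_acc <- function(model, x, y) {
  p <- nn_forward(model, x)$probs[, 2]
  list(loss = cross_entropy_loss(p[y == 1], p[y == 0]),
       acc = mean((p > 0.5) == (y == 1)))
}

#' Train a network on a meta-array dataset
#'
#' Optimizes the binary cross-entropy with Adam; a stratified
#' `val_fraction` of the data is held out as the early-stopping monitor
#' (patience epochs without validation-loss improvement stop training
#' and the best weights are restored). Deterministic given the config
#' seed.
#'
#' @param model An `nn_model` from [build_cnn()] or
#'   [build_mlp_baseline()].
#' @param data An `array_dataset` (training portion; both classes
#'   required).
#' @param config Optional [cnn_config()] override (default: the model's
#'   own).
#' @return List: `model` (trained), `trace` (data.frame per epoch:
#'   train/val loss and accuracy), `stopped_epoch`.
#' @export
nn_train <- function(model, data, config = model$config) {
  xy <- dataset_xy(data)
  x <- xy$x; y <- xy$y
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training data")
  with_seed(config$seed + 1L, {
    val_idx <- unlist(lapply(split(seq_along(y), y), function(idx)
      sample(idx, max(1, round(length(idx) * config$val_fraction)))),
      use.names = FALSE)
  })
  tr_idx <- setdiff(seq_along(y), val_idx)
  if (length(unique(y[tr_idx])) < 2 || length(unique(y[val_idx])) < 2)
    warning("early-stopping monitor split is single-class")
  xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  xva <- x[val_idx, , drop = FALSE]; yva <- y[val_idx]
  state <- adam_init(model)
  best <- list(loss = Inf, model = model, epoch = 0L)
  trace <- list(); t_step <- 0
  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(ytr))
      starts <- seq(1, length(ord), by = config$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1, length(ord))]
        fw <- nn_forward(model, xtr[idx, , drop = FALSE],
                         keep_cache = TRUE)
        if (!all(is.finite(fw$probs)))
          stop("training diverged (non-finite probabilities) at epoch ",
               epoch)
        grads <- nn_backward(model, fw, ytr[idx])
        t_step <- t_step + 1
        upd <- adam_step(model, grads, state, config$learning_rate,
                         t_step)
        model <- upd$model; state <- upd$state
      }
      tr <- batch_loss_acc(model, xtr, ytr)
      va <- batch_loss_acc(model, xva, yva)
      if (!is.finite(tr$loss) || !is.finite(va$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      trace[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = tr$loss,
                                   train_acc = tr$acc,
                                   val_loss = va$loss,
                                   val_acc = va$acc)
      if (va$loss < best$loss - 1e-8)
        best <- list(loss = va$loss, model = model, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
  })
  trace <- do.call(rbind, trace)
  list(model = best$model, trace = trace,
       stopped_epoch = nrow(trace))
}

#' Class probabilities of meta arrays
#'
#' @param object A trained `nn_model`.
#' @param newdata An `array_dataset` or a numeric matrix of flat
#'   200-vectors.
#' @param ... Unused.
#' @return Matrix n x 2 of softmax probabilities, columns
#'   `c("nonCWA", "CWA")`.
#' @export
predict.nn_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "array_dataset")) newdata$values else
    as.matrix(newdata)
  p <- nn_forward(object, x)$probs
  colnames(p) <- c("nonCWA", "CWA")
  p
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s on %s: %d trainable layers\n", x$kind,
              x$config$input_shape, n_trainable_layers(x)))
  invisible(x)
}

#' Evaluate a trained detector on held-out arrays
#'
#' Refuses evaluation sets containing SMOTE-synthesized rows (leakage
#' guard: oversampling must happen after the train/test division, so
#' test arrays are always real). Reports per-class F1 (CWA and nonCWA),
#' MCC, accuracy, ROC-AUC and AUPR, plus the precision-recall curve.
#'
#' @param model A trained `nn_model`.
#' @param data Held-out `array_dataset`.
#' @return List: `report` (eval_report, CWA = positive class),
#'   `f1_cwa`, `f1_noncwa`, `pr` (precision-recall curve + AUPR).
#' @export
evaluate_detector <- function(model, data) {
  stopifnot(inherits(data, "array_dataset"))
  if (any(data$synthetic))
    stop("evaluation set contains synthetic (SMOTE) arrays; ",
         "oversample only the training portion")
  y <- as.integer(data$class_labels == "CWA")
  scores <- predict(model, data)[, "CWA"]
  if (length(unique(y)) < 2)
    warning("single-class evaluation set; ranking metrics undefined")
  report <- evaluate_scores(scores, y)
  flipped <- confusion_metrics(tabulate_confusion(scores <= 0.5,
                                                  y == 0))
  pr <- pr_curve(scores, y)
  list(report = report, f1_cwa = report$f1, f1_noncwa = flipped$f1,
       pr = pr)
}
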