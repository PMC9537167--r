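#' @title Base DTI learners
#' @description The four binary classifiers of the model grid -- random
#'   forest (RF), decision tree (DT), support-vector machine (SVM) and
#'   k-nearest neighbour (KNN) -- behind one contract: `fit_base_model()`
#'   returns a model whose `predict()` yields a continuous positive-class
#'   score in `[0, 1]`. CART trees (and their bagged forest) are grown on
#'   binary fingerprint features with gini impurity; the SVM solves the
#'   C-SVM dual exactly with a radial kernel and calibrates scores by
#'   Platt scaling; KNN scores are the positive fraction among the k
#'   nearest training fingerprints.
#' @name learners
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old,
                              envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
         RF = list(n_trees = 50, max_depth = 16, min_split = 2,
                   mtry = NULL),     # NULL -> floor(sqrt(p))
         DT = list(max_depth = 16, min_split = 5),
         SVM = list(cost = 1, gamma = NULL),  # NULL -> 1/(p * var)
         KNN = list(k = 5),
         stop("unknown algorithm: ", algorithm))
}

## ---- CART on binary features ------------------------------------------

gini_split_gain <- function(n, n_pos, n1, n1_pos) {
  n0 <- n - n1; n0_pos <- n_pos - n1_pos
  p <- n_pos / n
  parent <- p * (1 - p)
  child <- function(m, m_pos) {
    ifelse(m == 0, 0, {
      q <- m_pos / pmax(m, 1); q * (1 - q)
    })
  }
  parent - (n1 / n) * child(n1, n1_pos) - (n0 / n) * child(n0, n0_pos)
}

grow_tree <- function(x, y, max_depth, min_split, mtry = NULL) {
  p <- ncol(x)
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(); nodes$left <- integer()
  nodes$right <- integer(); nodes$prob <- numeric()
  new_node <- function() {
    i <- length(nodes$feature) + 1L
    nodes$feature[i] <- NA_integer_; nodes$left[i] <- NA_integer_
    nodes$right[i] <- NA_integer_; nodes$prob[i] <- NA_real_
    i
  }
  build <- function(idx, depth) {
    id <- new_node()
    n <- length(idx); n_pos <- sum(y[idx])
    nodes$prob[id] <- n_pos / n
    if (depth >= max_depth || n < min_split || n_pos == 0 ||
        n_pos == n) return(id)
    cand <- if (is.null(mtry) || mtry >= p) seq_len(p) else
      sample.int(p, mtry)
    xs <- x[idx, cand, drop = FALSE]
    n1 <- colSums(xs)
    n1_pos <- as.numeric(crossprod(xs, y[idx]))
    gain <- gini_split_gain(n, n_pos, n1, n1_pos)
    gain[n1 == 0 | n1 == n] <- -Inf
    best <- which.max(gain)
    if (!is.finite(gain[best]) || gain[best] <= 1e-12) return(id)
    feat <- cand[best]
    go_right <- x[idx, feat] == 1
    nodes$feature[id] <- feat
    nodes$left[id] <- build(idx[!go_right], depth + 1L)
    nodes$right[id] <- build(idx[go_right], depth + 1L)
    id
  }
  root <- build(seq_len(nrow(x)), 0L)
  list(feature = nodes$feature, left = nodes$left, right = nodes$right,
       prob = nodes$prob, root = root)
}

predict_tree <- function(tree, x) {
  cur <- rep(tree$root, nrow(x))
  repeat {
    internal <- which(!is.na(tree$feature[cur]))
    if (!length(internal)) break
    feat <- tree$feature[cur[internal]]
    val <- x[cbind(internal, feat)]
    cur[internal] <- ifelse(val == 1, tree$right[cur[internal]],
                            tree$left[cur[internal]])
  }
  tree$prob[cur]
}

## ---- fitting entry point ----------------------------------------------

#' Fit one base classifier
#'
#' @param x Binary feature matrix (compounds x bits).
#' @param y Integer 0/1 labels (1 = active).
#' @param algorithm One of `"RF"`, `"DT"`, `"SVM"`, `"KNN"`.
#' @param seed Integer seed controlling all stochastic internals.
#' @param hyperparameters Named list overriding the algorithm defaults
#'   (`RF`: `n_trees`, `max_depth`, `min_split`, `mtry`; `DT`:
#'   `max_depth`, `min_split`; `SVM`: `cost`, `gamma`; `KNN`: `k`).
#' @return A `base_model` whose [predict()][predict.base_model] returns a
#'   positive-class score in `[0, 1]`.
#' @export
fit_base_model <- function(x, y, algorithm = DTI_ALGORITHMS, seed = 1,
                           hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x); y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  hp <- utils::modifyList(default_hyperparameters(algorithm),
                          hyperparameters)
  if (length(unique(y)) < 2) {
    warning("single-class training data; fitting constant model")
    fit <- list(constant = mean(y))
  } else {
    fit <- with_seed(seed, switch(algorithm,
      RF = fit_rf(x, y, hp), DT = fit_dt(x, y, hp),
      SVM = fit_svm(x, y, hp), KNN = fit_knn(x, y, hp)))
  }
  structure(list(algorithm = algorithm, fit = fit, seed = seed,
                 hyperparameters = hp, n_features = ncol(x)),
            class = "base_model")
}

fit_dt <- function(x, y, hp)
  list(tree = grow_tree(x, y, hp$max_depth, hp$min_split))

fit_rf <- function(x, y, hp) {
  mtry <- if (is.null(hp$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    hp$mtry
  n <- nrow(x)
  trees <- lapply(seq_len(hp$n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], y[idx], hp$max_depth,
              hp$min_split, mtry)
  })
  list(trees = trees)
}

fit_knn <- function(x, y, hp)
  list(x = x, y = y, k = min(hp$k, nrow(x)))

fit_svm <- function(x, y, hp) {
  n <- nrow(x)
  gamma <- if (is.null(hp$gamma)) {
    v <- mean(apply(x, 2, stats::var))
    1 / (ncol(x) * max(v, 1e-8))
  } else hp$gamma
  ys <- ifelse(y == 1, 1, -1)
  K <- rbf_kernel(x, x, gamma)
  Q <- (ys %o% ys) * K
  diag(Q) <- diag(Q) + 1e-8 * n   # ridge: keep the dual strictly convex
  C <- hp$cost
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = Q, dvec = rep(1, n), Amat = Amat,
                            bvec = bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6
  f_train <- as.numeric(K %*% (alpha * ys))
  margin <- sv & alpha < C - 1e-6
  b <- if (any(margin)) mean(ys[margin] - f_train[margin]) else
    mean(ys[sv] - f_train[sv])
  decision <- f_train + b
  # Platt scaling with regularized targets
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  t <- ifelse(y == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  platt <- suppressWarnings(stats::glm(t ~ decision,
                                       family = stats::quasibinomial()))
  list(x = x[sv, , drop = FALSE], coef = (alpha * ys)[sv], b = b,
       gamma = gamma, platt = stats::coef(platt))
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Score new compounds with a base model
#'
#' @param object A `base_model`.
#' @param newdata Binary feature matrix with the training bit length.
#' @param ... Unused.
#' @return Numeric positive-class scores in `[0, 1]`.
#' @export
predict.base_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("feature length mismatch: model expects ", object$n_features,
         " bits, got ", ncol(x))
  fit <- object$fit
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(x)))
  switch(object$algorithm,
    DT = predict_tree(fit$tree, x),
    RF = {
      preds <- vapply(fit$trees, predict_tree, numeric(nrow(x)),
                      x = x)
      if (nrow(x) == 1) mean(preds) else rowMeans(preds)
    },
    KNN = {
      nn <- FNN::get.knnx(fit$x, x, k = fit$k)$nn.index
      rowMeans(matrix(fit$y[nn], nrow = nrow(x)))
    },
    SVM = {
      f <- as.numeric(rbf_kernel(x, fit$x, fit$gamma) %*% fit$coef) +
        fit$b
      stats::plogis(fit$platt[1] + fit$platt[2] * f)
    })
}

#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model> %s (seed %d, %d features)\n", x$algorithm,
              x$seed, x$n_features))
  invisible(x)
}
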