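# Regression families mapping probe-molecule free energies (features, one
# column per probe, one row per material) to the free energies of all other
# molecules (responses).
#
# LR: ordinary least squares with intercept, one independent model per
#   response. AdaBoost: AdaBoost.R2 with depth-3 regression-tree base
#   learners, one ensemble per response. NN: a single one-hidden-layer
#   tanh network fit jointly over all responses with Adam.

#' Declarative regressor specification
#'
#' @param family `"lr"`, `"adaboost"` or `"nn"`.
#' @param seed integer seed for stochastic families (resampling, weight
#'   initialization); per-response / per-split seeds are derived from it.
#' @param n_estimators AdaBoost boosting iterations (default 50).
#' @param max_depth AdaBoost base-tree depth (default 3).
#' @param hidden NN hidden units (default 10, tanh activation).
#' @param l2 NN L2 penalty on weights (default 1e-4).
#' @param epochs NN full-batch Adam epochs (default 2000).
#' @param learning_rate NN Adam step size (default 1e-3).
#' @return list of class `regressor_spec`.
#' @export
regressor_spec <- function(family = c("lr", "adaboost", "nn"), seed = 1L,
                           n_estimators = 50L, max_depth = 3L,
                           hidden = 10L, l2 = 1e-4, epochs = 2000L,
                           learning_rate = 1e-3) {
  family <- match.arg(family)
  stopifnot(n_estimators >= 1L, max_depth >= 1L, hidden >= 1L, l2 >= 0,
            epochs >= 1L, learning_rate > 0)
  structure(list(family = family, seed = as.integer(seed),
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 hidden = as.integer(hidden), l2 = l2,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate),
            class = "regressor_spec")
}

.as_xy <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of materials", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("missing values in training data", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  list(X = X, Y = Y)
}

#' Fit a regression model from probe features to response free energies
#'
#' @param spec a [regressor_spec()].
#' @param X materials x features matrix (kJ/mol).
#' @param Y materials x responses matrix (kJ/mol).
#' @return a fitted model of class `fe_model`; use [predict()] with a new
#'   feature matrix whose columns match the training features.
#' @export
fit_regressor <- function(spec, X, Y) {
  stopifnot(inherits(spec, "regressor_spec"))
  d <- .as_xy(X, Y)
  fit <- switch(spec$family,
                lr = .fit_lr(d$X, d$Y),
                adaboost = .fit_adaboost(spec, d$X, d$Y),
                nn = .fit_nn(spec, d$X, d$Y))
  structure(list(spec = spec, fit = fit,
                 feature_ids = colnames(d$X),
                 response_ids = colnames(d$Y)),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> family=%s, %d features -> %d responses\n",
              x$spec$family, length(x$feature_ids),
              length(x$response_ids)))
  invisible(x)
}

#' Predict response free energies from probe features
#'
#' @param object a fitted `fe_model`.
#' @param newdata materials x features matrix; columns must match the
#'   training feature ids (reordered by name when named).
#' @param ... unused.
#' @return materials x responses matrix, kJ/mol.
#' @export
predict.fe_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), object$feature_ids))
      stop("feature columns do not match the trained features",
           call. = FALSE)
    X <- X[, object$feature_ids, drop = FALSE]
  } else if (ncol(X) != length(object$feature_ids)) {
    stop("wrong number of feature columns", call. = FALSE)
  }
  P <- switch(object$spec$family,
              lr = .predict_lr(object$fit, X),
              adaboost = .predict_adaboost(object$fit, X),
              nn = .predict_nn(object$fit, X))
  colnames(P) <- object$response_ids
  rownames(P) <- rownames(X)
  P
}

## ---- linear regression -------------------------------------------------

.fit_lr <- function(X, Y) {
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("rank-deficient design; using minimum-norm least squares")
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1L]
    coef <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], Y) / sv$d[pos])
  } else {
    coef <- qr.coef(qrA, Y)
  }
  rownames(coef) <- colnames(A)
  list(coef = coef)
}

.predict_lr <- function(fit, X) {
  cbind(1, X) %*% fit$coef
}

#' Coefficient table of a fitted linear model
#'
#' @param model an `fe_model` with family `"lr"`.
#' @return data.frame with one row per response molecule: intercept and one
#'   column per probe feature (kJ/mol per kJ/mol).
#' @export
lr_coefficients <- function(model) {
  stopifnot(inherits(model, "fe_model"), model$spec$family == "lr")
  co <- t(model$fit$coef)
  data.frame(response = rownames(co), co, check.names = FALSE,
             row.names = NULL)
}

## ---- AdaBoost.R2 -------------------------------------------------------

.base_tree <- function(X, y, max_depth) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  rpart::rpart(.y ~ ., data = df,
               control = rpart::rpart.control(maxdepth = max_depth,
                                              cp = 0, minsplit = 2L,
                                              minbucket = 1L, xval = 0L,
                                              maxsurrogate = 0L,
                                              maxcompete = 0L))
}

.tree_predict <- function(tree, X) {
  unname(stats::predict(tree, data.frame(X, check.names = FALSE)))
}

# AdaBoost.R2 (Drucker): weighted bootstrap resample per iteration, linear
# loss normalized by the largest absolute error, multiplicative weight
# update beta^(1 - loss), learner weight log(1/beta), prediction by
# weighted median of the base learners.
.adaboost_r2 <- function(X, y, n_estimators, max_depth, seed) {
  n <- length(y)
  withr::with_seed(as.integer(seed), {
    w <- rep(1 / n, n)
    learners <- list(); lw <- numeric(0)
    for (t in seq_len(n_estimators)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      tree <- .base_tree(X[idx, , drop = FALSE], y[idx], max_depth)
      err <- abs(.tree_predict(tree, X) - y)
      D <- max(err)
      if (D <= .Machine$double.eps) {        # perfect fit: stop boosting
        learners[[length(learners) + 1L]] <- tree
        lw <- c(lw, log(1 / .Machine$double.eps))
        break
      }
      loss <- err / D
      ebar <- sum(w * loss)
      if (ebar >= 0.5) {
        if (!length(learners)) {             # keep something predictive
          learners[[1L]] <- tree
          lw <- 1
        }
        break
      }
      beta <- ebar / (1 - ebar)
      learners[[length(learners) + 1L]] <- tree
      lw <- c(lw, log(1 / beta))
      w <- w * beta^(1 - loss)
      w <- w / sum(w)
    }
    list(learners = learners, weights = lw)
  })
}

.weighted_median <- function(values, weights) {
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= 0.5 * sum(weights))[1L]]
}

.adaboost_ensemble_predict <- function(ens, X) {
  P <- unlist(lapply(ens$learners, function(tr) .tree_predict(tr, X)))
  P <- matrix(P, nrow = nrow(X))
  apply(P, 1L, function(v) .weighted_median(v, ens$weights))
}

.fit_adaboost <- function(spec, X, Y) {
  ens <- lapply(seq_len(ncol(Y)), function(j)
    .adaboost_r2(X, Y[, j], spec$n_estimators, spec$max_depth,
                 seed = spec$seed + j))
  names(ens) <- colnames(Y)
  list(ensembles = ens)
}

.predict_adaboost <- function(fit, X) {
  P <- unname(unlist(lapply(fit$ensembles,
                            function(ens)
                              .adaboost_ensemble_predict(ens, X))))
  matrix(P, nrow = nrow(X),
         dimnames = list(NULL, names(fit$ensembles)))
}

## ---- one-hidden-layer neural network -----------------------------------

# Joint multi-output MLP: tanh hidden layer, linear outputs, L2 penalty,
# full-batch Adam. Features and responses are z-scaled internally for
# optimizer conditioning; predictions are mapped back to kJ/mol.
.fit_nn <- function(spec, X, Y) {
  p <- ncol(X); q <- ncol(Y); h <- spec$hidden
  xm <- colMeans(X); xs <- apply(X, 2L, stats::sd); xs[xs == 0] <- 1
  ym <- colMeans(Y); ys <- apply(Y, 2L, stats::sd); ys[ys == 0] <- 1
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  Ys <- sweep(sweep(Y, 2L, ym), 2L, ys, "/")
  n <- nrow(Xs)
  withr::with_seed(spec$seed, {
    W1 <- matrix(stats::rnorm(p * h, 0, sqrt(2 / (p + h))), p, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h * q, 0, sqrt(2 / (h + q))), h, q)
    b2 <- numeric(q)
    theta <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mom <- vel <- lapply(theta, function(z) z * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- spec$learning_rate
    best <- Inf; stall <- 0L
    converged <- FALSE
    for (it in seq_len(spec$epochs)) {
      H <- tanh(sweep(Xs %*% theta$W1, 2L, theta$b1, `+`))
      P <- sweep(H %*% theta$W2, 2L, theta$b2, `+`)
      E <- P - Ys
      loss <- mean(E^2) / 2 +
        spec$l2 * (sum(theta$W1^2) + sum(theta$W2^2)) / (2 * n)
      if (loss < best - 1e-10) { best <- loss; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= 20L) { converged <- TRUE; break }
      dP <- E / (n * q)
      gW2 <- crossprod(H, dP) + spec$l2 * theta$W2 / n
      gb2 <- colSums(dP)
      dH <- (dP %*% t(theta$W2)) * (1 - H^2)
      gW1 <- crossprod(Xs, dH) + spec$l2 * theta$W1 / n
      gb1 <- colSums(dH)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      for (nm in names(theta)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^it)
        vhat <- vel[[nm]] / (1 - beta2^it)
        theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (!converged)
      warning("NN optimizer reached the epoch budget without plateau; ",
              "model returned as-is")
    list(theta = theta, xm = xm, xs = xs, ym = ym, ys = ys,
         converged = converged, final_loss = best)
  })
}

.predict_nn <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$xm), 2L, fit$xs, "/")
  H <- tanh(sweep(Xs %*% fit$theta$W1, 2L, fit$theta$b1, `+`))
  P <- sweep(H %*% fit$theta$W2, 2L, fit$theta$b2, `+`)
  sweep(sweep(P, 2L, fit$ys, "*"), 2L, fit$ym, `+`)
}
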