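#' Hyperparameters for the multilayer perceptron
#'
#' Defaults are the selected values of the model-development grid search:
#' ReLU activation, the L-BFGS solver, L2 penalty `alpha = 1e-8`,
#' convergence tolerance `1e-3`, one hidden layer of 6 units, at most
#' 1,200 iterations, and random state 4. `learning_rate_init` is kept for
#' interface completeness but is not consumed by the quasi-Newton solver.
#'
#' @param activation Only `"relu"` is implemented.
#' @param solver Only `"lbfgs"` is implemented.
#' @param alpha L2 penalty on connection weights (not biases).
#' @param tol Projected-gradient tolerance passed to the solver.
#' @param learning_rate_init Unused by L-BFGS; retained for the record.
#' @param hidden Integer vector of hidden layer sizes.
#' @param max_iter Iteration cap.
#' @param random_state Seed for weight initialization.
#' @return Object of class `mlp_control`.
#' @export
mlp_control <- function(activation = "relu", solver = "lbfgs",
                        alpha = 1e-8, tol = 1e-3,
                        learning_rate_init = 0.1,
                        hidden = 6L, max_iter = 1200L, random_state = 4L) {
  activation <- match.arg(activation, "relu")
  solver <- match.arg(solver, "lbfgs")
  if (any(hidden < 1)) stop_config("hidden", "layer sizes must be positive")
  structure(list(activation = activation, solver = solver, alpha = alpha,
                 tol = tol, learning_rate_init = learning_rate_init,
                 hidden = as.integer(hidden), max_iter = as.integer(max_iter),
                 random_state = as.integer(random_state)),
            class = "mlp_control")
}

# pack / unpack the parameter vector
mlp_shapes <- function(sizes) {
  lapply(seq_len(length(sizes) - 1),
         function(l) c(sizes[l], sizes[l + 1]))
}

mlp_unpack <- function(par, shapes) {
  W <- list(); b <- list(); off <- 0
  for (l in seq_along(shapes)) {
    nw <- prod(shapes[[l]])
    W[[l]] <- matrix(par[off + seq_len(nw)], shapes[[l]][1], shapes[[l]][2])
    off <- off + nw
    b[[l]] <- par[off + seq_len(shapes[[l]][2])]
    off <- off + shapes[[l]][2]
  }
  list(W = W, b = b)
}

mlp_forward <- function(X, W, b) {
  L <- length(W)
  Z <- vector("list", L); A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else plogis(Z[[l]])
  }
  list(Z = Z, A = A)
}

#' Fit the multilayer perceptron
#'
#' Binary cross-entropy objective with an L2 penalty on connection
#' weights, minimized by `stats::optim(method = "L-BFGS-B")` with an
#' analytic backpropagation gradient. Features are z-scored internally on
#' the training data (constant columns get unit scale); weights use
#' Glorot-uniform initialization seeded by `random_state`, so refits are
#' bit-identical.
#'
#' @param x Numeric data frame or matrix of predictors.
#' @param y Binary outcome vector.
#' @param control An [mlp_control()].
#' @return Object of class `mlp_fit` with weights, scaler, and
#'   convergence status.
#' @export
fit_mlp <- function(x, y, control = mlp_control()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in features", call. = FALSE)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  n <- nrow(Xs)
  sizes <- c(ncol(Xs), control$hidden, 1L)
  shapes <- mlp_shapes(sizes)

  init <- withr::with_seed(control$random_state, {
    par <- numeric(0)
    for (sh in shapes) {
      bound <- sqrt(6 / (sh[1] + sh[2]))
      par <- c(par, runif(prod(sh), -bound, bound),
               runif(sh[2], -bound, bound))
    }
    par
  })

  yv <- as.numeric(y)
  alpha <- control$alpha
  # optim evaluates fn and gr at the same point; share one forward pass
  cache <- new.env(parent = emptyenv())
  fwd_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) {
      return(cache$val)
    }
    pr <- mlp_unpack(par, shapes)
    val <- list(pr = pr, fw = mlp_forward(Xs, pr$W, pr$b))
    cache$par <- par; cache$val <- val
    val
  }
  obj <- function(par) {
    v <- fwd_at(par)
    p <- clip01(as.numeric(v$fw$A[[length(shapes) + 1]]), eps = 1e-12)
    bce <- -mean(yv * log(p) + (1 - yv) * log(1 - p))
    bce + 0.5 * alpha * sum(vapply(v$pr$W, function(w) sum(w^2), 0)) / n
  }
  grad <- function(par) {
    v <- fwd_at(par)
    pr <- v$pr; fw <- v$fw
    L <- length(pr$W)
    p <- as.numeric(fw$A[[L + 1]])
    delta <- matrix((p - yv) / n, ncol = 1)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(fw$A[[l]], delta) + alpha * pr$W[[l]] / n
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(pr$W[[l]])) * (fw$Z[[l - 1]] > 0)
    }
    unlist(lapply(seq_len(L), function(l) c(as.numeric(gW[[l]]), gb[[l]])))
  }

  opt <- optim(init, obj, grad, method = "L-BFGS-B",
               control = list(maxit = control$max_iter, pgtol = control$tol,
                              factr = 10))
  pr <- mlp_unpack(opt$par, shapes)
  structure(list(W = pr$W, b = pr$b, sizes = sizes,
                 center = center, scale = scale_,
                 feature_names = colnames(x),
                 loss = opt$value, converged = opt$convergence == 0,
                 n_obs = n, control = control),
            class = "mlp_fit")
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("ReLU MLP (%s), layers %s, trained on %d rows; loss %.4f%s\n",
              x$control$solver, paste(x$sizes, collapse = "-"), x$n_obs,
              x$loss, if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

#' Predicted progression probabilities from the MLP
#'
#' @param object An `mlp_fit`.
#' @param newdata Data frame or matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities (`pANN`).
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss)) {
      stop(sprintf("newdata lacks column(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  if (ncol(newdata) != object$sizes[1]) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.numeric(mlp_forward(Xs, object$W, object$b)$A[[length(object$W) + 1]])
}

#' Rank MLP input features by first-layer weight mass
#'
#' A feature's importance is the sum of absolute weights on its
#' connections into the first hidden layer. The p-value is a one-sample
#' t-test of those signed weights against mean zero (undefined, hence
#' `NA`, with a single hidden unit); its power is limited by the handful
#' of weights per feature.
#'
#' @param fit An `mlp_fit`.
#' @param feature_names Optional display names.
#' @return Data frame with `rank`, `feature`, `importance`, `p_value`,
#'   `significant`, sorted by importance.
#' @export
rank_mlp_features <- function(fit, feature_names = NULL) {
  stopifnot(inherits(fit, "mlp_fit"))
  W1 <- fit$W[[1]]
  nms <- feature_names %||% fit$feature_names %||%
    paste0("x", seq_len(nrow(W1)))
  importance <- rowSums(abs(W1))
  p <- apply(W1, 1, function(w) {
    if (length(w) < 2 || sd(w) == 0) NA_real_ else t.test(w)$p.value
  })
  o <- order(-importance)
  data.frame(rank = seq_along(o), feature = nms[o],
             importance = unname(importance[o]), p_value = unname(p[o]),
             significant = !is.na(p[o]) & p[o] < 0.05,
             stringsAsFactors = FALSE)
}
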