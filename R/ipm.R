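#' Hyperparameters for the gradient-boosted meta-classifier
#'
#' Defaults match the ensemble's tuned values: 100 boosting iterations,
#' learning rate 0.01, depth-3 trees, a 60% subsample of the training set
#' per iteration drawn without replacement, and random state 28.
#'
#' @param random_state Seed for the boosting subsampling.
#' @param n_estimators Number of boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param max_depth Tree depth.
#' @param subsample Row subsample fraction per round (without replacement).
#' @return Object of class `gbc_control`.
#' @export
gbc_control <- function(random_state = 28L, n_estimators = 100L,
                        learning_rate = 0.01, max_depth = 3L,
                        subsample = 0.6) {
  if (subsample <= 0 || subsample > 1) stop_config("subsample", "must be in (0, 1]")
  if (n_estimators < 1) stop_config("n_estimators", "must be positive")
  structure(list(random_state = as.integer(random_state),
                 n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 subsample = subsample),
            class = "gbc_control")
}

#' Stratified train/test split
#'
#' Per-outcome-group random partition: `round(frac * n_g)` training rows
#' in each group (so 282 per group at 80% gives 226 training and 56 test
#' patients per group), disjoint and exhaustive, seeded.
#'
#' @param y Binary outcome vector.
#' @param frac Training fraction.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(y, frac = 0.8, seed = 1) {
  stopifnot(frac > 0, frac < 1)
  groups <- unique(y)
  if (length(groups) < 2) stop("both outcome groups must be present", call. = FALSE)
  withr::with_seed(seed, {
    train <- integer(0)
    for (g in sort(groups)) {
      idx <- which(y == g)
      n_tr <- round(frac * length(idx))
      if (n_tr < 1 || n_tr >= length(idx)) {
        stop(sprintf("outcome group %s too small to split", g), call. = FALSE)
      }
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

fit_booster <- function(stack, y, gbc) {
  withr::with_seed(gbc$random_state, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = gbc$learning_rate,
                    max_depth = gbc$max_depth,
                    subsample = gbc$subsample,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(stack, label = as.numeric(y)),
      nrounds = gbc$n_estimators, verbose = 0)
  })
}

#' Fit the integrated predictive model
#'
#' Fits both base learners on the training data — the IPTW-weighted
#' marginal structural model and the MLP — takes their predicted
#' progression probabilities as the two stack features `[pANN, pMSM]`,
#' and fits a gradient-boosted classifier on that pair. By default the
#' stack features are 5-fold out-of-fold base predictions computed within
#' the training partition (standard stacked generalization, so the
#' meta-learner sees honestly calibrated base probabilities);
#' `cross_fit = FALSE` uses in-sample base predictions instead. Either
#' way, every model sees only training rows, and the returned base
#' learners are fitted on the full training set.
#'
#' @param x Data frame of encoded training predictors.
#' @param y Binary training outcome.
#' @param weights Stabilized IPTW for the training patients (used only in
#'   fitting the MSM; prediction needs no weights). Defaults to 1.
#' @param mlp An [mlp_control()].
#' @param gbc A [gbc_control()].
#' @param threshold Classification threshold (default 0.5).
#' @param cross_fit Use 5-fold out-of-fold base predictions for stacking
#'   (default); `FALSE` stacks in-sample predictions.
#' @return Object of class `ipm` holding the MSM, MLP and booster.
#' @export
ipm <- function(x, y, weights = NULL, mlp = mlp_control(),
                gbc = gbc_control(), threshold = 0.5, cross_fit = TRUE) {
  stopifnot(is.data.frame(x), length(y) == nrow(x))
  weights <- weights %||% rep(1, nrow(x))
  msm_fit_ <- fit_msm(x, y, weights)
  mlp_fit_ <- fit_mlp(x, y, mlp)

  if (!cross_fit) {
    p_ann <- predict(mlp_fit_, x)
    p_msm <- predict(msm_fit_, x)
  } else {
    folds <- withr::with_seed(gbc$random_state,
                              sample(rep_len(1:5, nrow(x))))
    p_ann <- p_msm <- rep(NA_real_, nrow(x))
    for (k in 1:5) {
      tr <- folds != k
      m_k <- fit_msm(x[tr, , drop = FALSE], y[tr], weights[tr])
      n_k <- fit_mlp(x[tr, , drop = FALSE], y[tr], mlp)
      p_msm[!tr] <- predict(m_k, x[!tr, , drop = FALSE])
      p_ann[!tr] <- predict(n_k, x[!tr, , drop = FALSE])
    }
  }
  if (anyNA(p_ann) || anyNA(p_msm)) {
    stop("base-model probability missing for some training rows", call. = FALSE)
  }
  stack <- cbind(pANN = p_ann, pMSM = p_msm)
  booster <- fit_booster(stack, y, gbc)
  structure(list(msm = msm_fit_, mlp = mlp_fit_, booster = booster,
                 features = names(x), gbc = gbc, threshold = threshold,
                 cross_fit = cross_fit,
                 train_stack = stack, train_y = as.numeric(y)),
            class = "ipm")
}

#' Predict progression with the integrated model
#'
#' End-to-end: callers supply raw encoded predictor rows; the base models
#' are applied internally and their probabilities fed to the boosted
#' meta-classifier. Stack features are never supplied by the caller.
#'
#' @param object An [ipm()] fit.
#' @param newdata Data frame with the training predictor columns.
#' @param threshold Classification threshold (defaults to the fit's).
#' @param ... Unused.
#' @return Data frame with `pANN`, `pMSM`, `prob` and binary `class`.
#' @export
predict.ipm <- function(object, newdata, threshold = NULL, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop(sprintf("newdata lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  threshold <- threshold %||% object$threshold
  newdata <- newdata[, object$features, drop = FALSE]
  p_ann <- predict(object$mlp, newdata)
  p_msm <- predict(object$msm, newdata)
  stack <- cbind(pANN = p_ann, pMSM = p_msm)
  prob <- predict(object$booster, xgboost::xgb.DMatrix(stack))
  data.frame(pANN = p_ann, pMSM = p_msm, prob = as.numeric(prob),
             class = as.integer(prob >= threshold))
}

#' @export
print.ipm <- function(x, ...) {
  cat("Integrated predictive model (MSM + MLP stacked by gradient boosting)\n")
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  boosting: %d rounds, depth %d, eta %.3g, subsample %.2f%s\n",
              x$gbc$n_estimators, x$gbc$max_depth, x$gbc$learning_rate,
              x$gbc$subsample, if (x$cross_fit) " (cross-fitted stack)" else ""))
  invisible(x)
}

#' @export
summary.ipm <- function(object, ...) {
  print(object)
  cat("\nBase MSM:\n"); print(object$msm)
  cat("\nBase MLP:\n"); print(object$mlp)
  invisible(object)
}

#' @export
coef.ipm <- function(object, ...) coef(object$msm)

#' @export
residuals.ipm <- function(object, ...) {
  prob <- predict(object$booster, xgboost::xgb.DMatrix(object$train_stack))
  object$train_y - as.numeric(prob)
}

#' ROC overlay for the integrated model and its base learners
#'
#' @param x An [ipm()] fit.
#' @param newdata Encoded predictor rows (typically the test partition).
#' @param y True outcomes for `newdata`.
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics abline legend lines
#' @export
plot.ipm <- function(x, newdata, y, ...) {
  pr <- predict(x, newdata)
  curves <- list(MSM = pr$pMSM, MLP = pr$pANN, IPM = pr$prob)
  cols <- c(MSM = "grey40", MLP = "steelblue", IPM = "firebrick")
  plot(0:1, 0:1, type = "l", lty = 3, col = "grey70",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  labs <- character(0)
  for (nm in names(curves)) {
    r <- roc_points(y, curves[[nm]])
    lines(r$fpr, r$tpr, col = cols[nm], lwd = 2)
    labs <- c(labs, sprintf("%s (AUC %.2f)", nm, roc_auc(y, curves[[nm]])))
  }
  legend("bottomright", legend = labs, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
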