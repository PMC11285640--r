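#' Fit the marginal structural model by weighted least squares
#'
#' A linear probability model: the binary progression outcome is regressed
#' on the encoded predictors by least squares with the stabilized IPTW as
#' observation weights, so the coefficients estimate marginal
#' (population-level) associations under the weighting assumptions.
#' Standard errors are heteroskedasticity-robust (HC1) by default.
#'
#' @param x Data frame of numeric predictor columns.
#' @param y Binary outcome vector (0/1).
#' @param weights Positive per-patient weights (defaults to 1).
#' @param robust Use sandwich (HC1) standard errors.
#' @return Object of class `msm_fit`.
#' @export
fit_msm <- function(x, y, weights = NULL, robust = TRUE) {
  stopifnot(is.data.frame(x), length(y) == nrow(x))
  weights <- weights %||% rep(1, nrow(x))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  d <- cbind(data.frame(.y = as.numeric(y)), x)
  fit <- lm(.y ~ ., data = d, weights = weights)
  dropped <- character(0)
  if (anyNA(coef(fit))) {
    dropped <- setdiff(names(coef(fit))[is.na(coef(fit))], "(Intercept)")
    warning(sprintf("dropping aliased column(s): %s",
                    paste(dropped, collapse = ", ")))
    d <- d[, !names(d) %in% dropped, drop = FALSE]
    fit <- lm(.y ~ ., data = d, weights = weights)
  }
  vc <- if (robust) {
    # high-leverage observations in small weighted samples trigger a
    # near-singularity note from the HC1 estimator; harmless for ranking
    withCallingHandlers(
      sandwich::vcovHC(fit, type = "HC1"),
      warning = function(w) {
        if (grepl("close to.*singular|singular.*hat", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else stats::vcov(fit)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  structure(list(
    lm = fit,
    coefficients = coef(fit),
    se = ct[, "Std. Error"],
    p_values = ct[, ncol(ct)],
    features = setdiff(names(d), ".y"),
    dropped = dropped,
    robust = robust,
    weight_summary = summary(weights)
  ), class = "msm_fit")
}

#' @export
coef.msm_fit <- function(object, ...) object$coefficients

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("Marginal structural model (WLS, %s SEs): %d features\n",
              if (x$robust) "robust HC1" else "classical", length(x$features)))
  tab <- data.frame(coefficient = x$coefficients, se = x$se, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.msm_fit <- function(object, ...) {
  cat("Weight summary used in fitting:\n"); print(object$weight_summary)
  print(object)
  invisible(object)
}

#' Predicted progression probabilities from the MSM
#'
#' The linear predictor of the linear probability model, clipped to
#' `[0, 1]`. Weights play no role at prediction time.
#'
#' @param object An `msm_fit`.
#' @param newdata Data frame with the training predictor columns.
#' @param clip Clip to the unit interval (default); `FALSE` returns the
#'   raw linear predictor.
#' @param ... Unused.
#' @return Numeric vector of probabilities (`pMSM`).
#' @export
predict.msm_fit <- function(object, newdata, clip = TRUE, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop(sprintf("newdata lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  lp <- as.numeric(predict(object$lm, newdata = newdata))
  if (clip) clip01(lp) else lp
}

#' @export
residuals.msm_fit <- function(object, ...) stats::residuals(object$lm)

#' Rank MSM features by their WLS coefficients
#'
#' Features sorted by coefficient, largest first, with significance
#' starred at p < 0.05; ties keep input order.
#'
#' @param fit An `msm_fit`.
#' @return Data frame with `rank`, `feature`, `coefficient`, `p_value`,
#'   `significant`.
#' @export
rank_msm_features <- function(fit) {
  stopifnot(inherits(fit, "msm_fit"))
  keep <- names(fit$coefficients) != "(Intercept)"
  co <- fit$coefficients[keep]
  p <- fit$p_values[keep]
  o <- order(-co)
  data.frame(rank = seq_along(o), feature = names(co)[o],
             coefficient = unname(co[o]), p_value = unname(p[o]),
             significant = unname(p[o] < 0.05),
             stringsAsFactors = FALSE)
}
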