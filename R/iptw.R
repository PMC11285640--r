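# Logistic fit that falls back to a small ridge penalty when the ordinary
# fit reports perfect separation (fitted probabilities of 0/1).
safe_logit <- function(formula, data) {
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!separated) {
    return(structure(list(type = "glm", fit = fit, formula = formula),
                     class = "safe_logit"))
  }
  warning("perfect separation in exposure model; refitting with a ridge penalty")
  mf <- model.matrix(formula, data)
  x <- mf[, -1, drop = FALSE]
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, .pad = 0)
  y <- model.response(stats::model.frame(formula, data))
  rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1e-3)
  structure(list(type = "ridge", fit = rf, formula = formula, pad = pad),
            class = "safe_logit")
}

predict_prob <- function(object, newdata) {
  if (object$type == "glm") {
    as.numeric(predict(object$fit, newdata = newdata, type = "response"))
  } else {
    mf <- model.matrix(object$formula, newdata)
    x <- mf[, -1, drop = FALSE]
    if (object$pad) x <- cbind(x, .pad = 0)
    as.numeric(predict(object$fit, newx = x, type = "response"))
  }
}

#' Fit the numerator and denominator exposure models
#'
#' Pooled logistic regressions for the yearly exposure indicator. At the
#' baseline year both models condition on the baseline covariates only
#' (their ratio cancels exactly). For later years the numerator model
#' conditions on the previous exposure and the baseline covariates, and
#' the denominator model additionally on the lagged time-varying
#' covariates; both are pooled over years with year fixed effects. Years
#' in which every patient has the same exposure are degenerate: they are
#' left out of the pooled fits and contribute probability 1 to both
#' weight products.
#'
#' @param panel Output of [build_panel()].
#' @param baseline Baseline covariate columns (may be empty).
#' @param timevarying Lagged time-varying covariate columns used by the
#'   denominator model.
#' @param interactions If `TRUE`, terms enter fully crossed (`*`), which
#'   saturates the model on small discrete panels.
#' @param stabilizer `"as_printed"` keeps the baseline covariates in the
#'   numerator (the form the weighting equation states); `"conventional"`
#'   uses the textbook covariate-free stabilized numerator.
#' @return Object of class `exposure_models`.
#' @export
fit_exposure_models <- function(panel,
                                baseline = paste0("b_", c("age_group", "gender",
                                                          "race", "rural_urban", "hpsa")),
                                timevarying = c("l_util", "l_comorb", "l_cum_mdd"),
                                interactions = FALSE,
                                stabilizer = c("as_printed", "conventional")) {
  stabilizer <- match.arg(stabilizer)
  join <- if (interactions) " * " else " + "
  p0 <- panel[panel$t == 0, ]
  p1 <- panel[panel$t > 0, ]
  if (nrow(p1) == 0) stop("panel has a single year; no lagged exposure to model",
                          call. = FALSE)

  year_e <- tapply(p1$E, p1$year, function(e) length(unique(e)))
  degenerate <- as.integer(names(year_e)[year_e == 1])
  p1f <- p1[!p1$year %in% degenerate, ]
  active_years <- sort(unique(p1f$year))
  p1f$year_f <- factor(p1f$year, levels = active_years)

  num_base <- if (stabilizer == "as_printed") baseline else character(0)
  base_rhs <- if (length(num_base)) paste(num_base, collapse = join) else "1"
  base_fit <- safe_logit(as.formula(paste("E ~", base_rhs)),
                         if (stabilizer == "as_printed") p0 else p0)

  yr_term <- if (length(active_years) > 1) "year_f" else character(0)
  num_terms <- c("E_prev", num_base)
  den_terms <- c("E_prev", baseline, timevarying)
  mk <- function(tm) {
    rhs <- paste(tm, collapse = join)
    if (length(yr_term)) rhs <- paste(rhs, "+", yr_term)
    as.formula(paste("E ~", rhs))
  }
  num_fit <- safe_logit(mk(num_terms), p1f)
  den_fit <- safe_logit(mk(den_terms), p1f)

  # denominator baseline model always conditions on the full baseline set
  den_base_fit <- if (stabilizer == "as_printed") base_fit else {
    rhs <- if (length(baseline)) paste(baseline, collapse = join) else "1"
    safe_logit(as.formula(paste("E ~", rhs)), p0)
  }

  structure(list(base_num = base_fit, base_den = den_base_fit,
                 num = num_fit, den = den_fit,
                 degenerate_years = degenerate, active_years = active_years,
                 baseline = baseline, timevarying = timevarying,
                 stabilizer = stabilizer),
            class = "exposure_models")
}

#' @export
print.exposure_models <- function(x, ...) {
  cat("Pooled exposure models for stabilized IPTW\n")
  cat("  numerator:  ", deparse(x$num$formula), "\n")
  cat("  denominator:", deparse(x$den$formula), "\n")
  if (length(x$degenerate_years)) {
    cat("  degenerate years (probability 1):",
        paste(x$degenerate_years, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' For each patient the weight is the product over panel years of the
#' ratio of the numerator to the denominator model's probability of the
#' exposure actually received (`p` when exposed, `1 - p` when not). The
#' baseline-year terms cancel by construction; degenerate years contribute
#' 1. Denominator probabilities below `floor` are clipped, and the number
#' of clipped terms is reported.
#'
#' @param panel Output of [build_panel()].
#' @param models Output of [fit_exposure_models()].
#' @param floor Lower clip for realized denominator probabilities.
#' @return Object of class `stabilized_weights`: a data frame with
#'   `patient_id`, `weight`, `numerator_logprob`, `denominator_logprob`.
#' @export
compute_iptw <- function(panel, models, floor = 1e-6) {
  n <- nrow(panel)
  p_num <- rep(1, n); p_den <- rep(1, n)
  i0 <- panel$t == 0
  p_num[i0] <- predict_prob(models$base_num, panel[i0, ])
  p_den[i0] <- predict_prob(models$base_den, panel[i0, ])
  i1 <- panel$t > 0 & !panel$year %in% models$degenerate_years
  if (any(i1)) {
    nd <- panel[i1, ]
    nd$year_f <- factor(nd$year, levels = models$active_years)
    p_num[i1] <- predict_prob(models$num, nd)
    p_den[i1] <- predict_prob(models$den, nd)
  }
  w <- stabilized_product(panel$patient_id, p_num, p_den, panel$E, floor)
  n_clipped <- attr(w, "n_clipped")
  attr(w, "n_clipped") <- n_clipped
  attr(w, "mean_weight") <- mean(w$weight)
  attr(w, "extreme_fraction") <- mean(w$weight > 10 | w$weight < 0.1)
  class(w) <- c("stabilized_weights", "data.frame")
  w
}

# per-patient product of realized-probability ratios: the probability of
# the exposure actually received (p if E=1, 1-p if E=0) enters numerator
# and denominator alike
stabilized_product <- function(patient_id, p_num, p_den, E, floor = 1e-6) {
  r_num <- p_num * E + (1 - p_num) * (1 - E)
  r_den <- p_den * E + (1 - p_den) * (1 - E)
  n_clipped <- sum(r_den < floor)
  r_den <- pmax(r_den, floor)
  ln <- tapply(log(r_num), patient_id, sum)
  ld <- tapply(log(r_den), patient_id, sum)
  ids <- unique(patient_id)
  w <- data.frame(patient_id = ids,
                  weight = exp(as.numeric(ln[as.character(ids)]) -
                                 as.numeric(ld[as.character(ids)])),
                  numerator_logprob = as.numeric(ln[as.character(ids)]),
                  denominator_logprob = as.numeric(ld[as.character(ids)]),
                  stringsAsFactors = FALSE)
  stopifnot(all(is.finite(w$weight)), all(w$weight > 0))
  attr(w, "n_clipped") <- n_clipped
  w
}

#' @export
print.stabilized_weights <- function(x, ...) {
  cat(sprintf("Stabilized IPTW for %d patients: mean %.4f, range [%.4f, %.4f]\n",
              nrow(x), attr(x, "mean_weight"), min(x$weight), max(x$weight)))
  cat(sprintf("  extreme (<0.1 or >10): %.2f%%; clipped denominator terms: %d\n",
              100 * attr(x, "extreme_fraction"), attr(x, "n_clipped")))
  invisible(x)
}
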