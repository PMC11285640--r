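#' Configuration for MCMC multiple imputation
#'
#' @param m Number of imputed datasets.
#' @param burn_in Gibbs warm-up iterations per chain.
#' @param seed Master seed; each chain derives its own stream.
#' @param pooling `"per-dataset-mean"` averages evaluation metrics over
#'   the m completed datasets; `"single-dataset"` evaluates the first
#'   completed dataset only.
#' @return Object of class `imputation_config`.
#' @export
imputation_config <- function(m = 5L, burn_in = 50L, seed = 1L,
                              pooling = c("per-dataset-mean", "single-dataset")) {
  if (m < 1) stop_config("m", "need at least one imputation")
  if (burn_in < 0) stop_config("burn_in", "must be non-negative")
  structure(list(m = as.integer(m), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), pooling = match.arg(pooling)),
            class = "imputation_config")
}

# one data-augmentation Gibbs chain under a joint multivariate-normal
# model: posterior draws of (mu, Sigma) given the completed data, then
# conditional normal draws of the missing cells
mvn_da_chain <- function(X, M, burn_in) {
  n <- nrow(X); p <- ncol(X)
  Xc <- X
  for (j in seq_len(p)) Xc[M[, j], j] <- mean(X[!M[, j], j])
  patterns <- apply(M, 1, paste, collapse = "")
  groups <- split(seq_len(n), patterns)
  groups <- groups[vapply(groups, function(i) any(M[i[1], ]), TRUE)]
  for (iter in seq_len(burn_in + 1L)) {
    xbar <- colMeans(Xc)
    S <- crossprod(sweep(Xc, 2, xbar)) + diag(1e-8 * mean(diag(stats::cov(Xc))) + 1e-12, p)
    W <- rWishart(1, n - 1, solve(S))[, , 1]
    Sigma <- solve(W)
    Sigma <- (Sigma + t(Sigma)) / 2
    mu <- MASS::mvrnorm(1, xbar, Sigma / n)
    for (rows in groups) {
      mis <- M[rows[1], ]; obs <- !mis
      if (!any(obs)) {
        Xc[rows, ] <- MASS::mvrnorm(length(rows), mu, Sigma)
        next
      }
      Soo_inv <- solve(Sigma[obs, obs, drop = FALSE])
      B <- Sigma[mis, obs, drop = FALSE] %*% Soo_inv
      cond_cov <- Sigma[mis, mis, drop = FALSE] -
        B %*% Sigma[obs, mis, drop = FALSE]
      cond_cov <- (cond_cov + t(cond_cov)) / 2
      resid <- sweep(Xc[rows, obs, drop = FALSE], 2, mu[obs])
      cmean <- sweep(resid %*% t(B), 2, mu[mis], "+")
      ch <- chol(cond_cov + diag(1e-12, sum(mis)))
      z <- matrix(rnorm(length(rows) * sum(mis)), length(rows))
      Xc[rows, mis] <- cmean + z %*% ch
    }
  }
  Xc
}

#' Multiply impute missing predictor cells
#'
#' Categorical predictors are assumed to be numerically coded already
#' (see [encode_cohort()]); after the normal-model draws they are decoded
#' by nearest-level rounding. Observed cells are never altered, and the m
#' chains are seeded independently.
#'
#' @param table Data frame of numeric predictor columns with `NA`s.
#' @param config An [imputation_config()].
#' @param categorical Named list of valid numeric codes per categorical
#'   column; defaults to the codes of [predictor_levels()] for columns
#'   with those names.
#' @return List of `m` completed data frames (class `imputed_tables`).
#' @export
impute <- function(table, config = imputation_config(), categorical = NULL) {
  num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
  X <- as.matrix(table[, num_cols, drop = FALSE])
  M <- is.na(X)
  if (any(colSums(!M) == 0)) {
    stop(sprintf("column(s) entirely missing: %s",
                 paste(num_cols[colSums(!M) == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(categorical)) {
    lv <- predictor_levels()
    categorical <- lapply(lv[intersect(names(lv), num_cols)],
                          function(l) seq_along(l))
  }
  out <- vector("list", config$m)
  for (j in seq_len(config$m)) {
    if (!any(M)) {
      out[[j]] <- table
      next
    }
    Xc <- withr::with_seed(derive_seed(config$seed, paste0("chain", j)),
                           mvn_da_chain(X, M, config$burn_in))
    for (cl in names(categorical)) {
      codes <- categorical[[cl]]
      v <- Xc[, cl]
      miss <- M[, cl]
      v[miss] <- codes[vapply(v[miss],
                              function(z) which.min(abs(codes - z)), 0L)]
      Xc[, cl] <- v
    }
    # counts cannot go negative
    for (cl in intersect(c("utilization_days", "mdd_claim_count"), num_cols)) {
      Xc[M[, cl], cl] <- pmax(Xc[M[, cl], cl], 0)
    }
    comp <- table
    comp[, num_cols] <- as.data.frame(Xc)
    out[[j]] <- comp
  }
  structure(out, class = "imputed_tables", config = config)
}
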