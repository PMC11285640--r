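#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm lm predict binomial coef plogis qlogis rbinom rnorm
#'   rpois runif rWishart sd t.test chisq.test quantile model.matrix
#'   model.frame model.response as.formula setNames optim var
#' @importFrom utils write.table read.delim packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed and a short stage tag, so that stages have distinct,
#' reproducible random streams.
#'
#' @param master Master seed (integer).
#' @param tag Character stage tag, e.g. `"simulate"` or `"split"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(tag))
  h <- (abs(master) %% 2147483647)
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# small string hash for manifests (not cryptographic)
text_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
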