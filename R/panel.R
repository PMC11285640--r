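#' Build per-patient, per-year exposure panels
#'
#' Expands claims into a rectangular patient x year panel over the study
#' window. Yearly exposure `E` is 1 iff the patient has an MDD-coded claim
#' that year. Time-varying covariates are derived only from claims in
#' years at or before the panel year: yearly utilization days (`util`),
#' a yearly any-comorbidity flag (`comorb`), and the cumulative MDD claim
#' count (`cum_mdd`), each with its one-year lag (`l_` prefix, 0 at
#' baseline). Baseline covariates are the integer-coded demographics with
#' a `b_` prefix.
#'
#' @param patients Flat patient table.
#' @param claims Long-format claims.
#' @param start_year,end_year Study window; `t = 0` is `start_year`.
#' @param registry A [code_registry()].
#' @param ids Optional subset of patient ids (defaults to all patients).
#' @return Data frame with one row per patient-year, ordered by patient
#'   then `t` (0-based year index).
#' @export
build_panel <- function(patients, claims, start_year, end_year,
                        registry = code_registry(), ids = NULL) {
  if (start_year > end_year) stop("empty year window", call. = FALSE)
  years <- start_year:end_year
  ids <- ids %||% patients$patient_id
  cl <- claims[claims$patient_id %in% ids &
                 claims$year >= start_year & claims$year <= end_year, ]
  cls <- classify_code(cl$code_system, cl$code, registry)
  pidf <- factor(cl$patient_id, levels = ids)
  yrf <- factor(cl$year, levels = years)

  count_mat <- function(sel) {
    m <- table(pidf[sel], yrf[sel])
    matrix(as.numeric(m), nrow = length(ids), ncol = length(years),
           dimnames = NULL)
  }
  mdd_n <- count_mat(cls == "MDD")
  oth_n <- count_mat(cls == "OTHER")
  util <- matrix(0, length(ids), length(years))
  agg <- tapply(cl$utilization_days, list(pidf, yrf), sum)
  agg[is.na(agg)] <- 0
  util[] <- as.numeric(agg)

  E <- (mdd_n > 0) + 0L
  comorb <- (oth_n > 0) + 0L
  cum_mdd <- t(apply(mdd_n, 1, cumsum))
  lag0 <- function(m) cbind(0, m[, -ncol(m), drop = FALSE])

  Tn <- length(years)
  lv <- predictor_levels()
  base <- patients[match(ids, patients$patient_id), ]
  panel <- data.frame(
    patient_id = rep(ids, each = Tn),
    t = rep(0:(Tn - 1), times = length(ids)),
    year = rep(years, times = length(ids)),
    E = as.integer(t(E)),
    E_prev = as.integer(t(lag0(E))),
    util = as.numeric(t(util)),
    comorb = as.integer(t(comorb)),
    cum_mdd = as.numeric(t(cum_mdd)),
    l_util = as.numeric(t(lag0(util))),
    l_comorb = as.integer(t(lag0(comorb))),
    l_cum_mdd = as.numeric(t(lag0(cum_mdd))),
    stringsAsFactors = FALSE
  )
  for (nm in c("age_group", "gender", "race", "rural_urban", "hpsa")) {
    panel[[paste0("b_", nm)]] <- rep(as.numeric(match(base[[nm]], lv[[nm]])),
                                     each = Tn)
  }
  panel
}
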