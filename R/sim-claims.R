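#' Configuration for the synthetic claims simulator
#'
#' The simulator emulates the longitudinal structure of an inpatient /
#' skilled-nursing Medicare claims extract: two study arms of MDD patients
#' (progressed to AD vs remained MDD) observed over an 8-year window,
#' ICD-9 coding through 2015 and ICD-10 from 2016 on, yearly exposure
#' (an MDD-coded claim) confounded by a time-varying illness-burden
#' process that is itself affected by past exposure, and a latent
#' unmeasured factor entering only the outcome hazard.
#'
#' @param n_per_group Patients per study arm (case-control mode).
#' @param start_year,end_year Calendar window (defaults 2012--2019).
#' @param confounding_strength Coefficient of the lagged illness burden in
#'   the yearly exposure model, and of the current burden in the outcome
#'   hazard. A single knob scales both arrows of the confounding path, so
#'   zero removes the confounder entirely.
#' @param exposure_effect Log-odds increment of the yearly progression
#'   hazard per cumulative exposed year.
#' @param latent_effect Coefficient of the standard-normal latent factor
#'   U in the outcome hazard (unmeasured confounding stand-in).
#' @param nonlinear_effect Coefficient of a baseline interaction term
#'   (XOR of older-age and urban residence) in the outcome hazard. This
#'   signal is invisible to a main-effects linear model but learnable by
#'   the network, giving the cohort both linear and non-linear structure.
#' @param missing_rate Fraction of predictor cells masked when the
#'   sensitivity protocol is run on this cohort; in `[0, 1)`.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @param covariate_prevalences Named list of per-predictor category
#'   probability vectors (each summing to 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 282,
                       start_year = 2012, end_year = 2019,
                       confounding_strength = 0.6,
                       exposure_effect = 0.25,
                       latent_effect = 0.5,
                       nonlinear_effect = 1.0,
                       missing_rate = 0,
                       seed = 1,
                       covariate_prevalences = default_prevalences()) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1 ||
      n_per_group < 1 || n_per_group != floor(n_per_group)) {
    stop_config("n_per_group", "must be a positive integer")
  }
  if (!is.numeric(start_year) || !is.numeric(end_year) ||
      start_year >= end_year) {
    stop_config("start_year/end_year", "need start_year < end_year")
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop_config("missing_rate", "must lie in [0, 1)")
  }
  if (!is.numeric(seed) || length(seed) != 1) {
    stop_config("seed", "must be a single integer")
  }
  for (nm in names(covariate_prevalences)) {
    p <- covariate_prevalences[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_config(sprintf("covariate_prevalences$%s", nm),
                  "probabilities must be non-negative and sum to 1")
    }
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    confounding_strength = confounding_strength,
    exposure_effect = exposure_effect,
    latent_effect = latent_effect,
    nonlinear_effect = nonlinear_effect,
    missing_rate = missing_rate,
    seed = as.integer(seed),
    covariate_prevalences = covariate_prevalences
  ), class = "sim_config")
}

#' Default covariate prevalences
#'
#' Marginal category frequencies of the demographic and county predictors,
#' pooled over both study arms of the descriptive sample the package
#' emulates, so that synthetic descriptive tables have face validity.
#'
#' @return Named list of probability vectors.
#' @export
default_prevalences <- function() {
  list(
    age_group  = c("<65" = 149, "65-69" = 47, "70-74" = 50,
                   "75-79" = 166, "80-84" = 90, ">84" = 62) / 564,
    gender     = c(male = 211, female = 353) / 564,
    race       = c(white = 486, black = 56, other = 22) / 564,
    rural_urban = c(rural = 437, urban = 127) / 564,
    hpsa       = c(none = 62, whole = 167, partly = 335) / 564
  )
}

# draw one batch of patients through the structural equations; returns
# patients / claims / truth data frames with temporary integer ids
simulate_batch <- function(nb, config, intervene = FALSE) {
  years <- config$start_year:config$end_year
  Tn <- length(years)
  prev <- config$covariate_prevalences

  draw_cat <- function(p) names(p)[sample.int(length(p), nb, replace = TRUE, prob = p)]
  age_group <- draw_cat(prev$age_group)
  gender <- draw_cat(prev$gender)
  race <- draw_cat(prev$race)
  rural_urban <- draw_cat(prev$rural_urban)
  hpsa <- draw_cat(prev$hpsa)

  age_code <- match(age_group, names(prev$age_group))
  U <- rnorm(nb)
  # linear-invisible baseline signal: XOR of older age and urban residence
  g <- as.numeric(xor(age_code >= 4, rural_urban == "urban"))

  first_t <- sample.int(3L, nb, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  Z <- matrix(0, nb, Tn)
  E <- matrix(0L, nb, Tn)
  ad_t <- rep(NA_integer_, nb)
  Z[, 1] <- rnorm(nb)
  for (t in seq_len(Tn)) {
    if (t > 1) {
      Z[, t] <- 0.7 * Z[, t - 1] + 0.4 * E[, t - 1] + rnorm(nb, 0, 0.6)
    }
    conf_e <- if (intervene) 0 else config$confounding_strength
    pE <- plogis(-0.5 + conf_e * Z[, pmax(t - 1, 1)] +
                   0.8 * (if (t > 1) E[, t - 1] else 0))
    Et <- as.integer(rbinom(nb, 1, pE))
    Et[t < first_t] <- 0L
    Et[t == first_t] <- 1L
    E[, t] <- Et
    # yearly progression hazard, at risk strictly after first MDD year
    cumE <- if (t == 1) E[, 1] else rowSums(E[, 1:t, drop = FALSE])
    h <- plogis(-3.4 + config$exposure_effect * cumE +
                  config$confounding_strength * Z[, t] +
                  config$latent_effect * U +
                  config$nonlinear_effect * (g - 0.5))
    ev <- rbinom(nb, 1, h)
    new_ad <- is.na(ad_t) & ev == 1 & t > first_t
    ad_t[new_ad] <- t
  }
  # --- claims assembly -------------------------------------------------
  mdd_idx <- which(E == 1L, arr.ind = TRUE)
  mdd_year <- years[mdd_idx[, 2]]
  mdd_z <- Z[mdd_idx]
  n_mdd <- nrow(mdd_idx)
  mdd_code <- ifelse(mdd_year <= 2015,
    paste0("296.2", sample.int(7L, n_mdd, replace = TRUE) - 1L),
    paste0("F32.", sample.int(6L, n_mdd, replace = TRUE) - 1L))
  mdd_days <- rpois(n_mdd, exp(1.0 + 0.25 * pmin(pmax(mdd_z, -3), 3)))

  com_mask <- matrix(rbinom(nb * Tn, 1, plogis(-0.8 + 0.5 * Z)), nb, Tn) == 1
  com_idx <- which(com_mask, arr.ind = TRUE)
  com_year <- years[com_idx[, 2]]
  n_com <- nrow(com_idx)
  icd9_other <- c("401.9", "250.00", "414.01")
  icd10_other <- c("I10", "E11.9", "I25.10")
  pick <- sample.int(3L, n_com, replace = TRUE)
  com_code <- ifelse(com_year <= 2015, icd9_other[pick], icd10_other[pick])
  com_days <- rpois(n_com, exp(0.7 + 0.25 * pmin(pmax(Z[com_idx], -3), 3)))

  prog <- which(!is.na(ad_t))
  ad_year <- years[ad_t[prog]]
  n_ad <- length(prog)
  g30 <- c("G30.0", "G30.1", "G30.8", "G30.9")
  ad_code <- ifelse(ad_year <= 2015, "331.0",
                    g30[sample.int(4L, n_ad, replace = TRUE, prob = c(.1, .05, .05, .8))])
  # the AD-onset claim marks the diagnosis; it carries no utilization days,
  # so the endpoint itself never leaks into the utilization feature
  ad_days <- rep(0L, n_ad)

  claims <- data.frame(
    idx = c(mdd_idx[, 1], com_idx[, 1], prog),
    year = c(mdd_year, com_year, ad_year),
    code = c(mdd_code, com_code, ad_code),
    utilization_days = c(mdd_days, com_days, ad_days),
    stringsAsFactors = FALSE
  )
  claims$code_system <- code_system_for_year(claims$year)
  claims <- claims[order(claims$idx, claims$year, claims$code), ]

  list(
    patients = data.frame(idx = seq_len(nb), age_group = age_group,
                          gender = gender, race = race,
                          rural_urban = rural_urban, hpsa = hpsa,
                          stringsAsFactors = FALSE),
    claims = claims,
    truth = data.frame(idx = seq_len(nb), U = U, nonlinear_term = g,
                       first_mdd_year = years[first_t],
                       ad_year = ifelse(is.na(ad_t), NA_integer_, years[ad_t]),
                       progressed = as.integer(!is.na(ad_t)))
  )
}

#' Simulate a synthetic claims cohort
#'
#' In `"case_control"` mode (the study design emulated by default) batches
#' of patients are drawn through the structural equations and the first
#' `n_per_group` progressors and `n_per_group` never-progressed controls
#' are retained, giving exactly `2 * n_per_group` records. In
#' `"population"` mode the first `n` simulated patients are returned
#' without any outcome-conditioned selection, which is the appropriate
#' design for effect-estimation Monte Carlo.
#'
#' @param config A [sim_config()].
#' @param mode `"case_control"` or `"population"`.
#' @param n Number of patients in population mode (defaults to
#'   `2 * n_per_group`).
#' @param intervene If `TRUE`, the illness-burden term is removed from the
#'   exposure equation (exposure then depends only on past exposure) while
#'   every outcome equation is unchanged — the unconfounded counterfactual
#'   regime used to compute true marginal exposure effects, matching the
#'   pseudo-population that stabilized weighting targets.
#' @return A `claims_cohort`: list with `patients`, `claims` and `truth`
#'   data frames, plus the config and mode.
#' @export
simulate_cohort <- function(config, mode = c("case_control", "population"),
                            n = NULL, intervene = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  withr::with_seed(config$seed, {
    if (mode == "population") {
      n <- n %||% (2L * config$n_per_group)
      out <- simulate_batch(n, config, intervene)
    } else {
      want <- config$n_per_group
      acc <- list()
      got_p <- 0L; got_c <- 0L; guard <- 0L
      while (got_p < want || got_c < want) {
        guard <- guard + 1L
        if (guard > 200L) {
          stop("case-control sampling failed to fill both arms; ",
               "check the hazard configuration", call. = FALSE)
        }
        b <- simulate_batch(max(4L * want, 500L), config, intervene)
        keep_p <- b$truth$idx[b$truth$progressed == 1][seq_len(
          min(want - got_p, sum(b$truth$progressed == 1)))]
        keep_c <- b$truth$idx[b$truth$progressed == 0][seq_len(
          min(want - got_c, sum(b$truth$progressed == 0)))]
        keep <- c(keep_p, keep_c)
        if (length(keep)) {
          kept <- lapply(b, function(d) d[d$idx %in% keep, ])
          # disambiguate batch-local indices before concatenation
          kept <- lapply(kept, function(d) {
            d$idx <- d$idx + guard * 1e7
            d
          })
          acc[[length(acc) + 1L]] <- kept
          got_p <- got_p + length(keep_p); got_c <- got_c + length(keep_c)
        }
      }
      out <- list(
        patients = do.call(rbind, lapply(acc, `[[`, "patients")),
        claims = do.call(rbind, lapply(acc, `[[`, "claims")),
        truth = do.call(rbind, lapply(acc, `[[`, "truth"))
      )
    }
    # stable opaque ids replacing batch-local indices
    pid <- sprintf("P%06d", seq_len(nrow(out$patients)))
    key <- function(idx) match(idx, out$patients$idx)
    out$claims$patient_id <- pid[key(out$claims$idx)]
    out$truth$patient_id <- pid[key(out$truth$idx)]
    out$patients$patient_id <- pid
    out$patients$idx <- out$claims$idx <- out$truth$idx <- NULL
    out$patients <- out$patients[, c("patient_id", "age_group", "gender",
                                     "race", "rural_urban", "hpsa")]
    out$claims <- out$claims[, c("patient_id", "year", "code_system",
                                 "code", "utilization_days")]
    out$claims <- out$claims[order(out$claims$patient_id, out$claims$year,
                                   out$claims$code), ]
    rownames(out$patients) <- rownames(out$claims) <- rownames(out$truth) <- NULL
    structure(c(out, list(config = config, mode = mode,
                          intervene = intervene)),
              class = "claims_cohort")
  })
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat(sprintf("Synthetic claims cohort (%s mode): %d patients, %d claims, %d-%d\n",
              x$mode, nrow(x$patients), nrow(x$claims),
              x$config$start_year, x$config$end_year))
  cat(sprintf("  progressed to AD: %d / remained MDD: %d\n",
              sum(x$truth$progressed), sum(1 - x$truth$progressed)))
  invisible(x)
}

#' Mask predictor cells completely at random
#'
#' Each predictor cell is masked independently with probability `rate`;
#' the outcome column and identifier columns are never touched. This is
#' the deliberate-distortion step of the sensitivity protocol (default
#' rate there is 40%).
#'
#' @param table A data frame of features.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param exclude Column names never masked.
#' @return The table with masked cells set to `NA`.
#' @export
inject_missingness <- function(table, rate, seed,
                               exclude = c("patient_id", "outcome")) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(table)
  cols <- setdiff(names(table), exclude)
  withr::with_seed(seed, {
    for (cl in cols) {
      mask <- runif(nrow(table)) < rate
      table[[cl]][mask] <- NA
    }
  })
  table
}

#' Write a claims cohort as delimited text with a provenance sidecar
#'
#' Emits `patients.tsv` (flat demographics/county file), `claims.tsv`
#' (long-format claims) and `provenance.json` recording the seed, a config
#' hash and the generator version.
#'
#' @param cohort A `claims_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_claims_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "claims_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$patients, file.path(dir, "patients.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cohort$claims, file.path(dir, "claims.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  prov <- list(seed = cohort$config$seed,
               config_hash = text_hash(cohort$config),
               generator_version = as.character(packageVersion("adprogress")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
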