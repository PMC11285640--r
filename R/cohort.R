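#' Canonical predictor levels
#'
#' Level orderings used everywhere a predictor is encoded numerically.
#' The first level is the reference; ordered variables (age band, HPSA
#' severity) are listed in their natural order.
#'
#' @return Named list of character level vectors.
#' @export
predictor_levels <- function() {
  list(
    age_group = c("<65", "65-69", "70-74", "75-79", "80-84", ">84"),
    gender = c("male", "female"),
    race = c("white", "black", "other"),
    rural_urban = c("rural", "urban"),
    hpsa = c("none", "whole", "partly"),
    comorbidity = c("none", "one-or-more"),
    follow_up = c("no-follow-up", "at-least-two-visits")
  )
}

predictor_names <- function() {
  c("age_group", "gender", "race", "rural_urban", "hpsa",
    "comorbidity", "follow_up", "utilization_days", "mdd_claim_count")
}

#' Label patients by progression status
#'
#' A patient progressed iff their first MDD-coded claim year strictly
#' precedes their first AD-coded claim year. Patients whose first AD year
#' is at or before their first MDD year are excluded (precedence cannot be
#' established at year resolution), patients with AD but no MDD claims are
#' dropped, and patients with MDD claims only are candidates for the
#' remained-MDD control arm.
#'
#' @param claims Long-format claims data frame with `patient_id`, `year`,
#'   `code_system`, `code`.
#' @param registry A [code_registry()].
#' @return Data frame with `patient_id`, `first_mdd_year`, `first_ad_year`,
#'   `status` in `{"progressed","remained","excluded","dropped"}`.
#' @export
build_outcome <- function(claims, registry = code_registry()) {
  cls <- classify_code(claims$code_system, claims$code, registry)
  ids <- unique(claims$patient_id)
  min_year_by <- function(sel) {
    if (!any(sel)) return(rep(NA_real_, length(ids)))
    unname(tapply(claims$year[sel], claims$patient_id[sel], min)[ids])
  }
  first_mdd <- min_year_by(cls == "MDD")
  first_ad <- min_year_by(cls == "AD")
  status <- ifelse(is.na(first_mdd), "dropped",
            ifelse(is.na(first_ad), "remained",
            ifelse(first_mdd < first_ad, "progressed", "excluded")))
  data.frame(patient_id = ids,
             first_mdd_year = as.integer(first_mdd),
             first_ad_year = as.integer(first_ad),
             status = status, stringsAsFactors = FALSE)
}

#' Randomly sample the control arm
#'
#' Simple random sample without replacement of `n` remained-MDD candidates.
#'
#' @param candidates Character vector of candidate patient ids.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Character vector of sampled ids.
#' @export
sample_controls <- function(candidates, n, seed) {
  if (length(candidates) < n) {
    stop(sprintf("need %d controls but only %d candidates (shortfall %d)",
                 n, length(candidates), n - length(candidates)), call. = FALSE)
  }
  withr::with_seed(seed, sample(candidates, n))
}

#' Derive the analysis feature vector for each patient
#'
#' Implements the predictor definitions: total utilization days over claims
#' in or after the first MDD year; comorbidity flag for any claim outside
#' the MDD/AD code sets; the MDD claim count; and the follow-up indicator
#' (at least two MDD-coded visits).
#'
#' @param patients Flat patient table (demographics and county attributes).
#' @param claims Long-format claims.
#' @param outcome Output of [build_outcome()]; only `"progressed"` and
#'   rows whose ids appear in `keep_ids` are retained.
#' @param keep_ids Patient ids to keep (e.g. cases plus sampled controls);
#'   defaults to all non-excluded patients.
#' @param registry A [code_registry()].
#' @return A data frame of analysis rows (one per patient) with the binary
#'   `outcome` column (1 = progressed to AD), carrying exclusion counts in
#'   the `"exclusions"` attribute.
#' @export
derive_features <- function(patients, claims, outcome, keep_ids = NULL,
                            registry = code_registry()) {
  ok <- outcome$status %in% c("progressed", "remained")
  if (!is.null(keep_ids)) ok <- ok & outcome$patient_id %in% keep_ids
  kept <- outcome[ok, ]
  if (nrow(kept) == 0) stop("no analyzable patients", call. = FALSE)
  missing_claims <- setdiff(patients$patient_id, claims$patient_id)
  if (length(missing_claims)) {
    warning(sprintf("%d patient(s) with zero claims dropped",
                    length(missing_claims)))
  }

  cls <- classify_code(claims$code_system, claims$code, registry)
  cl <- claims[claims$patient_id %in% kept$patient_id, ]
  cl_cls <- cls[claims$patient_id %in% kept$patient_id]
  first_mdd <- setNames(kept$first_mdd_year, kept$patient_id)
  post <- cl$year >= first_mdd[cl$patient_id]

  sum_by <- function(x, ids, universe) {
    s <- tapply(x, ids, sum)
    out <- s[universe]; out[is.na(out)] <- 0
    unname(out)
  }
  ids <- kept$patient_id
  util <- sum_by(cl$utilization_days[post], cl$patient_id[post], ids)
  mddn <- sum_by(as.numeric(cl_cls == "MDD"), cl$patient_id, ids)
  othn <- sum_by(as.numeric(cl_cls == "OTHER"), cl$patient_id, ids)
  if (any(mddn < 1)) stop("patient without an MDD claim reached feature derivation",
                          call. = FALSE)

  lv <- predictor_levels()
  rows <- patients[match(ids, patients$patient_id),
                   c("patient_id", "age_group", "gender", "race",
                     "rural_urban", "hpsa")]
  rows$comorbidity <- ifelse(othn >= 1, "one-or-more", "none")
  rows$follow_up <- ifelse(mddn >= 2, "at-least-two-visits", "no-follow-up")
  rows$utilization_days <- as.numeric(util)
  rows$mdd_claim_count <- as.numeric(mddn)
  rows$outcome <- as.integer(kept$status == "progressed")
  rownames(rows) <- NULL
  attr(rows, "exclusions") <- c(
    excluded_ad_precedes = sum(outcome$status == "excluded"),
    dropped_no_mdd = sum(outcome$status == "dropped"),
    dropped_zero_claims = length(missing_claims)
  )
  rows
}

#' Build the analysis cohort from raw claims
#'
#' Convenience wrapper: classify codes, construct the outcome, optionally
#' sample an equal-sized control arm, and derive features.
#'
#' @param patients,claims Raw tables (simulated or ingested).
#' @param registry A [code_registry()].
#' @param equal_controls If `TRUE`, sample as many controls as there are
#'   progressors.
#' @param seed Seed for control sampling.
#' @return Analysis cohort data frame (see [derive_features()]).
#' @export
build_cohort <- function(patients, claims, registry = code_registry(),
                         equal_controls = FALSE, seed = 1) {
  out <- build_outcome(claims, registry)
  keep <- NULL
  if (equal_controls) {
    cases <- out$patient_id[out$status == "progressed"]
    cand <- out$patient_id[out$status == "remained"]
    keep <- c(cases, sample_controls(cand, length(cases), seed))
  }
  derive_features(patients, claims, out, keep_ids = keep, registry = registry)
}

#' Encode cohort predictors as numeric columns
#'
#' Each predictor becomes a single numeric column: categorical variables
#' are integer-coded in the order of [predictor_levels()] (1-based), counts
#' and utilization days stay numeric. One column per predictor mirrors the
#' reporting convention of the feature-ranking tables (one coefficient /
#' one weight sum per predictor).
#'
#' @param cohort Analysis cohort from [build_cohort()].
#' @return Data frame with nine numeric predictor columns plus `outcome`
#'   and `patient_id` when present.
#' @export
encode_cohort <- function(cohort) {
  lv <- predictor_levels()
  enc <- data.frame(row.names = seq_len(nrow(cohort)))
  if ("patient_id" %in% names(cohort)) enc$patient_id <- cohort$patient_id
  for (nm in predictor_names()) {
    if (nm %in% names(lv)) {
      v <- match(cohort[[nm]], lv[[nm]])
      if (any(is.na(v) & !is.na(cohort[[nm]]))) {
        stop(sprintf("unknown level in '%s'", nm), call. = FALSE)
      }
      enc[[nm]] <- as.numeric(v)
    } else {
      enc[[nm]] <- as.numeric(cohort[[nm]])
    }
  }
  if ("outcome" %in% names(cohort)) enc$outcome <- cohort$outcome
  enc
}

#' Descriptive characteristics by outcome group
#'
#' Per-group counts and within-group percentages for the categorical
#' predictors with chi-square tests of independence (no continuity
#' correction by default), and means with standard deviations for the
#' numeric predictors with two-sided independent-sample t-tests.
#' Significance is flagged at the 95% level.
#'
#' @param cohort Analysis cohort with an `outcome` column.
#' @param correct Continuity correction for 2x2 chi-square tables.
#' @return Object of class `descriptive_table`.
#' @export
descriptive_table <- function(cohort, correct = FALSE) {
  stopifnot(all(c(0, 1) %in% cohort$outcome))
  lv <- predictor_levels()
  g0 <- cohort[cohort$outcome == 0, ]
  g1 <- cohort[cohort$outcome == 1, ]
  cat_rows <- list(); tests <- list()
  for (nm in names(lv)) {
    n0 <- table(factor(g0[[nm]], levels = lv[[nm]]))
    n1 <- table(factor(g1[[nm]], levels = lv[[nm]]))
    tab <- rbind(as.numeric(n0), as.numeric(n1))
    keep <- colSums(tab) > 0
    p <- NA_real_; note <- ""
    if (sum(keep) >= 2) {
      p <- suppressWarnings(
        chisq.test(tab[, keep, drop = FALSE], correct = correct)$p.value)
    } else {
      note <- "single observed level; chi-square skipped"
    }
    cat_rows[[nm]] <- data.frame(
      variable = nm, level = lv[[nm]],
      n_remained = as.numeric(n0),
      pct_remained = 100 * as.numeric(n0) / nrow(g0),
      n_progressed = as.numeric(n1),
      pct_progressed = 100 * as.numeric(n1) / nrow(g1),
      stringsAsFactors = FALSE)
    tests[[nm]] <- data.frame(variable = nm, test = "chi-square",
                              p_value = p, note = note,
                              stringsAsFactors = FALSE)
  }
  num_rows <- list()
  for (nm in c("utilization_days", "mdd_claim_count")) {
    p <- tryCatch(t.test(g0[[nm]], g1[[nm]])$p.value, error = function(e) NA_real_)
    num_rows[[nm]] <- data.frame(
      variable = nm,
      mean_remained = mean(g0[[nm]]), sd_remained = sd(g0[[nm]]),
      mean_progressed = mean(g1[[nm]]), sd_progressed = sd(g1[[nm]]),
      stringsAsFactors = FALSE)
    tests[[nm]] <- data.frame(variable = nm, test = "t-test",
                              p_value = p, note = "", stringsAsFactors = FALSE)
  }
  res <- list(categorical = do.call(rbind, cat_rows),
              numeric = do.call(rbind, num_rows),
              tests = do.call(rbind, tests),
              n = c(remained = nrow(g0), progressed = nrow(g1)))
  rownames(res$categorical) <- rownames(res$numeric) <- rownames(res$tests) <- NULL
  res$tests$significant <- !is.na(res$tests$p_value) & res$tests$p_value < 0.05
  class(res) <- "descriptive_table"
  res
}

#' @export
print.descriptive_table <- function(x, digits = 2, ...) {
  cat(sprintf("Descriptive characteristics (remained MDD n=%d, progressed to AD n=%d)\n\n",
              x$n["remained"], x$n["progressed"]))
  for (v in unique(x$categorical$variable)) {
    tst <- x$tests[x$tests$variable == v, ]
    star <- if (isTRUE(tst$significant)) " *" else ""
    cat(sprintf("%s%s\n", v, star))
    d <- x$categorical[x$categorical$variable == v, ]
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %-22s %5d %6.2f%% %5d %6.2f%%\n", d$level[i],
                  d$n_remained[i], d$pct_remained[i],
                  d$n_progressed[i], d$pct_progressed[i]))
    }
  }
  cat("\n")
  for (i in seq_len(nrow(x$numeric))) {
    d <- x$numeric[i, ]
    tst <- x$tests[x$tests$variable == d$variable, ]
    star <- if (isTRUE(tst$significant)) " *" else ""
    cat(sprintf("%-24s %6.2f +/- %5.2f  %6.2f +/- %5.2f%s\n", d$variable,
                d$mean_remained, d$sd_remained,
                d$mean_progressed, d$sd_progressed, star))
  }
  invisible(x)
}
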