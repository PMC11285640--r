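# small in-code fixtures shared across tests

# a tiny hand-written claims table: one progressor, one control, one
# excluded (AD precedes MDD), one tie year (excluded)
tiny_claims <- function() {
  data.frame(
    patient_id = c("A", "A", "A", "B", "C", "C", "D", "D"),
    year = c(2013, 2012, 2015, 2014, 2013, 2015, 2014, 2014),
    code_system = c("ICD9", "ICD9", "ICD9", "ICD9",
                    "ICD9", "ICD9", "ICD9", "ICD9"),
    code = c("296.21", "401.9", "296.24", "296.20",
             "331.0", "296.22", "296.23", "331.0"),
    utilization_days = c(3, 5, 4, 2, 1, 2, 3, 1),
    stringsAsFactors = FALSE
  )
}

tiny_patients <- function(ids = c("A", "B", "C", "D")) {
  data.frame(
    patient_id = ids,
    age_group = rep("75-79", length(ids)),
    gender = rep("female", length(ids)),
    race = rep("white", length(ids)),
    rural_urban = rep("rural", length(ids)),
    hpsa = rep("partly", length(ids)),
    stringsAsFactors = FALSE
  )
}

# simulated encoded cohort ready for model fitting
sim_encoded <- function(n_per_group = 60, seed = 1) {
  raw <- simulate_cohort(sim_config(n_per_group = n_per_group, seed = seed))
  cohort <- build_cohort(raw$patients, raw$claims)
  enc <- encode_cohort(cohort)
  list(raw = raw, cohort = cohort,
       x = enc[, setdiff(names(enc), c("patient_id", "outcome"))],
       y = enc$outcome)
}

# direct-enumeration AUC oracle: Mann-Whitney U / (n1 * n0)
auc_u_oracle <- function(y, s) {
  u <- unname(suppressWarnings(
    stats::wilcox.test(s[y == 1], s[y == 0])$statistic))
  u / (sum(y == 1) * sum(y == 0))
}
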