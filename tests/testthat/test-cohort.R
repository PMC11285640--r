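test_that("code classification matches the registry families", {
  expect_equal(classify_code("ICD10", "G30.9"), "AD")
  expect_equal(classify_code("ICD9", "296.21"), "MDD")
  expect_equal(classify_code("ICD9", "296.2"), "MDD")
  expect_equal(classify_code("ICD10", "F32.0"), "MDD")
  expect_equal(classify_code("ICD9", "331.0"), "AD")
  expect_equal(classify_code("ICD9", "331.00"), "OTHER")  # AD is exact-match
  expect_equal(classify_code("ICD10", "I10"), "OTHER")
  expect_error(classify_code("ICD11", "foo"), "code system")
  expect_error(classify_code("ICD9", ""), "empty")
})

test_that("recurrent-depression codes are OTHER by default, MDD only when extended", {
  expect_equal(classify_code("ICD10", "F33.1"), "OTHER")
  expect_equal(classify_code("ICD9", "296.30"), "OTHER")
  ext <- code_registry(extended = TRUE)
  expect_equal(classify_code("ICD10", "F33.1", ext), "MDD")
  expect_equal(classify_code("ICD9", "296.30", ext), "MDD")
})

test_that("outcome construction implements the precedence rule", {
  out <- build_outcome(tiny_claims())
  status <- setNames(out$status, out$patient_id)
  expect_equal(unname(status["A"]), "remained")    # MDD only
  expect_equal(unname(status["B"]), "remained")
  expect_equal(unname(status["C"]), "excluded")    # AD 2013 before MDD 2015
  expect_equal(unname(status["D"]), "excluded")    # tie year
  prog <- build_outcome(data.frame(
    patient_id = "P", year = c(2013, 2017), code_system = c("ICD9", "ICD10"),
    code = c("296.21", "G30.9"), utilization_days = c(1, 1)))
  expect_equal(prog$status, "progressed")
})

test_that("outcome labels are invariant to claim order", {
  cl <- tiny_claims()
  base <- build_outcome(cl)
  for (s in 1:5) {
    perm <- withr::with_seed(s, cl[sample(nrow(cl)), ])
    out <- build_outcome(perm)
    expect_equal(out[order(out$patient_id), ], base[order(base$patient_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("feature derivation follows the stated rules", {
  cl <- data.frame(
    patient_id = "A",
    year = c(2013, 2012, 2015),
    code_system = "ICD9",
    code = c("296.21", "401.9", "296.24"),
    utilization_days = c(3, 5, 4))
  out <- build_outcome(cl)
  f <- derive_features(tiny_patients("A"), cl, out)
  expect_equal(f$utilization_days, 7)        # pre-MDD 2012 claim excluded
  expect_equal(f$comorbidity, "one-or-more") # the OTHER claim still counts
  expect_equal(f$mdd_claim_count, 2)
  expect_equal(f$follow_up, "at-least-two-visits")
  expect_equal(f$outcome, 0L)

  single <- cl[1, ]
  f1 <- derive_features(tiny_patients("A"), single, build_outcome(single))
  expect_equal(f1$comorbidity, "none")
  expect_equal(f1$follow_up, "no-follow-up")
  expect_equal(f1$mdd_claim_count, 1)

  # pure function: repeated calls agree
  expect_identical(f, derive_features(tiny_patients("A"), cl, out))
})

test_that("control sampling is seeded, exhaustive at the boundary, and unbiased", {
  cand <- sprintf("C%04d", 1:500)
  expect_setequal(sample_controls(cand, 500, 1), cand)
  expect_identical(sample_controls(cand, 100, 42), sample_controls(cand, 100, 42))
  expect_error(sample_controls(cand, 501, 1), "shortfall")
  # inclusion frequency over reseeded draws approximates n/N
  hits <- integer(length(cand))
  n_draws <- 400
  for (s in seq_len(n_draws)) {
    hits[match(sample_controls(cand, 100, s), cand)] <-
      hits[match(sample_controls(cand, 100, s), cand)] + 1L
  }
  p <- 100 / 500
  se <- sqrt(p * (1 - p) / n_draws)
  within3 <- abs(hits / n_draws - p) <= 3 * se
  expect_gte(mean(within3), 0.99)
  expect_equal(mean(hits) / n_draws, p)  # exact by construction
})

test_that("descriptive table percentages are within-group and sum to 100", {
  fx <- sim_encoded(n_per_group = 50, seed = 4)
  d <- descriptive_table(fx$cohort)
  for (v in unique(d$categorical$variable)) {
    rows <- d$categorical[d$categorical$variable == v, ]
    expect_equal(sum(rows$pct_remained), 100, tolerance = 1e-9)
    expect_equal(sum(rows$pct_progressed), 100, tolerance = 1e-9)
  }
  expect_true(all(d$tests$p_value >= 0 & d$tests$p_value <= 1, na.rm = TRUE))
})

test_that("degenerate descriptive cases are handled explicitly", {
  cohort <- data.frame(
    age_group = "75-79", gender = "female", race = "white",
    rural_urban = "rural", hpsa = "partly", comorbidity = "none",
    follow_up = "no-follow-up",
    utilization_days = rep(c(3, 5), 20), mdd_claim_count = rep(c(1, 2), 20),
    outcome = rep(0:1, each = 20))
  d <- descriptive_table(cohort)
  chi <- d$tests[d$tests$test == "chi-square", ]
  expect_true(all(is.na(chi$p_value)))
  expect_true(all(grepl("single observed level", chi$note)))
  # identical numeric distributions across groups: t-test far from significant
  num <- d$tests[d$tests$test == "t-test", ]
  expect_true(all(num$p_value > 0.99))
})

test_that("encoding maps levels to the documented integer codes", {
  fx <- sim_encoded(n_per_group = 20, seed = 6)
  enc <- encode_cohort(fx$cohort)
  expect_true(all(enc$gender %in% 1:2))
  expect_true(all(enc$age_group %in% 1:6))
  expect_true(all(enc$hpsa %in% 1:3))
  i <- which(fx$cohort$gender == "male")[1]
  expect_equal(enc$gender[i], 1)
  bad <- fx$cohort
  bad$race[1] <- "martian"
  expect_error(encode_cohort(bad), "race")
})
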