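test_that("config validation names the offending field", {
  expect_error(sim_config(n_per_group = 0), "n_per_group")
  expect_error(sim_config(start_year = 2019, end_year = 2012), "start_year")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  bad <- default_prevalences()
  bad$gender <- c(male = 0.5, female = 0.6)
  expect_error(sim_config(covariate_prevalences = bad), "gender")
})

test_that("identical config and seed give a bit-identical cohort", {
  a <- simulate_cohort(sim_config(n_per_group = 40, seed = 7))
  b <- simulate_cohort(sim_config(n_per_group = 40, seed = 7))
  expect_identical(a$patients, b$patients)
  expect_identical(a$claims, b$claims)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(sim_config(n_per_group = 40, seed = 8))
  expect_false(identical(a$claims, c$claims))
})

test_that("case-control mode returns two exact arms", {
  cc <- simulate_cohort(sim_config(n_per_group = 35, seed = 3))
  expect_equal(nrow(cc$patients), 70)
  expect_equal(sum(cc$truth$progressed), 35)
  expect_equal(sum(cc$truth$progressed == 0), 35)
})

test_that("every progressor's first AD claim is strictly after first MDD claim", {
  cc <- simulate_cohort(sim_config(n_per_group = 80, seed = 11))
  cls <- classify_code(cc$claims$code_system, cc$claims$code)
  first <- function(sel) tapply(cc$claims$year[sel], cc$claims$patient_id[sel], min)
  fm <- first(cls == "MDD"); fa <- first(cls == "AD")
  prog <- cc$truth$patient_id[cc$truth$progressed == 1]
  expect_true(all(prog %in% names(fa)))
  expect_true(all(fm[prog] < fa[prog]))
  # controls carry no AD code at all
  ctrl <- cc$truth$patient_id[cc$truth$progressed == 0]
  expect_false(any(ctrl %in% names(fa)))
})

test_that("coding system follows the calendar: ICD-9 through 2015, ICD-10 after", {
  cc <- simulate_cohort(sim_config(n_per_group = 60, seed = 2))
  expect_true(all(cc$claims$code_system[cc$claims$year <= 2015] == "ICD9"))
  expect_true(all(cc$claims$code_system[cc$claims$year >= 2016] == "ICD10"))
  expect_false(any(grepl("^(F32|G30|F33)", cc$claims$code[cc$claims$year <= 2015])))
  expect_false(any(grepl("^(296|331)", cc$claims$code[cc$claims$year >= 2016])))
})

test_that("the confounding knob induces a positive covariate-exposure association", {
  pop <- simulate_cohort(sim_config(confounding_strength = 0.8, seed = 5),
                         mode = "population", n = 3000)
  pan <- build_panel(pop$patients, pop$claims, 2012, 2019)
  late <- pan[pan$t > 2, ]  # past the forced first-claim years
  hi <- late$l_util > stats::median(late$l_util)
  or <- (mean(late$E[hi]) / (1 - mean(late$E[hi]))) /
    (mean(late$E[!hi]) / (1 - mean(late$E[!hi])))
  expect_gt(or, 1)
})

test_that("null configuration gives equal progression rates across covariate strata", {
  pop <- simulate_cohort(
    sim_config(exposure_effect = 0, confounding_strength = 0,
               nonlinear_effect = 0, seed = 9),
    mode = "population", n = 4000)
  cohort <- build_cohort(pop$patients, pop$claims)
  hi <- cohort$utilization_days > stats::median(cohort$utilization_days)
  p1 <- mean(cohort$outcome[hi]); p2 <- mean(cohort$outcome[!hi])
  se <- sqrt(mean(cohort$outcome) * (1 - mean(cohort$outcome)) *
               (1 / sum(hi) + 1 / sum(!hi)))
  expect_lt(abs(p1 - p2), 3 * se)
})

test_that("missingness injection is MCAR at the requested rate and spares the outcome", {
  x <- as.data.frame(matrix(rnorm(564 * 9), 564, 9))
  names(x) <- paste0("p", 1:9)
  x$outcome <- rbinom(564, 1, 0.5)
  expect_identical(inject_missingness(x, 0, seed = 1), x)
  masked <- inject_missingness(x, 0.4, seed = 21)
  n_cells <- 564 * 9
  n_masked <- sum(is.na(masked[paste0("p", 1:9)]))
  expect_lt(abs(n_masked - 0.4 * n_cells), 3 * sqrt(n_cells * 0.4 * 0.6))
  expect_identical(masked$outcome, x$outcome)
  expect_error(inject_missingness(x, 1, seed = 1), "rate")
})

test_that("cohort writer round-trips through the external reader", {
  cc <- simulate_cohort(sim_config(n_per_group = 15, seed = 13))
  dir <- withr::local_tempdir()
  write_claims_cohort(cc, dir)
  expect_true(file.exists(file.path(dir, "provenance.json")))
  back <- ingest_external(file.path(dir, "claims.tsv"),
                          file.path(dir, "patients.tsv"))
  expect_equal(back$patients, cc$patients)
  expect_equal(back$claims, cc$claims, ignore_attr = TRUE)
})
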