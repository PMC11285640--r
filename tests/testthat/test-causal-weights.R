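test_that("panels are rectangular with causally ordered covariates", {
  fx <- sim_encoded(n_per_group = 25, seed = 3)
  pan <- build_panel(fx$raw$patients, fx$raw$claims, 2012, 2019)
  expect_equal(nrow(pan), 50 * 8)
  expect_equal(max(pan$t), 7)
  expect_true(all(table(pan$patient_id) == 8))
  expect_true(all(pan$E %in% 0:1))
  expect_error(build_panel(fx$raw$patients, fx$raw$claims, 2019, 2012), "window")
})

test_that("a patient with claims only in the first year has E_0 = 1 and zeros after", {
  cl <- data.frame(patient_id = "A", year = 2012, code_system = "ICD9",
                   code = "296.21", utilization_days = 4)
  pan <- build_panel(tiny_patients("A"), cl, 2012, 2019)
  expect_equal(pan$E, c(1L, rep(0L, 7)))
  expect_equal(pan$cum_mdd, rep(1, 8))
  expect_equal(pan$util, c(4, rep(0, 7)))
})

test_that("time-varying covariates never use future claims", {
  fx <- sim_encoded(n_per_group = 20, seed = 5)
  pan0 <- build_panel(fx$raw$patients, fx$raw$claims, 2012, 2019)
  pert <- fx$raw$claims
  late <- pert$year >= 2016
  pert$utilization_days[late] <- pert$utilization_days[late] + 50
  pan1 <- build_panel(fx$raw$patients, pert, 2012, 2019)
  early <- pan0$t <= 3
  cols <- c("E", "util", "comorb", "cum_mdd", "l_util", "l_comorb", "l_cum_mdd")
  expect_identical(pan0[early, cols], pan1[early, cols])
})

test_that("model-based weights equal direct-enumeration weights on a saturated panel", {
  # two periods, one binary time-varying covariate; cell counts chosen so
  # every (E_prev, x) cell has both exposure outcomes
  cells <- expand.grid(E0 = 0:1, x = 0:1)
  counts <- list(c(3, 5), c(4, 2), c(2, 6), c(5, 3))  # (E1=1, E1=0) per cell
  rows <- list(); pid <- 0
  for (i in seq_len(nrow(cells))) {
    for (e1 in c(rep(1, counts[[i]][1]), rep(0, counts[[i]][2]))) {
      pid <- pid + 1
      rows[[pid]] <- data.frame(
        patient_id = sprintf("S%02d", pid), t = 0:1, year = 2012:2013,
        E = c(cells$E0[i], e1), E_prev = c(0L, cells$E0[i]),
        l_x = c(0, cells$x[i]))
    }
  }
  pan <- do.call(rbind, rows)
  models <- fit_exposure_models(pan, baseline = character(0),
                                timevarying = "l_x", interactions = TRUE)
  w <- compute_iptw(pan, models)

  # enumeration oracle from raw conditional frequencies
  d1 <- pan[pan$t == 1, ]
  p_num_1 <- vapply(seq_len(nrow(d1)), function(i) {
    sel <- d1$E_prev == d1$E_prev[i]
    mean(d1$E[sel] == 1)
  }, 0)
  p_den_1 <- vapply(seq_len(nrow(d1)), function(i) {
    sel <- d1$E_prev == d1$E_prev[i] & d1$l_x == d1$l_x[i]
    mean(d1$E[sel] == 1)
  }, 0)
  realized <- function(p, e) p * e + (1 - p) * (1 - e)
  oracle <- realized(p_num_1, d1$E) / realized(p_den_1, d1$E)
  expect_equal(w$weight[match(d1$patient_id, w$patient_id)], oracle,
               tolerance = 1e-8)
})

test_that("weights are exactly one when numerator and denominator models coincide", {
  fx <- sim_encoded(n_per_group = 30, seed = 8)
  pan <- build_panel(fx$raw$patients, fx$raw$claims, 2012, 2019)
  models <- fit_exposure_models(pan, timevarying = character(0))
  w <- compute_iptw(pan, models)
  expect_equal(w$weight, rep(1, nrow(w)), tolerance = 1e-12)
})

test_that("the stabilized product reproduces a hand-computed toy weight", {
  w <- adprogress:::stabilized_product(
    patient_id = c("p", "p"), p_num = c(0.5, 0.5), p_den = c(0.8, 0.4),
    E = c(1, 1))
  expect_equal(w$weight, (0.5 * 0.5) / (0.8 * 0.4))
  expect_equal(w$weight, 0.78125)
})

test_that("weights stay positive and finite and grow more variable with confounding", {
  var_by_strength <- vapply(c(0, 1.0), function(cs) {
    pop <- simulate_cohort(sim_config(confounding_strength = cs, seed = 17),
                           mode = "population", n = 2000)
    pan <- build_panel(pop$patients, pop$claims, 2012, 2019)
    w <- compute_iptw(pan, fit_exposure_models(pan))
    expect_true(all(is.finite(w$weight) & w$weight > 0))
    stats::var(w$weight)
  }, 0)
  expect_gt(var_by_strength[2], var_by_strength[1])
})

test_that("WLS with equal weights is ordinary least squares", {
  fx <- sim_encoded(n_per_group = 40, seed = 10)
  f1 <- fit_msm(fx$x, fx$y)
  f2 <- lm(y ~ ., data = cbind(data.frame(y = fx$y), fx$x))
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-10)
})

test_that("duplicating rows with halved weights leaves coefficients unchanged", {
  fx <- sim_encoded(n_per_group = 30, seed = 12)
  w <- runif(nrow(fx$x), 0.5, 2)
  f1 <- fit_msm(fx$x, fx$y, w)
  f2 <- fit_msm(rbind(fx$x, fx$x), c(fx$y, fx$y), c(w / 2, w / 2))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("aliased columns are dropped with a warning", {
  fx <- sim_encoded(n_per_group = 20, seed = 14)
  x <- fx$x
  x$dup <- x$utilization_days * 2
  expect_warning(f <- fit_msm(x, fx$y), "aliased")
  expect_false("dup" %in% f$features)
})

test_that("MSM predictions are clipped linear predictors", {
  x <- data.frame(z = c(0, 1, 0, 1, 0, 1))
  y <- c(0, 1, 0, 1, 0, 1)
  f <- fit_msm(x, y)
  expect_equal(predict(f, x), y, tolerance = 1e-10)
  far <- data.frame(z = c(2, -1))
  expect_equal(predict(f, far), c(1, 0))          # clipped
  expect_equal(predict(f, far, clip = FALSE), c(2, -1), tolerance = 1e-10)
  # training rows reproduce fitted values pre-clipping
  fx <- sim_encoded(n_per_group = 25, seed = 16)
  fit <- fit_msm(fx$x, fx$y)
  expect_equal(predict(fit, fx$x, clip = FALSE),
               unname(stats::fitted(fit$lm)), tolerance = 1e-10)
  expect_error(predict(fit, fx$x[, 1:3]), "lacks column")
})

test_that("feature ranking is ordered by coefficient with significance stars", {
  n <- 200
  x <- withr::with_seed(1, data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n)))
  y <- 0.145 * x$a + 0.142 * x$b + 0.089 * x$c  # exact linear outcome
  f <- fit_msm(x, y)
  r <- rank_msm_features(f)
  expect_equal(r$feature, c("a", "b", "c"))
  expect_equal(r$coefficient, c(0.145, 0.142, 0.089), tolerance = 1e-8)
  # flipping one coefficient's sign moves its rank accordingly
  y2 <- 0.145 * x$a + 0.142 * x$b - 0.089 * x$c
  r2 <- rank_msm_features(fit_msm(x, y2))
  expect_equal(r2$feature[3], "c")
  expect_lt(r2$coefficient[3], 0)
})
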