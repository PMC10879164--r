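test_that("survival function has the right anchors and shape", {
  m <- gompertz_model(c(const = log(0.01)), gamma = 0.08)
  nd <- data.frame(dummy = 1)
  expect_equal(survival_prob(m, nd, 0), 1)
  # hand evaluation at lambda = 0.01, gamma = 0.08, t = 20
  expect_equal(survival_prob(m, nd, 20), exp(0.125 * (1 - exp(1.6))),
               tolerance = 1e-12)
  expect_equal(survival_prob(m, nd, 20), 0.6101, tolerance = 1e-4)
  grid <- sapply(seq(0, 40, by = 0.5), function(t) survival_prob(m, nd, t))
  expect_true(all(diff(grid) < 0))
  expect_error(survival_prob(m, nd, -1), ">= 0")
})

test_that("median remaining life expectancy solves s(t) = 0.5", {
  m <- gompertz_model(c(const = log(0.001)), gamma = 0.1)
  le <- median_remaining_le(m, data.frame(dummy = 1))$median_le
  expect_equal(le, 42.53, tolerance = 1e-3)
  expect_equal(le, gompertz_quantile_time(0.001, 0.1), tolerance = 1e-8)
  # median age at death = age + t
  le2 <- median_remaining_le(m, data.frame(age = 50))
  expect_equal(le2$median_age_at_death, 50 + le2$median_le)
  # doubling lambda strictly shortens the median
  m2 <- gompertz_model(c(const = log(0.002)), gamma = 0.1)
  expect_lt(median_remaining_le(m2, data.frame(dummy = 1))$median_le, le)
})

test_that("numeric median solver agrees with the closed form across parameters", {
  set.seed(21)
  for (i in 1:100) {
    lambda <- exp(runif(1, log(1e-5), log(0.05)))
    gamma <- runif(1, 0.01, 0.2)
    m <- gompertz_model(c(const = log(lambda)), gamma = gamma)
    num <- median_remaining_le(m, data.frame(dummy = 1))$median_le
    expect_lt(abs(num - gompertz_quantile_time(lambda, gamma)), 1e-8)
  }
})

test_that("mortality risk is the survival complement with sane monotonicity", {
  m <- gompertz_model(c(bioage = 0.08, const = log(0.01) - 0.08 * 50),
                      gamma = 0.08)
  expect_equal(mortality_risk(m, data.frame(bioage = 50), horizon = 0), 0)
  expect_equal(mortality_risk(m, data.frame(bioage = 50)), 0.3899,
               tolerance = 1e-4)
  risks <- mortality_risk(m, data.frame(bioage = c(45, 50, 55, 60)))
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks >= 0 & risks <= 1))
})

test_that("maximum likelihood recovers known Gompertz PH parameters", {
  truth <- gompertz_model(c(age = 0.05, bioage = 0.08, const = -13),
                          gamma = 0.09)
  records <- simulate_survival_records(8000, truth, seed = 31)
  fit <- fit_gompertz_ph(records)
  for (nm in c("age", "bioage", "const")) {
    expect_lt(abs(fit$coef[nm] - truth$coef[nm]) / abs(truth$coef[nm]), 0.15)
  }
  expect_lt(abs(fit$gamma - truth$gamma) / truth$gamma, 0.15)
})

test_that("fit agrees with an independent Gompertz PH implementation", {
  skip_if_not_installed("flexsurv")
  truth <- gompertz_model(c(age = 0.05, bioage = 0.08, const = -13),
                          gamma = 0.09)
  records <- simulate_survival_records(2000, truth, seed = 17)
  fit <- fit_gompertz_ph(records)
  ref <- flexsurv::flexsurvreg(
    survival::Surv(time, event) ~ age + bioage,
    data = records, dist = "gompertz"
  )
  rc <- coef(ref)  # shape, log-rate intercept, covariate effects
  expect_equal(unname(fit$gamma), unname(rc["shape"]), tolerance = 1e-3)
  expect_equal(unname(fit$coef["age"]), unname(rc["age"]), tolerance = 1e-3)
  expect_equal(unname(fit$coef["bioage"]), unname(rc["bioage"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$coef["const"]), unname(rc["rate"]), tolerance = 1e-3)
})

test_that("degenerate survival inputs are refused", {
  truth <- default_gompertz_truth()
  records <- simulate_survival_records(200, truth, seed = 5)
  censored <- records
  censored$event <- 0L
  expect_error(fit_gompertz_ph(censored), "no events")
  expect_error(fit_gompertz_ph(records[1:20, ]), "at least 50")
})

test_that("cause-specific fit on single-cause data equals the all-cause fit", {
  truth <- default_gompertz_truth()
  records <- simulate_survival_records(3000, truth, seed = 13)
  records$cause <- ifelse(records$event == 1, "heart", NA)
  fit_all <- fit_gompertz_ph(records, cause = "all")
  fit_heart <- fit_gompertz_ph(records, cause = "heart")
  expect_equal(fit_heart$coef, fit_all$coef, tolerance = 1e-6)
  expect_equal(fit_heart$gamma, fit_all$gamma, tolerance = 1e-6)
})

test_that("two causes with 2:1 hazards yield ordered cause-specific risks", {
  set.seed(19)
  n <- 6000
  age <- runif(n, 40, 80)
  lam_a <- exp(0.06 * age - 12)       # cause a
  lam_b <- lam_a / 2                  # cause b at half the hazard
  t_a <- sample_gompertz_event_time(lam_a, 0.09, runif(n))
  t_b <- sample_gompertz_event_time(lam_b, 0.09, runif(n))
  t <- pmin(t_a, t_b, 23)
  ev <- as.integer(pmin(t_a, t_b) <= 23)
  records <- data.frame(
    time = t, event = ev,
    cause = ifelse(ev == 1, ifelse(t_a < t_b, "a", "b"), NA),
    age = age
  )
  fit_a <- fit_gompertz_ph(records, covariates = "age", cause = "a")
  fit_b <- fit_gompertz_ph(records, covariates = "age", cause = "b")
  suite <- cause_specific_risk_suite(list(a = fit_a, b = fit_b),
                                     data.frame(age = 60))
  expect_gt(suite$a, suite$b)
  expect_equal(suite$a / suite$b, 2, tolerance = 0.35)
})

test_that("risk suite falls monotonically with biological age and validates models", {
  m <- gompertz_model(c(age = 0.05, bioage = 0.08, const = -13), gamma = 0.09)
  suite_bl <- cause_specific_risk_suite(list(all = m),
                                        data.frame(age = 60, bioage = 62))
  suite_fu <- cause_specific_risk_suite(list(all = m),
                                        data.frame(age = 60, bioage = 59))
  expect_lt(suite_fu$all, suite_bl$all)
  expect_error(cause_specific_risk_suite(list(m), data.frame(age = 1)),
               "named")
  expect_error(cause_specific_risk_suite(list(heart = "nope"),
                                         data.frame(age = 1)), "heart")
})

test_that("a weight term with zero coefficient reproduces the base model", {
  base <- gompertz_model(c(age = 0.05, bioage = 0.08, const = -13),
                         gamma = 0.09)
  with_wt <- gompertz_model(c(age = 0.05, bioage = 0.08, weight = 0,
                              const = -13), gamma = 0.09)
  nd <- data.frame(age = 55, bioage = 58, weight = 80)
  expect_equal(survival_prob(with_wt, nd, 20), survival_prob(base, nd, 20),
               tolerance = 1e-14)
  expect_equal(median_remaining_le(with_wt, nd)$median_le,
               median_remaining_le(base, nd)$median_le, tolerance = 1e-10)
})

test_that("relative reduction reproduces printed percentages and guards zero", {
  expect_equal(relative_reduction(11.25, 10.07), 10.5)
  expect_equal(relative_reduction(2.30, 1.90), 17.4)
  expect_equal(relative_reduction(5, 5), 0)
  expect_equal(relative_reduction(2.30, 1.90, digits = NULL),
               100 * 0.4 / 2.3, tolerance = 1e-12)
  expect_error(relative_reduction(0, 1), "> 0")
})

test_that("Gompertz models survive a JSON round-trip", {
  m <- gompertz_model(c(age = 0.05, bioage = 0.08, const = -13),
                      gamma = 0.09, cause = "heart")
  path <- withr::local_tempfile(fileext = ".json")
  write_gompertz_model(m, path)
  back <- read_gompertz_model(path)
  expect_equal(back$coef, m$coef, tolerance = 1e-15)
  expect_equal(back$gamma, m$gamma)
  expect_equal(back$cause, "heart")
})
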