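# Kaplan-Meier estimation, group hazard ratios, covariate retention,
# multivariate adjustment, likelihood-ratio comparison, PH diagnostics.

test_that("product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)

  # all censored: flat at 1, median not reached
  km0 <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(km0$curve$surv == 1))
  expect_true(is.na(km0$median))

  # heavy censoring: agree with the definitional oracle at event times
  toy <- make_toy_surv(10, seed = 31, p_event = 0.4)
  km1 <- km_estimate(toy$time, toy$event)
  orc <- oracle_km(toy$time, toy$event)
  got <- km1$curve$surv[match(orc$time, km1$curve$time)]
  expect_equal(got, orc$surv, tolerance = 1e-12)
})

test_that("KM curve is right-continuous, non-increasing, starts at 1", {
  toy <- make_toy_surv(40, seed = 32, p_event = 0.6)
  km <- km_estimate(toy$time, toy$event)
  expect_true(all(diff(km$curve$surv) <= 1e-12))
  expect_true(km$curve$surv[1] <= 1)
  expect_true(all(km$curve$surv >= 0))
})

make_pred <- function(clin, unlikely) {
  data.frame(patient_id = clin$patient_id,
             risk_score = as.numeric(unlikely),
             label = factor(ifelse(unlikely, "unlikely_benefit",
                                   "likely_benefit"),
                            levels = c("likely_benefit",
                                       "unlikely_benefit")),
             stringsAsFactors = FALSE)
}

test_that("identical survival in both groups gives HR = 1 and label
           swapping inverts the HR", {
  toy <- make_toy_surv(20, seed = 33)
  clin <- make_clinical(c(toy$time, toy$time), c(toy$event, toy$event))
  pred <- make_pred(clin, c(rep(FALSE, 20), rep(TRUE, 20)))
  gh <- group_hr(pred, clin)
  expect_equal(gh$hr[gh$group == "unlikely_benefit"], 1, tolerance = 1e-9)

  toy2 <- make_toy_surv(30, seed = 34)
  clin2 <- make_clinical(toy2$time, toy2$event)
  flag <- rep(c(TRUE, FALSE), 15)
  g1 <- group_hr(make_pred(clin2, flag), clin2)
  g2 <- group_hr(make_pred(clin2, !flag), clin2)
  expect_equal(g1$hr[g1$group == "unlikely_benefit"],
               1 / g2$hr[g2$group == "unlikely_benefit"], tolerance = 1e-9)
})

test_that("group HR matches the partial-likelihood oracle and log-rank
           agrees with the Cox score test", {
  toy <- make_toy_surv(10, seed = 35)
  clin <- make_clinical(toy$time, toy$event)
  flag <- rep(c(TRUE, FALSE), 5)
  gh <- group_hr(make_pred(clin, flag), clin)
  oracle <- oracle_cox_efron(matrix(as.numeric(flag)), toy$time, toy$event)
  expect_equal(log(gh$hr[gh$group == "unlikely_benefit"]), oracle$coef[1],
               tolerance = 1e-6)

  fit <- attr(gh, "model")
  sc <- summary(fit)$sctest["pvalue"]
  expect_equal(unname(attr(gh, "logrank_p")), unname(sc), tolerance = 1e-8)
})

test_that("group HR errors on empty groups or no events", {
  toy <- make_toy_surv(10, seed = 36)
  clin <- make_clinical(toy$time, toy$event)
  expect_error(group_hr(make_pred(clin, rep(FALSE, 10)), clin), "nonempty")
  clin0 <- make_clinical(toy$time, rep(0, 10))
  expect_error(group_hr(make_pred(clin0, rep(c(TRUE, FALSE), 5)), clin0),
               "no events")
})

test_that("evaluation output is invariant to sample ordering", {
  toy <- make_toy_surv(24, seed = 37)
  clin <- make_clinical(toy$time, toy$event)
  pred <- make_pred(clin, rep(c(TRUE, FALSE), 12))
  perm <- sample(24)
  gh1 <- group_hr(pred, clin)
  gh2 <- group_hr(pred[perm, ], clin[rev(perm), ])
  attr(gh1, "model") <- attr(gh2, "model") <- NULL
  expect_equal(gh1, gh2, tolerance = 1e-12)
})

test_that("a strong covariate is retained, a single-level covariate is
           excluded", {
  set.seed(38)
  n <- 150
  risky <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.05 * exp(1.2 * risky))
  clin <- make_clinical(round(time, 4), rep(1, n))
  clin$braf <- ifelse(risky == 1, "mutant", "wild-type")
  clin$subtype <- "cutaneous"  # single level
  pred <- make_pred(clin, rbinom(n, 1, 0.3) == 1)
  ret <- covariate_retention(clin, pred, covariates = c("braf", "subtype"))
  expect_true(ret$retained[ret$variable == "braf"])
  expect_match(ret$note[ret$variable == "subtype"], "single level")
  expect_false(ret$retained[ret$variable == "subtype"])
})

test_that("multivariate model nests to the unadjusted group HR and matches
           the oracle on a toy", {
  toy <- make_toy_surv(30, seed = 39)
  clin <- make_clinical(toy$time, toy$event)
  pred <- make_pred(clin, rep(c(TRUE, FALSE), 15))
  mv <- multivariate_cox(clin, pred, covariates = character(0))
  gh <- group_hr(pred, clin)
  expect_equal(mv$hr[mv$variable == "label"],
               gh$hr[gh$group == "unlikely_benefit"], tolerance = 1e-9)

  mv2 <- multivariate_cox(clin, pred, covariates = "age")
  X <- cbind(as.numeric(pred$label == "unlikely_benefit"), clin$age)
  oracle <- oracle_cox_efron(X, toy$time, toy$event)
  expect_equal(log(mv2$hr), oracle$coef, tolerance = 1e-6)

  clin$dup <- clin$braf  # aliased with braf
  expect_error(multivariate_cox(clin, pred,
                                covariates = c("braf", "dup")),
               "aliased")
})

test_that("partial likelihood-ratio test: identity gives p = 1, null added
           predictor is calibrated chi-square(1)", {
  toy <- make_toy_surv(50, seed = 40)
  clin <- make_clinical(toy$time, toy$event)
  d <- data.frame(time = toy$time, event = toy$event, age = clin$age)
  f1 <- survival::coxph(survival::Surv(time, event) ~ age, data = d)
  same <- partial_lrt(f1, f1)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)

  d$z <- rnorm(50)
  f2 <- survival::coxph(survival::Surv(time, event) ~ z, data = d)
  expect_error(partial_lrt(f2, f1), "not nested")

  set.seed(41)
  stats_null <- replicate(200, {
    n <- 100
    tm <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.8); x <- rnorm(n)
    dd <- data.frame(tm, ev, x)
    full <- survival::coxph(survival::Surv(tm, ev) ~ x, data = dd)
    reduced <- survival::coxph(survival::Surv(tm, ev) ~ 1, data = dd)
    partial_lrt(full, reduced)$statistic
  })
  expect_equal(mean(stats_null), 1, tolerance = 0.3)
})

test_that("PH diagnostics: one term equals the global test; too few events
           warn and skip", {
  toy <- make_toy_surv(60, seed = 42)
  clin <- make_clinical(toy$time, toy$event)
  d <- data.frame(time = toy$time, event = toy$event,
                  x = rnorm(60))
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
  ph <- ph_diagnostics(fit)
  expect_equal(nrow(ph), 2L)  # term + GLOBAL
  expect_equal(ph$p[1], ph$p[2], tolerance = 1e-9)

  d2 <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 0, 1),
                   x = c(0.3, 1, -1, 0.5))
  fit2 <- survival::coxph(survival::Surv(time, event) ~ x, data = d2)
  expect_warning(out <- ph_diagnostics(fit2), "fewer than 3")
  expect_null(out)
})
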