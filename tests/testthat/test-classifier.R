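# Stratified splitting, penalized Cox fitting, threshold selection,
# prediction contracts.

test_that("stratified split hits exact proportions and is deterministic", {
  clin <- make_clinical(runif(100, 1, 60), rbinom(100, 1, 0.6), seed = 1)
  clin$regimen <- "anti-PD-1"; clin$subtype <- "cutaneous"
  groups <- data.frame(patient_id = clin$patient_id,
                       group = factor("other", levels = c("EF", "SC",
                                                          "other")))
  s1 <- stratified_split(clin, groups, seed = 3)
  expect_equal(as.integer(table(s1$set)), c(40L, 30L, 30L))
  s2 <- stratified_split(clin, groups, seed = 3)
  expect_identical(s1, s2)

  # two strata of 50: 20/15/15 within each
  clin$regimen <- rep(c("anti-PD-1", "anti-PD-1 + anti-CTLA-4"), each = 50)
  s3 <- stratified_split(clin, groups, seed = 3)
  for (r in unique(clin$regimen)) {
    idx <- clin$regimen == r
    expect_equal(as.integer(table(s3$set[idx])), c(20L, 15L, 15L))
  }
  expect_error(stratified_split(clin, groups, fractions = c(0.5, 0.2)),
               "sum to 1")
})

test_that("concordance matches the brute-force pairwise oracle", {
  set.seed(14)
  for (i in 1:25) {
    toy <- make_toy_surv(sample(8:20, 1), seed = i)
    score <- sample(5, length(toy$time), replace = TRUE) + runif(1)
    if (sum(toy$event) == 0) next
    expect_equal(cindex(toy$time, toy$event, score),
                 oracle_cindex(toy$time, toy$event, score),
                 tolerance = 1e-12)
  }
})

test_that("threshold selection separates a perfectly ordered toy and
           matches exhaustive search with censoring", {
  # the two high scores die first: cutting between 2 and 9 is perfect
  time <- c(3, 4, 1, 2)
  event <- c(1, 1, 1, 1)
  score <- c(1, 2, 9, 10)
  tau <- choose_threshold(score, time, event)
  expect_equal(tau, 5.5)
  # all 4 between-group pairs concordant; within-group ties count 1/2
  expect_equal(cindex(time, event, as.numeric(score > tau)), 5 / 6)

  set.seed(15)
  for (i in 1:50) {
    toy <- make_toy_surv(8, seed = 200 + i, p_event = 0.6)
    score <- round(rnorm(8), 2)
    if (sum(toy$event) == 0 || length(unique(score)) < 2) next
    expect_equal(choose_threshold(score, toy$time, toy$event),
                 oracle_best_threshold(score, toy$time, toy$event))
  }

  # protective (reversed) scores still yield the global maximizer
  toy <- make_toy_surv(10, seed = 99, p_event = 0.8)
  score <- -rank(toy$time)  # low score = dies late
  expect_equal(choose_threshold(score, toy$time, toy$event),
               oracle_best_threshold(score, toy$time, toy$event))

  expect_error(choose_threshold(rep(1, 5), 1:5, rep(1, 5)), "equal")
  expect_error(choose_threshold(1:5, 1:5, rep(0, 5)), "event")
})

test_that("an overwhelming penalty selects nothing and lambda = 0 matches
           the unpenalized oracle", {
  toy <- make_toy_surv(20, seed = 16)
  clin <- make_clinical(toy$time, toy$event)
  set.seed(17)
  x <- matrix(2^rnorm(40, 8, 1), 20, 2,
              dimnames = list(clin$patient_id, c("f1", "f2")))
  # plant signal so the unpenalized fit is informative
  x[, 1] <- x[, 1] * 2^(scale(clin$os_time) * -1)

  big <- fit_lasso_cox(x, clin, lambda = 100)
  expect_equal(big$status, "null_model")
  expect_equal(length(big$coef), 0L)

  fit0 <- fit_lasso_cox(x, clin, lambda = 0)
  z <- sapply(1:2, function(j) as.numeric(standardize_log_feature(x[, j])))
  oracle <- oracle_cox_efron(z, toy$time, toy$event)
  expect_equal(unname(fit0$coef[c("f1", "f2")]), oracle$coef,
               tolerance = 1e-4)
})

test_that("the number of selected features is non-increasing along the
           penalty path and the CV fit is deterministic", {
  cfg <- simulation_config(
    n_patients = 120, n_proteins = 5, n_occ_glycopeptides = 15,
    n_ra_glycopeptides = 5, n_nlinked_occ_sites = 3,
    planted = data.frame(selector = "ra_glycopeptide", n = 2, beta = log(2)),
    seed = 18)
  coh <- simulate_cohort(cfg)
  conc <- feature_family(coh$features, "concentration_family")
  m1 <- fit_lasso_cox(conc, coh$clinical, repeats = 2, seed = 5)
  m2 <- fit_lasso_cox(conc, coh$clinical, repeats = 2, seed = 5)
  expect_identical(names(m1$coef), names(m2$coef))
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$threshold, m2$threshold)
  # path knots ordered by decreasing lambda: active set grows as the
  # penalty relaxes, up to single-feature exchanges where one predictor
  # replaces another
  expect_true(all(diff(m1$cv$nonzero) >= -1))
  expect_gt(m1$cv$nonzero[nrow(m1$cv)], m1$cv$nonzero[1])
})

test_that("prediction obeys the sparsity, self-consistency and
           missing-feature contracts", {
  cfg <- simulation_config(
    n_patients = 100, n_proteins = 4, n_occ_glycopeptides = 12,
    n_ra_glycopeptides = 4, n_nlinked_occ_sites = 2,
    planted = data.frame(selector = "ra_glycopeptide", n = 2, beta = log(3)),
    seed = 19)
  coh <- simulate_cohort(cfg)
  conc <- feature_family(coh$features, "concentration_family")
  m <- fit_lasso_cox(conc, coh$clinical, repeats = 2, seed = 7)
  expect_equal(m$status, "ok")
  pred <- predict(m, conc)
  # labels reproduce the threshold rule
  expect_equal(pred$label == "unlikely_benefit",
               pred$risk_score > m$threshold)

  # shifting an unselected feature leaves predictions unchanged
  unsel <- setdiff(colnames(conc$values), names(m$coef))[1]
  shifted <- conc
  shifted$values[, unsel] <- shifted$values[, unsel] * 10
  expect_equal(predict(m, shifted)$risk_score, pred$risk_score)

  # dropping a selected feature is an error naming it
  dropped <- conc$values[, setdiff(colnames(conc$values),
                                   names(m$coef)[1])]
  expect_error(predict(m, dropped), names(m$coef)[1], fixed = TRUE)

  # null model: all zero scores, everyone likely to benefit
  null_m <- fit_lasso_cox(conc$values[, 1:3], coh$clinical, lambda = 50)
  pred0 <- predict(null_m, conc$values[, 1:3])
  expect_true(all(pred0$risk_score == 0))
  expect_true(all(pred0$label == "likely_benefit"))
})

test_that("model JSON serialization round-trips and exposes only fit-time
           quantities", {
  cfg <- simulation_config(
    n_patients = 80, n_proteins = 4, n_occ_glycopeptides = 12,
    n_ra_glycopeptides = 4, n_nlinked_occ_sites = 2,
    planted = data.frame(selector = "peptide", n = 1, beta = log(3)),
    seed = 20)
  coh <- simulate_cohort(cfg)
  conc <- feature_family(coh$features, "concentration_family")
  m <- fit_lasso_cox(conc, coh$clinical, repeats = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_glyco_model(m, path)
  m2 <- read_glyco_model(path)
  expect_equal(m2$coef, m$coef)
  expect_equal(m2$threshold, m$threshold)
  expect_equal(m2$center, m$center)
  expect_equal(predict(m2, conc)$risk_score, predict(m, conc)$risk_score)
})

test_that("the fucose model selects only pre-filter survivors", {
  cfg <- simulation_config(
    n_patients = 150, n_proteins = 6, n_occ_glycopeptides = 30,
    n_ra_glycopeptides = 4, n_nlinked_occ_sites = 6,
    planted = data.frame(selector = "fucose_site", n = 2, beta = log(3)),
    seed = 22)
  coh <- simulate_cohort(cfg)
  m <- fit_fucose_model(coh$monomer, coh$clinical, repeats = 2, seed = 3)
  pass <- m$prefilter$feature_id[m$prefilter$significant]
  expect_true(all(names(m$coef) %in% pass))
  expect_true(length(pass) >= 2)
})
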