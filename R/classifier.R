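# Prognostic classifier: stratified splitting, repeated cross-validated
# L1-penalized Cox regression, and concordance-maximized dichotomization of
# the resulting risk scores.

#' Harrell's concordance index of a risk score
#'
#' Probability that, among comparable patient pairs, the patient with the
#' higher score experiences the event first; ties in the score count 1/2.
#'
#' @param time,event survival times and event indicators.
#' @param score numeric risk score (higher = higher risk).
#' @return concordance index in `[0, 1]`.
#' @export
cindex <- function(time, event, score) {
  if (length(unique(score)) == 1L) return(0.5)
  cf <- survival::concordance(survival::Surv(time, event) ~ score,
                              reverse = TRUE)
  unname(cf$concordance)
}

#' Stratified assignment of patients to training / validation / test sets
#'
#' Randomly splits the cohort in the requested proportions within strata
#' defined by immunotherapy regimen, melanoma subtype, and early-failure /
#' sustained-control outcome group. Within each stratum the set sizes match
#' the target fractions up to integer rounding (largest-remainder
#' apportionment). Strata smaller than the number of sets are pooled and
#' assigned by the global proportions, with a warning.
#'
#' @param clinical clinical data.frame (with `regimen`, `subtype`).
#' @param outcome_groups data.frame from [assign_outcome_group()].
#' @param fractions named fractions summing to 1 (default
#'   `c(training = 0.4, validation = 0.3, test = 0.3)`).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return data.frame with `patient_id`, `set` and `strata_key`.
#' @export
stratified_split <- function(clinical, outcome_groups,
                             fractions = c(training = 0.4, validation = 0.3,
                                           test = 0.3),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(stage_seed(seed, "split"))
  grp <- outcome_groups$group[match(clinical$patient_id,
                                    outcome_groups$patient_id)]
  strata <- paste(clinical$regimen, clinical$subtype, grp, sep = "/")
  sets <- names(fractions)
  n_sets <- length(fractions)

  assign_block <- function(ids) {
    n <- length(ids)
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0L) {
      frac_part <- fractions * n - base
      extra <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    stats::setNames(rep(sets, base)[order(sample.int(n))], ids)
  }

  tab <- table(strata)
  small <- names(tab)[tab < n_sets]
  out <- character(nrow(clinical))
  names(out) <- clinical$patient_id
  for (s in setdiff(names(tab), small)) {
    ids <- clinical$patient_id[strata == s]
    out[ids] <- assign_block(ids)
  }
  if (length(small)) {
    warning(length(small), " stratum/strata smaller than the number of ",
            "sets; assigned by global proportions")
    ids <- clinical$patient_id[strata %in% small]
    out[ids] <- assign_block(ids)
  }
  data.frame(patient_id = clinical$patient_id,
             set = factor(unname(out[clinical$patient_id]), levels = sets),
             strata_key = strata, stringsAsFactors = FALSE)
}

# Internal: per-feature log2 + standardization parameters learned on the
# fitting set, applied consistently at prediction time.
learn_feature_scaling <- function(x) {
  p <- ncol(x)
  center <- scale <- offset <- numeric(p)
  z <- matrix(NA_real_, nrow(x), p, dimnames = dimnames(x))
  for (j in seq_len(p)) {
    v <- x[, j]
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    s <- standardize_log_feature(v)
    z[, j] <- as.numeric(s)
    center[j] <- attr(s, "center")
    scale[j] <- attr(s, "scale")
    offset[j] <- attr(s, "offset")
  }
  list(z = z, center = stats::setNames(center, colnames(x)),
       scale = stats::setNames(scale, colnames(x)),
       offset = stats::setNames(offset, colnames(x)))
}

apply_feature_scaling <- function(x, model) {
  feats <- names(model$coef)
  z <- matrix(0, nrow(x), length(feats),
              dimnames = list(rownames(x), feats))
  for (f in feats) {
    z[, f] <- (log2(pmax(x[, f], 0) + model$offset[f]) -
                 model$center[f]) / model$scale[f]
  }
  z
}

#' Fit a repeated cross-validated L1-penalized Cox classifier
#'
#' Features are log2-transformed and standardized on the fitting set, then
#' an L1-penalized Cox model is fit over a path of 100 log-spaced penalty
#' values from the smallest all-zero penalty down to 1% of it. The penalty
#' is chosen to maximize the mean held-out Harrell concordance of the
#' linear predictor over `folds`-fold cross-validation repeated `repeats`
#' times (ties resolved toward the sparser, larger penalty; mean held-out
#' partial-likelihood deviance is available as an alternative objective).
#' The final model is refit on all fitting data at the chosen penalty, and
#' its training risk scores are dichotomized at the concordance-maximizing
#' threshold from [choose_threshold()].
#'
#' @param features a `glyco_features` object or numeric matrix
#'   (samples x features, natural scale).
#' @param clinical clinical data.frame aligned with the feature rows.
#' @param endpoint `"os"` or `"pfs"`.
#' @param folds number of cross-validation folds (default 5).
#' @param repeats number of cross-validation repeats (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param cv_metric `"cindex"` (default) or `"deviance"`.
#' @param nlambda,lambda_min_ratio penalty path controls.
#' @param lambda optional fixed penalty; when given, cross-validation is
#'   skipped and the model is fit at exactly this penalty (0 gives the
#'   unpenalized fit).
#' @return an object of class `glyco_cox_model`: selected features and
#'   coefficients, penalty, per-feature scaling, threshold, training
#'   concordance, the cross-validation trace, and a status that is
#'   `"null_model"` when no penalty selects any feature.
#' @export
fit_lasso_cox <- function(features, clinical, endpoint = "os", folds = 5L,
                          repeats = 10L, seed = 1L,
                          cv_metric = c("cindex", "deviance"),
                          nlambda = 100L, lambda_min_ratio = 0.01,
                          lambda = NULL) {
  cv_metric <- match.arg(cv_metric)
  x <- if (inherits(features, "glyco_features")) features$values else features
  if (inherits(features, "glyco_features")) {
    x <- x[clinical$patient_id, , drop = FALSE]
  }
  time <- clinical[[paste0(endpoint, "_time")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  n <- nrow(x)
  if (sum(event) < folds) {
    stop("too few events (", sum(event), ") for ", folds, "-fold ",
         "cross-validation")
  }
  keep <- apply(x, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && stats::sd(v) > 0
  })
  x <- x[, keep, drop = FALSE]
  sc <- learn_feature_scaling(x)
  z <- sc$z
  y <- survival::Surv(time, event)

  if (ncol(z) == 0L) {
    return(structure(list(coef = numeric(0L), lambda = NA_real_,
                          center = numeric(0L), scale = numeric(0L),
                          offset = numeric(0L), threshold = NA_real_,
                          training_cindex = NA_real_, cv = NULL,
                          cv_metric = cv_metric, endpoint = endpoint,
                          folds = folds, repeats = repeats, seed = seed,
                          status = "null_model"),
                     class = "glyco_cox_model"))
  }
  if (ncol(z) == 1L) {
    # a single candidate needs no selection; fit it unpenalized
    fit1 <- survival::coxph(y ~ z, ties = "efron")
    nz <- stats::setNames(unname(fit1$coefficients), colnames(z))
    score <- as.numeric(z * nz)
    model <- structure(list(
      coef = nz, lambda = 0,
      center = sc$center, scale = sc$scale, offset = sc$offset,
      threshold = NA_real_,
      training_cindex = cindex(time, event, score),
      cv = NULL, cv_metric = cv_metric, endpoint = endpoint,
      folds = folds, repeats = repeats, seed = seed, status = "ok"),
      class = "glyco_cox_model")
    if (length(unique(score)) > 1L) {
      model$threshold <- choose_threshold(score, time, event)
    }
    return(model)
  }

  if (!is.null(lambda)) {
    # fixed penalty: no selection needed; fit along a short path ending at
    # the requested value so the solution is well warm-started
    lmax <- max(glmnet::glmnet(z, y, family = "cox", standardize = FALSE,
                               nlambda = 5L)$lambda, lambda * 1.01 + 1e-9)
    lseq <- sort(unique(c(lambda, exp(seq(log(lmax), log(max(lambda,
                                                             lmax * 1e-4)),
                                          length.out = 25L)))),
                 decreasing = TRUE)
    fit0 <- glmnet::glmnet(z, y, family = "cox", standardize = FALSE,
                           lambda = lseq, thresh = 1e-14)
    beta <- as.numeric(stats::coef(fit0, s = lambda, exact = FALSE))
    names(beta) <- rownames(stats::coef(fit0))
    nz <- beta[beta != 0]
    model <- structure(list(
      coef = nz, lambda = lambda,
      center = sc$center[names(nz)], scale = sc$scale[names(nz)],
      offset = sc$offset[names(nz)],
      threshold = NA_real_, training_cindex = NA_real_, cv = NULL,
      cv_metric = cv_metric, endpoint = endpoint, folds = folds,
      repeats = repeats, seed = seed,
      status = if (length(nz)) "ok" else "null_model"),
      class = "glyco_cox_model")
    if (length(nz)) {
      score <- as.numeric(z[, names(nz), drop = FALSE] %*% nz)
      model$training_cindex <- cindex(time, event, score)
      if (length(unique(score)) > 1L) {
        model$threshold <- choose_threshold(score, time, event)
      }
    }
    return(model)
  }

  path <- glmnet::glmnet(z, y, family = "cox", standardize = FALSE,
                         nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio)
  lambda_seq <- path$lambda

  set.seed(stage_seed(seed, "cv_folds"))
  metric <- matrix(NA_real_, length(lambda_seq), folds * repeats)
  col <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (k in seq_len(folds)) {
      col <- col + 1L
      in_k <- fold_id == k
      if (sum(event[!in_k]) < 2L || sum(event[in_k]) < 1L) next
      fit_k <- glmnet::glmnet(z[!in_k, , drop = FALSE], y[!in_k],
                              family = "cox", standardize = FALSE,
                              lambda = lambda_seq)
      lp <- stats::predict(fit_k, newx = z[in_k, , drop = FALSE],
                           s = lambda_seq, type = "link")
      for (l in seq_len(ncol(lp))) {
        metric[l, col] <- if (cv_metric == "cindex") {
          cindex(time[in_k], event[in_k], lp[, l])
        } else {
          -glmnet::coxnet.deviance(lp[, l], y[in_k])
        }
      }
    }
  }
  mean_metric <- rowMeans(metric, na.rm = TRUE)
  best <- which(mean_metric >= max(mean_metric, na.rm = TRUE) - 1e-12)
  best <- best[1L]  # lambda_seq is decreasing: first index = largest penalty
  lambda <- lambda_seq[best]

  beta <- as.numeric(stats::coef(path, s = lambda, exact = FALSE))
  names(beta) <- rownames(stats::coef(path))
  nz <- beta[beta != 0]

  model <- structure(list(
    coef = nz, lambda = lambda,
    center = sc$center[names(nz)], scale = sc$scale[names(nz)],
    offset = sc$offset[names(nz)],
    threshold = NA_real_, training_cindex = NA_real_,
    cv = data.frame(lambda = lambda_seq, metric = mean_metric,
                    nonzero = path$df),
    cv_metric = cv_metric, endpoint = endpoint,
    folds = folds, repeats = repeats, seed = seed,
    status = if (length(nz)) "ok" else "null_model"
  ), class = "glyco_cox_model")

  if (length(nz)) {
    score <- as.numeric(z[, names(nz), drop = FALSE] %*% nz)
    model$training_cindex <- cindex(time, event, score)
    if (length(unique(score)) > 1L && sum(event) >= 1L) {
      model$threshold <- choose_threshold(score, time, event)
    }
  }
  model
}

#' @export
print.glyco_cox_model <- function(x, ...) {
  if (x$status == "null_model") {
    cat("L1-penalized Cox model: null model (no features selected)\n")
  } else {
    cat("L1-penalized Cox model:", length(x$coef), "features selected,",
        "lambda =", signif(x$lambda, 4), "\n")
    cat("Risk-score threshold:", signif(x$threshold, 4),
        "; training c-index:", round(x$training_cindex, 3), "\n")
  }
  invisible(x)
}

#' Choose the risk-score threshold that maximizes the concordance index
#'
#' Candidate cuts are the midpoints between consecutive sorted unique risk
#' scores. Each cut dichotomizes the cohort into a high-risk and low-risk
#' group; the cut whose *binary* indicator attains the highest Harrell
#' concordance index with the survival outcome is returned, ties broken
#' toward the smallest threshold.
#'
#' @param risk_scores numeric risk scores (higher = higher risk).
#' @param time,event survival outcome used to evaluate concordance.
#' @return the chosen threshold.
#' @export
choose_threshold <- function(risk_scores, time, event) {
  if (sum(event) < 1L) stop("threshold selection requires at least 1 event")
  us <- sort(unique(risk_scores))
  if (length(us) < 2L) stop("all risk scores equal; no informative threshold")
  cand <- (us[-length(us)] + us[-1L]) / 2
  cvals <- vapply(cand, function(tau) {
    cindex(time, event, as.numeric(risk_scores > tau))
  }, numeric(1L))
  cand[which.max(cvals)]  # which.max takes the first (smallest) maximizer
}

#' Predict risk scores and benefit labels from a fitted classifier
#'
#' Applies the fit-time feature scaling and sparse coefficients to new
#' samples and labels each patient by the model's fixed threshold: risk
#' scores above the threshold are `"unlikely_benefit"`, the rest
#' `"likely_benefit"`. The threshold is never re-estimated on new cohorts.
#' A null model scores every patient 0 and labels all as likely to benefit.
#'
#' @param object a `glyco_cox_model`.
#' @param features a `glyco_features` object or numeric matrix containing
#'   every selected feature (missing selected features are an error).
#' @param ... unused.
#' @return data.frame with `patient_id`, `risk_score`, `label`.
#' @export
predict.glyco_cox_model <- function(object, features, ...) {
  x <- if (inherits(features, "glyco_features")) features$values else features
  ids <- if (inherits(features, "glyco_features")) features$samples else
    rownames(x)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(x)))
  lab <- c("likely_benefit", "unlikely_benefit")
  if (object$status == "null_model" || length(object$coef) == 0L) {
    return(data.frame(patient_id = ids, risk_score = 0,
                      label = factor(rep("likely_benefit", nrow(x)),
                                     levels = lab),
                      stringsAsFactors = FALSE))
  }
  missing_f <- setdiff(names(object$coef), colnames(x))
  if (length(missing_f)) {
    stop("selected feature(s) absent from input: ",
         paste(missing_f, collapse = ", "))
  }
  z <- apply_feature_scaling(x, object)
  score <- as.numeric(z %*% object$coef)
  label <- factor(ifelse(score > object$threshold, "unlikely_benefit",
                         "likely_benefit"), levels = lab)
  data.frame(patient_id = ids, risk_score = score, label = label,
             stringsAsFactors = FALSE)
}

#' Fit the fucose monomer-weight classifier
#'
#' Restricts the classifier to site-level fucose monomer-weight features
#' that pass an FDR pre-filter in univariate age- and sex-adjusted Cox
#' regression on the fitting set, then applies the same penalized-Cox and
#' threshold machinery as [fit_lasso_cox()]. Intended to be run on the same
#' training set assignment as the main concentration-feature model.
#'
#' @param monomer_features a `glyco_features` object of monomer-weight
#'   features (see [fucose_feature_panel()]).
#' @param clinical clinical data.frame for the fitting set.
#' @param screen_results optional precomputed [screen_features()] output
#'   for the monomer features on the same fitting set; computed internally
#'   when `NULL`.
#' @param alpha_fdr FDR pre-filter level (default 0.05).
#' @param folds,repeats,seed,... passed to [fit_lasso_cox()].
#' @return a `glyco_cox_model` (status `"null_model"` when no feature
#'   passes the pre-filter); the pre-filter table is attached as
#'   `$prefilter`.
#' @export
fit_fucose_model <- function(monomer_features, clinical,
                             screen_results = NULL, alpha_fdr = 0.05,
                             folds = 5L, repeats = 10L, seed = 1L, ...) {
  if (is.null(screen_results)) {
    screen_results <- screen_features(monomer_features, clinical,
                                      alpha_fdr = alpha_fdr, family = NULL,
                                      ph_diag = FALSE)
  }
  pass <- screen_results$feature_id[screen_results$significant]
  if (length(pass) == 0L) {
    model <- structure(list(coef = numeric(0L), lambda = NA_real_,
                            center = numeric(0L), scale = numeric(0L),
                            offset = numeric(0L), threshold = NA_real_,
                            training_cindex = NA_real_, cv = NULL,
                            cv_metric = "cindex", endpoint = "os",
                            folds = folds, repeats = repeats, seed = seed,
                            status = "null_model"),
                       class = "glyco_cox_model")
    model$prefilter <- screen_results
    return(model)
  }
  keep <- monomer_features$features$feature_id %in% pass
  sub <- new_glyco_features(
    monomer_features$values[, keep, drop = FALSE],
    monomer_features$features[keep, , drop = FALSE],
    monomer_features$samples)
  model <- fit_lasso_cox(sub, clinical, folds = folds, repeats = repeats,
                         seed = seed, ...)
  model$prefilter <- screen_results
  model
}

#' Serialize a fitted classifier to JSON
#'
#' Stores the selected features, coefficients, penalty, per-feature
#' scaling, threshold and seed so predictions are reproducible and it is
#' auditable that every fit-time quantity came from the training set.
#'
#' @param model a `glyco_cox_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_glyco_model <- function(model, path) {
  obj <- list(
    type = "glyco_cox_model", status = model$status,
    endpoint = model$endpoint, lambda = model$lambda,
    threshold = model$threshold, training_cindex = model$training_cindex,
    folds = model$folds, repeats = model$repeats, seed = model$seed,
    cv_metric = model$cv_metric,
    features = lapply(seq_along(model$coef), function(i) list(
      feature_id = names(model$coef)[i],
      coefficient = unname(model$coef[i]),
      center = unname(model$center[i]),
      scale = unname(model$scale[i]),
      offset = unname(model$offset[i])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized classifier
#'
#' @param path JSON file written by [write_glyco_model()].
#' @return a `glyco_cox_model`.
#' @export
read_glyco_model <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  nm <- vapply(feats, `[[`, character(1L), "feature_id")
  num <- function(field) stats::setNames(
    vapply(feats, function(f) as.numeric(f[[field]]), numeric(1L)), nm)
  structure(list(
    coef = num("coefficient"), lambda = as.numeric(obj$lambda),
    center = num("center"), scale = num("scale"), offset = num("offset"),
    threshold = as.numeric(obj$threshold),
    training_cindex = as.numeric(obj$training_cindex),
    cv = NULL, cv_metric = obj$cv_metric, endpoint = obj$endpoint,
    folds = obj$folds, repeats = obj$repeats, seed = obj$seed,
    status = obj$status), class = "glyco_cox_model")
}
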