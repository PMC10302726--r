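# Survival evaluation layer: Kaplan-Meier estimation, between-group hazard
# ratios, covariate retention screening, multivariate adjustment, partial
# likelihood-ratio model comparison and proportional-hazards diagnostics.

#' Kaplan-Meier estimate with median survival and confidence interval
#'
#' Product-limit estimator of the survival function. The median is the
#' smallest time at which the estimated survival drops to 0.5 or below;
#' when the curve never crosses 0.5 the median (or a CI bound) is "not
#' reached", encoded as `NA`. Confidence intervals use the complementary
#' log-log transform.
#'
#' @param time,event survival times (months, >= 0) and event indicators.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `km_estimate`: `curve` (data.frame `time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`), `median`,
#'   `median_ci`, `n`, `events`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) >= 1L, all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  curve <- data.frame(time = s$time, n_risk = s$n.risk,
                      n_event = s$n.event, surv = s$surv,
                      lower = s$lower, upper = s$upper)
  tab <- summary(fit)$table
  # median defined as the smallest time with survival <= 0.5 (survfit
  # averages the two flanking times when the curve sits exactly at 0.5)
  cross <- curve$time[curve$surv <= 0.5 + 1e-12]
  med <- if (length(cross)) min(cross) else NA_real_
  ci <- c(unname(tab["0.95LCL"]), unname(tab["0.95UCL"]))
  structure(list(curve = curve, median = med, median_ci = ci,
                 n = length(time), events = sum(event)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NR", format(round(v, 1)))
  cat("Kaplan-Meier estimate:", x$events, "events /", x$n, "subjects\n")
  cat("Median survival:", fmt(x$median), "(95% CI:", fmt(x$median_ci[1L]),
      ",", fmt(x$median_ci[2L]), ")\n")
  invisible(x)
}

#' Hazard ratio between predicted benefit groups
#'
#' Fits a Cox model with the classifier prediction as group indicator
#' (reference: likely to benefit), optionally adjusted for clinical
#' covariates, and summarizes each group with events/N and Kaplan-Meier
#' median OS with CI — the layout of a classifier performance table. The
#' unadjusted two-group log-rank p-value is also reported.
#'
#' @param predictions data.frame from [predict.glyco_cox_model()] (or any
#'   data.frame with `patient_id` and a two-level `label`).
#' @param clinical clinical data.frame.
#' @param adjust optional character vector of clinical covariate columns to
#'   adjust for.
#' @param endpoint `"os"` or `"pfs"`.
#' @return data.frame with one row per group (`group`, `n`, `events`,
#'   `median_os`, `median_ci_low`, `median_ci_high`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`; reference row carries `hr = 1` and `NA`
#'   inference columns), with attributes `logrank_p` and `model`.
#' @export
group_hr <- function(predictions, clinical, adjust = NULL,
                     endpoint = "os") {
  d <- merge(clinical, predictions[, c("patient_id", "label")],
             by = "patient_id")
  d$label <- droplevels(factor(d$label,
                               levels = c("likely_benefit",
                                          "unlikely_benefit")))
  if (nlevels(d$label) < 2L) {
    stop("both prediction groups must be nonempty")
  }
  time <- d[[paste0(endpoint, "_time")]]
  event <- d[[paste0(endpoint, "_event")]]
  if (sum(event) < 1L) stop("no events in either group")

  rhs <- paste(c("label", adjust), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
    data = cbind(d, time = time, event = event), ties = "efron")
  i <- grep("^label", names(fit$coefficients))[1L]
  beta <- fit$coefficients[i]
  se <- sqrt(diag(fit$var))[i]
  lr <- survival::survdiff(survival::Surv(time, event) ~ label, data = d)
  logrank_p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)

  out <- do.call(rbind, lapply(levels(d$label), function(g) {
    idx <- d$label == g
    km <- km_estimate(time[idx], event[idx])
    data.frame(group = g, n = sum(idx), events = sum(event[idx]),
               median_os = km$median, median_ci_low = km$median_ci[1L],
               median_ci_high = km$median_ci[2L],
               hr = if (g == "likely_benefit") 1 else unname(exp(beta)),
               ci_low = if (g == "likely_benefit") NA_real_ else
                 unname(exp(beta - 1.959964 * se)),
               ci_high = if (g == "likely_benefit") NA_real_ else
                 unname(exp(beta + 1.959964 * se)),
               p_value = if (g == "likely_benefit") NA_real_ else
                 unname(2 * stats::pnorm(-abs(beta / se))),
               stringsAsFactors = FALSE)
  }))
  attr(out, "logrank_p") <- logrank_p
  attr(out, "model") <- fit
  out
}

#' Screen clinical covariates for retention in multivariate modelling
#'
#' For each candidate covariate, fits a Cox model with and without
#' adjustment for the classifier prediction and computes the covariate's
#' likelihood-ratio p-value in each. A covariate is retained when it is
#' associated with the endpoint at `p < p_threshold` in *both* analyses.
#' Covariates observed at a single level are excluded with a note; by
#' default missing-category levels are kept as their own stratum.
#'
#' @param clinical clinical data.frame.
#' @param predictions classifier predictions (`patient_id`, `label`).
#' @param covariates character vector of clinical column names to screen.
#' @param p_threshold retention threshold (default 0.15).
#' @param complete_case drop records with a `"missing"` level instead of
#'   keeping it as a category (default `FALSE`).
#' @param endpoint `"os"` or `"pfs"`.
#' @return data.frame with `variable`, `p_unadjusted`, `p_adjusted`,
#'   `retained`, `note`.
#' @export
covariate_retention <- function(clinical, predictions,
                                covariates = c("age", "braf",
                                               "ldh_category", "ecog",
                                               "m_stage", "subtype",
                                               "line_of_therapy"),
                                p_threshold = 0.15, complete_case = FALSE,
                                endpoint = "os") {
  d <- merge(clinical, predictions[, c("patient_id", "label")],
             by = "patient_id")
  time <- d[[paste0(endpoint, "_time")]]
  event <- d[[paste0(endpoint, "_event")]]
  res <- lapply(covariates, function(v) {
    x <- d[[v]]
    keep <- rep(TRUE, nrow(d))
    if (complete_case && is.character(x)) keep <- x != "missing"
    xv <- x[keep]
    if (!is.numeric(xv) && length(unique(xv[!is.na(xv)])) < 2L) {
      return(data.frame(variable = v, p_unadjusted = NA_real_,
                        p_adjusted = NA_real_, retained = FALSE,
                        note = "single level; excluded",
                        stringsAsFactors = FALSE))
    }
    dd <- data.frame(time = time[keep], event = event[keep], x = xv,
                     label = d$label[keep])
    if (is.character(dd$x)) dd$x <- factor(dd$x)
    lrt_p <- function(with_label) {
      rhs_full <- if (with_label) "x + label" else "x"
      full <- survival::coxph(stats::as.formula(
        paste("survival::Surv(time, event) ~", rhs_full)), data = dd)
      if (with_label) {
        red <- survival::coxph(survival::Surv(time, event) ~ label,
                               data = dd)
        partial_lrt(full, red)$p_value
      } else {
        stats::pchisq(2 * (full$loglik[2L] - full$loglik[1L]),
                      df = length(full$coefficients),
                      lower.tail = FALSE)
      }
    }
    pu <- tryCatch(lrt_p(FALSE), error = function(e) NA_real_)
    pa <- tryCatch(lrt_p(TRUE), error = function(e) NA_real_)
    data.frame(variable = v, p_unadjusted = pu, p_adjusted = pa,
               retained = !is.na(pu) && !is.na(pa) &&
                 pu < p_threshold && pa < p_threshold,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Multivariate Cox model of classifier prediction with clinical adjustment
#'
#' Fits a single Cox model with the classifier prediction as the primary
#' variable and the supplied covariates as adjustments, using the
#' conventional reference levels (LDH below the upper limit of normal,
#' ECOG 0, M0, cutaneous subtype, first-line therapy, wild-type BRAF).
#' Per-level hazard ratios with Wald confidence intervals and p-values are
#' reported; a singular (aliased) design is an error naming the terms.
#'
#' @param clinical clinical data.frame.
#' @param predictions classifier predictions (`patient_id`, `label`).
#' @param covariates clinical columns to adjust for.
#' @param endpoint `"os"` or `"pfs"`.
#' @return data.frame with `variable`, `level`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`; the fitted model is attached as attribute `"model"`.
#' @export
multivariate_cox <- function(clinical, predictions,
                             covariates = c("age", "braf", "ldh_category",
                                            "ecog", "m_stage", "subtype",
                                            "line_of_therapy"),
                             endpoint = "os") {
  d <- merge(clinical, predictions[, c("patient_id", "label")],
             by = "patient_id")
  d$label <- factor(d$label, levels = c("likely_benefit",
                                        "unlikely_benefit"))
  refs <- c(ldh_category = "<ULN", ecog = "0", m_stage = "M0",
            subtype = "cutaneous", line_of_therapy = "first",
            braf = "wild-type", sex = "male", regimen = "anti-PD-1")
  for (v in covariates) {
    if (!is.numeric(d[[v]])) {
      d[[v]] <- factor(d[[v]])
      if (!is.na(refs[v]) && refs[v] %in% levels(d[[v]])) {
        d[[v]] <- stats::relevel(d[[v]], ref = unname(refs[v]))
      }
      d[[v]] <- droplevels(d[[v]])
    }
  }
  time <- d[[paste0(endpoint, "_time")]]
  event <- d[[paste0(endpoint, "_event")]]
  rhs <- paste(c("label", covariates), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
    data = cbind(d, time = time, event = event), ties = "efron")
  if (any(is.na(fit$coefficients))) {
    stop("singular design; aliased terms: ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)],
               collapse = ", "))
  }
  cf <- fit$coefficients
  se <- sqrt(diag(fit$var))
  term_of <- function(nm) {
    for (v in c("label", covariates)) {
      if (startsWith(nm, v)) return(c(v, sub(paste0("^", v), "", nm)))
    }
    c(nm, "")
  }
  parts <- t(vapply(names(cf), term_of, character(2L)))
  out <- data.frame(variable = parts[, 1L],
                    level = ifelse(parts[, 2L] == "", "continuous",
                                   parts[, 2L]),
                    hr = unname(exp(cf)),
                    ci_low = unname(exp(cf - 1.959964 * se)),
                    ci_high = unname(exp(cf + 1.959964 * se)),
                    p_value = unname(2 * stats::pnorm(-abs(cf / se))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "model") <- fit
  out
}

#' Partial likelihood-ratio test between nested Cox models
#'
#' Compares two Cox models fit to the same samples, the reduced model
#' nested in the full one: twice the difference in maximized log partial
#' likelihood is referred to a chi-square distribution with degrees of
#' freedom equal to the difference in parameter count.
#'
#' @param full,reduced fitted `coxph` models.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
partial_lrt <- function(full, reduced) {
  if (full$n != reduced$n) {
    stop("models were fit to different sample sets")
  }
  tf <- attr(stats::terms(full), "term.labels")
  tr <- attr(stats::terms(reduced), "term.labels")
  if (!all(tr %in% tf)) stop("reduced model is not nested in the full model")
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0L) stop("reduced model has more parameters than the full model")
  ll <- function(m) m$loglik[length(m$loglik)]  # ~1 models have length 1
  stat <- max(0, 2 * (ll(full) - ll(reduced)))
  list(statistic = stat, df = df,
       p_value = if (df == 0L) 1 else
         stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Proportional-hazards diagnostics for a fitted Cox model
#'
#' Scaled Schoenfeld-residual association test per model term plus the
#' global test; terms with `p < alpha` are flagged as violating the
#' proportional-hazards assumption.
#'
#' @param model a fitted `coxph` model.
#' @param alpha flag threshold (default 0.05).
#' @return data.frame with `term`, `chisq`, `df`, `p`, `violation`, or
#'   `NULL` (with a warning) when the model has fewer than 3 events.
#' @export
ph_diagnostics <- function(model, alpha = 0.05) {
  if (model$nevent < 3L) {
    warning("fewer than 3 events; proportional-hazards diagnostic skipped")
    return(NULL)
  }
  zp <- survival::cox.zph(model)
  tab <- as.data.frame(zp$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, violation = tab$p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
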