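# Outcome-group labelling and univariate Cox screening of normalized
# glycoproteomic features.

#' Log-transform and standardize an intensity-like feature
#'
#' Modelling operates on `log2(x + offset)` centered and scaled to unit
#' variance, where `offset` is half the smallest positive value (so zeros
#' are representable); intensity-like quantities are approximately
#' log-normal. Missing values are preserved.
#'
#' @param x numeric vector of natural-scale feature values.
#' @param center,scale optional pre-computed location/scale of the log2
#'   values (used to apply a training-set transform to new samples).
#' @return standardized numeric vector, with the applied `center`, `scale`
#'   and `offset` as attributes.
#' @export
standardize_log_feature <- function(x, center = NULL, scale = NULL) {
  pos <- x[!is.na(x) & x > 0]
  off <- if (length(pos)) min(pos) / 2 else 1
  lx <- log2(pmax(x, 0) + off)
  if (is.null(center)) center <- mean(lx, na.rm = TRUE)
  if (is.null(scale)) scale <- stats::sd(lx, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1
  z <- (lx - center) / scale
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  attr(z, "offset") <- off
  z
}

#' Assign early-failure / sustained-control outcome groups
#'
#' Patients who died within six months of treatment start are labelled
#' early failure (`EF`, boundary inclusive); patients whose follow-up
#' reaches 36 months with neither progression nor death in those 36 months
#' are labelled sustained control (`SC`); everyone else is `other`. The
#' three groups partition the cohort.
#'
#' @param clinical clinical data.frame with `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event` (times in months).
#' @return data.frame with `patient_id` and factor `group`.
#' @export
assign_outcome_group <- function(clinical) {
  ef <- clinical$os_event & clinical$os_time <= 6
  event36 <- (clinical$os_event & clinical$os_time <= 36) |
    (clinical$pfs_event & clinical$pfs_time <= 36)
  sc <- !ef & clinical$pfs_time >= 36 & !event36
  group <- ifelse(ef, "EF", ifelse(sc, "SC", "other"))
  data.frame(patient_id = clinical$patient_id,
             group = factor(group, levels = c("EF", "SC", "other")),
             stringsAsFactors = FALSE)
}

#' Univariate age- and sex-adjusted Cox regression for one feature
#'
#' Fits `Surv(time, event) ~ feature + age + sex` with Efron tie handling
#' and reports Wald statistics for the (standardized) feature coefficient,
#' together with a scaled-Schoenfeld-residual proportional-hazards test.
#'
#' @param x numeric feature values, one per clinical row.
#' @param clinical clinical data.frame.
#' @param endpoint `"os"` or `"pfs"`.
#' @param transform log2-transform and standardize `x` first (default).
#' @param ph_diag run the proportional-hazards diagnostic (default `TRUE`).
#' @return one-row data.frame: `log_hr`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `ph_p`, `status` (`"ok"`, `"skipped_constant"` or
#'   `"nonconverged"`).
#' @export
cox_univariate <- function(x, clinical, endpoint = c("os", "pfs"),
                           transform = TRUE, ph_diag = TRUE) {
  endpoint <- match.arg(endpoint)
  time <- clinical[[paste0(endpoint, "_time")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  if (sum(event) < 2L) stop("fewer than 2 events for endpoint ", endpoint)
  empty <- data.frame(log_hr = NA_real_, hr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      ph_p = NA_real_, status = "skipped_constant",
                      stringsAsFactors = FALSE)
  if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) %in% c(0, NA)) {
    return(empty)
  }
  z <- if (transform) as.numeric(standardize_log_feature(x)) else x
  sexf <- factor(clinical$sex)
  two_sex <- nlevels(droplevels(sexf)) > 1L
  if (ph_diag) {
    # full model object needed for the Schoenfeld-residual diagnostic
    df <- data.frame(time = time, event = event, z = z,
                     age = clinical$age, sex = sexf)
    fit <- tryCatch({
      f <- if (two_sex) {
        survival::coxph(survival::Surv(time, event) ~ z + age + sex,
                        data = df, ties = "efron")
      } else {
        survival::coxph(survival::Surv(time, event) ~ z + age, data = df,
                        ties = "efron")
      }
      if (!is.finite(f$coefficients["z"]) ||
          !is.finite(sqrt(diag(f$var))[1L])) stop("non-finite fit")
      f
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      empty$status <- "nonconverged"
      return(empty)
    }
    beta <- unname(fit$coefficients["z"])
    se <- sqrt(diag(fit$var))[1L]
    ph_p <- NA_real_
    if (sum(event) >= 3L) {
      ph_p <- tryCatch(survival::cox.zph(fit)$table["z", "p"],
                       error = function(e) NA_real_)
    }
  } else {
    # formula-free fitting path (same Efron likelihood, much less
    # per-feature overhead during large screens)
    X <- if (two_sex) cbind(z = z, age = clinical$age,
                            sex = as.numeric(sexf == levels(sexf)[2L]))
         else cbind(z = z, age = clinical$age)
    fit <- tryCatch(
      survival::coxph.fit(X, survival::Surv(time, event), strata = NULL,
                          offset = NULL, init = rep(0, ncol(X)),
                          control = survival::coxph.control(),
                          weights = NULL, method = "efron",
                          rownames = NULL, resid = FALSE),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[1L]) ||
        !is.finite(sqrt(diag(fit$var))[1L]) ||
        sqrt(diag(fit$var))[1L] == 0) {
      empty$status <- "nonconverged"
      return(empty)
    }
    beta <- unname(fit$coefficients[1L])
    se <- sqrt(diag(fit$var))[1L]
    ph_p <- NA_real_
  }
  data.frame(log_hr = beta, hr = exp(beta),
             ci_low = exp(beta - 1.959964 * se),
             ci_high = exp(beta + 1.959964 * se),
             p_value = 2 * stats::pnorm(-abs(beta / se)),
             ph_p = ph_p, status = "ok", stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values; monotone in p-value rank and bounded by 1.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return numeric vector of q-values (empty input gives an empty vector).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0L))
  if (any(!is.na(p_values) & (p_values <= 0 | p_values > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Screen all features for association with a survival endpoint
#'
#' Runs [cox_univariate()] per feature of the requested normalization
#' family, applies Benjamini-Hochberg FDR control over the converged fits,
#' and flags features significant at `alpha_fdr`. Missing feature values
#' are median-imputed within the screened sample set before fitting.
#'
#' @param features a `glyco_features` object.
#' @param clinical clinical data.frame; `patient_id` must match
#'   `features$samples` as a set.
#' @param endpoint `"os"` or `"pfs"`.
#' @param alpha_fdr FDR significance level (default 0.05).
#' @param family normalization family to screen (see [feature_family()];
#'   default the concentration-normalized biomarkers). Use `NULL` to screen
#'   every feature in `features`.
#' @param transform,ph_diag passed to [cox_univariate()].
#' @return data.frame, one row per screened feature: the [cox_univariate()]
#'   columns plus `feature_id`, `normalization`, `fdr_q` and `significant`.
#' @export
screen_features <- function(features, clinical, endpoint = "os",
                            alpha_fdr = 0.05,
                            family = "concentration_family",
                            transform = TRUE, ph_diag = TRUE) {
  if (!setequal(features$samples, clinical$patient_id)) {
    stop("sample ids in feature matrix and clinical table do not match")
  }
  if (!is.null(family)) features <- feature_family(features, family)
  vals <- features$values[clinical$patient_id, , drop = FALSE]
  res <- vector("list", ncol(vals))
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    if (anyNA(x)) {
      med <- stats::median(x, na.rm = TRUE)
      x[is.na(x)] <- med
    }
    res[[j]] <- cox_univariate(x, clinical, endpoint, transform = transform,
                               ph_diag = ph_diag)
  }
  out <- do.call(rbind, res)
  out <- cbind(data.frame(feature_id = features$features$feature_id,
                          normalization = features$features$normalization,
                          stringsAsFactors = FALSE), out)
  out$fdr_q <- NA_real_
  ok <- out$status == "ok"
  out$fdr_q[ok] <- bh_fdr(out$p_value[ok])
  out$significant <- !is.na(out$fdr_q) & out$fdr_q < alpha_fdr
  rownames(out) <- NULL
  out
}

#' Differential expression between early-failure and sustained-control
#' patients
#'
#' Compares feature distributions of the EF and SC outcome groups
#' (patients labelled `other` are excluded), with Benjamini-Hochberg
#' correction. The default test is an age- and sex-adjusted logistic
#' regression of group membership on the standardized log2 feature; a
#' rank-based Wilcoxon alternative (unadjusted) is available.
#'
#' @param features a `glyco_features` object.
#' @param outcome_groups data.frame from [assign_outcome_group()].
#' @param clinical clinical data.frame.
#' @param method `"logistic"` (default) or `"wilcoxon"`.
#' @param alpha_fdr FDR level for the `significant` flag.
#' @param family normalization family to test (default concentration).
#' @return data.frame with `feature_id`, `estimate` (log-odds of EF per SD
#'   for the logistic method), `p_value`, `fdr_q`, `significant`, `status`.
#' @export
ef_sc_differential <- function(features, outcome_groups, clinical,
                               method = c("logistic", "wilcoxon"),
                               alpha_fdr = 0.05,
                               family = "concentration_family") {
  method <- match.arg(method)
  if (!is.null(family)) features <- feature_family(features, family)
  keep <- outcome_groups$patient_id[outcome_groups$group %in% c("EF", "SC")]
  if (length(keep) == 0L) stop("no patients labelled EF or SC")
  grp <- outcome_groups$group[match(keep, outcome_groups$patient_id)]
  if (sum(grp == "EF") < 2L || sum(grp == "SC") < 2L) {
    stop("each compared group needs at least 2 patients")
  }
  clin <- clinical[match(keep, clinical$patient_id), , drop = FALSE]
  vals <- features$values[keep, , drop = FALSE]
  is_ef <- as.integer(grp == "EF")
  sexf <- factor(clin$sex)
  n_feat <- ncol(vals)
  est <- p <- rep(NA_real_, n_feat)
  status <- rep("ok", n_feat)
  for (j in seq_len(n_feat)) {
    x <- vals[, j]
    if (anyNA(x)) x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) %in% c(0, NA)) {
      status[j] <- "skipped_constant"
      next
    }
    z <- as.numeric(standardize_log_feature(x))
    if (method == "logistic") {
      fit <- tryCatch({
        f <- if (nlevels(droplevels(sexf)) > 1L) {
          stats::glm(is_ef ~ z + clin$age + sexf, family = stats::binomial())
        } else {
          stats::glm(is_ef ~ z + clin$age, family = stats::binomial())
        }
        s <- summary(f)$coefficients
        if (!"z" %in% rownames(s)) stop("dropped term")
        s["z", c("Estimate", "Pr(>|z|)")]
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) {
        status[j] <- "nonconverged"
      } else {
        est[j] <- fit[1L]
        p[j] <- fit[2L]
      }
    } else {
      wt <- stats::wilcox.test(z[is_ef == 1L], z[is_ef == 0L], exact = FALSE)
      est[j] <- stats::median(z[is_ef == 1L]) - stats::median(z[is_ef == 0L])
      p[j] <- wt$p.value
    }
  }
  out <- data.frame(feature_id = features$features$feature_id,
                    estimate = est, p_value = p, fdr_q = NA_real_,
                    status = status, stringsAsFactors = FALSE)
  ok <- out$status == "ok" & !is.na(out$p_value)
  out$fdr_q[ok] <- bh_fdr(out$p_value[ok])
  out$significant <- !is.na(out$fdr_q) & out$fdr_q < alpha_fdr
  out
}
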