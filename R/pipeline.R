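# End-to-end orchestration: simulate -> quantify -> glycan features ->
# screen -> split -> classify -> evaluate, with a machine-readable report.

safe_group_hr <- function(predictions, clinical, ...) {
  tryCatch(group_hr(predictions, clinical, ...),
           error = function(e) {
             structure(list(), note = conditionMessage(e))
           })
}

summarize_eval <- function(gh) {
  if (length(gh) == 0L) {
    return(list(available = FALSE, note = attr(gh, "note")))
  }
  list(available = TRUE,
       groups = gh,
       hr = gh$hr[gh$group == "unlikely_benefit"],
       hr_ci = c(gh$ci_low[gh$group == "unlikely_benefit"],
                 gh$ci_high[gh$group == "unlikely_benefit"]),
       p_value = gh$p_value[gh$group == "unlikely_benefit"],
       logrank_p = attr(gh, "logrank_p"))
}

km_series <- function(predictions, clinical, endpoint = "os") {
  d <- merge(clinical, predictions[, c("patient_id", "label")],
             by = "patient_id")
  time <- d[[paste0(endpoint, "_time")]]
  event <- d[[paste0(endpoint, "_event")]]
  lapply(split(seq_len(nrow(d)), d$label), function(idx) {
    if (length(idx) == 0L) return(NULL)
    km_estimate(time[idx], event[idx])$curve
  })
}

#' Run the full glycoproteomic survival-biomarker pipeline on a synthetic
#' cohort
#'
#' One call exercises every stage: cohort simulation, drift correction and
#' feature building (done inside [simulate_cohort()]), fucose monomer
#' weights, outcome-group labelling, univariate Cox screening and
#' early-failure vs sustained-control differential testing, stratified
#' cohort splitting, the repeated cross-validated penalized Cox classifier
#' with concordance-maximized dichotomization, the FDR-pre-filtered fucose
#' monomer-weight classifier on the same splits, and layered survival
#' evaluation (per-split dichotomized hazard ratios with Kaplan-Meier
#' medians, covariate retention, multivariate adjustment, partial
#' likelihood-ratio comparison, proportional-hazards diagnostics).
#'
#' Everything is deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param alpha_fdr FDR level used by the screens and the fucose
#'   pre-filter.
#' @param folds,repeats cross-validation controls for both classifiers.
#' @param split_fractions training/validation/test fractions.
#' @param out optional directory; when given, the report JSON, the model
#'   JSON, predictions and screen tables are written there.
#' @return an object of class `glyco_pipeline`: the cohort, screen tables,
#'   split, models, predictions and the structured `report` list.
#' @export
run_pipeline <- function(config = simulation_config(),
                         alpha_fdr = 0.05, folds = 5L, repeats = 10L,
                         split_fractions = c(training = 0.4,
                                             validation = 0.3, test = 0.3),
                         out = NULL) {
  cohort <- simulate_cohort(config)
  clinical <- cohort$clinical
  features <- cohort$features
  monomer <- cohort$monomer

  groups <- assign_outcome_group(clinical)
  screen_os <- screen_features(features, clinical, alpha_fdr = alpha_fdr,
                               family = "concentration_family")
  diff_efsc <- tryCatch(
    ef_sc_differential(features, groups, clinical, alpha_fdr = alpha_fdr),
    error = function(e) NULL)

  split <- stratified_split(clinical, groups, split_fractions,
                            seed = config$seed)
  train_ids <- split$patient_id[split$set == "training"]
  clin_train <- clinical[match(train_ids, clinical$patient_id), ,
                         drop = FALSE]

  conc <- feature_family(features, "concentration_family")
  model <- fit_lasso_cox(subset_samples(conc, train_ids), clin_train,
                         folds = folds, repeats = repeats,
                         seed = config$seed)
  predictions <- stats::predict(model, conc)

  eval_sets <- list(full = clinical$patient_id)
  for (s in levels(split$set)) {
    eval_sets[[s]] <- split$patient_id[split$set == s]
  }
  evaluation <- lapply(eval_sets, function(ids) {
    summarize_eval(safe_group_hr(
      predictions[predictions$patient_id %in% ids, , drop = FALSE],
      clinical[clinical$patient_id %in% ids, , drop = FALSE]))
  })
  km <- km_series(predictions, clinical)

  # fucose monomer-weight classifier on the same training assignment
  fucose <- NULL
  if (!is.null(monomer) && ncol(monomer$values) > 0L) {
    fmodel <- fit_fucose_model(subset_samples(monomer, train_ids),
                               clin_train, alpha_fdr = alpha_fdr,
                               folds = folds, repeats = repeats,
                               seed = config$seed)
    fpred <- stats::predict(fmodel, monomer)
    feval <- lapply(eval_sets, function(ids) {
      summarize_eval(safe_group_hr(
        fpred[fpred$patient_id %in% ids, , drop = FALSE],
        clinical[clinical$patient_id %in% ids, , drop = FALSE]))
    })
    fucose <- list(model = fmodel, predictions = fpred,
                   evaluation = feval,
                   n_features = ncol(monomer$values),
                   n_prefilter_significant =
                     sum(fmodel$prefilter$significant))
  }

  # multivariate adjustment on the held-out (validation + test) patients
  ho_ids <- split$patient_id[split$set != "training"]
  clin_ho <- clinical[clinical$patient_id %in% ho_ids, , drop = FALSE]
  pred_ho <- predictions[predictions$patient_id %in% ho_ids, , drop = FALSE]
  multivariate <- NULL
  if (model$status == "ok" &&
      nlevels(droplevels(factor(pred_ho$label))) == 2L) {
    retention <- tryCatch(
      covariate_retention(clin_ho, pred_ho), error = function(e) NULL)
    retained <- if (is.null(retention)) character(0L) else
      retention$variable[retention$retained]
    mv <- tryCatch(multivariate_cox(clin_ho, pred_ho,
                                    covariates = retained),
                   error = function(e) NULL)
    lrt <- NULL
    ph <- NULL
    if (!is.null(mv)) {
      # compare the adjusted model with vs without the classifier term;
      # with no retained covariates this reduces to classifier vs null
      full_fit <- attr(mv, "model")
      d <- merge(clin_ho, pred_ho[, c("patient_id", "label")],
                 by = "patient_id")
      rhs <- if (length(retained)) paste(retained, collapse = " + ")
             else "1"
      reduced_fit <- survival::coxph(
        stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                rhs)),
        data = d, ties = "efron")
      lrt <- tryCatch(partial_lrt(full_fit, reduced_fit),
                      error = function(e) NULL)
      ph <- tryCatch(ph_diagnostics(full_fit), error = function(e) NULL)
    }
    multivariate <- list(retention = retention, table = mv,
                         partial_lrt = lrt, ph_diagnostics = ph)
  }

  result <- structure(list(
    cohort = cohort, groups = groups, screen_os = screen_os,
    diff_efsc = diff_efsc, split = split, model = model,
    predictions = predictions, evaluation = evaluation, km = km,
    fucose = fucose, multivariate = multivariate,
    config = config), class = "glyco_pipeline")
  result$report <- build_report(result)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_report(result$report, file.path(out, "report.json"))
    write_glyco_model(model, file.path(out, "model.json"))
    write_tsv(predictions, file.path(out, "predictions.tsv"))
    write_tsv(screen_os, file.path(out, "screen_os.tsv"))
    write_tsv(split, file.path(out, "split.tsv"))
  }
  result
}

#' Build the structured report of a pipeline run
#'
#' Collects every statistic the run produced into one machine-readable
#' list: cohort structure, outcome-group sizes, screen hit counts,
#' classifier content, per-set performance tables (events/N, median OS
#' with CI, HR with CI, p, log-rank p), Kaplan-Meier step series, the
#' fucose-model section and the multivariate section. Empty sections are
#' explicit.
#'
#' @param result a `glyco_pipeline` object.
#' @return a nested list, JSON-serializable via [write_report()].
#' @export
build_report <- function(result) {
  meta <- result$cohort$features$features
  grp_tab <- table(result$groups$group)
  clin <- result$cohort$clinical
  ev <- lapply(result$evaluation, function(e) {
    if (!isTRUE(e$available)) return(list(available = FALSE))
    list(available = TRUE, table = e$groups, hr = e$hr, hr_ci = e$hr_ci,
         p_value = e$p_value, logrank_p = e$logrank_p)
  })
  rep <- list(
    cohort = list(
      n_patients = nrow(clin),
      n_events = sum(clin$os_event),
      event_fraction = mean(clin$os_event),
      km_median_os = km_estimate(clin$os_time, clin$os_event)$median,
      n_analytes = nrow(result$cohort$manifest),
      n_features_concentration = sum(meta$normalization %in%
                                       c("concentration",
                                         "peptide_concentration")),
      n_occupancy_based_conc = sum(
        meta$normalization == "concentration" &
          meta$site_key %in%
            meta$site_key[meta$normalization == "site_occupancy"]),
      n_ra_based_conc = sum(
        meta$normalization == "concentration" &
          meta$site_key %in%
            meta$site_key[meta$normalization == "relative_abundance"]),
      n_glycopeptide_conc = sum(meta$normalization == "concentration"),
      n_peptide_conc = sum(meta$normalization == "peptide_concentration"),
      n_features_ra_family = sum(meta$normalization %in%
                                   c("relative_abundance",
                                     "site_occupancy")),
      outcome_groups = list(EF = unname(grp_tab["EF"]),
                            SC = unname(grp_tab["SC"]),
                            other = unname(grp_tab["other"]))),
    screening = list(
      n_screened = sum(result$screen_os$status == "ok"),
      n_significant = sum(result$screen_os$significant),
      n_differential_ef_sc = if (is.null(result$diff_efsc)) NA else
        sum(result$diff_efsc$significant)),
    classifier = list(
      status = result$model$status,
      n_selected = length(result$model$coef),
      lambda = result$model$lambda,
      threshold = result$model$threshold,
      training_cindex = result$model$training_cindex,
      selected_features = names(result$model$coef)),
    evaluation = ev,
    km = result$km,
    fucose = if (is.null(result$fucose)) list(available = FALSE) else list(
      available = TRUE,
      n_features = result$fucose$n_features,
      n_prefilter_significant = result$fucose$n_prefilter_significant,
      status = result$fucose$model$status,
      n_selected = length(result$fucose$model$coef),
      evaluation = lapply(result$fucose$evaluation, function(e) {
        if (!isTRUE(e$available)) return(list(available = FALSE))
        list(available = TRUE, hr = e$hr, hr_ci = e$hr_ci,
             p_value = e$p_value)
      })),
    multivariate = if (is.null(result$multivariate))
      list(available = FALSE) else list(
        available = TRUE,
        retention = result$multivariate$retention,
        table = result$multivariate$table,
        partial_lrt = result$multivariate$partial_lrt,
        ph_diagnostics = result$multivariate$ph_diagnostics),
    seed = result$config$seed
  )
  rep
}

#' Write a pipeline report as JSON
#'
#' @param report list from [build_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  cat("Glycoproteomic survival pipeline run (seed", x$config$seed, ")\n")
  cat(" cohort:", nrow(x$cohort$clinical), "patients,",
      x$report$cohort$n_features_concentration,
      "concentration-normalized features\n")
  cat(" screen:", x$report$screening$n_significant,
      "features at FDR <", 0.05, "\n")
  cat(" classifier:", x$report$classifier$n_selected,
      "features selected (", x$report$classifier$status, ")\n")
  for (s in c("training", "validation", "test")) {
    e <- x$evaluation[[s]]
    if (isTRUE(e$available)) {
      cat(sprintf("  %s: HR = %.2f (%.2f, %.2f), p = %.3g\n", s, e$hr,
                  e$hr_ci[1L], e$hr_ci[2L], e$p_value))
    }
  }
  invisible(x)
}
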