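# Synthetic survival-glycoproteomics cohorts.
#
# The simulator emulates the data structure of a targeted plasma
# glycoproteomics study of checkpoint-inhibitor-treated melanoma: a panel
# manifest of glycopeptides/peptides/heavy standards, a raw intensity matrix
# with injection-order drift and interspersed pooled-QC injections, and a
# clinical table with right-censored OS/PFS endpoints. Hazard effects can be
# planted on chosen derived features so downstream recovery is testable.

# Deterministic per-stage sub-seeds derived from the single config seed, so
# each generation stage is individually reproducible.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003) * 1009 + h * 97) %% 2147483647L
}

#' Simulation configuration for a synthetic glycoproteomics cohort
#'
#' Defaults describe a cohort shaped like the metastatic-melanoma study the
#' pipeline targets: 202 patients, 75 proteins each with one heavy-standard
#' calibrated reference peptide, 443 glycopeptides at occupancy-normalized
#' sites plus 78 at relative-abundance sites (596 concentration-normalized
#' features in total), 51 N-linked occupancy sites, roughly 56% death
#' events with median OS near 40 months and early-failure / sustained-
#' control fractions near 20% and 28%.
#'
#' @param n_patients number of patients (>= 10).
#' @param n_proteins number of proteins; each contributes one reference
#'   peptide (with heavy standard) and hosts glycosylation sites.
#' @param n_occ_glycopeptides total glycopeptides at occupancy-normalized
#'   sites (each such site carries more than two glycan species).
#' @param n_ra_glycopeptides total glycopeptides at relative-abundance
#'   sites (one or two glycan species per site).
#' @param occ_glycans_range integer range of glycan species per occupancy
#'   site (minimum must be > 2).
#' @param n_nlinked_occ_sites number of occupancy sites that are N-linked
#'   (the rest are O-linked); these drive the fucose monomer-weight panel.
#' @param fraction_fucosylated probability that a sampled glycan carries
#'   fucose.
#' @param planted `NULL` or a data.frame with columns `selector` (one of
#'   `"peptide"`, `"ra_glycopeptide"`, `"occ_glycopeptide"`,
#'   `"fucose_site"`), `n` (features per selector) and `beta` (log hazard
#'   ratio per standard deviation of the realized feature). An optional
#'   `trait` column makes all features of a row (or of several rows with
#'   the same trait name) co-vary through one shared latent driver that
#'   enters the hazard once — emulating correlated prognostic features;
#'   rows without a trait plant independent per-feature effects.
#' @param plant_sigma log-scale shift magnitude linking the latent
#'   per-patient trait to the planted analyte intensities.
#' @param weibull_shape,weibull_scale baseline Weibull hazard shape and
#'   scale (months). `weibull_scale = NULL` sets scale from `median_os`
#'   (and is recalibrated when `ef_sc_targets` is supplied).
#' @param median_os target marginal median OS in months (used only when
#'   `weibull_scale` is `NULL`).
#' @param censor_rate rate (per month) of the independent exponential
#'   loss-to-follow-up process.
#' @param horizon administrative censoring horizon in months (may be `Inf`).
#' @param calibrate_median when `TRUE` (and `ef_sc_targets` is set), the
#'   Weibull shape is calibrated jointly with the scale so that the
#'   *marginal* median event time under the supplied risk-score
#'   heterogeneity matches `median_os` while the early-failure fraction
#'   matches its target; useful when planted effects are strong enough to
#'   distort the marginal survival curve.
#' @param ef_sc_targets `NULL`, or named proportions `c(ef =, sc =)`:
#'   target fractions of early-failure (death within 6 months) and
#'   sustained-control (event-free through 36 months) patients, achieved by
#'   calibrating the baseline scale and the progression-fraction
#'   distribution rather than by relabeling.
#' @param pfs_frac_shape Beta(shape1, shape2) parameters of the fraction of
#'   the death time at which progression occurs (progression precedes
#'   death); shape1 is recalibrated when an `sc` target is supplied.
#' @param qc_interval one QC-pool injection every `qc_interval` test
#'   injections (plus one at each run end).
#' @param drift_amplitude log-scale amplitude of the smooth injection-order
#'   drift shared by all analytes.
#' @param drift_knots number of spline knots of the drift curve.
#' @param noise_cv multiplicative measurement noise CV per analyte
#'   (applies to every injection, QC pools included).
#' @param bio_cv per-patient biological coefficient of variation of analyte
#'   intensities (QC pools carry none).
#' @param seed integer master seed; all stages derive sub-seeds from it.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 202L,
                              n_proteins = 75L,
                              n_occ_glycopeptides = 443L,
                              n_ra_glycopeptides = 78L,
                              occ_glycans_range = c(3L, 7L),
                              n_nlinked_occ_sites = 51L,
                              fraction_fucosylated = 0.5,
                              planted = NULL,
                              plant_sigma = 0.8,
                              weibull_shape = 0.6,
                              weibull_scale = NULL,
                              median_os = 40.1,
                              censor_rate = 0.010,
                              horizon = 78,
                              ef_sc_targets = c(ef = 40 / 202, sc = 56 / 202),
                              pfs_frac_shape = c(0.8, 3),
                              calibrate_median = FALSE,
                              qc_interval = 10L,
                              drift_amplitude = 0.15,
                              drift_knots = 4L,
                              noise_cv = 0.1,
                              bio_cv = 0.25,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_proteins = as.integer(n_proteins),
              n_occ_glycopeptides = as.integer(n_occ_glycopeptides),
              n_ra_glycopeptides = as.integer(n_ra_glycopeptides),
              occ_glycans_range = as.integer(occ_glycans_range),
              n_nlinked_occ_sites = as.integer(n_nlinked_occ_sites),
              fraction_fucosylated = fraction_fucosylated,
              planted = planted, plant_sigma = plant_sigma,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              median_os = median_os, censor_rate = censor_rate,
              horizon = horizon, ef_sc_targets = ef_sc_targets,
              pfs_frac_shape = pfs_frac_shape,
              calibrate_median = isTRUE(calibrate_median),
              qc_interval = as.integer(qc_interval),
              drift_amplitude = drift_amplitude,
              drift_knots = as.integer(drift_knots),
              noise_cv = noise_cv, bio_cv = bio_cv, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 10L)
  if (cfg$n_proteins < 1L ||
      (cfg$n_occ_glycopeptides + cfg$n_ra_glycopeptides +
         cfg$n_proteins) < 1L) {
    stop("configuration cannot yield at least one analyte")
  }
  props <- c(cfg$fraction_fucosylated, cfg$ef_sc_targets)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$weibull_shape <= 0 || cfg$censor_rate < 0 || cfg$horizon <= 0 ||
      (!is.null(cfg$weibull_scale) && cfg$weibull_scale <= 0)) {
    stop("hazard and censoring parameters must be strictly positive")
  }
  if (cfg$n_occ_glycopeptides > 0L && cfg$occ_glycans_range[1L] <= 2L) {
    stop("occupancy sites need more than 2 glycan species")
  }
  if (cfg$n_occ_glycopeptides > 0L &&
      cfg$n_occ_glycopeptides < cfg$occ_glycans_range[1L]) {
    stop("n_occ_glycopeptides too small for the minimum site size")
  }
  cfg
}

# Partition `total` into site sizes within [lo, hi], cycling through the
# range so requested glycopeptide counts are met exactly.
partition_sites <- function(total, lo, hi) {
  if (total == 0L) return(integer())
  sizes <- integer()
  rem <- total
  cyc <- seq.int(lo, hi)
  i <- 1L
  while (rem > 0L) {
    s <- cyc[(i - 1L) %% length(cyc) + 1L]
    if (rem - s > 0L && rem - s < lo) {
      s <- if (rem <= hi) rem else rem - lo
    }
    s <- min(s, rem)
    if (s < lo) {
      sizes[length(sizes)] <- sizes[length(sizes)] + rem
      break
    }
    sizes <- c(sizes, s)
    rem <- rem - s
    i <- i + 1L
  }
  sizes
}

sample_compositions <- function(n, fraction_fucosylated) {
  codes <- character(0L)
  guard <- 0L
  while (length(codes) < n && guard < 200L) {
    hex <- sample(3:9, n, replace = TRUE)
    hexnac <- sample(2:6, n, replace = TRUE)
    fuc <- ifelse(runif(n) < fraction_fucosylated,
                  sample(1:2, n, replace = TRUE), 0L)
    sia <- vapply(hexnac, function(h) sample.int(min(4L, h) + 1L, 1L) - 1L,
                  integer(1L))
    cand <- sprintf("%d%d%d%d", hex, hexnac, fuc, sia)
    codes <- unique(c(codes, cand))
    guard <- guard + 1L
  }
  codes[seq_len(n)]
}

random_peptide <- function(n_res) {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P", "Q", "S",
          "T", "V", "W", "Y")
  vapply(n_res, function(k)
    paste0(c(sample(aa, k - 1L, replace = TRUE), sample(c("K", "R"), 1L)),
           collapse = ""), character(1L))
}

#' Generate a synthetic panel manifest
#'
#' Builds the analyte panel implied by a [simulation_config()]: per protein
#' one designated non-glycosylated reference peptide paired with a heavy
#' standard, and glycosylation sites carrying glycan species. Sites with
#' more than two glycan species are tagged `site_occupancy`; sites with one
#' or two species are tagged `relative_abundance`.
#'
#' @param config a `sim_config` object.
#' @return manifest data.frame with columns `analyte_id`, `protein`,
#'   `peptide`, `site`, `glycan`, `linkage`, `kind`,
#'   `reference_peptide_id`, `heavy_standard_id`, `spike_concentration`,
#'   `site_normalization`, `site_key`.
#' @export
generate_panel <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "panel"))
  proteins <- sprintf("P%03d", seq_len(config$n_proteins))

  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  # reference peptides + heavy standards
  ref_pep <- random_peptide(sample(8:14, config$n_proteins, replace = TRUE))
  ref_id <- paste0(proteins, "|", ref_pep)
  hs_id <- paste0(ref_id, "*")
  spike <- round(runif(config$n_proteins, 2, 50), 2)
  for (i in seq_len(config$n_proteins)) {
    add_row(analyte_id = ref_id[i], protein = proteins[i],
            peptide = ref_pep[i], site = NA_integer_,
            glycan = NA_character_, linkage = "none", kind = "peptide",
            reference_peptide_id = ref_id[i], heavy_standard_id = hs_id[i],
            spike_concentration = spike[i], site_normalization = NA_character_,
            site_key = paste0(proteins[i], "|", ref_pep[i]))
    add_row(analyte_id = hs_id[i], protein = proteins[i],
            peptide = ref_pep[i], site = NA_integer_,
            glycan = NA_character_, linkage = "none", kind = "heavy_standard",
            reference_peptide_id = ref_id[i], heavy_standard_id = NA_character_,
            spike_concentration = spike[i], site_normalization = NA_character_,
            site_key = paste0(proteins[i], "|", ref_pep[i]))
  }

  occ_sizes <- partition_sites(config$n_occ_glycopeptides,
                               config$occ_glycans_range[1L],
                               config$occ_glycans_range[2L])
  ra_sizes <- partition_sites(config$n_ra_glycopeptides, 1L, 2L)
  n_occ_sites <- length(occ_sizes)
  site_sizes <- c(occ_sizes, ra_sizes)
  site_norm <- rep(c("site_occupancy", "relative_abundance"),
                   c(length(occ_sizes), length(ra_sizes)))
  n_nl <- min(config$n_nlinked_occ_sites, n_occ_sites)
  site_link <- c(rep(c("N", "O"), c(n_nl, n_occ_sites - n_nl)),
                 rep("N", length(ra_sizes)))

  glyco_pep <- random_peptide(sample(8:14, length(site_sizes), replace = TRUE))
  for (s in seq_along(site_sizes)) {
    prot_i <- (s - 1L) %% config$n_proteins + 1L
    pos <- 40L + 17L * ((s - 1L) %/% config$n_proteins + 1L)
    glycans <- sample_compositions(site_sizes[s], config$fraction_fucosylated)
    sk <- paste0(proteins[prot_i], "|", glyco_pep[s], "|", pos)
    for (g in glycans) {
      add_row(analyte_id = paste0(proteins[prot_i], "|", glyco_pep[s], "@",
                                  site_link[s], pos, "|", g),
              protein = proteins[prot_i], peptide = glyco_pep[s],
              site = pos, glycan = g, linkage = site_link[s],
              kind = "glycopeptide", reference_peptide_id = ref_id[prot_i],
              heavy_standard_id = NA_character_,
              spike_concentration = NA_real_,
              site_normalization = site_norm[s], site_key = sk)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (anyDuplicated(manifest$analyte_id)) {
    stop("internal error: duplicate analyte ids in generated manifest")
  }
  manifest
}

#' Generate a synthetic clinical table under a Weibull proportional-hazards
#' model
#'
#' Event times are drawn by inverse-transform sampling from a Weibull
#' baseline hazard scaled by `exp(risk_score)`; censoring combines an
#' independent exponential loss-to-follow-up process with an administrative
#' horizon. Progression times are the death times multiplied by a
#' Beta-distributed fraction, so progression never follows death. When the
#' config carries early-failure / sustained-control targets, the baseline
#' scale and the progression-fraction mean are calibrated (deterministic
#' numeric integration plus root finding, no relabeling) so the expected
#' EF and SC fractions match the targets.
#'
#' @param config a `sim_config` object.
#' @param risk_scores numeric vector, one finite linear-predictor value per
#'   patient (use zeros for a null cohort).
#' @return a clinical data.frame with demographics, covariates, `os_time`,
#'   `os_event`, `pfs_time`, `pfs_event` and the latent uncensored event
#'   time in attribute `"true_event_time"`.
#' @export
generate_clinical <- function(config, risk_scores) {
  validate_sim_config(config)
  n <- config$n_patients
  if (length(risk_scores) != n || any(!is.finite(risk_scores))) {
    stop("risk_scores must be finite, one per patient")
  }
  set.seed(stage_seed(config$seed, "clinical"))

  shape <- config$weibull_shape
  scale <- config$weibull_scale
  if (is.null(scale)) scale <- config$median_os / log(2)^(1 / shape)
  pfs_shape <- config$pfs_frac_shape

  if (!is.null(config$ef_sc_targets)) {
    cal <- calibrate_ef_sc(config, risk_scores, shape, scale, pfs_shape)
    scale <- cal$scale
    shape <- cal$shape
    pfs_shape <- cal$pfs_shape
  }

  u <- runif(n)
  t_event <- scale * (-log(u) / exp(risk_scores))^(1 / shape)
  c_loss <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)
  c_all <- pmin(c_loss, config$horizon)
  os_time <- pmin(t_event, c_all)
  os_event <- t_event <= c_all
  b <- rbeta(n, pfs_shape[1L], pfs_shape[2L])
  t_prog <- b * t_event
  pfs_time <- pmin(t_prog, c_all)
  pfs_event <- t_prog <= c_all

  clin <- data.frame(
    patient_id = sprintf("PT%04d", seq_len(n)),
    age = pmin(pmax(round(rnorm(n, 65, 10)), 25), 92),
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.69, 0.31)),
    regimen = sample(c("anti-PD-1", "anti-PD-1 + anti-CTLA-4"), n, TRUE,
                     prob = c(0.55, 0.45)),
    subtype = sample(c("cutaneous", "unknown_primary", "mucosal", "uveal",
                       "acral"), n, TRUE,
                     prob = c(0.63, 0.17, 0.08, 0.07, 0.05)),
    ldh_category = sample(c("<ULN", "1-2xULN", ">2xULN", "missing"), n, TRUE,
                          prob = c(0.54, 0.33, 0.10, 0.03)),
    ecog = sample(c("0", "1", ">=2", "missing"), n, TRUE,
                  prob = c(0.58, 0.32, 0.07, 0.03)),
    braf = sample(c("mutant", "wild-type", "missing"), n, TRUE,
                  prob = c(0.33, 0.64, 0.03)),
    m_stage = sample(c("M0", "M1a", "M1b", "M1c", "M1d"), n, TRUE,
                     prob = c(0.05, 0.07, 0.15, 0.55, 0.18)),
    line_of_therapy = sample(c("first", "later"), n, TRUE,
                             prob = c(0.73, 0.27)),
    os_time = os_time, os_event = os_event,
    pfs_time = pfs_time, pfs_event = pfs_event,
    stringsAsFactors = FALSE
  )
  attr(clin, "true_event_time") <- t_event
  attr(clin, "weibull") <- c(shape = shape, scale = scale)
  clin
}

# Expected EF fraction (death observed within 6 months) and SC fraction
# (event-free follow-up through 36 months) under the simulator's model,
# averaged over the supplied linear predictors; used to calibrate the
# baseline scale and progression-fraction mean toward target proportions.
expected_ef_sc <- function(lp, shape, scale, censor_rate, horizon,
                           pfs_shape) {
  sc_t <- function(t, lpi) exp(-exp(lpi) * (t / scale)^shape)
  # EF = E_lp[ integral over [0,6] of S_C(t) dF(t) ]; integration by parts
  # avoids the hazard singularity at t = 0 when shape < 1
  hz <- min(6, horizon)
  tg <- seq(0, hz, length.out = 241L)
  dt <- tg[2L] - tg[1L]
  ef_i <- vapply(lp, function(lpi) {
    ft <- 1 - sc_t(tg, lpi)
    tail_term <- exp(-censor_rate * hz) * ft[length(tg)]
    trap <- censor_rate * sum((ft * exp(-censor_rate * tg))[-1L] +
                                (ft * exp(-censor_rate * tg))[-length(tg)]) *
      dt / 2
    tail_term + trap
  }, numeric(1L))
  ef <- mean(ef_i)
  # SC: progression time b*T > 36 and censoring/horizon beyond 36
  if (horizon < 36) {
    sc <- 0
  } else {
    bg <- seq(0.002, 0.998, length.out = 200L)
    db <- stats::dbeta(bg, pfs_shape[1L], pfs_shape[2L])
    db <- db / sum(db)
    sc_i <- vapply(lp, function(lpi) sum(db * sc_t(36 / bg, lpi)),
                   numeric(1L))
    sc <- mean(sc_i) * exp(-censor_rate * 36)
  }
  c(ef = ef, sc = sc)
}

# Marginal median event time under linear-predictor heterogeneity: the t
# with mean_i S(t | lp_i) = 0.5.
marginal_median <- function(lp, shape, scale) {
  s_marg <- function(t) mean(exp(-exp(lp) * (t / scale)^shape)) - 0.5
  if (s_marg(1e-3) < 0 || s_marg(5e3) > 0) return(NA_real_)
  stats::uniroot(s_marg, c(1e-3, 5e3), tol = 1e-4)$root
}

calibrate_ef_sc <- function(config, lp, shape, scale, pfs_shape) {
  targets <- config$ef_sc_targets
  solve_scale <- function(shp, start_scale) {
    f <- function(log_scale) {
      expected_ef_sc(lp, shp, exp(log_scale), config$censor_rate,
                     config$horizon, pfs_shape)["ef"] - targets["ef"]
    }
    lo <- log(2); hi <- log(5000)
    if (f(lo) > 0 && f(hi) < 0) {
      exp(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root)
    } else {
      NA_real_
    }
  }
  if (!is.na(targets["ef"]) && targets["ef"] > 0) {
    if (config$calibrate_median) {
      # joint calibration: for each candidate shape, set the scale to hit
      # the EF target, then pick the shape whose marginal median matches
      g <- function(shp) {
        sc <- solve_scale(shp, scale)
        if (is.na(sc)) return(NA_real_)
        marginal_median(lp, shp, sc) - config$median_os
      }
      grid <- seq(0.3, 2.5, by = 0.1)
      gv <- vapply(grid, g, numeric(1L))
      ok <- which(is.finite(gv))
      br <- ok[which(diff(sign(gv[ok])) != 0)]
      if (length(br)) {
        i <- br[1L]
        j <- ok[which(ok > i)][1L]
        shape <- stats::uniroot(g, c(grid[i], grid[j]), tol = 1e-3)$root
      } else {
        warning("median target unreachable; keeping configured shape")
      }
    }
    sc <- solve_scale(shape, scale)
    if (!is.na(sc)) {
      scale <- sc
    } else {
      warning("EF target unreachable; keeping uncalibrated scale")
    }
  }
  if (!is.na(targets["sc"]) && targets["sc"] > 0 && config$horizon >= 36) {
    g <- function(log_s1) {
      expected_ef_sc(lp, shape, scale, config$censor_rate, config$horizon,
                     c(exp(log_s1), pfs_shape[2L]))["sc"] - targets["sc"]
    }
    lo <- log(0.02); hi <- log(50)
    if (g(lo) < 0 && g(hi) > 0) {
      pfs_shape[1L] <- exp(stats::uniroot(g, c(lo, hi), tol = 1e-4)$root)
    } else {
      warning("SC target unreachable; keeping progression-fraction shape")
    }
  }
  list(scale = scale, shape = shape, pfs_shape = pfs_shape)
}

#' Generate a raw abundance matrix for a manifest and cohort
#'
#' Log-normal analyte intensities with per-patient biological variation, a
#' shared smooth injection-order drift multiplier, multiplicative
#' measurement noise, and QC-pool injections (biological variance zero)
#' inserted at both run ends and every `qc_interval` test injections.
#' Planted features shift the targeted analytes per patient proportionally
#' to the latent traits supplied in `latent`.
#'
#' @param manifest panel manifest data.frame.
#' @param clinical clinical table (defines the patient sample ids).
#' @param config a `sim_config` object.
#' @param latent optional list with matrix `u` (patients x planted traits)
#'   and `plan`, a list of per-trait analyte effects (as produced by
#'   [simulate_cohort()]); `NULL` plants nothing.
#' @return a `glyco_raw` object.
#' @export
generate_abundances <- function(manifest, clinical, config, latent = NULL) {
  set.seed(stage_seed(config$seed, "abundance"))
  n <- nrow(clinical)
  analytes <- manifest$analyte_id
  m <- length(analytes)

  # per-analyte base log-intensities; glycans at a site share the site total
  base <- numeric(m)
  names(base) <- analytes
  is_pep <- manifest$kind == "peptide"
  is_hs <- manifest$kind == "heavy_standard"
  base[is_pep] <- log(1e6) + rnorm(sum(is_pep), 0, 0.7)
  base[is_hs] <- log(3e5) + rnorm(sum(is_hs), 0, 0.4)
  gsites <- unique(manifest$site_key[manifest$kind == "glycopeptide"])
  for (sk in gsites) {
    idx <- which(manifest$site_key == sk & manifest$kind == "glycopeptide")
    tot <- log(5e5) + rnorm(1L, 0, 0.7)
    w <- stats::rgamma(length(idx), shape = 1.5)
    base[idx] <- tot + log(w / sum(w))
  }

  # injection layout: randomized patient order, QC pools interspersed
  ord_pat <- sample.int(n)
  k <- max(1L, config$qc_interval)
  seq_ids <- character(0L)
  qc_count <- 0L
  push_qc <- function(ids) {
    qc_count <<- qc_count + 1L
    c(ids, sprintf("QC%03d", qc_count))
  }
  seq_ids <- push_qc(seq_ids)
  for (i in seq_len(n)) {
    seq_ids <- c(seq_ids, clinical$patient_id[ord_pat[i]])
    if (i %% k == 0L && i < n) seq_ids <- push_qc(seq_ids)
  }
  seq_ids <- push_qc(seq_ids)
  n_inj <- length(seq_ids)
  is_qc <- grepl("^QC", seq_ids)

  # smooth shared drift multiplier over injection order
  if (config$drift_amplitude > 0 && config$drift_knots >= 2L) {
    kx <- seq(1L, n_inj, length.out = config$drift_knots)
    ky <- rnorm(config$drift_knots)
    ky <- ky - mean(ky)
    sp <- stats::spline(kx, ky, xout = seq_len(n_inj))$y
    drift <- exp(config$drift_amplitude * sp)
  } else {
    drift <- rep(1, n_inj)
  }

  sigma_bio <- sqrt(log(1 + config$bio_cv^2))
  sigma_meas <- sqrt(log(1 + config$noise_cv^2))

  log_bio <- matrix(0, nrow = n, ncol = m, dimnames = list(clinical$patient_id,
                                                           analytes))
  if (sigma_bio > 0) {
    bio_cols <- !(is_hs)  # heavy standards are spiked, not biological
    log_bio[, bio_cols] <- rnorm(n * sum(bio_cols), 0, sigma_bio)
  }

  # planted shifts tied to latent traits
  if (!is.null(latent) && length(latent$plan)) {
    for (j in seq_along(latent$plan)) {
      pl <- latent$plan[[j]]
      uj <- latent$u[, pl$trait]
      for (a in seq_along(pl$analytes)) {
        log_bio[, pl$analytes[a]] <- log_bio[, pl$analytes[a]] +
          pl$sigma * pl$direction[a] * uj
      }
    }
  }

  logint <- matrix(rep(base, each = n_inj), nrow = n_inj, ncol = m,
                   dimnames = list(seq_ids, analytes))
  logint[!is_qc, ] <- logint[!is_qc, ] + log_bio[seq_ids[!is_qc], ]
  if (sigma_meas > 0) logint <- logint + rnorm(n_inj * m, 0, sigma_meas)
  logint <- logint + log(drift)

  samples <- data.frame(sample_id = seq_ids,
                        injection_order = seq_len(n_inj),
                        is_qc_pool = is_qc, stringsAsFactors = FALSE)
  new_glyco_raw(exp(logint), samples)
}

# Resolve abstract planted-feature selectors against a concrete manifest.
# Returns a list of plans: affected analyte ids, per-analyte shift
# direction, shift magnitude, the derived feature id carrying the effect,
# the planted log hazard ratio, and the latent trait the feature follows.
# Plans with distinct traits get independent latent drivers; plans sharing
# a trait (a `trait` column in `planted`) are driven by one latent
# variable, emulating co-varying prognostic features without inflating the
# total risk heterogeneity.
resolve_planted <- function(manifest, planted, plant_sigma, seed) {
  if (is.null(planted) || nrow(planted) == 0L) return(list())
  set.seed(stage_seed(seed, "plant"))
  plans <- list()
  glyco <- manifest[manifest$kind == "glycopeptide", , drop = FALSE]
  for (r in seq_len(nrow(planted))) {
    sel <- planted$selector[r]
    n_feat <- planted$n[r]
    beta <- planted$beta[r]
    row_trait <- if ("trait" %in% names(planted) &&
                       !is.na(planted$trait[r]))
      planted$trait[r] else NA_character_
    next_trait <- function() {
      if (is.na(row_trait)) paste0(".plan", length(plans) + 1L)
      else row_trait
    }
    if (sel == "peptide") {
      pool <- manifest[manifest$kind == "peptide", , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), n_feat), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        plans[[length(plans) + 1L]] <- list(
          analytes = pick$analyte_id[i], direction = 1,
          sigma = plant_sigma, beta = beta, trait = next_trait(),
          feature_id = paste0(pick$analyte_id[i], "|pepconc"))
      }
    } else if (sel %in% c("ra_glycopeptide", "occ_glycopeptide")) {
      norm <- if (sel == "ra_glycopeptide") "relative_abundance" else
        "site_occupancy"
      pool <- glyco[glyco$site_normalization == norm, , drop = FALSE]
      # at most one planted glycan per site, so effects do not collide in
      # the occupancy denominator
      pool <- pool[!duplicated(pool$site_key), , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), n_feat), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        plans[[length(plans) + 1L]] <- list(
          analytes = pick$analyte_id[i], direction = 1,
          sigma = plant_sigma, beta = beta, trait = next_trait(),
          feature_id = paste0(pick$analyte_id[i], "|conc"))
      }
    } else if (sel == "fucose_site") {
      occ <- glyco[glyco$site_normalization == "site_occupancy" &
                     glyco$linkage == "N", , drop = FALSE]
      comp <- parse_composition(occ$glycan)
      occ$fuc <- comp$fucose > 0L
      eligible <- vapply(split(occ$fuc, occ$site_key),
                         function(f) any(f) && any(!f), logical(1L))
      sites <- names(eligible)[eligible]
      if (length(sites) < n_feat) {
        stop("not enough N-linked occupancy sites with mixed fucosylation ",
             "to plant ", n_feat, " fucose-site effects")
      }
      pick <- sample(sites, n_feat)
      for (sk in pick) {
        rows <- occ[occ$site_key == sk, , drop = FALSE]
        plans[[length(plans) + 1L]] <- list(
          analytes = rows$analyte_id,
          direction = ifelse(rows$fuc, 1, -1),
          sigma = plant_sigma, beta = beta, trait = next_trait(),
          feature_id = paste0("fucose_weight|", sk))
      }
    } else {
      stop("unknown planted-feature selector: ", sel)
    }
  }
  plans
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates panel, abundance and clinical generation. Latent standard
#' normal traits drive the planted analyte shifts; the linear predictor that
#' generates event times is the sum of planted log hazard ratios times the
#' *realized* standardized log2 feature values, so a planted `beta` is, by
#' construction, the log hazard ratio per standard deviation of the derived
#' feature a downstream Cox fit sees.
#'
#' @param config a `sim_config` object.
#' @return an object of class `glyco_cohort`: list with `manifest`, `raw`
#'   (drifted, uncorrected), `clinical`, `features` (drift-corrected
#'   feature matrix), `monomer` (fucose monomer-weight panel, when
#'   occupancy N-sites exist), `truth` (planted feature ids and log-HRs,
#'   plus true event times), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  manifest <- generate_panel(config)
  plans <- resolve_planted(manifest, config$planted, config$plant_sigma,
                           config$seed)

  traits <- unique(vapply(plans, `[[`, character(1L), "trait"))
  set.seed(stage_seed(config$seed, "latent"))
  u <- matrix(rnorm(config$n_patients * max(1L, length(traits))),
              nrow = config$n_patients)
  colnames(u) <- if (length(traits)) traits else ".none"

  # covariate/sample scaffolding for abundance generation (survival columns
  # are filled after the realized linear predictor is known)
  proto <- data.frame(patient_id = sprintf("PT%04d",
                                           seq_len(config$n_patients)),
                      stringsAsFactors = FALSE)
  latent <- if (length(plans)) list(u = u, plan = plans) else NULL
  raw <- generate_abundances(manifest, proto, config, latent)

  features <- build_feature_matrix(manifest, drift_correct(raw))
  monomer <- NULL
  has_occ_n <- any(features$features$normalization == "site_occupancy" &
                     features$features$linkage == "N")
  if (has_occ_n) monomer <- fucose_feature_panel(features, manifest)

  lp <- rep(0, config$n_patients)
  truth <- data.frame(feature_id = character(), beta = numeric(),
                      trait = character(), stringsAsFactors = FALSE)
  if (length(plans)) {
    plan_traits <- vapply(plans, `[[`, character(1L), "trait")
    for (j in seq_along(plans)) {
      fid <- plans[[j]]$feature_id
      shared <- sum(plan_traits == plans[[j]]$trait) > 1L
      if (shared) {
        # co-varying features share one latent driver; it enters the
        # hazard once (per-feature marginal effects are then beta times
        # the feature/trait correlation, slightly below beta)
        if (j == match(plans[[j]]$trait, plan_traits)) {
          lp <- lp + plans[[j]]$beta * u[, plans[[j]]$trait]
        }
      } else {
        x <- if (startsWith(fid, "fucose_weight|")) {
          monomer$values[proto$patient_id, fid]
        } else {
          features$values[proto$patient_id, fid]
        }
        z <- standardize_log_feature(x)
        lp <- lp + plans[[j]]$beta * z
      }
      truth <- rbind(truth, data.frame(feature_id = fid,
                                       beta = plans[[j]]$beta,
                                       trait = plans[[j]]$trait,
                                       stringsAsFactors = FALSE))
    }
  }

  clinical <- generate_clinical(config, lp)
  truth_obj <- list(planted = truth,
                    event_time = attr(clinical, "true_event_time"),
                    linear_predictor = lp)
  structure(list(manifest = manifest, raw = raw, clinical = clinical,
                 features = features, monomer = monomer, truth = truth_obj,
                 config = config),
            class = "glyco_cohort")
}

#' @export
print.glyco_cohort <- function(x, ...) {
  cat("Synthetic glycoproteomics cohort:", nrow(x$clinical), "patients,",
      nrow(x$manifest), "analytes,",
      sum(x$features$features$normalization %in%
            c("concentration", "peptide_concentration")),
      "concentration-normalized features\n")
  cat("Events:", sum(x$clinical$os_event), "/", nrow(x$clinical), "\n")
  if (nrow(x$truth$planted)) {
    cat("Planted effects:", nrow(x$truth$planted), "\n")
  }
  invisible(x)
}
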