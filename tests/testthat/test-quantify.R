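# Drift correction and the three normalization families.

test_that("constant QC intensities make correction a flat rescaling", {
  fix <- make_mini_fixture()
  corrected <- drift_correct(fix$raw)
  # QC intensities are constant per analyte, so every sample is divided by
  # that constant
  for (j in seq_len(ncol(fix$raw$values))) {
    expect_equal(corrected$values[, j],
                 fix$raw$values[, j] / fix$raw$values[1, j])
  }
  qc <- corrected$values[corrected$samples$is_qc_pool, ]
  expect_equal(unname(apply(qc, 2, median)), rep(1, ncol(qc)))
})

test_that("linear QC drift is inverted exactly by interpolation", {
  n <- 9
  drift <- seq(1, 2, length.out = n)  # x2 across the run
  vals <- cbind(a = 100 * drift, b = 7 * drift)
  samples <- data.frame(sample_id = sprintf("I%02d", 1:n),
                        injection_order = 1:n,
                        is_qc_pool = c(TRUE, FALSE, FALSE, FALSE, TRUE,
                                       FALSE, FALSE, FALSE, TRUE))
  raw <- glycosurv:::new_glyco_raw(vals, samples)
  corrected <- drift_correct(raw)
  # corrected QC values all equal (to 1); test samples back on flat scale
  expect_equal(unname(corrected$values[samples$is_qc_pool, "a"]),
               rep(1, 3))
  expect_equal(unname(corrected$values[, "a"]), rep(1, n) * 100 / 100,
               tolerance = 1e-12)
  expect_equal(unname(corrected$values[, "b"]), rep(1, n), tolerance = 1e-12)
})

test_that("drift correction is idempotent and refuses <2 QC injections", {
  cfg <- simulation_config(n_patients = 15, n_proteins = 3,
                           n_occ_glycopeptides = 6, n_ra_glycopeptides = 2,
                           n_nlinked_occ_sites = 2, seed = 3)
  coh <- simulate_cohort(cfg)
  once <- drift_correct(coh$raw)
  twice <- drift_correct(once)
  expect_equal(twice$values, once$values, tolerance = 1e-9)

  one_qc <- coh$raw
  keep <- !one_qc$samples$is_qc_pool
  keep[which(one_qc$samples$is_qc_pool)[1]] <- TRUE
  raw1 <- glycosurv:::new_glyco_raw(one_qc$values[keep, ],
                                    one_qc$samples[keep, ])
  expect_error(drift_correct(raw1), "at least 2 QC")
})

test_that("simulated drift inflates QC variation and correction removes
           at least half of it", {
  cfg <- simulation_config(n_patients = 60, n_proteins = 4,
                           n_occ_glycopeptides = 12, n_ra_glycopeptides = 2,
                           n_nlinked_occ_sites = 2, drift_amplitude = 0.2,
                           noise_cv = 0.02, seed = 11)
  coh <- simulate_cohort(cfg)
  qc <- coh$raw$samples$is_qc_pool
  cv <- function(x) sd(x) / mean(x)
  pre <- apply(coh$raw$values[qc, ], 2, cv)
  post <- apply(drift_correct(coh$raw)$values[qc, ], 2, cv)
  expect_true(all(pre > 0))
  expect_true(mean(post) < 0.5 * mean(pre))
})

test_that("peptide concentration is (light/heavy) x spike with missing
           propagation", {
  expect_equal(peptide_concentration(5, 5, 10), 10)
  expect_equal(peptide_concentration(10, 5, 5), 10)
  expect_warning(out <- peptide_concentration(10, 0, 5), "missing")
  expect_true(is.na(out))
  expect_error(peptide_concentration(1, 1, 0), "spike")
})

test_that("relative abundance and site occupancy follow their definitions", {
  expect_equal(relative_abundance(4, 2), 2)
  expect_equal(relative_abundance(0, 2), 0)
  expect_true(is.na(relative_abundance(3, 0)))

  expect_equal(site_occupancy(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(site_occupancy(c(0, 1, 1)), c(0, 0.5, 0.5))
  expect_true(all(is.na(site_occupancy(c(0, 0, 0)))))
})

test_that("occupancies sum to 1 on random positive intensity vectors", {
  set.seed(1)
  for (i in 1:1000) {
    x <- rexp(sample(3:9, 1)) * 10^runif(1, 0, 4)
    occ <- site_occupancy(x)
    expect_equal(sum(occ), 1, tolerance = 1e-12)
  }
})

test_that("full quantification chain matches hand computation on the
           single-protein fixture", {
  fix <- make_mini_fixture()
  feats <- build_feature_matrix(fix$manifest, drift_correct(fix$raw))
  # QC rows excluded
  expect_equal(feats$samples, c("S1", "S2"))
  # drift flat: S1 light=200/100=2, heavy=50/50=1 -> conc = 2*10 = 20
  expect_equal(unname(feats$values["S1", "P1|REFPEPK|pepconc"]), 20)
  # S2: light=1, heavy=0.5 -> 2*10 = 20
  expect_equal(unname(feats$values["S2", "P1|REFPEPK|pepconc"]), 20)
  # occupancies: S1 glycans (20,30,50)/(10,20,30) QC -> (2,1.5,5/3);
  # total = 31/6 -> occ = (12/31, 9/31, 10/31)
  expect_equal(unname(feats$values["S1", "P1|GLYPEPK@N5|5401|occ"]), 12 / 31)
  expect_equal(unname(feats$values["S1", "P1|GLYPEPK@N5|5402|occ"]), 9 / 31)
  expect_equal(unname(feats$values["S1", "P1|GLYPEPK@N5|5510|occ"]), 10 / 31)
  expect_equal(sum(feats$values["S1", feats$features$normalization ==
                                  "site_occupancy"]), 1, tolerance = 1e-12)
  # concentration = occupancy x peptide concentration
  expect_equal(unname(feats$values["S1", "P1|GLYPEPK@N5|5401|conc"]),
               12 / 31 * 20)
})

test_that("feature counts follow the manifest structure", {
  # default assay structure: 443 occupancy + 78 RA + 75 peptide = 596
  cfg <- simulation_config(seed = 2)
  man <- generate_panel(cfg)
  expect_equal(sum(man$kind == "glycopeptide" &
                     man$site_normalization == "site_occupancy"), 443L)
  expect_equal(sum(man$kind == "glycopeptide" &
                     man$site_normalization == "relative_abundance"), 78L)
  expect_equal(sum(man$kind == "peptide"), 75L)

  coh <- simulate_cohort(cfg)
  meta <- coh$features$features
  expect_equal(sum(meta$normalization %in%
                     c("concentration", "peptide_concentration")), 596L)

  # minimal 1-protein, 1-site, 1-glycan panel: RA + conc + pepconc
  mini <- simulation_config(n_patients = 10, n_proteins = 1,
                            n_occ_glycopeptides = 0, n_ra_glycopeptides = 1,
                            n_nlinked_occ_sites = 0, seed = 1)
  man2 <- generate_panel(mini)
  expect_equal(nrow(man2), 3L)  # peptide + heavy standard + glycopeptide
  expect_equal(man2$site_normalization[man2$kind == "glycopeptide"],
               "relative_abundance")
  coh2 <- simulate_cohort(mini)
  expect_equal(ncol(coh2$features$values), 3L)
})

test_that("sites with more than two glycans are occupancy-normalized", {
  cfg <- simulation_config(n_patients = 10, n_proteins = 1,
                           n_occ_glycopeptides = 4, n_ra_glycopeptides = 0,
                           occ_glycans_range = c(4L, 4L),
                           n_nlinked_occ_sites = 1, seed = 1)
  man <- generate_panel(cfg)
  expect_true(all(man$site_normalization[man$kind == "glycopeptide"] ==
                    "site_occupancy"))
})

test_that("unknown analytes in the raw matrix are an error, and an empty
           sample set keeps the schema", {
  fix <- make_mini_fixture()
  bad <- fix$raw
  colnames(bad$values)[3] <- "NOT|IN|MANIFEST"
  expect_error(build_feature_matrix(fix$manifest, bad), "NOT\\|IN\\|MANIFEST")

  qc_only <- glycosurv:::new_glyco_raw(
    fix$raw$values[c(1, 4), ], fix$raw$samples[c(1, 4), ])
  feats <- build_feature_matrix(fix$manifest, qc_only)
  expect_equal(length(feats$samples), 0L)
  expect_equal(nrow(feats$features), 7L)  # 3 occ + 3 conc + 1 pepconc
})

test_that("relative abundance and occupancy are invariant to a global
           per-sample intensity rescaling", {
  fix <- make_mini_fixture()
  feats1 <- build_feature_matrix(fix$manifest, fix$raw)
  scaled <- fix$raw
  scaled$values["S1", ] <- scaled$values["S1", ] * 7.3
  feats2 <- build_feature_matrix(fix$manifest, scaled)
  keep <- feats1$features$normalization %in% c("relative_abundance",
                                               "site_occupancy")
  expect_equal(feats2$values["S1", keep], feats1$values["S1", keep],
               tolerance = 1e-12)
})

test_that("missing heavy standard gives missing concentrations, never zero", {
  fix <- make_mini_fixture()
  raw <- fix$raw
  raw$values["S1", "P1|REFPEPK*"] <- NA
  feats <- suppressWarnings(build_feature_matrix(fix$manifest, raw))
  expect_true(is.na(feats$values["S1", "P1|REFPEPK|pepconc"]))
  expect_true(is.na(feats$values["S1", "P1|GLYPEPK@N5|5401|conc"]))
  # occupancy does not depend on the reference peptide
  expect_false(is.na(feats$values["S1", "P1|GLYPEPK@N5|5401|occ"]))
})
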