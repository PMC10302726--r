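#' @importFrom stats approx median rnorm runif rexp rbinom rbeta quantile
#'   setNames complete.cases
NULL

# Internal constructors for the two data containers shared across the
# pipeline. Both are plain lists with a class attribute; the matrix layout
# (samples in rows, analytes/features in columns) is the one modelling code
# expects.

new_glyco_raw <- function(values, samples) {
  stopifnot(is.matrix(values), nrow(values) == nrow(samples))
  stopifnot(all(c("sample_id", "injection_order", "is_qc_pool") %in%
                  names(samples)))
  if (anyDuplicated(samples$injection_order)) {
    stop("injection_order must be unique within a run")
  }
  rownames(values) <- samples$sample_id
  structure(list(values = values, samples = samples), class = "glyco_raw")
}

new_glyco_features <- function(values, features, samples) {
  stopifnot(is.matrix(values), ncol(values) == nrow(features))
  structure(list(values = values, features = features,
                 samples = samples),
            class = "glyco_features")
}

#' @export
print.glyco_raw <- function(x, ...) {
  cat("Raw abundance matrix:", nrow(x$values), "injections x",
      ncol(x$values), "analytes (", sum(x$samples$is_qc_pool),
      "QC-pool )\n")
  invisible(x)
}

#' @export
print.glyco_features <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features\n")
  print(table(x$features$normalization))
  invisible(x)
}

#' Correct within-run signal drift using pooled-QC injections
#'
#' Long LC-MS runs drift in baseline signal over injection order. Reference
#' pooled plasma injections interspersed with the test samples carry no
#' biological variance, so per analyte their intensity trace over injection
#' order estimates the drift. The correction curve is a piecewise-linear
#' interpolation through the QC-pool intensities (flat extrapolation beyond
#' the first/last QC injection); every intensity is divided by it, which
#' leaves QC-pool intensities at 1 (median 1 per analyte) and test samples
#' expressed as fold-of-QC-pool.
#'
#' Dividing by a per-analyte curve that depends only on injection order
#' preserves the across-sample rank order of any analyte at a fixed
#' injection position and is idempotent: a second pass fits a flat curve.
#'
#' @param raw a `glyco_raw` object containing at least two QC-pool
#'   injections.
#' @return a `glyco_raw` object with corrected intensities.
#' @export
drift_correct <- function(raw) {
  qc <- raw$samples$is_qc_pool
  if (sum(qc) < 2L) {
    stop("drift correction requires at least 2 QC-pool injections")
  }
  ord <- raw$samples$injection_order
  qc_ord <- ord[qc]
  vals <- raw$values
  corrected <- vals
  for (j in seq_len(ncol(vals))) {
    qc_y <- vals[qc, j]
    keep <- !is.na(qc_y) & qc_y > 0
    if (sum(keep) < 2L) next
    curve <- approx(qc_ord[keep], qc_y[keep], xout = ord, rule = 2L)$y
    corrected[, j] <- vals[, j] / curve
  }
  new_glyco_raw(corrected, raw$samples)
}

#' Peptide concentration from a spiked heavy-isotope internal standard
#'
#' Single-point calibration against a stable isotope-labelled internal
#' standard: `concentration = (light / heavy) * spike`, where `spike` is the
#' known spiked-in amount of the heavy standard. A missing or non-positive
#' heavy-standard signal yields a missing concentration (with a warning),
#' never zero.
#'
#' @param raw_light,raw_heavy numeric vectors of light- and heavy-channel
#'   intensities.
#' @param spike spiked-in heavy standard amount(s), strictly positive.
#' @return numeric vector of concentrations in the units of `spike`.
#' @export
peptide_concentration <- function(raw_light, raw_heavy, spike) {
  if (any(spike <= 0, na.rm = TRUE)) stop("spike concentration must be > 0")
  bad <- is.na(raw_heavy) | raw_heavy <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with missing/non-positive heavy-standard ",
            "signal; concentration set to missing")
  }
  out <- (raw_light / raw_heavy) * spike
  out[bad] <- NA_real_
  out
}

#' Relative abundance of a glycopeptide
#'
#' The quotient of the glycopeptide's raw abundance and the raw abundance of
#' the protein's designated non-glycosylated reference peptide. Used for
#' glycopeptides at sites with at most two glycan species, where site
#' occupancy is not computed.
#'
#' @param glyco_raw,reference_raw numeric vectors of raw intensities.
#' @return numeric vector of ratios; missing where the reference is missing
#'   or non-positive.
#' @export
relative_abundance <- function(glyco_raw, reference_raw) {
  bad <- is.na(reference_raw) | reference_raw <= 0
  out <- glyco_raw / reference_raw
  out[bad] <- NA_real_
  out
}

#' Site occupancy of glycan species at a glycosylation site
#'
#' For a site quantified with more than two glycan species, the occupancy of
#' each species is its fractional abundance: intensity divided by the
#' aggregate intensity of all species observed at the site. Occupancies at a
#' site sum to 1 by construction; a zero (or missing) aggregate makes every
#' occupancy at that site missing for that sample.
#'
#' @param site_raw numeric vector (one sample) or matrix (samples in rows)
#'   of raw intensities, one column per glycan species at the site.
#' @return object of the same shape with occupancies.
#' @export
site_occupancy <- function(site_raw) {
  vec <- is.null(dim(site_raw))
  if (vec) site_raw <- matrix(site_raw, nrow = 1L)
  total <- rowSums(site_raw)
  bad <- is.na(total) | total <= 0
  occ <- sweep(site_raw, 1L, total, "/")
  occ[bad, ] <- NA_real_
  if (vec) occ <- drop(occ)
  occ
}

#' Concentration-normalize a glycopeptide feature
#'
#' The approximate glycopeptide concentration ("normalized abundance") is
#' the product of a glycopeptide's site occupancy or relative abundance and
#' the concentration of the protein's reference peptide. Missing inputs
#' propagate to a missing output.
#'
#' @param feature_value site occupancy (proportion) or relative abundance
#'   (ratio).
#' @param pep_conc reference peptide concentration.
#' @return numeric vector of approximate glycopeptide concentrations.
#' @export
concentration_normalize <- function(feature_value, pep_conc) {
  feature_value * pep_conc
}

#' Build the normalized feature matrix from a panel manifest and raw data
#'
#' Turns drift-corrected raw analyte intensities into the two normalized
#' feature families used downstream:
#'
#' * the concentration-normalized family: per-glycopeptide approximate
#'   concentrations (site occupancy or relative abundance times the
#'   reference peptide concentration, tagged `"concentration"`) plus the
#'   reference peptide concentrations themselves
#'   (tagged `"peptide_concentration"`);
#' * the relative-abundance family: glycopeptide/reference-peptide ratios at
#'   sites with at most two glycan species (tagged `"relative_abundance"`)
#'   and site occupancies at sites with more than two species (tagged
#'   `"site_occupancy"`), which double as that family's representation for
#'   occupancy sites.
#'
#' QC-pool injections are dropped from the output. No value is fabricated:
#' wherever a required input is missing the derived feature is missing.
#'
#' @param manifest panel manifest data.frame (see [generate_panel()] for the
#'   column schema).
#' @param raw a `glyco_raw` object, normally already passed through
#'   [drift_correct()].
#' @return a `glyco_features` object; `$features` carries the feature
#'   metadata (normalization provenance, protein, peptide, site, glycan
#'   code, linkage, site key).
#' @export
build_feature_matrix <- function(manifest, raw) {
  unknown <- setdiff(colnames(raw$values), manifest$analyte_id)
  if (length(unknown)) {
    stop("analytes present in raw matrix but absent from manifest: ",
         paste(unknown, collapse = ", "))
  }
  keep <- !raw$samples$is_qc_pool
  vals <- raw$values[keep, , drop = FALSE]
  samples <- raw$samples$sample_id[keep]

  col <- function(id) {
    if (length(id) == 1L && id %in% colnames(vals)) vals[, id]
    else rep(NA_real_, length(samples))
  }

  peptides <- manifest[manifest$kind == "peptide", , drop = FALSE]
  glycos <- manifest[manifest$kind == "glycopeptide", , drop = FALSE]

  # reference peptide concentrations (heavy-standard calibrated)
  pep_conc <- matrix(NA_real_, nrow = length(samples), ncol = nrow(peptides),
                     dimnames = list(samples, peptides$analyte_id))
  for (i in seq_len(nrow(peptides))) {
    hs <- manifest[manifest$analyte_id == peptides$heavy_standard_id[i], ,
                   drop = FALSE]
    if (nrow(hs) != 1L) {
      stop("peptide ", peptides$analyte_id[i],
           " lacks a resolvable heavy standard")
    }
    suppressWarnings(
      pep_conc[, i] <- peptide_concentration(col(peptides$analyte_id[i]),
                                             col(hs$analyte_id),
                                             hs$spike_concentration)
    )
  }

  feat_vals <- list()
  feat_meta <- list()
  add <- function(id, x, normalization, protein, peptide, site, glycan,
                  linkage, site_key) {
    feat_vals[[id]] <<- x
    feat_meta[[id]] <<- data.frame(
      feature_id = id, normalization = normalization, protein = protein,
      peptide = peptide, site = site, glycan = glycan, linkage = linkage,
      site_key = site_key, stringsAsFactors = FALSE)
  }

  # glycopeptide features, site by site
  site_keys <- unique(glycos$site_key)
  for (sk in site_keys) {
    rows <- glycos[glycos$site_key == sk, , drop = FALSE]
    ref_id <- rows$reference_peptide_id[1L]
    ref_conc <- pep_conc[, ref_id]
    if (rows$site_normalization[1L] == "site_occupancy") {
      occ <- site_occupancy(vals[, rows$analyte_id, drop = FALSE])
      for (i in seq_len(nrow(rows))) {
        base <- paste0(rows$analyte_id[i], "|")
        add(paste0(base, "occ"), occ[, i], "site_occupancy",
            rows$protein[i], rows$peptide[i], rows$site[i], rows$glycan[i],
            rows$linkage[i], sk)
        add(paste0(base, "conc"), concentration_normalize(occ[, i], ref_conc),
            "concentration", rows$protein[i], rows$peptide[i], rows$site[i],
            rows$glycan[i], rows$linkage[i], sk)
      }
    } else {
      ref_raw <- col(ref_id)
      for (i in seq_len(nrow(rows))) {
        base <- paste0(rows$analyte_id[i], "|")
        ra <- relative_abundance(col(rows$analyte_id[i]), ref_raw)
        add(paste0(base, "ra"), ra, "relative_abundance",
            rows$protein[i], rows$peptide[i], rows$site[i], rows$glycan[i],
            rows$linkage[i], sk)
        add(paste0(base, "conc"), concentration_normalize(ra, ref_conc),
            "concentration", rows$protein[i], rows$peptide[i], rows$site[i],
            rows$glycan[i], rows$linkage[i], sk)
      }
    }
  }

  # reference peptide concentrations as features of the concentration family
  for (i in seq_len(nrow(peptides))) {
    add(paste0(peptides$analyte_id[i], "|pepconc"), pep_conc[, i],
        "peptide_concentration", peptides$protein[i], peptides$peptide[i],
        NA_integer_, NA_character_, "none",
        paste0(peptides$protein[i], "|", peptides$peptide[i]))
  }

  meta <- do.call(rbind, feat_meta)
  rownames(meta) <- NULL
  values <- do.call(cbind, feat_vals)
  if (is.null(values)) {
    values <- matrix(numeric(), nrow = length(samples), ncol = 0L)
  }
  colnames(values) <- meta$feature_id
  rownames(values) <- samples
  new_glyco_features(values, meta, samples)
}

#' Subset a feature matrix by normalization family
#'
#' @param features a `glyco_features` object.
#' @param families character vector of normalization tags to keep. The
#'   shortcut `"concentration_family"` expands to
#'   `c("concentration", "peptide_concentration")` (the
#'   concentration-normalized biomarkers) and `"ra_family"` to
#'   `c("relative_abundance", "site_occupancy")`.
#' @return a `glyco_features` object restricted to those features.
#' @export
feature_family <- function(features, families) {
  families <- unlist(lapply(families, function(f) {
    switch(f,
           concentration_family = c("concentration", "peptide_concentration"),
           ra_family = c("relative_abundance", "site_occupancy"),
           f)
  }))
  keep <- features$features$normalization %in% families
  new_glyco_features(features$values[, keep, drop = FALSE],
                     features$features[keep, , drop = FALSE],
                     features$samples)
}
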