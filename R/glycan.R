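#' Parse glycan composition codes
#'
#' Targeted glycoproteomics panels describe a glycan by four monosaccharide
#' counts: hexose (Hex), N-acetyl-hexosamine (HexNAc), fucose (Fuc) and
#' sialic acid (NeuAc). Two encodings are accepted:
#'
#' * the compact four-digit code, one digit per count in the order
#'   hexose, HexNAc, fucose, sialic acid (e.g. `"5402"`);
#' * the delimited extended code `"H<h>N<n>F<f>S<s>"` (e.g. `"H5N4F1S2"`),
#'   needed when any count exceeds 9.
#'
#' @param code character vector of composition codes.
#' @return a data.frame with integer columns `hexose`, `hexnac`, `fucose`,
#'   `sialic`, one row per code, with `code` as row-identifying column.
#' @examples
#' parse_composition("5402")
#' parse_composition("H5N4F1S2")
#' @export
parse_composition <- function(code) {
  if (length(code) == 0L) {
    return(data.frame(code = character(), hexose = integer(),
                      hexnac = integer(), fucose = integer(),
                      sialic = integer(), stringsAsFactors = FALSE))
  }
  code <- as.character(code)
  four <- grepl("^[0-9]{4}$", code)
  ext <- grepl("^H[0-9]+N[0-9]+F[0-9]+S[0-9]+$", code)
  bad <- !(four | ext)
  if (any(bad)) {
    stop("invalid glycan composition code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  }
  out <- matrix(0L, nrow = length(code), ncol = 4L)
  if (any(four)) {
    digs <- do.call(rbind, strsplit(code[four], "", fixed = TRUE))
    out[four, ] <- matrix(as.integer(digs), ncol = 4L)
  }
  if (any(ext)) {
    m <- regmatches(code[ext],
                    regexec("^H([0-9]+)N([0-9]+)F([0-9]+)S([0-9]+)$", code[ext]))
    out[ext, ] <- t(vapply(m, function(x) as.integer(x[-1]), integer(4L)))
  }
  empty <- rowSums(out) == 0L
  if (any(empty)) {
    stop("empty glycan composition (all counts zero): ",
         paste(unique(code[empty]), collapse = ", "))
  }
  data.frame(code = code, hexose = out[, 1L], hexnac = out[, 2L],
             fucose = out[, 3L], sialic = out[, 4L],
             stringsAsFactors = FALSE)
}

#' Format a glycan composition back into its code
#'
#' The inverse of [parse_composition()]. Compositions whose counts are all
#' single digits use the compact four-digit code; otherwise the extended
#' `"HxNxFxSx"` form is produced.
#'
#' @param comp data.frame with columns `hexose`, `hexnac`, `fucose`, `sialic`.
#' @return character vector of codes.
#' @export
format_composition <- function(comp) {
  counts <- as.matrix(comp[, c("hexose", "hexnac", "fucose", "sialic")])
  if (any(counts < 0L)) stop("negative monosaccharide count")
  if (any(rowSums(counts) == 0L)) stop("empty glycan composition")
  compact <- apply(counts, 1L, function(x) paste0(x, collapse = ""))
  ext <- sprintf("H%dN%dF%dS%d", counts[, 1L], counts[, 2L],
                 counts[, 3L], counts[, 4L])
  ifelse(apply(counts <= 9L, 1L, all), compact, ext)
}

#' Classify glycopeptides by glycan structure
#'
#' Derives the structural labels used to stratify differentially expressed
#' glycopeptides: fucosylation status, sialic acid level, and the
#' di-sialylated O-glycopeptide flag. Classification is a pure function of
#' the composition and linkage.
#'
#' @param comp data.frame as returned by [parse_composition()] (or with the
#'   same count columns).
#' @param linkage character vector, `"N"`, `"O"` or `"none"`, recycled to
#'   the number of compositions.
#' @return a data.frame with columns `fucosylated` (logical), `sialic_count`
#'   (integer), `o_disialylated` (logical).
#' @export
classify_glycan <- function(comp, linkage = "N") {
  n <- nrow(comp)
  linkage <- rep_len(as.character(linkage), n)
  if (!all(linkage %in% c("N", "O", "none"))) {
    stop("linkage must be one of 'N', 'O', 'none'")
  }
  data.frame(
    fucosylated = comp$fucose > 0L,
    sialic_count = as.integer(comp$sialic),
    o_disialylated = linkage == "O" & comp$sialic == 2L,
    stringsAsFactors = FALSE
  )
}

#' Occupancy-weighted monomer weight of a glycosylation site
#'
#' The monomer weight of a site is the expected count of one monosaccharide
#' over the glycan species observed at that site, weighted by their site
#' occupancies: `sum_g occupancy(g) * count_monomer(g)`. Computed per sample
#' when `occupancies` is a matrix.
#'
#' @param occupancies numeric vector (one sample) or matrix (samples in
#'   rows, glycans in columns) of site occupancies; each sample's
#'   occupancies must sum to 1 within `tol`.
#' @param glycans character vector of composition codes, one per glycan
#'   (column), or a data.frame of parsed compositions.
#' @param monomer one of `"hexose"`, `"hexnac"`, `"fucose"`, `"sialic"`.
#' @param tol tolerance on the occupancy sum (default `1e-6`).
#' @return numeric vector of expected monomer counts, one per sample.
#'   Samples with any missing occupancy yield `NA`.
#' @examples
#' monomer_weight(c(0.5, 0.5), c("5400", "5410"), "fucose")
#' @export
monomer_weight <- function(occupancies, glycans, monomer = "fucose",
                           tol = 1e-6) {
  monomer <- match.arg(monomer, c("hexose", "hexnac", "fucose", "sialic"))
  if (is.data.frame(glycans)) {
    comp <- glycans
  } else {
    comp <- parse_composition(glycans)
  }
  if (is.null(dim(occupancies))) {
    occupancies <- matrix(occupancies, nrow = 1L)
  }
  if (ncol(occupancies) != nrow(comp)) {
    stop("number of occupancy columns must match number of glycans")
  }
  sums <- rowSums(occupancies)
  ok <- !is.na(sums)
  if (any(abs(sums[ok] - 1) > tol)) {
    stop("site occupancies do not sum to 1 (unnormalized input)")
  }
  out <- as.numeric(occupancies %*% comp[[monomer]])
  out[!ok] <- NA_real_
  out
}

#' Site-level monomer-weight feature panel
#'
#' Builds one monomer-weight feature per occupancy-normalized glycosylation
#' site from a feature matrix containing site-occupancy features. By default
#' only N-linked sites enter the panel and the monomer is fucose, the
#' configuration used to probe fucosylation signatures; other monomers and
#' linkages are available through the arguments.
#'
#' Monomer weights are defined only where site occupancy is defined, i.e. at
#' sites quantified with more than two glycan species; relative-abundance
#' sites are excluded.
#'
#' @param features a `glyco_features` object (see [build_feature_matrix()])
#'   containing `site_occupancy` features.
#' @param manifest a panel manifest data.frame.
#' @param monomer monosaccharide to weight (default `"fucose"`).
#' @param linkage site linkages to include (default `"N"`).
#' @return a `glyco_features` object with one `monomer_weight` feature per
#'   eligible site (empty, with full schema, when there is none).
#' @export
fucose_feature_panel <- function(features, manifest, monomer = "fucose",
                                 linkage = "N") {
  monomer <- match.arg(monomer, c("hexose", "hexnac", "fucose", "sialic"))
  meta <- features$features
  occ <- meta[meta$normalization == "site_occupancy", , drop = FALSE]
  occ <- occ[occ$linkage %in% linkage, , drop = FALSE]
  sites <- unique(occ$site_key)
  vals <- matrix(NA_real_, nrow = length(features$samples),
                 ncol = length(sites))
  meta_out <- data.frame(
    feature_id = character(length(sites)),
    normalization = rep("monomer_weight", length(sites)),
    protein = character(length(sites)), peptide = character(length(sites)),
    site = integer(length(sites)),
    glycan = rep(NA_character_, length(sites)),
    linkage = character(length(sites)), site_key = sites,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(sites)) {
    rows <- occ[occ$site_key == sites[i], , drop = FALSE]
    occ_mat <- features$values[, rows$feature_id, drop = FALSE]
    vals[, i] <- monomer_weight(occ_mat, rows$glycan, monomer)
    meta_out$feature_id[i] <- paste0(monomer, "_weight|", sites[i])
    meta_out$protein[i] <- rows$protein[1L]
    meta_out$peptide[i] <- rows$peptide[1L]
    meta_out$site[i] <- rows$site[1L]
    meta_out$linkage[i] <- rows$linkage[1L]
  }
  colnames(vals) <- meta_out$feature_id
  rownames(vals) <- features$samples
  new_glyco_features(vals, meta_out, features$samples)
}
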