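# Plain-text (TSV) readers and writers for the pipeline's tabular
# artifacts, plus small container helpers.

#' Subset a feature matrix to a set of samples
#'
#' @param features a `glyco_features` object.
#' @param ids sample ids to keep (order preserved as given).
#' @return a `glyco_features` object.
#' @export
subset_samples <- function(features, ids) {
  missing_ids <- setdiff(ids, features$samples)
  if (length(missing_ids)) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  }
  new_glyco_features(features$values[ids, , drop = FALSE],
                     features$features, ids)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write / read a panel manifest as TSV
#'
#' @param manifest manifest data.frame (see [generate_panel()]).
#' @param path file path.
#' @return the path (writer, invisibly) or the manifest (reader).
#' @export
write_manifest <- function(manifest, path) write_tsv(manifest, path)

#' @rdname write_manifest
#' @export
read_manifest <- function(path) read_tsv(path)

#' Write / read a raw abundance matrix as wide TSV
#'
#' Columns: `sample_id`, `injection_order`, `is_qc_pool`, then one column
#' per analyte.
#'
#' @param raw a `glyco_raw` object.
#' @param path file path.
#' @return the path (writer, invisibly) or a `glyco_raw` (reader).
#' @export
write_raw_matrix <- function(raw, path) {
  df <- cbind(raw$samples, as.data.frame(raw$values, check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname write_raw_matrix
#' @export
read_raw_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  meta_cols <- c("sample_id", "injection_order", "is_qc_pool")
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  new_glyco_raw(vals, df[, meta_cols])
}

#' Write / read a feature matrix as wide TSV plus feature metadata TSV
#'
#' `path` receives the samples x features value table (first column
#' `sample_id`); `meta_path` receives the feature metadata.
#'
#' @param features a `glyco_features` object.
#' @param path,meta_path file paths.
#' @return the path (writer, invisibly) or a `glyco_features` (reader).
#' @export
write_features <- function(features, path, meta_path) {
  df <- cbind(data.frame(sample_id = features$samples,
                         stringsAsFactors = FALSE),
              as.data.frame(features$values, check.names = FALSE))
  write_tsv(df, path)
  write_tsv(features$features, meta_path)
}

#' @rdname write_features
#' @export
read_features <- function(path, meta_path) {
  df <- read_tsv(path, check.names = FALSE)
  meta <- read_tsv(meta_path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$sample_id
  new_glyco_features(vals, meta, df$sample_id)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `manifest.tsv`, `raw.tsv`, `clinical.tsv` and `truth.tsv` (the
#' planted effects), plus `config.yaml` when the `yaml` package is
#' available.
#'
#' @param cohort a `glyco_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_raw_matrix(cohort$raw, file.path(dir, "raw.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(cohort$truth$planted, file.path(dir, "truth.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- cohort$config
    cfg$planted <- if (is.null(cfg$planted)) NULL else
      as.list(cfg$planted)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
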