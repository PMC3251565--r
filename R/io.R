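#' Read and write the package's tab-separated tables
#'
#' All tabular I/O is TSV with documented headers: the long decay schema
#' (residue, experiment, replicate, delay_s, height), the per-residue rate
#' table (residue, R1, R1_err, R2, R2_err, NOE, NOE_err, ...) and the
#' model-free results table (residue, model, S2, S2_err, te_ns, te_err, rex,
#' rex_err, chi2, ...).
#'
#' @param path file path.
#' @return data.frame.
#' @name table-io
NULL

#' @rdname table-io
#' @export
readDecayTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateDecayTable(df)
  df
}

.writeTsv <- function(df, path) {
  # atomic write: temp file in the target directory, then rename
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname table-io
#' @param df table to write.
#' @export
writeDecayTable <- function(df, path) {
  validateDecayTable(df)
  .writeTsv(df, path)
}

#' @rdname table-io
#' @export
readRateTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  relaxationRecords(df)
}

#' @rdname table-io
#' @export
writeRateTable <- function(df, path) .writeTsv(df, path)

#' @rdname table-io
#' @export
readModelfreeResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname table-io
#' @export
writeModelfreeResults <- function(df, path) .writeTsv(df, path)

#' Write or read a JSON run manifest
#'
#' @param manifest named list.
#' @param path file path.
#' @export
writeManifest <- function(manifest, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
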