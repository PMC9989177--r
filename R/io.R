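# Readers and writers for the plain-text interchange formats: reports and
# screens as TSV, labs/patients as CSV, counts/lengths as TSV, term and
# gene lists as one entry per line.

#' Read a spontaneous-report table
#'
#' TSV with columns report_id, case_id, version, drugs, events; drug and
#' event lists are pipe-delimited within their cells.
#'
#' @param path File path.
#' @return Report data.frame.
#' @export
read_reports <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  out$version <- as.integer(out$version)
  check_report_columns(out)
}

#' Write a spontaneous-report table
#' @param reports Report data.frame.
#' @param path File path.
#' @export
write_reports <- function(reports, path) {
  check_report_columns(reports)
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a drug-name map (TSV: raw_name, generic_name)
#' @param path File path.
#' @return Data.frame with raw_name and generic_name columns.
#' @export
read_drug_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read an event definition (one preferred term per line)
#' @param path File path.
#' @return Character vector of terms.
#' @export
read_event_terms <- function(path) {
  terms <- readLines(path, warn = FALSE)
  terms[nzchar(trimws(terms))]
}

#' Write screen results as TSV
#' @param results Signal data.frame from a screen.
#' @param path File path.
#' @export
write_screen <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read screen results written by [write_screen()]
#' @param path File path.
#' @return Signal data.frame.
#' @export
read_screen <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a long-format laboratory table (CSV: patient_id, analyte, value,
#' date)
#' @param path File path.
#' @return Lab data.frame; the date column is parsed as Date when it is
#'   ISO-8601 text, otherwise kept numeric.
#' @export
read_labs <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(out$date)) out$date <- as.Date(out$date)
  out
}

#' Write a long-format laboratory table as CSV
#' @param labs Lab data.frame.
#' @param path File path.
#' @export
write_labs <- function(labs, path) {
  utils::write.csv(labs, path, row.names = FALSE, quote = FALSE)
}

#' Read a patient table (CSV, one row per patient)
#' @param path File path.
#' @return Patient data.frame; index_date parsed as Date when ISO-8601.
#' @export
read_patients <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(out$index_date) && is.character(out$index_date)) {
    out$index_date <- as.Date(out$index_date)
  }
  out
}

#' Write a patient table as CSV
#' @param patients Patient data.frame.
#' @param path File path.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, quote = FALSE)
}

#' Read a gene set (one identifier per line)
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_set <- function(path) {
  g <- readLines(path, warn = FALSE)
  g[nzchar(trimws(g))]
}

#' Read a counts matrix (TSV, first column gene identifiers)
#' @param path File path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a counts matrix as TSV
#' @param counts Matrix with gene rownames.
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
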