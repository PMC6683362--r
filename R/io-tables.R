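#' Read a population map
#'
#' Tab-separated table with header columns `sample`, `population` and
#' optionally `taxon_hint`. The taxon hint marks parental reference panels
#' used for diagnostic-locus discovery: `LL_REF` (*P. lessonae*-type),
#' `RR_REF` (*P. ridibundus*-type) or `UNKNOWN` (the default for every sample
#' when the column is absent).
#'
#' @param path path to the TSV file (lines starting `#` are ignored).
#' @return a data.frame with columns `sample`, `population`, `taxon_hint`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  validate_population_map(df)
}

#' Validate a population map data.frame
#'
#' @param df data.frame with columns `sample`, `population` and optionally
#'   `taxon_hint`.
#' @return the validated data.frame (taxon_hint filled with `UNKNOWN` when
#'   absent).
#' @export
validate_population_map <- function(df) {
  need <- c("sample", "population")
  if (!all(need %in% names(df)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  df$sample <- as.character(df$sample)
  df$population <- as.character(df$population)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in population map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (is.null(df$taxon_hint)) {
    df$taxon_hint <- "UNKNOWN"
  } else {
    df$taxon_hint <- as.character(df$taxon_hint)
    allowed <- c("LL_REF", "RR_REF", "UNKNOWN")
    bad <- setdiff(unique(df$taxon_hint), allowed)
    if (length(bad))
      stop("unknown taxon_hint token(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "))
  }
  df[, c("sample", "population", "taxon_hint")]
}

#' Write a population map
#' @param pm data.frame as returned by [read_population_map()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(pm, path) {
  pm <- validate_population_map(pm)
  utils::write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a microsatellite peak table
#'
#' Tab-separated table with header `sample`, `locus`, `allele`, `height`
#' (a GeneMapper-style export: one row per scored peak, allele sizes in base
#' pairs, heights in arbitrary absorbance units). Absent peaks are absent
#' rows, never zero heights.
#'
#' @param path path to the TSV file.
#' @return a validated data.frame with those four columns.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  validate_peak_table(df)
}

#' Validate a peak table data.frame
#' @param df data.frame with columns `sample`, `locus`, `allele`, `height`.
#' @return the validated data.frame.
#' @export
validate_peak_table <- function(df) {
  need <- c("sample", "locus", "allele", "height")
  if (!all(need %in% names(df)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  df$sample <- as.character(df$sample)
  df$locus <- as.character(df$locus)
  df$allele <- as.integer(df$allele)
  df$height <- as.numeric(df$height)
  if (anyNA(df$allele)) stop("peak table: allele sizes must be integers")
  if (anyNA(df$height) || any(df$height <= 0))
    stop("peak table: peak heights must be positive ",
         "(absent peaks are absent records, not zeros)")
  key <- paste(df$sample, df$locus, df$allele, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (sample, locus, allele) record: ",
         d$sample, ", ", d$locus, ", ", d$allele)
  }
  df[, need]
}

#' Write a microsatellite peak table
#' @param peaks data.frame as returned by [read_peak_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- validate_peak_table(peaks)
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a diagnostic panel TSV
#'
#' Columns `locus`, `L_allele`, `R_allele`, `n_LL_called`, `n_RR_called`,
#' as produced by [find_diagnostic_loci()].
#'
#' @param path TSV path.
#' @return data.frame (for the reader); `path` invisibly (for the writer).
#' @export
read_diagnostic_panel <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus", "L_allele", "R_allele")
  if (!all(need %in% names(df)))
    stop("diagnostic panel must have columns: ", paste(need, collapse = ", "))
  df$locus <- as.character(df$locus)
  df$L_allele <- as.character(df$L_allele)
  df$R_allele <- as.character(df$R_allele)
  if (any(df$L_allele == df$R_allele))
    stop("diagnostic panel: L_allele must differ from R_allele")
  df
}

#' @rdname read_diagnostic_panel
#' @param panel data.frame as produced by [find_diagnostic_loci()].
#' @param header_lines optional character vector of comment lines (written
#'   with a leading `# `).
#' @export
write_diagnostic_panel <- function(panel, path, header_lines = character()) {
  write_report_tsv(panel, path, header_lines)
}

#' Write a report table as TSV with comment header lines
#'
#' Shared writer for the pipeline's TSV reports: optional `# `-prefixed
#' header lines (tool version, seed, configuration hash) followed by a
#' tab-separated table.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param header_lines character vector of comment lines (without the `# `).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
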