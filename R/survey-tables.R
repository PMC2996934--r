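#' Published summary counts from the eight-cat light-coverage survey
#'
#' Two small tables of printed summary numbers from the eight-cat
#' light-coverage SNP survey this package models, bundled for arithmetic
#' checks and worked examples: the per-chromosome category SNP counts with
#' non-N base tallies and printed bases-per-SNP cells
#' (`survey_chromosome_counts()`), and the per-cat read/SNP totals with
#' printed SNP rates (`survey_read_counts()`). These are inputs (printed
#' counts), not results computed by this package.
#'
#' @return A tibble.
#' @export
survey_chromosome_counts <- function() {
  readr::read_tsv(system.file("extdata", "snp_counts_by_chromosome.tsv",
                              package = "lightsnp"),
                  show_col_types = FALSE)
}

#' @rdname survey_chromosome_counts
#' @export
survey_read_counts <- function() {
  readr::read_tsv(system.file("extdata", "sequencing_summary.tsv",
                              package = "lightsnp"),
                  show_col_types = FALSE)
}
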