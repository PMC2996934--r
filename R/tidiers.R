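#' Tidy and glance methods for pipeline objects
#'
#' `tidy()` returns the object's row-per-observation table (truth variants,
#' per-read call records, selected panel sites); `glance()` returns a
#' one-row summary.
#'
#' @param x A `truth_set`, `callset`, or `panel_design`.
#' @param ... Unused.
#' @return A tibble.
#' @name lightsnp-tidiers
NULL

#' @rdname lightsnp-tidiers
#' @export
tidy.truth_set <- function(x, ...) {
  as_tibble(x$variants)
}

#' @rdname lightsnp-tidiers
#' @export
glance.truth_set <- function(x, ...) {
  tibble(n_variants = nrow(x$variants),
         n_snps = sum(x$variants$type == "SNP"),
         n_dips = sum(x$variants$type == "DIP"),
         n_individuals = nrow(x$individuals),
         genome_length = sum(x$assembly$seqinfo$length),
         non_n_bases = sum(x$assembly$seqinfo$non_n),
         hom_tract_fraction = truth_hom_fraction(x))
}

#' @rdname lightsnp-tidiers
#' @export
tidy.callset <- function(x, ...) {
  as_tibble(x$records)
}

#' @rdname lightsnp-tidiers
#' @export
glance.callset <- function(x, ...) {
  tibble(n_records = nrow(x$records),
         n_snp_records = sum(x$records$type == "SNP"),
         n_dip_records = sum(x$records$type == "DIP"),
         n_individuals = length(x$nqs_bases),
         nqs_bases = sum(x$nqs_bases))
}

#' @rdname lightsnp-tidiers
#' @export
tidy.panel_design <- function(x, ...) {
  as_tibble(x$selected)
}

#' @rdname lightsnp-tidiers
#' @export
glance.panel_design <- function(x, ...) {
  panel_summary(x)
}
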