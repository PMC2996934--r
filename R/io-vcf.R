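#' Write variant sites to VCF v4.2
#'
#' SNP records carry the site base itself; DIP (short indel) records are
#' stored internally anchored on the last matching reference base, so an
#' internal deletion of `"G"` anchored on `"A"` at 0-based position 9 is
#' emitted as `POS 10, REF AG, ALT A`. INFO carries `TYPE` (SNP/DIP) and
#' `DISC`, the comma-separated set of discovering individuals.
#'
#' @param sites Tibble with columns `chrom`, `pos` (0-based), `type`, `ref`,
#'   `alt`, and optionally `discoverers` (list of character vectors).
#' @param path Output path.
#' @param asm Optional [assembly()] for `##contig` header lines.
#' @param genotypes Optional tibble (one row per site, aligned with `sites`)
#'   of per-sample genotype strings (`"0/1"`, `"1"`, ...); its column names
#'   become the VCF sample columns.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, asm = NULL, genotypes = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=lightsnp", con)
  if (!is.null(asm)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       asm$seqinfo$chrom, asm$seqinfo$length), con)
  }
  writeLines(c(
    '##INFO=<ID=TYPE,Number=1,Type=String,Description="Variant class: SNP or DIP">',
    '##INFO=<ID=DISC,Number=.,Type=String,Description="Individuals the variant was discovered in">'
  ), con)
  samples <- character(0)
  if (!is.null(genotypes)) {
    stopifnot(nrow(genotypes) == nrow(sites))
    samples <- names(genotypes)
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     if (length(samples)) c("FORMAT", samples)), collapse = "\t"), con)
  if (nrow(sites) > 0) {
    o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
    sites <- sites[o, ]
    info <- paste0("TYPE=", sites$type)
    if ("discoverers" %in% names(sites)) {
      info <- paste0(info, ";DISC=",
                     vapply(sites$discoverers, paste, character(1), collapse = ","))
    }
    line <- paste(sites$chrom, sites$pos + 1L, ".", sites$ref, sites$alt,
                  ".", "PASS", info, sep = "\t")
    if (length(samples)) {
      gt <- genotypes[o, , drop = FALSE]
      gt_str <- do.call(paste, c(as.list(gt), sep = "\t"))
      line <- paste(line, "GT", gt_str, sep = "\t")
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a VCF into a variant-site tibble
#'
#' Uses \pkg{vcfR} for parsing; `TYPE` and `DISC` INFO fields written by
#' [write_vcf()] are decoded, and per-sample `GT` columns (if any) are
#' returned as a `genotypes` attribute tibble.
#'
#' @param path Path to an uncompressed VCF.
#' @return Tibble with `chrom`, `pos` (0-based), `type`, `ref`, `alt`,
#'   `discoverers` (list column; `character(0)` when absent).
#' @export
read_vcf <- function(path) {
  empty <- tibble(chrom = character(), pos = integer(), type = character(),
                  ref = character(), alt = character(),
                  discoverers = list())
  lines <- readLines(path)
  if (!any(!startsWith(lines, "#"))) {
    return(empty)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    out <- rep(NA_character_, nrow(fix))
    hit <- regexpr(paste0("(?:^|;)", key, "=[^;]*"), fix$INFO)
    has <- hit > 0
    out[has] <- sub(paste0("^;?", key, "="), "", regmatches(fix$INFO, hit))
    out
  }
  type <- info_get("TYPE")
  fallback <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  type[is.na(type)] <- ifelse(fallback[is.na(type)], "SNP", "DIP")
  disc <- info_get("DISC")
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    type = type,
    ref = fix$REF,
    alt = fix$ALT,
    discoverers = strsplit(ifelse(is.na(disc), "", disc), ",", fixed = TRUE)
  )
  for (cn in unique(out$chrom)) {
    p <- out$pos[out$chrom == cn]
    if (is.unsorted(p)) abort(paste0("VCF records out of order on ", cn))
  }
  if (ncol(v@gt) > 1) {
    gt <- as.data.frame(v@gt[, -1, drop = FALSE], stringsAsFactors = FALSE)
    if (nrow(gt) == nrow(out)) attr(out, "genotypes") <- as_tibble(gt)
  }
  out
}
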