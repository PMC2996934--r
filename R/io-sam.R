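#' Write aligned reads to SAM
#'
#' Reads are held internally in a tibble with 0-based `start` coordinates and
#' reference-oriented `seq`/`qual`; SAM output is 1-based with the reverse
#' strand encoded in FLAG bit 0x10 and the individual carried in the `RG` tag.
#' Only M/I/D CIGAR operations are produced or accepted.
#'
#' @param reads Tibble with columns `read_id`, `individual`, `chrom`, `start`
#'   (0-based), `strand` (`"+"`/`"-"`), `cigar`, `seq`, `qual`.
#' @param asm An [assembly()] supplying `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, asm, path) {
  stopifnot(inherits(asm, "assembly"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", asm$seqinfo$chrom, asm$seqinfo$length), con)
  for (ind in unique(reads$individual)) {
    writeLines(sprintf("@RG\tID:%s\tSM:%s", ind, ind), con)
  }
  if (nrow(reads) > 0) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    writeLines(paste(reads$read_id, flag, reads$chrom, reads$start + 1L, 60L,
                     reads$cigar, "*", 0L, 0L, reads$seq, reads$qual,
                     paste0("RG:Z:", reads$individual), sep = "\t"), con)
  }
  invisible(path)
}

#' Read aligned reads from SAM
#'
#' Strict by default: missing base qualities and CIGAR operations other than
#' M/I/D are errors. SAM 1-based POS is converted to the internal 0-based
#' convention.
#'
#' @param path Path to a plain-text SAM file.
#' @param lenient If `TRUE`, records with unsupported CIGAR operations or
#'   missing qualities are dropped with a warning instead of aborting.
#' @return A tibble of aligned reads (see [write_sam()] for columns).
#' @export
read_sam <- function(path, lenient = FALSE) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(tibble(read_id = character(), individual = character(),
                  chrom = character(), start = integer(), strand = character(),
                  cigar = character(), seq = character(), qual = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_one <- function(f) {
    if (length(f) < 11) abort("SAM record with fewer than 11 fields")
    qual <- f[11]
    cigar <- f[6]
    if (qual == "*") {
      if (lenient) return(NULL)
      abort(paste0("read ", f[1], " has no base qualities"))
    }
    ok <- tryCatch({ parse_cigar(cigar); TRUE },
                   error = function(e) if (lenient) FALSE else stop(e))
    if (!ok) return(NULL)
    rg <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
    tibble(read_id = f[1],
           individual = if (length(rg)) sub("^RG:Z:", "", rg[1]) else NA_character_,
           chrom = f[3],
           start = as.integer(f[4]) - 1L,
           strand = if (bitwAnd(as.integer(f[2]), 16L) > 0) "-" else "+",
           cigar = cigar, seq = f[10], qual = qual)
  }
  out <- bind_rows(purrr::compact(lapply(fields, parse_one)))
  dropped <- length(body) - nrow(out)
  if (dropped > 0) warn(paste0("dropped ", dropped, " SAM record(s) in lenient mode"))
  out
}

#' Write reads to FASTQ (PHRED+33)
#'
#' Reads are written in sequencing orientation: minus-strand reads are
#' reverse-complemented (and their quality strings reversed) back to the
#' order the instrument read them.
#'
#' @param reads Aligned-reads tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    minus <- reads$strand == "-"
    seqs <- reads$seq
    quals <- reads$qual
    if (any(minus)) {
      seqs[minus] <- revcomp(seqs[minus])
      quals[minus] <- vapply(quals[minus], function(q)
        intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
    }
    writeLines(paste0("@", reads$read_id, "\n", seqs, "\n+\n", quals), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Tibble with `read_id`, `seq`, `qual` (sequencing orientation).
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
}
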