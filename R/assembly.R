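#' Reference assembly container
#'
#' Holds an ordered set of consensus chromosomes/contigs over the alphabet
#' \{A, C, G, T, N\}, with an index of N-gap runs and non-N base tallies.
#' All internal coordinates are 0-based half-open; emitted standard formats
#' follow their own conventions (SAM/VCF 1-based, BED 0-based half-open).
#'
#' @param sequences Named character vector of sequences (one per chromosome).
#'   Lowercase (soft-masked) bases are uppercased; they are never treated as
#'   gaps.
#' @param strict If `TRUE` (default), characters outside A/C/G/T/N are an
#'   error; otherwise they are replaced by N with a warning.
#' @return An object of class `assembly`: a list with `sequences` (named
#'   character), `seqinfo` (tibble: `chrom`, `length`, `non_n`), and `n_runs`
#'   (tibble: `chrom`, `start`, `end`, 0-based half-open).
#' @examples
#' asm <- assembly(c(chr1 = "ACGTNNNAC"))
#' asm$seqinfo$non_n  # 6
#' asm$n_runs         # one run [4, 7)
#' @export
assembly <- function(sequences, strict = TRUE) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == "")) {
    abort("all sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    abort("duplicate sequence names in assembly")
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    if (strict) {
      abort(paste0("non-IUPAC-core characters in sequence(s): ",
                   paste(names(sequences)[bad], collapse = ", ")))
    }
    warn("replacing characters outside {A,C,G,T,N} with N")
    sequences <- gsub("[^ACGTN]", "N", sequences)
  }
  n_runs <- purrr::map2(names(sequences), sequences, function(nm, s) {
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    st <- as.integer(m) - 1L
    tibble(chrom = nm, start = st, end = st + attr(m, "match.length"))
  })
  n_runs <- bind_rows(n_runs)
  len <- nchar(sequences)
  n_per <- vapply(names(sequences), function(nm) {
    sum(n_runs$end[n_runs$chrom == nm] - n_runs$start[n_runs$chrom == nm])
  }, integer(1))
  out <- list(
    sequences = sequences,
    seqinfo = tibble(chrom = names(sequences),
                     length = as.integer(len),
                     non_n = as.integer(len) - as.integer(n_per)),
    n_runs = n_runs
  )
  class(out) <- "assembly"
  out
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly> ", nrow(x$seqinfo), " sequence(s), ",
      format(sum(x$seqinfo$length), big.mark = ","), " bp (",
      format(sum(x$seqinfo$non_n), big.mark = ","), " non-N), ",
      nrow(x$n_runs), " N-run(s)\n", sep = "")
  print(x$seqinfo, ...)
  invisible(x)
}

#' Read a reference assembly from FASTA
#'
#' @param path Path to a FASTA file.
#' @param strict Passed to [assembly()].
#' @return An [assembly()] object with uppercase-normalized sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # drop FASTA description after first whitespace, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(ss))
  assembly(seqs, strict = FALSE)
}

#' Write a reference assembly to FASTA (60-column wrapped)
#'
#' @param asm An [assembly()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(asm, path) {
  stopifnot(inherits(asm, "assembly"))
  ss <- Biostrings::DNAStringSet(asm$sequences)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Contig N50
#'
#' Largest length L such that contigs of length >= L together contain at
#' least half of the total assembled bases.
#'
#' @param lengths Positive numeric vector of contig lengths.
#' @return The N50 length.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("empty contig length list")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("contig lengths must be positive")
  }
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

# Distance (in bases) from each 0-based position to the nearest N run or
# contig terminus; positions just past the ends behave like flanking Ns.
gap_distance <- function(asm, chrom, pos) {
  stopifnot(inherits(asm, "assembly"))
  out <- rep(NA_real_, length(pos))
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    L <- asm$seqinfo$length[asm$seqinfo$chrom == cn]
    if (length(L) == 0) abort(paste0("unknown chromosome: ", cn))
    runs <- asm$n_runs[asm$n_runs$chrom == cn, ]
    # boundaries act like N at -1 and L
    starts <- c(runs$start, L)
    ends <- c(0L, runs$end)   # run end (exclusive) -> first non-N position after
    p <- pos[idx]
    # distance to next N at or after p: min over starts >= p of (start - p) + 1? see below
    d_right <- vapply(p, function(pp) {
      s <- starts[starts > pp]
      if (length(s) == 0) Inf else min(s) - pp
    }, numeric(1))
    d_left <- vapply(p, function(pp) {
      e <- ends[ends <= pp]
      if (length(e) == 0) Inf else pp - max(e) + 1
    }, numeric(1))
    out[idx] <- pmin(d_left, d_right)
  }
  out
}
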