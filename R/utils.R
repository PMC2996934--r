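#' Round half away from zero to an integer
#'
#' Average-spacing cells in SNP resource tables are reported as integers with
#' the conventional "round half up" rule, which differs from [base::round()]'s
#' round-half-even behaviour at exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, rounded.
#' @export
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Stable 31-bit string hash (polynomial, mod 2^31 - 1) so per-stage and
# per-individual child seeds do not depend on list order: adding an
# individual never perturbs another individual's stream.
str_hash31 <- function(s) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

#' Derive a child random seed from a parent seed and a label
#'
#' A single pipeline seed fans out to deterministic per-stage / per-individual
#' seeds keyed by label, so independent stages draw from independent streams.
#'
#' @param seed Parent integer seed.
#' @param label Character label (stage or individual name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + str_hash31(label)) %% m)
}

qual_string <- function(q) {
  intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L, multiple = FALSE)
}

qual_ints <- function(s) {
  utf8ToInt(s) - 33L
}

# Parse a CIGAR string restricted to M/I/D into a two-column data frame.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    abort("CIGAR string missing")
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0) {
    abort(paste0("malformed CIGAR: ", cigar))
  }
  bad <- setdiff(ops, c("M", "I", "D"))
  if (length(bad) > 0) {
    abort(paste0("unsupported CIGAR operation(s): ", paste(bad, collapse = ", ")))
  }
  list(op = ops, len = lens)
}

cigar_string <- function(op, len) {
  paste0(paste0(len, op), collapse = "")
}

cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D")])
}

cigar_read_len <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I")])
}

# Rolling window sum of x over a centred window of half-width w;
# positions without a complete window get NA.
window_sum <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2 * w + 1) return(out)
  cs <- c(0, cumsum(x))
  i <- (w + 1):(n - w)
  out[i] <- cs[i + w + 1] - cs[i - w]
  out
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
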