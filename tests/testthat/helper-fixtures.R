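# Small programmatic fixtures shared across tests.

random_assembly <- function(n_chrom = 1, len = 2000, seed = 1, n_gaps = 0,
                            gap_len = 20) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (n_gaps > 0) {
        starts <- sort(sample.int(len - gap_len, n_gaps))
        for (s in starts) chars[s:(s + gap_len - 1)] <- "N"
      }
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    assembly(seqs)
  })
}

# Build one perfectly aligned read row over asm starting at 0-based start0.
# Optional named tweaks: mismatch = c(offset = ...), qualities set via q
# (scalar or vector), cigar defaults to all-M.
make_read <- function(asm, chrom = "chr1", start0 = 0, len = 50, q = 40,
                      read_id = "r1", individual = "ind1", mismatch = integer(0),
                      cigar = NULL, seq = NULL, strand = "+") {
  refseq <- asm$sequences[[chrom]]
  if (is.null(seq)) {
    chars <- strsplit(substr(refseq, start0 + 1, start0 + len), "")[[1]]
    for (off in mismatch) {
      chars[off] <- setdiff(c("A", "C", "G", "T"), chars[off])[1]
    }
    seq <- paste(chars, collapse = "")
  }
  n <- nchar(seq)
  if (length(q) == 1) q <- rep(q, n)
  tibble::tibble(read_id = read_id, individual = individual, chrom = chrom,
                 start = as.integer(start0), strand = strand,
                 cigar = cigar %||% paste0(n, "M"),
                 seq = seq,
                 qual = intToUtf8(pmin(pmax(q, 0), 93) + 33))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small but full-featured simulated scenario reused by several suites.
small_scenario <- function(seed = 11, genome = 3e5, coverage = 2.8,
                           error_model = "phred") {
  pm <- population_model(genome_length = genome)
  truth <- simulate_population(pm, seed)
  rs <- simulate_reads(truth,
                       read_model(insert_mean = min(30000, genome / 20),
                                  total_coverage = coverage,
                                  error_model = error_model),
                       seed)
  list(model = pm, truth = truth, reads = rs)
}
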