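#' Neighborhood Quality Standard and calling parameters
#'
#' The NQS rule qualifies a base for variant evidence when the base itself is
#' high quality, its flanking neighborhood is reasonably high quality, and
#' the neighborhood aligns almost perfectly to the consensus: PHRED >= 23 at
#' the center, PHRED >= 15 at the five bases on either side, and at least
#' nine of those ten flanking bases perfect matches. Calling additionally
#' caps pileup depth (collapsed repeats masquerade as high-depth variant
#' columns under light coverage) and ignores indels longer than
#' `max_dip_length`.
#'
#' @param center_min_q Minimum PHRED at the candidate base (default 23).
#' @param flank_min_q Minimum PHRED in the flanks (default 15).
#' @param flank_width Flank half-width in bases (default 5).
#' @param min_flank_matches Minimum matching flank bases out of
#'   `2 * flank_width` (default 9).
#' @param max_depth Coverage cap: columns deeper than this emit no calls
#'   (default 8).
#' @param max_dip_length Longest insertion/deletion called as a DIP
#'   (default 10).
#' @return An object of class `nqs_params`.
#' @export
nqs_params <- function(center_min_q = 23, flank_min_q = 15, flank_width = 5,
                       min_flank_matches = 9, max_depth = 8,
                       max_dip_length = 10) {
  if (min_flank_matches > 2 * flank_width) {
    abort("min_flank_matches cannot exceed 2 * flank_width")
  }
  if (any(c(center_min_q, flank_min_q, flank_width, min_flank_matches,
            max_depth, max_dip_length) < 0)) {
    abort("all NQS thresholds must be >= 0")
  }
  structure(list(center_min_q = center_min_q, flank_min_q = flank_min_q,
                 flank_width = as.integer(flank_width),
                 min_flank_matches = as.integer(min_flank_matches),
                 max_depth = max_depth,
                 max_dip_length = as.integer(max_dip_length)),
            class = "nqs_params")
}

# Per-read alignment arrays: for each read base (M and I positions), the
# aligned reference base ("-" under insertions), 0-based reference position
# (NA under insertions), quality, and the id of the alignment operation the
# base belongs to. Ops are numbered over all CIGAR ops so that M runs on the
# two sides of any I or D gap carry different ids.
read_arrays <- function(seq, qual, cigar, start0, refseq) {
  cg <- parse_cigar(cigar)
  opid <- integer(0)
  refpos <- integer(0)
  rcur <- start0
  pieces <- character(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op == "M") {
      pieces <- c(pieces, substr(refseq, rcur + 1L, rcur + len))
      refpos <- c(refpos, rcur + 0:(len - 1L))
      opid <- c(opid, rep(k, len))
      rcur <- rcur + len
    } else if (op == "I") {
      pieces <- c(pieces, strrep("-", len))
      refpos <- c(refpos, rep(NA_integer_, len))
      opid <- c(opid, rep(k, len))
    } else {
      rcur <- rcur + len
    }
  }
  list(read = strsplit(seq, "", fixed = TRUE)[[1]],
       refaln = strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1]],
       q = qual_ints(qual),
       opid = opid,
       refpos = refpos,
       is_m = !is.na(refpos),
       ops = cg)
}

# Vectorized NQS qualification over one read's arrays.
qualify_vector <- function(ar, params) {
  n <- length(ar$q)
  w <- params$flank_width
  match <- ar$is_m & ar$read == ar$refaln & ar$refaln != "N" & ar$read != "N"
  ind_fq <- ar$q >= params$flank_min_q
  s_fq <- window_sum(ind_fq, w)
  s_mt <- window_sum(match, w)
  qualified <- rep(FALSE, n)
  if (n >= 2 * w + 1) {
    i <- (w + 1):(n - w)
    same_op <- ar$opid[i - w] == ar$opid[i + w] & ar$is_m[i]
    qualified[i] <- same_op &
      ar$q[i] >= params$center_min_q &
      (s_fq[i] - ind_fq[i]) == 2 * w &
      (s_mt[i] - match[i]) >= params$min_flank_matches
  }
  list(qualified = qualified, match = match)
}

#' Does one read base meet the Neighborhood Quality Standard?
#'
#' A base qualifies when its own quality is at least `center_min_q`, all
#' `2 * flank_width` neighborhood bases have quality at least `flank_min_q`,
#' at least `min_flank_matches` of them match the consensus, and the whole
#' neighborhood lies inside the read with no alignment gap crossing it
#' (bases near read ends or near indels never qualify).
#'
#' @param read One row of an aligned-reads tibble (or a one-row tibble).
#' @param offset 1-based position within the read.
#' @param asm The reference [assembly()].
#' @param params [nqs_params()].
#' @return Logical scalar.
#' @export
qualify_base <- function(read, offset, asm, params = nqs_params()) {
  stopifnot(inherits(asm, "assembly"))
  read <- as.list(read)
  ar <- read_arrays(read$seq, read$qual, read$cigar, read$start,
                    asm$sequences[[read$chrom]])
  if (offset < 1 || offset > length(ar$q)) {
    abort("offset outside the read")
  }
  qualify_vector(ar, params)$qualified[offset]
}

#' Build a per-position pileup of aligned read bases
#'
#' Each aligned (M) read base appears in exactly one column. Column depth —
#' the number of reads whose reference span covers the position, including
#' spans covering it via a deletion — is reported alongside, as is each
#' base's NQS qualification flag.
#'
#' @param reads Aligned-reads tibble.
#' @param asm Reference [assembly()].
#' @param params [nqs_params()].
#' @return Tibble: `chrom`, `pos` (0-based), `individual`, `read_id`, `base`,
#'   `qual`, `qualified`, `ref`, `depth`.
#' @export
build_pileup <- function(reads, asm, params = nqs_params()) {
  stopifnot(inherits(asm, "assembly"))
  unknown <- setdiff(unique(reads$chrom), asm$seqinfo$chrom)
  if (length(unknown) > 0) {
    abort(paste0("reads reference unknown chromosome(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(reads) == 0) {
    return(tibble(chrom = character(), pos = integer(), individual = character(),
                  read_id = character(), base = character(), qual = integer(),
                  qualified = logical(), ref = character(), depth = integer()))
  }
  depth <- depth_lookup(reads, asm)
  rows <- purrr::map(seq_len(nrow(reads)), function(i) {
    ar <- read_arrays(reads$seq[i], reads$qual[i], reads$cigar[i],
                      reads$start[i], asm$sequences[[reads$chrom[i]]])
    qv <- qualify_vector(ar, params)
    m <- ar$is_m
    tibble(chrom = reads$chrom[i], pos = ar$refpos[m],
           individual = reads$individual[i], read_id = reads$read_id[i],
           base = ar$read[m], qual = ar$q[m], qualified = qv$qualified[m],
           ref = ar$refaln[m])
  })
  out <- bind_rows(rows)
  out$depth <- depth(out$chrom, out$pos)
  arrange(out, match(.data$chrom, asm$seqinfo$chrom), .data$pos)
}

# Closure mapping (chrom, 0-based pos) -> read depth, built from IRanges
# coverage of reference spans.
depth_lookup <- function(reads, asm) {
  covs <- list()
  for (cn in unique(reads$chrom)) {
    idx <- reads$chrom == cn
    span <- vapply(reads$cigar[idx], cigar_ref_span, numeric(1), USE.NAMES = FALSE)
    cov <- IRanges::coverage(
      IRanges::IRanges(start = reads$start[idx] + 1L,
                       width = as.integer(span)),
      width = asm$seqinfo$length[asm$seqinfo$chrom == cn])
    covs[[cn]] <- as.integer(cov)
  }
  function(chrom, pos) {
    out <- integer(length(pos))
    for (cn in unique(chrom)) {
      ii <- chrom == cn
      out[ii] <- covs[[cn]][pos[ii] + 1L]
    }
    out
  }
}

# Positions within flank_width of an N run (or inside one) are excluded from
# calling; returns a predicate over (chrom, pos).
near_n_lookup <- function(asm, w) {
  runs <- asm$n_runs
  function(chrom, pos) {
    out <- logical(length(pos))
    for (cn in unique(chrom)) {
      ii <- which(chrom == cn)
      r <- runs[runs$chrom == cn, ]
      if (nrow(r) == 0) next
      ir <- IRanges::IRanges(start = r$start + 1L - w, end = r$end + w)
      q <- IRanges::IRanges(start = pos[ii] + 1L, width = 1L)
      out[ii] <- IRanges::overlapsAny(q, ir)
    }
    out
  }
}

#' Call SNPs and DIPs from reads against the consensus
#'
#' Scans every read once: NQS-qualified bases that differ from the consensus
#' become per-read SNP records; insertions/deletions of at most
#' `max_dip_length` bases whose two immediately flanking read bases both meet
#' the NQS rule (with the gap itself spliced out of their neighborhoods)
#' become per-read DIP records. Columns deeper than `max_depth`, reference-N
#' columns, and columns within `flank_width` of an N run emit nothing.
#'
#' @param reads Aligned-reads tibble (e.g. from [simulate_reads()] or
#'   [read_sam()]).
#' @param asm Reference [assembly()].
#' @param params [nqs_params()].
#' @return An object of class `callset`: `records` (per-read discrepancy
#'   tibble: `chrom`, `pos` 0-based, `type`, `ref`, `alt`, `individual`,
#'   `read_id`), and `nqs_bases`, the per-individual count of NQS-qualified
#'   bases (summed over reads, the SNP-rate denominator).
#' @export
call_variants <- function(reads, asm, params = nqs_params()) {
  stopifnot(inherits(asm, "assembly"))
  unknown <- setdiff(unique(reads$chrom), asm$seqinfo$chrom)
  if (length(unknown) > 0) {
    abort(paste0("reads reference unknown chromosome(s): ",
                 paste(unknown, collapse = ", ")))
  }
  empty <- tibble(chrom = character(), pos = integer(), type = character(),
                  ref = character(), alt = character(), individual = character(),
                  read_id = character())
  nqs_bases <- setNames(rep(0, length(unique(reads$individual))),
                        unique(reads$individual))
  if (nrow(reads) == 0) {
    return(structure(list(records = empty, nqs_bases = nqs_bases,
                          params = params), class = "callset"))
  }
  snp_rows <- vector("list", nrow(reads))
  dip_rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    refseq <- asm$sequences[[reads$chrom[i]]]
    ar <- read_arrays(reads$seq[i], reads$qual[i], reads$cigar[i],
                      reads$start[i], refseq)
    qv <- qualify_vector(ar, params)
    nqs_bases[reads$individual[i]] <-
      nqs_bases[reads$individual[i]] + sum(qv$qualified)
    cand <- which(qv$qualified & !qv$match & ar$refaln %in% c("A", "C", "G", "T") &
                    ar$read %in% c("A", "C", "G", "T"))
    if (length(cand) > 0) {
      snp_rows[[i]] <- tibble(chrom = reads$chrom[i], pos = ar$refpos[cand],
                              type = "SNP", ref = ar$refaln[cand],
                              alt = ar$read[cand],
                              individual = reads$individual[i],
                              read_id = reads$read_id[i])
    }
    dips <- scan_dips(ar, refseq, params)
    if (!is.null(dips)) {
      dip_rows[[i]] <- mutate(dips, chrom = reads$chrom[i],
                              individual = reads$individual[i],
                              read_id = reads$read_id[i])
    }
  }
  records <- bind_rows(c(purrr::compact(snp_rows), purrr::compact(dip_rows)))
  if (nrow(records) > 0) {
    depth <- depth_lookup(reads, asm)
    near_n <- near_n_lookup(asm, params$flank_width)
    records <- records[depth(records$chrom, records$pos) <= params$max_depth &
                         !near_n(records$chrom, records$pos), , drop = FALSE]
    records <- arrange(records, match(.data$chrom, asm$seqinfo$chrom),
                       .data$pos, .data$type, .data$alt, .data$individual)
  } else {
    records <- empty
  }
  structure(list(records = records, nqs_bases = nqs_bases, params = params),
            class = "callset")
}

# DIP detection within one read: I/D ops of length <= max_dip_length whose
# flanking M bases both qualify under the gap-excluded neighborhood rule.
scan_dips <- function(ar, refseq, params) {
  gaps <- which(ar$ops$op %in% c("I", "D"))
  gaps <- gaps[ar$ops$len[gaps] <= params$max_dip_length]
  if (length(gaps) == 0) return(NULL)
  w <- params$flank_width
  # M-only arrays (gap bases spliced out)
  m <- ar$is_m
  mq <- ar$q[m]
  mmatch <- (ar$read == ar$refaln & ar$refaln != "N" & ar$read != "N")[m]
  mop <- ar$opid[m]
  mrefpos <- ar$refpos[m]
  nm <- length(mq)
  out <- list()
  center_ok <- function(j, gap_left, gap_right) {
    # neighborhood = M positions j-w .. j+w; the DIP's own gap sits between
    # M indices gap_left and gap_right; any other op boundary disqualifies
    if (j - w < 1 || j + w > nm) return(FALSE)
    if (mop[max(j - w, 1)] != mop[gap_left]) return(FALSE)
    if (mop[min(j + w, nm)] != mop[gap_right]) return(FALSE)
    win <- (j - w):(j + w)
    flank <- setdiff(win, j)
    mq[j] >= params$center_min_q &&
      all(mq[flank] >= params$flank_min_q) &&
      sum(mmatch[flank]) >= params$min_flank_matches
  }
  for (g in gaps) {
    jl <- sum(ar$opid[m] < g)          # last M index before the gap
    jr <- jl + 1L
    if (jl < 1 || jr > nm) next        # gap at a read end: no flanking pair
    # flanking M runs must be immediately adjacent to this gap (no second
    # gap hiding between the flanks)
    if (mop[jl] != g - 1L || mop[jr] != g + 1L) next
    if (ar$ops$op[g] == "I" &&
        !all(ar$read[ar$opid == g] %in% c("A", "C", "G", "T"))) next
    if (!center_ok(jl, jl, jr) || !center_ok(jr, jl, jr)) next
    anchor <- mrefpos[jl]
    if (is.na(anchor)) next
    anchor_base <- substr(refseq, anchor + 1L, anchor + 1L)
    if (anchor_base == "N") next
    if (ar$ops$op[g] == "D") {
      dlen <- ar$ops$len[g]
      ref <- substr(refseq, anchor + 1L, anchor + 1L + dlen)
      if (grepl("N", ref, fixed = TRUE)) next
      rec <- tibble(chrom = NA_character_, pos = anchor, type = "DIP",
                    ref = ref, alt = anchor_base)
    } else {
      ins <- paste(ar$read[ar$opid == g], collapse = "")
      rec <- tibble(chrom = NA_character_, pos = anchor, type = "DIP",
                    ref = anchor_base, alt = paste0(anchor_base, ins))
    }
    out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0) return(NULL)
  bind_rows(out)
}

#' @rdname call_variants
#' @return `call_snps()` and `call_dips()` return just the corresponding
#'   per-read record tibbles.
#' @export
call_snps <- function(reads, asm, params = nqs_params()) {
  cs <- call_variants(reads, asm, params)
  filter(cs$records, .data$type == "SNP")
}

#' @rdname call_variants
#' @export
call_dips <- function(reads, asm, params = nqs_params()) {
  cs <- call_variants(reads, asm, params)
  filter(cs$records, .data$type == "DIP")
}

#' @export
print.callset <- function(x, ...) {
  cat("<callset> ", format(nrow(x$records), big.mark = ","), " record(s) (",
      sum(x$records$type == "SNP"), " SNP / ", sum(x$records$type == "DIP"),
      " DIP) from ", length(x$nqs_bases), " individual(s); ",
      format(sum(x$nqs_bases), big.mark = ","), " NQS bases\n", sep = "")
  invisible(x)
}

#' Merge per-read discrepancy records into non-redundant variant sites
#'
#' One site per distinct (chromosome, position, type, alternate allele);
#' multi-allelic positions yield one site per alternate allele. Because the
#' same site can be discovered independently in several individuals, the sum
#' of per-individual record-site counts is always at least the non-redundant
#' site count.
#'
#' @param records Per-read records from [call_variants()] (or a `callset`).
#' @return Tibble of variant sites: `chrom`, `pos`, `type`, `ref`, `alt`,
#'   `discoverers` (list of individual names), `n_discoverers`, `support`
#'   (list of named per-individual read counts), `n_reads`.
#' @export
merge_sites <- function(records) {
  if (inherits(records, "callset")) records <- records$records
  if (nrow(records) == 0) {
    return(tibble(chrom = character(), pos = integer(), type = character(),
                  ref = character(), alt = character(), discoverers = list(),
                  n_discoverers = integer(), support = list(),
                  n_reads = integer()))
  }
  records |>
    group_by(.data$chrom, .data$pos, .data$type, .data$ref, .data$alt) |>
    summarise(
      discoverers = list(sort(unique(.data$individual))),
      n_discoverers = length(unique(.data$individual)),
      support = list(table_to_named(.data$individual)),
      n_reads = n(),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos, .data$alt)
}

table_to_named <- function(x) {
  tb <- table(x)
  setNames(as.integer(tb), names(tb))
}

#' Per-individual SNP rate (bases per SNP)
#'
#' The rate "one SNP per x bases" for an individual is the number of
#' NQS-qualified bases across that individual's reads (depth counted once per
#' read base) divided by the number of SNP records detected from those reads.
#'
#' @param individual Individual name.
#' @param records Per-read records (or `callset`).
#' @param reads Aligned-reads tibble.
#' @param asm Reference [assembly()].
#' @param params [nqs_params()].
#' @return One-row tibble: `individual`, `nqs_bases`, `snp_count`,
#'   `bases_per_snp` (rounded half-up). Zero SNPs is an error (the rate is
#'   undefined).
#' @export
snp_rate <- function(individual, records, reads, asm, params = nqs_params()) {
  if (inherits(records, "callset")) records <- records$records
  snps <- sum(records$type == "SNP" & records$individual == individual)
  if (snps == 0) abort(paste0("SNP rate undefined: no SNP records for ", individual))
  nq <- count_nqs_bases(reads[reads$individual == individual, , drop = FALSE],
                        asm, params)
  tibble(individual = individual, nqs_bases = nq, snp_count = snps,
         bases_per_snp = round_half_up(nq / snps))
}

#' Total NQS-qualified bases across a set of reads
#'
#' @param reads Aligned-reads tibble.
#' @param asm Reference [assembly()].
#' @param params [nqs_params()].
#' @return Numeric count (each read base counted once per read it occurs in).
#' @export
count_nqs_bases <- function(reads, asm, params = nqs_params()) {
  total <- 0
  for (i in seq_len(nrow(reads))) {
    ar <- read_arrays(reads$seq[i], reads$qual[i], reads$cigar[i],
                      reads$start[i], asm$sequences[[reads$chrom[i]]])
    total <- total + sum(qualify_vector(ar, params)$qualified)
  }
  total
}

#' Per-individual SNP rate table
#'
#' [snp_rate()] applied to every individual with at least one SNP record;
#' individuals with none are reported with `NA` rates.
#'
#' @param cs A `callset` from [call_variants()].
#' @param reads Aligned-reads tibble.
#' @param asm Reference [assembly()].
#' @return Tibble with one row per individual.
#' @export
snp_rate_table <- function(cs, reads, asm) {
  stopifnot(inherits(cs, "callset"))
  inds <- unique(reads$individual)
  bind_rows(purrr::map(inds, function(nm) {
    snps <- sum(cs$records$type == "SNP" & cs$records$individual == nm)
    nq <- cs$nqs_bases[[nm]] %||% 0
    tibble(individual = nm, nqs_bases = nq, snp_count = snps,
           bases_per_snp = if (snps > 0) round_half_up(nq / snps) else NA_real_)
  }))
}
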