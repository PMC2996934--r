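# Independent, deliberately naive re-implementations used as oracles.
# These are written directly from the rule definitions with plain loops and
# must stay independent of the package's vectorized internals.

# Exhaustive NQS evaluation at one read position (1-based offset).
# read/refaln are character vectors over read positions ("-" for insertion
# bases), q integer qualities, opid the alignment-operation id per position.
oracle_qualify <- function(read, refaln, q, opid, offset,
                           center_min_q = 23, flank_min_q = 15,
                           flank_width = 5, min_flank_matches = 9) {
  n <- length(read)
  lo <- offset - flank_width
  hi <- offset + flank_width
  if (lo < 1 || hi > n) return(FALSE)
  # no alignment gap may cross the neighborhood
  for (k in lo:hi) {
    if (opid[k] != opid[lo]) return(FALSE)
  }
  if (refaln[offset] == "-") return(FALSE)
  if (q[offset] < center_min_q) return(FALSE)
  matches <- 0
  for (k in lo:hi) {
    if (k == offset) next
    if (q[k] < flank_min_q) return(FALSE)
    if (read[k] == refaln[k] && read[k] != "N" && refaln[k] != "N") {
      matches <- matches + 1
    }
  }
  matches >= min_flank_matches
}

# Brute-force interval stabbing: how many reads' reference spans cover pos.
oracle_depth <- function(starts, spans, pos) {
  d <- 0
  for (i in seq_along(starts)) {
    if (pos >= starts[i] && pos < starts[i] + spans[i]) d <- d + 1
  }
  d
}

# Direct binning of positions into half-open windows.
oracle_bin <- function(pos, chrom_len, window) {
  n_win <- ceiling(chrom_len / window)
  counts <- integer(n_win)
  for (p in pos) {
    counts[p %/% window + 1] <- counts[p %/% window + 1] + 1
  }
  counts
}

# N50 by scanning every candidate length.
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  best <- 0
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= half && L > best) best <- L
  }
  best
}

# Hash-grouping of per-read records into non-redundant sites.
oracle_group_sites <- function(records) {
  keys <- paste(records$chrom, records$pos, records$type, records$alt, sep = "\r")
  env <- new.env()
  for (i in seq_len(nrow(records))) {
    k <- keys[i]
    cur <- if (!is.null(env[[k]])) env[[k]] else character(0)
    env[[k]] <- union(cur, records$individual[i])
  }
  ks <- ls(env)
  list(n_sites = length(ks),
       discoverer_sets = lapply(ks, function(k) sort(env[[k]])))
}

# Discoverer-category partition by literal rule application.
oracle_partition <- function(discoverer_sets, inbred, wildcat) {
  A <- B <- C <- logical(length(discoverer_sets))
  for (i in seq_along(discoverer_sets)) {
    d <- discoverer_sets[[i]]
    A[i] <- any(!(d %in% c(inbred, wildcat)))
    B[i] <- any(!(d %in% inbred))
    C[i] <- TRUE
  }
  list(A = A, B = B, C = C)
}

# Linear scan of distance to nearest N or contig end for one position.
oracle_gap_distance <- function(seq_chars, pos0) {
  L <- length(seq_chars)
  d <- Inf
  for (i in seq_len(L)) {
    if (seq_chars[i] == "N") {
      # a site immediately adjacent to an N has distance 1 on either side
      dd <- abs((i - 1) - pos0)
      d <- min(d, dd)
    }
  }
  d <- min(d, pos0 + 1, L - pos0)
  d
}
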