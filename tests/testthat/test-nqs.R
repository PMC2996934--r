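test_that("qualify_base honors the exact rule boundaries", {
  asm <- random_assembly(len = 100, seed = 2)
  # center at offset 10, mismatching the reference, neighborhood perfect
  q <- rep(40, 30)
  q[10] <- 23
  q[c(5:9, 11:15)] <- 15
  rd <- make_read(asm, start0 = 0, len = 30, q = q, mismatch = 10)
  expect_true(qualify_base(rd, 10, asm))

  q[10] <- 22
  rd <- make_read(asm, start0 = 0, len = 30, q = q, mismatch = 10)
  expect_false(qualify_base(rd, 10, asm))

  # a single flank base below 15 disqualifies
  q[10] <- 23
  q[7] <- 14
  rd <- make_read(asm, start0 = 0, len = 30, q = q, mismatch = 10)
  expect_false(qualify_base(rd, 10, asm))

  # 9 of 10 flank matches qualifies; 8 of 10 does not
  rd <- make_read(asm, start0 = 0, len = 30, q = 40, mismatch = c(10, 12))
  expect_true(qualify_base(rd, 10, asm))
  rd <- make_read(asm, start0 = 0, len = 30, q = 40, mismatch = c(10, 12, 13))
  expect_false(qualify_base(rd, 10, asm))

  # incomplete neighborhood near the read start never qualifies
  rd <- make_read(asm, start0 = 0, len = 30, q = 40)
  expect_false(qualify_base(rd, 3, asm))
  expect_true(qualify_base(rd, 6, asm))
  expect_error(qualify_base(rd, 31, asm), "offset")
})

test_that("alignment gaps crossing the neighborhood disqualify bases", {
  asm <- random_assembly(len = 200, seed = 4)
  refseq <- asm$sequences[["chr1"]]
  # read with a 2-base deletion after its 20th base
  seq <- paste0(substr(refseq, 1, 20), substr(refseq, 23, 42))
  rd <- make_read(asm, start0 = 0, seq = seq, q = 40, cigar = "20M2D20M")
  for (off in 16:25) expect_false(qualify_base(rd, off, asm), label = off)
  expect_true(qualify_base(rd, 15, asm))
  expect_true(qualify_base(rd, 26, asm))
})

test_that("vectorized qualification matches the exhaustive oracle on simulated reads", {
  sc <- small_scenario(seed = 21, genome = 1.2e5, coverage = 1.5)
  reads <- sc$reads$reads
  reads <- reads[seq_len(min(120, nrow(reads))), ]
  params <- nqs_params()
  for (i in seq_len(nrow(reads))) {
    ar <- lightsnp:::read_arrays(reads$seq[i], reads$qual[i], reads$cigar[i],
                                 reads$start[i],
                                 sc$truth$assembly$sequences[[reads$chrom[i]]])
    got <- lightsnp:::qualify_vector(ar, params)$qualified
    want <- vapply(seq_along(got), function(off)
      oracle_qualify(ar$read, ar$refaln, ar$q, ar$opid, off), logical(1))
    expect_identical(got, want)
  }
})

test_that("build_pileup depths equal brute-force interval stabbing", {
  expect_equal(nrow(build_pileup(
    tibble::tibble(read_id = character(), individual = character(),
                   chrom = character(), start = integer(), strand = character(),
                   cigar = character(), seq = character(), qual = character()),
    random_assembly(len = 100))), 0)

  asm <- random_assembly(len = 600, seed = 12)
  reads <- dplyr::bind_rows(lapply(1:50, function(i) {
    withr::with_seed(100 + i, {
      make_read(asm, start0 = sample(0:500, 1), len = sample(30:90, 1),
                read_id = paste0("r", i), individual = sample(c("a", "b"), 1))
    })
  }))
  pu <- build_pileup(reads, asm)
  expect_equal(nrow(pu), sum(nchar(reads$seq)))
  spans <- vapply(reads$cigar, lightsnp:::cigar_ref_span, numeric(1))
  for (p in sample(unique(pu$pos), 40)) {
    expect_equal(pu$depth[pu$pos == p][1],
                 oracle_depth(reads$start, spans, p))
  }
  two <- dplyr::bind_rows(
    make_read(asm, start0 = 0, len = 40, read_id = "x"),
    make_read(asm, start0 = 20, len = 40, read_id = "y"))
  pu2 <- build_pileup(two, asm)
  expect_equal(unique(pu2$depth[pu2$pos == 25]), 2L)
})

test_that("call_snps emits qualified mismatches and respects the coverage cap", {
  asm <- random_assembly(len = 300, seed = 6)
  params <- nqs_params(max_depth = 3)
  mk_stack <- function(n, mismatch = 50) {
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      make_read(asm, start0 = 0, len = 100, read_id = paste0("s", i),
                individual = "catA",
                mismatch = if (i == 1) mismatch else integer(0))))
  }
  # depth 3 (= cap): the record is emitted
  recs <- call_snps(mk_stack(3), asm, params)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$pos, 49L)
  expect_equal(recs$individual, "catA")
  # depth 4 (> cap): nothing
  expect_equal(nrow(call_snps(mk_stack(4), asm, params)), 0)
  # unqualified mismatch (flank at q14): nothing
  q <- rep(40, 100); q[52] <- 14
  rd <- make_read(asm, start0 = 0, len = 100, q = q, mismatch = 50)
  expect_equal(nrow(call_snps(rd, asm, params)), 0)
})

test_that("reference-N columns and N-adjacent columns emit nothing", {
  chars <- strsplit(paste(rep("ACGT", 100), collapse = ""), "")[[1]]
  chars[201:210] <- "N"
  asm <- assembly(c(chr1 = paste(chars, collapse = "")))
  # mismatch 3 bases left of the N run: inside the flank_width exclusion zone
  rd <- make_read(asm, start0 = 150, len = 45, mismatch = 48)
  expect_equal(nrow(call_snps(rd, asm, nqs_params())), 0)
  # well away from the N run it is called
  rd2 <- make_read(asm, start0 = 100, len = 60, mismatch = 30)
  expect_equal(nrow(call_snps(rd2, asm, nqs_params())), 1)
})

test_that("call_dips requires qualified flanks and bounded gap length", {
  asm <- random_assembly(len = 400, seed = 31)
  refseq <- asm$sequences[["chr1"]]
  del_read <- function(dlen, q = 40) {
    seq <- paste0(substr(refseq, 1, 30), substr(refseq, 31 + dlen, 60 + dlen))
    make_read(asm, start0 = 0, seq = seq, q = q,
              cigar = sprintf("30M%dD30M", dlen))
  }
  recs <- call_dips(del_read(1), asm)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$type, "DIP")
  expect_equal(recs$pos, 29L)        # anchor = last matching base, 0-based
  expect_equal(recs$ref, substr(refseq, 30, 31))
  expect_equal(recs$alt, substr(refseq, 30, 30))

  # a flank base at q14 adjacent to the gap blocks the call
  q <- rep(40, 60); q[31] <- 14
  expect_equal(nrow(call_dips(del_read(1, q = q), asm)), 0)

  # gaps longer than max_dip_length are ignored
  expect_equal(nrow(call_dips(del_read(11), asm)), 0)
  expect_equal(nrow(call_dips(del_read(10), asm)), 1)

  # insertions are anchored with the inserted bases in ALT
  ins <- "GT"
  seq <- paste0(substr(refseq, 1, 30), ins, substr(refseq, 31, 55))
  rd <- make_read(asm, start0 = 0, seq = seq, cigar = "30M2I25M")
  recs <- call_dips(rd, asm)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$alt, paste0(substr(refseq, 30, 30), ins))
})

test_that("merge_sites groups by site and alt allele with discoverer union", {
  recs <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 10L, 10L, 20L),
    type = "SNP", ref = "A",
    alt = c("G", "G", "T", "C"),
    individual = c("Pixel", "Nancy", "Pixel", "Nancy"),
    read_id = paste0("r", 1:4))
  sites <- merge_sites(recs)
  expect_equal(nrow(sites), 3)
  s10g <- sites[sites$pos == 10 & sites$alt == "G", ]
  expect_equal(s10g$discoverers[[1]], c("Nancy", "Pixel"))
  expect_equal(s10g$n_discoverers, 2L)

  # conservation + agreement with a hash-grouping oracle on random records
  rr <- withr::with_seed(77, tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 300, TRUE),
    pos = sample(1:40, 300, TRUE),
    type = "SNP", ref = "A",
    alt = sample(c("C", "G", "T"), 300, TRUE),
    individual = sample(c("a", "b", "c"), 300, TRUE),
    read_id = paste0("r", 1:300)))
  merged <- merge_sites(rr)
  oracle <- oracle_group_sites(rr)
  expect_equal(nrow(merged), oracle$n_sites)
  per_cat_sum <- sum(vapply(c("a", "b", "c"), function(ind)
    nrow(dplyr::distinct(rr[rr$individual == ind,
                            c("chrom", "pos", "type", "alt")])), numeric(1)))
  expect_gte(per_cat_sum, nrow(merged))
  expect_setequal(
    vapply(merged$discoverers, paste, character(1), collapse = ","),
    vapply(oracle$discoverer_sets, paste, character(1), collapse = ","))
})

test_that("snp_rate divides NQS bases by SNP records and rejects zero SNPs", {
  asm <- random_assembly(len = 300, seed = 41)
  reads <- dplyr::bind_rows(
    make_read(asm, start0 = 0, len = 100, read_id = "a1", individual = "catA",
              mismatch = 50),
    make_read(asm, start0 = 120, len = 100, read_id = "a2", individual = "catA"))
  cs <- call_variants(reads, asm)
  r <- snp_rate("catA", cs, reads, asm)
  # denominator equals a brute-force per-base qualification count
  brute <- 0
  for (i in 1:2) {
    ar <- lightsnp:::read_arrays(reads$seq[i], reads$qual[i], reads$cigar[i],
                                 reads$start[i], asm$sequences[["chr1"]])
    brute <- brute + sum(vapply(seq_along(ar$q), function(off)
      oracle_qualify(ar$read, ar$refaln, ar$q, ar$opid, off), logical(1)))
  }
  expect_equal(r$nqs_bases, brute)
  expect_equal(r$snp_count, 1L)
  expect_equal(r$bases_per_snp, round(brute / 1))
  expect_error(snp_rate("catB", cs, reads, asm), "undefined")

  # pure arithmetic: 1,000,000 qualified bases over 2,000 SNPs = one per 500
  expect_equal(bases_per_snp(1e6, 2000), 500)
})

test_that("relaxing the center quality threshold never removes records", {
  sc <- small_scenario(seed = 51, genome = 1e5, coverage = 2)
  reads <- sc$reads$reads
  asm <- sc$truth$assembly
  n23 <- nrow(call_variants(reads, asm, nqs_params(center_min_q = 23))$records)
  for (cq in c(20, 15, 10)) {
    expect_gte(nrow(call_variants(reads, asm, nqs_params(center_min_q = cq))$records),
               n23)
  }
})

test_that("nqs_params validates its invariants", {
  expect_error(nqs_params(min_flank_matches = 11), "cannot exceed")
  expect_error(nqs_params(center_min_q = -1), ">= 0")
  expect_silent(nqs_params(min_flank_matches = 10))
})
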