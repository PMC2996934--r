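one_cat <- function(class = "domestic", sex = "F", name = "Solo") {
  tibble::tibble(name = name, breed = "x", sex = sex, class = class,
                 read_share = 1)
}

test_that("zero polymorphism rates give an empty catalog and reference haplotypes", {
  pm <- population_model(
    genome_length = 5e4, domestic_het_rate = 0, wildcat_extra_rate = 0,
    gap_start_prob = 0,
    chromosomes = tibble::tibble(name = "chr1", length = 5e4, is_X = FALSE),
    individuals = default_individuals())
  tr <- simulate_population(pm, 3)
  expect_equal(nrow(tr$variants), 0)
  expect_identical(haplotype_sequence(tr, "Pixel", "chr1", 1),
                   tr$assembly$sequences[["chr1"]])
  expect_identical(haplotype_sequence(tr, "Cinnamon", "chr1", 2),
                   tr$assembly$sequences[["chr1"]])
})

test_that("model validation rejects bad rates and lengths", {
  expect_error(population_model(genome_length = 0), "positive")
  expect_error(population_model(domestic_het_rate = -0.1), "rates")
  expect_error(population_model(domestic_het_rate = 1), "rates")
  expect_error(simulate_population(population_model(genome_length = 1e4)),
               "seed")
  expect_error(read_model(insert_cv = 0.2), "insert_cv")
})

test_that("a domestic cat's heterozygosity matches the configured rate", {
  pm <- population_model(
    genome_length = 6e5, gap_start_prob = 0, dip_fraction = 0,
    chromosomes = tibble::tibble(name = "chr1", length = 6e5, is_X = FALSE),
    individuals = one_cat())
  tr <- simulate_population(pm, 5)
  het <- sum(xor(tr$carry1[, "Solo"], tr$carry2[, "Solo"]))
  expect_lt(abs(het - 1000), 4 * sqrt(1000))
})

test_that("the inbred tract mosaic concentrates near its stationary fraction", {
  pm <- population_model(
    genome_length = 1e7, gap_start_prob = 0,
    chromosomes = tibble::tibble(name = "chr1", length = 1e7, is_X = FALSE),
    individuals = one_cat(class = "inbred", name = "Cinnamon"),
    wildcat_extra_rate = 0)
  # mean over three independent 10-Mb realizations: a single realization has
  # sampling SD ~0.03 around the stationary value by renewal-process theory
  fr <- vapply(c(9, 10, 11), function(s)
    truth_hom_fraction(simulate_population(pm, s)), numeric(1))
  expect_lt(abs(mean(fr) - 0.60), 0.05)
  # inbred heterozygous sites fall only inside heterozygous tracts
  tr <- simulate_population(pm, 9)
  het_tr <- tr$tracts[tr$tracts$state == "het", ]
  pos <- tr$variants$pos[tr$variants$class == "inbred_private"]
  idx <- findInterval(pos, het_tr$start)
  expect_true(all(idx >= 1 & pos < het_tr$end[idx]))
})

test_that("males are hemizygous: exactly one X haplotype exists", {
  pm <- population_model(genome_length = 1e5,
                         individuals = default_individuals())
  tr <- simulate_population(pm, 13)
  expect_equal(n_haplotypes(tr, "Tipper", "chrX"), 1L)
  expect_equal(n_haplotypes(tr, "Tipper", "chrA1"), 2L)
  expect_equal(n_haplotypes(tr, "Pixel", "chrX"), 2L)
  expect_error(haplotype_sequence(tr, "Tipper", "chrX", 2), "no haplotype")
  # and no male is heterozygous on X
  x_sites <- tr$variants$chrom == "chrX"
  expect_false(any(tr$carry2[x_sites, "Tipper"]))
  expect_false(any(tr$carry2[x_sites, "Scooter"]))
})

test_that("truth-variant density orders wildcat > domestic > inbred", {
  sc <- small_scenario(seed = 31, genome = 4e5)
  tr <- sc$truth
  dens <- function(nm) sum(tr$carry1[, nm] | tr$carry2[, nm])
  expect_gt(dens("Nancy"), dens("Pixel"))
  expect_gt(dens("Pixel"), dens("Cinnamon"))
})

test_that("simulation is deterministic for a fixed seed", {
  pm <- population_model(genome_length = 1e5)
  a <- simulate_population(pm, 17)
  b <- simulate_population(pm, 17)
  expect_identical(a$assembly$sequences, b$assembly$sequences)
  expect_identical(a$variants, b$variants)
  expect_identical(a$carry1, b$carry1)
  ra <- simulate_reads(a, read_model(insert_mean = 5000), 17)
  rb <- simulate_reads(b, read_model(insert_mean = 5000), 17)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$errors, rb$errors)
})

test_that("adding an individual does not perturb the others' reads", {
  pm <- population_model(genome_length = 1e5,
                         individuals = default_individuals()[1:3, ])
  pm2 <- population_model(genome_length = 1e5,
                          individuals = default_individuals()[1:4, ])
  t1 <- simulate_population(pm, 23)
  t2 <- simulate_population(pm2, 23)
  cov <- setNames(rep(0.5, 4), default_individuals()$name[1:4])
  r1 <- simulate_reads(t1, read_model(insert_mean = 5000, coverage = cov[1:3]), 23)
  r2 <- simulate_reads(t2, read_model(insert_mean = 5000, coverage = cov), 23)
  # same genome, so the first three cats' reads are identical
  expect_identical(t1$assembly$sequences, t2$assembly$sequences)
  keep <- r2$reads$individual %in% pm$individuals$name
  expect_identical(r1$reads$seq, r2$reads$seq[keep])
})

test_that("emitted reads reconstruct exactly from reference + variants + errors", {
  sc <- small_scenario(seed = 41, genome = 2e5, coverage = 1)
  tr <- sc$truth
  reads <- sc$reads$reads
  errs <- sc$reads$errors
  take <- withr::with_seed(1, sample(nrow(reads), 50))
  for (i in take) {
    hv <- lightsnp:::haplotype_variants(tr, reads$individual[i],
                                        reads$chrom[i], reads$hap[i])
    span <- lightsnp:::cigar_ref_span(reads$cigar[i])
    al <- lightsnp:::apply_variants(tr$assembly$sequences[[reads$chrom[i]]],
                                    hv, reads$start[i], reads$start[i] + span)
    expect_identical(al$cigar, reads$cigar[i])
    chars <- strsplit(al$seq, "")[[1]]
    e <- errs[errs$read_id == reads$read_id[i], ]
    if (nrow(e) > 0) {
      expect_identical(chars[e$offset], e$truth_base)
      chars[e$offset] <- e$observed_base
    }
    expect_identical(paste(chars, collapse = ""), reads$seq[i])
  }
})

test_that("read counts follow coverage arithmetic", {
  pm <- population_model(
    genome_length = 1e6, gap_start_prob = 0,
    chromosomes = tibble::tibble(name = "chr1", length = 1e6, is_X = FALSE),
    individuals = one_cat())
  tr <- simulate_population(pm, 7)
  rs <- simulate_reads(tr, read_model(coverage = c(Solo = 3),
                                      error_model = "none"), 7)
  expect_lt(abs(nrow(rs$reads) - 3e6 / 700) / (3e6 / 700), 0.1)
})

test_that("insert sizes match the fosmid model: mean ~37 kb, CV < 10%", {
  pm <- population_model(
    genome_length = 2e5, gap_start_prob = 0, domestic_het_rate = 0,
    wildcat_extra_rate = 0,
    chromosomes = tibble::tibble(name = "chr1", length = 2e5, is_X = FALSE),
    individuals = one_cat())
  tr <- simulate_population(pm, 19)
  rs <- simulate_reads(tr, read_model(reads_per_individual = c(Solo = 10000),
                                      error_model = "none"), 19)
  reads <- rs$reads
  r1 <- reads[reads$mate == 1, ]
  r2 <- reads[reads$mate == 2, ]
  ins <- (r2$start + vapply(r2$cigar, lightsnp:::cigar_ref_span, numeric(1))) -
    r1$start[match(r2$pair_id, r1$pair_id)]
  se <- sd(ins) / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 37000), 3 * se)
  expect_lt(sd(ins) / mean(ins), 0.10)
  expect_error(
    simulate_reads(tr, read_model(insert_mean = 3e5), 19), "insert mean")
})

test_that("constant-quality reads collect errors at the PHRED-implied rate", {
  pm <- population_model(
    genome_length = 1e6, gap_start_prob = 0, domestic_het_rate = 0,
    wildcat_extra_rate = 0,
    chromosomes = tibble::tibble(name = "chr1", length = 1e6, is_X = FALSE),
    individuals = one_cat())
  tr <- simulate_population(pm, 29)
  rs <- simulate_reads(tr, read_model(q_plateau = 40, q_end = 40, q_jitter = 0,
                                      reads_per_individual = c(Solo = 715)),
                       29)
  n_bases <- sum(nchar(rs$reads$seq))
  expect_gt(n_bases, 9e5)
  expected <- n_bases * 1e-4
  expect_lt(abs(nrow(rs$errors) - expected), 4 * sqrt(expected))
})

test_that("write_truth emits files that round-trip losslessly", {
  sc <- small_scenario(seed = 43, genome = 1e5, coverage = 1)
  dir <- withr::local_tempdir()
  paths <- write_truth(sc$truth, dir, sc$reads)
  expect_true(all(file.exists(paths)))
  asm <- read_fasta(paths[["reference"]])
  expect_identical(asm$sequences, sc$truth$assembly$sequences)
  v <- read_vcf(paths[["truth_vcf"]])
  expect_equal(nrow(v), nrow(sc$truth$variants))
  expect_equal(v$pos, sc$truth$variants$pos)
  expect_equal(v$alt, sc$truth$variants$alt)
  gt <- attr(v, "genotypes")
  expect_identical(names(gt), sc$truth$individuals$name)
  back <- read_sam(paths[["sam"]])
  expect_equal(nrow(back), nrow(sc$reads$reads))
  expect_identical(back$seq, sc$reads$reads$seq)
})

test_that("a donor consensus makes that individual nearly invisible to calling", {
  inds <- default_individuals()
  pm <- population_model(genome_length = 2e5, consensus_from = "Cinnamon",
                         individuals = inds)
  tr <- simulate_population(pm, 47)
  j <- match("Cinnamon", inds$name)
  # hap1 of the donor never differs from the consensus
  expect_false(any(tr$carry1[, j]))
  expect_identical(haplotype_sequence(tr, "Cinnamon", "chrA1", 1),
                   tr$assembly$sequences[["chrA1"]])
})
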