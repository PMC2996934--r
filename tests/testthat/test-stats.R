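mk_sites <- function(discoverer_sets, pos = NULL, chrom = "chr1") {
  n <- length(discoverer_sets)
  tibble::tibble(chrom = chrom, pos = pos %||% seq(10, by = 100, length.out = n),
                 type = "SNP", ref = "A", alt = "G",
                 discoverers = discoverer_sets)
}

test_that("categorize applies the discoverer rules for A, B and C", {
  sites <- mk_sites(list("Nancy", "Cinnamon", c("Pixel", "Nancy"),
                         c("Cinnamon", "Nancy"), "Speedy"))
  out <- categorize(sites)
  expect_equal(out$cat_A, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$cat_B, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$cat_C, rep(TRUE, 5))
  expect_error(categorize(sites, inbred = "Nobody"), "unknown individual")
  expect_error(categorize(mk_sites(list(character(0)))), "non-empty")
})

test_that("categorization matches the brute-force partition and nests A in B in C", {
  pool <- c("Pixel", "Zeelie", "Tipper", "Nancy", "Cinnamon")
  sets <- withr::with_seed(3, replicate(200, sample(pool, sample(1:3, 1)),
                                        simplify = FALSE))
  out <- categorize(mk_sites(sets, pos = 1:200))
  oracle <- oracle_partition(sets, "Cinnamon", "Nancy")
  expect_equal(out$cat_A, oracle$A)
  expect_equal(out$cat_B, oracle$B)
  expect_true(all(out$cat_B[out$cat_A]))
  expect_true(all(out$cat_C[out$cat_B]))
})

test_that("bases_per_snp rounds half up and flags undefined rates", {
  expect_equal(bases_per_snp(164170763, 77824), 2110)
  expect_equal(bases_per_snp(1992182257, 964285), 2066)
  expect_equal(bases_per_snp(1e6, 2000), 500)
  expect_true(is.na(bases_per_snp(123, 0)))
  expect_error(bases_per_snp(-1, 5), "non-negative")
  # exact .5 boundary rounds up, unlike base round()
  expect_equal(bases_per_snp(5, 2), 3)
})

test_that("category_table per-chromosome counts sum to the Total row", {
  sc <- small_scenario(seed = 61, genome = 2e5)
  sites <- categorize(merge_sites(call_variants(sc$reads$reads,
                                                sc$truth$assembly)),
                      individuals = sc$truth$individuals$name)
  tab <- category_table(sites, sc$truth$assembly)
  tot <- tab[tab$chrom == "Total", ]
  per <- tab[tab$chrom != "Total", ]
  expect_equal(sum(per$A), tot$A)
  expect_equal(sum(per$B), tot$B)
  expect_equal(sum(per$C), tot$C)
  expect_equal(sum(per$non_n_bases), tot$non_n_bases)
  expect_true(all(per$A <= per$B & per$B <= per$C))
})

test_that("window_density bins sites into half-open windows", {
  asm <- assembly(c(chr1 = strrep("A", 2e6)))
  sites <- tibble::tibble(chrom = "chr1", pos = c(5e5, 15e5))
  wt <- window_density(sites, asm, window = 1e6)
  expect_equal(wt$n_snps, c(1L, 1L))
  expect_false(any(wt$undetermined))

  # all-N chromosome: every window undetermined
  asm_n <- suppressWarnings(assembly(c(chr1 = strrep("N", 3e4)), strict = FALSE))
  wtn <- window_density(sites[0, ], asm_n, window = 1e4)
  expect_true(all(wtn$undetermined))

  # final partial window is kept, shorter
  wt3 <- window_density(sites[0, ], assembly(c(chr1 = strrep("A", 25000))),
                        window = 1e4)
  expect_equal(wt3$end - wt3$start, c(10000, 10000, 5000))
  expect_error(window_density(sites, asm, window = 0), "positive")
})

test_that("window counts equal direct binning on random sites", {
  asm <- random_assembly(len = 50000, seed = 8, n_gaps = 3, gap_len = 400)
  pos <- withr::with_seed(12, sort(sample(0:49999, 500)))
  sites <- tibble::tibble(chrom = "chr1", pos = pos)
  wt <- window_density(sites, asm, window = 3000)
  expect_equal(wt$n_snps, oracle_bin(pos, 50000, 3000))
  expect_equal(sum(wt$n_snps), 500)
  g <- glance(wt)
  expect_equal(g$n_windows, ceiling(50000 / 3000))
  expect_equal(g$total_snps, 500)
})

test_that("occupancy_curve reports occupied fractions over determined windows", {
  asm <- assembly(c(chr1 = strrep("A", 1e4)))
  one <- tibble::tibble(chrom = "chr1", pos = 5000)
  expect_equal(occupancy_curve(one, asm, 2e4)$fraction, 1.0)
  expect_equal(occupancy_curve(one[0, ], asm, c(1e3, 1e4))$fraction, c(0, 0))
  expect_error(occupancy_curve(one, asm, numeric(0)), "non-empty")

  # at window size 1 on an all-mapped assembly: occupied fraction equals
  # SNP-bearing positions / genome length
  pos <- withr::with_seed(4, sort(sample(0:9999, 120)))
  sites <- tibble::tibble(chrom = "chr1", pos = pos)
  oc1 <- occupancy_curve(sites, asm, 1)
  expect_equal(oc1$fraction, length(unique(pos)) / 1e4)

  # random sites at two window sizes match brute-force occupancy
  for (w in c(500, 2000)) {
    oc <- occupancy_curve(sites, asm, w)
    expect_equal(oc$n_occupied, sum(oracle_bin(pos, 1e4, w) > 0))
  }
  # monotone non-decreasing on nested tilings
  oc <- occupancy_curve(sites, asm, c(250, 500, 1000, 2000))
  expect_true(all(diff(oc$fraction) >= 0))
})

test_that("undetermined windows leave the occupancy denominator unless asked", {
  chars <- c(rep("A", 1e4), rep("N", 1e4))
  asm <- suppressWarnings(assembly(c(chr1 = paste(chars, collapse = ""))))
  sites <- tibble::tibble(chrom = "chr1", pos = 5000)
  oc <- occupancy_curve(sites, asm, 1e4)
  expect_equal(oc$n_determined, 1L)
  expect_equal(oc$fraction, 1.0)
  oc2 <- occupancy_curve(sites, asm, 1e4, include_unmapped = TRUE)
  expect_equal(oc2$fraction, 0.5)
})

test_that("informative_fraction reproduces the validation-genotype arithmetic", {
  vt <- example_validation_table()
  all_cats <- informative_fraction(vt)
  expect_equal(all_cats$n_scored, 92L)
  expect_equal(all_cats$n_singleton, 24L)
  expect_equal(all_cats$singleton_pct, 26)
  expect_equal(all_cats$multi_pct, 74)

  domestic <- informative_fraction(
    vt, restrict_to = default_individuals()$name[1:6],
    extrapolation_base = 964285)
  expect_equal(domestic$n_scored, 57L)
  expect_equal(domestic$n_multi, 50L)
  expect_equal(domestic$multi_pct, 88)
  expect_equal(domestic$extrapolated_informative, 849000)

  # every variant in >= 2 cats: multi fraction 100%
  vt2 <- vt[vt$amplimer == "ok", ]
  two <- vt2
  for (cc in default_individuals()$name[1:2]) two[[cc]] <- "A/G"
  expect_equal(informative_fraction(two)$multi_pct, 100)
  expect_error(informative_fraction(vt[0, ]), "empty")
})

test_that("n50 equals the brute-force cumulative scan", {
  expect_equal(n50(1), 1)
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_error(n50(numeric(0)), "empty")
  expect_error(n50(c(3, 0)), "positive")
  lens <- withr::with_seed(10, sample(1:5000, 200, replace = TRUE))
  expect_equal(n50(lens), oracle_n50(lens))
})

test_that("tract_homozygosity merges dense calls into heterozygous segments", {
  asm <- assembly(c(chr1 = strrep("A", 1e5)))
  # sites only in the first half of the chromosome for "Cinnamon"
  sites <- tibble::tibble(chrom = "chr1",
                          pos = seq(500L, 49500L, by = 500L),
                          discoverers = replicate(99, "Cinnamon",
                                                  simplify = FALSE))
  th <- tract_homozygosity(sites, "Cinnamon", asm, max_gap = 1000)
  expect_equal(th$n_segments, 1L)
  expect_equal(th$hom_fraction, 0.5)
  # a site cluster split by a large gap forms two segments
  th2 <- tract_homozygosity(sites, "Cinnamon", asm, max_gap = 400)
  expect_equal(th2$n_segments, 99L)
  # no calls at all: everything is homozygous-silent
  none <- tract_homozygosity(sites, "Pixel", asm)
  expect_equal(none$hom_fraction, 1)
})
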