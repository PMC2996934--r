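#' Default eight-individual study population
#'
#' The default population mirrors an eight-cat light-coverage resequencing
#' survey: six outbred domestic breed cats, one deeply sequenced inbred
#' individual (Cinnamon, an Abyssinian whose genome is a mosaic of homozygous
#' and heterozygous tracts), and one African wildcat (Nancy) carrying extra
#' divergence relative to the domestic breeds. `read_share` gives each
#' individual's share of total sequencing (the inbred reference animal
#' dominates), used to split total coverage.
#'
#' @return Tibble with columns `name`, `breed`, `sex` (`"F"`/`"M"`), `class`
#'   (`domestic`/`inbred`/`wildcat`), `read_share`.
#' @export
default_individuals <- function() {
  tibble(
    name  = c("Pixel", "Zeelie", "Tipper", "Scooter", "Speedy", "Cocoa",
              "Nancy", "Cinnamon"),
    breed = c("Burmese", "Persian", "Cornish Rex", "Ragdoll",
              "Domestic Shorthair", "Siamese", "African wildcat", "Abyssinian"),
    sex   = c("F", "F", "M", "M", "F", "F", "F", "F"),
    class = c(rep("domestic", 6), "wildcat", "inbred"),
    read_share = c(331813, 298332, 272607, 298409, 310364, 293712,
                   1373060, 8186934)
  )
}

#' Population model for the synthetic genome generator
#'
#' Describes the genome (chromosome plan with N-gap model) and the
#' population's diversity structure: shared domestic polymorphism with a
#' symmetric-Beta site frequency spectrum, private divergent sites in the
#' wildcat, and a two-state homozygous/heterozygous tract mosaic in the
#' inbred individual. Defaults encode the study conditions: domestic
#' heterozygosity of one site per 600 bp, ~60% of the inbred genome in
#' homozygous tracts, and an elevated wildcat rate.
#'
#' @param genome_length Total genome size in bases (desk-scale default 5 Mb).
#' @param chromosomes Optional tibble (`name`, `length`, `is_X`). Default: one
#'   autosome (90% of the genome) plus chrX (10%).
#' @param gap_start_prob Per-base probability that an assembly N-gap starts.
#' @param gap_mean_length Mean N-run length in bases.
#' @param domestic_het_rate Expected heterozygous sites per base in a domestic
#'   cat (default 1/600).
#' @param wildcat_extra_rate Additional per-base rate of divergent sites
#'   private to (and fixed in) the wildcat.
#' @param dip_fraction Fraction of polymorphic sites that are short indels
#'   (DIPs) rather than SNPs; default 0.18, the genome-wide DIP:SNP balance
#'   of the survey this emulates.
#' @param inbred_homozygous_fraction Stationary fraction of the inbred genome
#'   inside homozygous tracts (default 0.60).
#' @param inbred_tract_mean_length Mean homozygous tract length in bases
#'   (default 50 kb; see the methods vignette for the desk-scale rationale).
#' @param freq_grid_size Haplotype pool size the allele-frequency spectrum is
#'   discretized to (default 16 = 8 diploid individuals).
#' @param individuals Individual table as in [default_individuals()].
#' @param consensus_from Optional individual name whose first haplotype is
#'   substituted as the consensus reference, emulating a read-dominated
#'   assembly where that animal's reads mostly match their own haploid.
#' @return An object of class `population_model`.
#' @export
population_model <- function(genome_length = 5e6,
                             chromosomes = NULL,
                             gap_start_prob = 1e-5,
                             gap_mean_length = 500,
                             domestic_het_rate = 1 / 600,
                             wildcat_extra_rate = 1 / 720,
                             dip_fraction = 0.18,
                             inbred_homozygous_fraction = 0.60,
                             inbred_tract_mean_length = 5e4,
                             freq_grid_size = 16,
                             individuals = default_individuals(),
                             consensus_from = NULL) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    abort("genome_length must be positive")
  }
  rates <- c(gap_start_prob, domestic_het_rate, wildcat_extra_rate, dip_fraction)
  if (any(rates < 0 | rates >= 1)) {
    abort("per-base rates must lie in [0, 1)")
  }
  if (inbred_homozygous_fraction < 0 || inbred_homozygous_fraction > 1) {
    abort("inbred_homozygous_fraction must lie in [0, 1]")
  }
  if (is.null(chromosomes)) {
    la <- round(genome_length * 0.9)
    chromosomes <- tibble(name = c("chrA1", "chrX"),
                          length = c(la, genome_length - la),
                          is_X = c(FALSE, TRUE))
    chromosomes <- chromosomes[chromosomes$length > 0, ]
  }
  stopifnot(all(c("name", "length", "is_X") %in% names(chromosomes)))
  stopifnot(all(c("name", "sex", "class") %in% names(individuals)))
  if (!all(individuals$class %in% c("domestic", "inbred", "wildcat"))) {
    abort("individual class must be domestic, inbred or wildcat")
  }
  if (!is.null(consensus_from) && !consensus_from %in% individuals$name) {
    abort("consensus_from must name a configured individual")
  }
  if (anyDuplicated(individuals$name)) abort("duplicate individual names")
  out <- list(
    genome_length = genome_length,
    chromosomes = as_tibble(chromosomes),
    gap_start_prob = gap_start_prob,
    gap_mean_length = gap_mean_length,
    domestic_het_rate = domestic_het_rate,
    wildcat_extra_rate = wildcat_extra_rate,
    dip_fraction = dip_fraction,
    inbred_homozygous_fraction = inbred_homozygous_fraction,
    inbred_tract_mean_length = inbred_tract_mean_length,
    freq_grid_size = as.integer(freq_grid_size),
    individuals = as_tibble(individuals),
    consensus_from = consensus_from
  )
  class(out) <- "population_model"
  out
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> ", format(x$genome_length, big.mark = ","), " bp, ",
      nrow(x$chromosomes), " chromosome(s), ", nrow(x$individuals),
      " individual(s)\n", sep = "")
  cat("  domestic het rate 1/", round(1 / x$domestic_het_rate),
      ", wildcat extra 1/", round(1 / x$wildcat_extra_rate),
      ", inbred homozygous fraction ", x$inbred_homozygous_fraction, "\n", sep = "")
  invisible(x)
}

# Discretized symmetric Beta(0.5, 0.5) site-frequency spectrum on the
# attainable grid k/m, k = 1..m-1.
freq_spectrum <- function(m = 16) {
  k <- seq_len(m - 1)
  edges <- (c(k) - 0.5) / m
  p <- pbeta((k + 0.5) / m, 0.5, 0.5) - pbeta((k - 0.5) / m, 0.5, 0.5)
  p <- p / sum(p)
  list(f = k / m, p = p,
       e_het = sum(p * 2 * (k / m) * (1 - k / m)))
}

#' Sanger-style read model
#'
#' Fosmid paired-end Sanger reads: ~700-bp reads from the two ends of ~37-kb
#' inserts with a tight (<10% CV) insert-size distribution, a mid-read PHRED
#' quality plateau near 40 decaying logistically toward ~10 at the read ends,
#' and substitution errors injected at the per-base rate `10^(-q/10)`.
#'
#' @param read_length_mean,read_length_sd Normal read-length parameters,
#'   truncated to `read_length_range`.
#' @param read_length_range Truncation bounds in bases (default 100-1000).
#' @param insert_mean Mean fosmid insert size in bases (default 37,000).
#' @param insert_cv Coefficient of variation of insert size; must be < 0.10.
#' @param q_plateau,q_end Plateau and end-of-read PHRED quality means.
#' @param q_jitter SD of integer per-base quality jitter.
#' @param error_model `"phred"` injects substitution errors at `10^(-q/10)`;
#'   `"none"` produces error-free reads (qualities still emitted).
#' @param total_coverage Total fold-coverage across all individuals, split by
#'   their `read_share` (default 2.8, the survey's read redundancy).
#' @param coverage Optional named per-individual fold-coverages, overriding
#'   the `read_share` split.
#' @param reads_per_individual Optional named read-pair counts, overriding
#'   coverage arithmetic entirely.
#' @return An object of class `read_model`.
#' @export
read_model <- function(read_length_mean = 700,
                       read_length_sd = 50,
                       read_length_range = c(100, 1000),
                       insert_mean = 37000,
                       insert_cv = 0.08,
                       q_plateau = 40,
                       q_end = 10,
                       q_jitter = 2,
                       error_model = c("phred", "none"),
                       total_coverage = 2.8,
                       coverage = NULL,
                       reads_per_individual = NULL) {
  error_model <- match.arg(error_model)
  if (insert_cv >= 0.10) abort("insert_cv must be < 0.10")
  if (q_plateau < 0 || q_plateau > 60 || q_end < 0 || q_end > 60) {
    abort("quality means must lie in [0, 60]")
  }
  if (read_length_range[1] <= 22) {
    abort("minimum read length must exceed twice the NQS window half-width")
  }
  out <- list(read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              read_length_range = read_length_range,
              insert_mean = insert_mean,
              insert_cv = insert_cv,
              q_plateau = q_plateau,
              q_end = q_end,
              q_jitter = q_jitter,
              error_model = error_model,
              total_coverage = total_coverage,
              coverage = coverage,
              reads_per_individual = reads_per_individual)
  class(out) <- "read_model"
  out
}

# PHRED mean profile along a read of length n: sharp logistic rise from the
# start, plateau, sharp logistic decay over the final ~60 bases. The ramps
# are steep, emulating quality-trimmed Sanger traces: the intermediate-
# quality shoulder (q ~ 20-35), where calibrated errors would still pass a
# neighborhood filter, is short.
quality_profile <- function(n, q_plateau = 40, q_end = 10) {
  i <- seq_len(n)
  rise <- 1 / (1 + exp(-(i - 18) / 5))
  fall <- 1 / (1 + exp((i - (n - 60)) / 10))
  q_end + (q_plateau - q_end) * rise * fall
}
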