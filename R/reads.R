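#' Simulate fosmid paired-end Sanger reads from a truth set
#'
#' Draws insert positions uniformly along chromosomes (chromosome chosen
#' proportional to length, haplotype uniformly among those the individual
#' carries), one read from each insert end on opposite strands. Read bases
#' are taken from the haplotype sequence, so every truth variant under a read
#' appears in it; the true gapped alignment to the reference (CIGAR over
#' M/I/D) is emitted alongside. PHRED qualities follow the read model's
#' profile and substitution errors are injected at `10^(-q/10)` per base
#' (unless `error_model = "none"`); every injected error is recorded.
#'
#' @param truth A `truth_set` from [simulate_population()].
#' @param rm A [read_model()].
#' @param seed Integer seed. Each individual draws from its own child stream.
#' @return An object of class `read_set`: `reads` (aligned-reads tibble with
#'   0-based `start`, reference-oriented `seq`/`qual`, `cigar`, `strand`,
#'   `pair_id`, `hap`) and `errors` (`read_id`, `offset` 1-based in the
#'   stored orientation, `truth_base`, `observed_base`).
#' @export
simulate_reads <- function(truth, rm = read_model(), seed) {
  stopifnot(inherits(truth, "truth_set"), inherits(rm, "read_model"))
  if (missing(seed) || is.null(seed)) abort("seed is required")
  chrs <- truth$chromosomes
  if (rm$insert_mean > min(chrs$length)) {
    abort("insert mean exceeds the shortest chromosome length")
  }
  genome_len <- sum(chrs$length)
  inds <- truth$individuals
  n_pairs <- pair_counts(rm, inds, genome_len)

  hapvar_cache <- list()
  get_hapvars <- function(nm, cn, hap) {
    key <- paste(nm, cn, hap, sep = "\r")
    hv <- hapvar_cache[[key]]
    if (is.null(hv)) {
      hv <- haplotype_variants(truth, nm, cn, hap)
      hapvar_cache[[key]] <<- hv
    }
    hv
  }

  read_rows <- list()
  err_rows <- list()
  for (j in seq_len(nrow(inds))) {
    nm <- inds$name[j]
    np <- n_pairs[[nm]]
    if (np == 0) next
    withr::with_seed(child_seed(seed, paste0("reads:", nm)), {
      ci <- sample.int(nrow(chrs), np, replace = TRUE, prob = chrs$length)
      ins <- round(rnorm(np, rm$insert_mean, rm$insert_cv * rm$insert_mean))
      ins <- pmin(pmax(ins, 2L * rm$read_length_range[1]), chrs$length[ci])
      start0 <- floor(runif(np) * (chrs$length[ci] - ins + 1))
      l1 <- trunc_norm(np, rm$read_length_mean, rm$read_length_sd, rm$read_length_range)
      l2 <- trunc_norm(np, rm$read_length_mean, rm$read_length_sd, rm$read_length_range)
      l1 <- pmin(l1, floor(ins / 2)); l2 <- pmin(l2, floor(ins / 2))
      hap_n <- vapply(chrs$name[ci], function(cn) n_haplotypes(truth, nm, cn), integer(1))
      hap <- ifelse(hap_n == 2L, sample.int(2L, np, replace = TRUE), 1L)

      rid <- sprintf("%s_%06d", nm, seq_len(np))
      rows <- vector("list", 2L * np)
      errs <- vector("list", 2L * np)
      for (k in seq_len(np)) {
        cn <- chrs$name[ci[k]]
        refseq <- truth$assembly$sequences[[cn]]
        hv <- get_hapvars(nm, cn, hap[k])
        for (mate in 1:2) {
          if (mate == 1) {
            s0 <- start0[k]; e0 <- s0 + l1[k]; strand <- "+"
          } else {
            e0 <- start0[k] + ins[k]; s0 <- e0 - l2[k]; strand <- "-"
          }
          al <- apply_variants(refseq, hv, s0, e0)
          n <- nchar(al$seq)
          q <- round(quality_profile(n, rm$q_plateau, rm$q_end) +
                       rnorm(n, 0, rm$q_jitter))
          q <- pmin(pmax(q, 2L), 60L)
          if (strand == "-") q <- rev(q)
          sq <- al$seq
          er <- NULL
          if (rm$error_model == "phred") {
            bchars <- strsplit(sq, "", fixed = TRUE)[[1]]
            hit <- which(runif(n) < 10^(-q / 10) & bchars != "N")
            if (length(hit) > 0) {
              truthb <- bchars[hit]
              obs <- vapply(truthb, function(b)
                sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
                USE.NAMES = FALSE)
              bchars[hit] <- obs
              sq <- paste(bchars, collapse = "")
              er <- tibble(read_id = paste0(rid[k], "_", mate), offset = hit,
                           truth_base = truthb, observed_base = obs)
            }
          }
          rows[[2 * (k - 1) + mate]] <- list(
            read_id = paste0(rid[k], "_", mate), individual = nm, chrom = cn,
            start = as.integer(s0), strand = strand, cigar = al$cigar,
            seq = sq, qual = qual_string(q), pair_id = rid[k],
            mate = mate, hap = hap[k])
          if (!is.null(er)) errs[[2 * (k - 1) + mate]] <- er
        }
      }
      read_rows[[nm]] <- bind_rows(rows)
      err_rows[[nm]] <- bind_rows(purrr::compact(errs))
    })
  }
  reads <- bind_rows(read_rows)
  if (nrow(reads) == 0) {
    reads <- tibble(read_id = character(), individual = character(),
                    chrom = character(), start = integer(), strand = character(),
                    cigar = character(), seq = character(), qual = character(),
                    pair_id = character(), mate = integer(), hap = integer())
  }
  errors <- bind_rows(err_rows)
  if (nrow(errors) == 0) {
    errors <- tibble(read_id = character(), offset = integer(),
                     truth_base = character(), observed_base = character())
  }
  structure(list(reads = reads, errors = errors, model = rm, seed = seed),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", format(nrow(x$reads), big.mark = ","), " read(s), ",
      format(sum(nchar(x$reads$seq)), big.mark = ","), " base(s), ",
      format(nrow(x$errors), big.mark = ","), " injected error(s)\n", sep = "")
  invisible(x)
}

trunc_norm <- function(n, mean, sd, range) {
  as.integer(pmin(pmax(round(rnorm(n, mean, sd)), range[1]), range[2]))
}

pair_counts <- function(rm, inds, genome_len) {
  if (!is.null(rm$reads_per_individual)) {
    np <- rm$reads_per_individual[inds$name]
    if (anyNA(np)) abort("reads_per_individual must name every individual")
    return(as.list(round(np)))
  }
  if (!is.null(rm$coverage)) {
    cov <- rm$coverage[inds$name]
    if (anyNA(cov)) abort("coverage must name every individual")
  } else {
    share <- if ("read_share" %in% names(inds)) inds$read_share else rep(1, nrow(inds))
    cov <- rm$total_coverage * share / sum(share)
    names(cov) <- inds$name
  }
  as.list(setNames(round(cov * genome_len / (2 * rm$read_length_mean)),
                   inds$name))
}

#' Write a truth set (and optionally its reads) to standard formats
#'
#' Writes `reference.fasta` (60-column), `truth.vcf` (VCF v4.2 with phased
#' per-individual GT columns), `tracts.tsv`, and with `reads` also
#' `reads.fastq` (PHRED+33, sequencing orientation), `alignments.sam` (true
#' gapped alignments, 1-based POS) and `errors.tsv`. Files round-trip through
#' the package's readers losslessly.
#'
#' @param truth A `truth_set`.
#' @param out_dir Output directory (created if needed).
#' @param reads Optional `read_set`.
#' @return Named character vector of file paths, invisibly.
#' @export
write_truth <- function(truth, out_dir, reads = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  paths <- c(reference = file.path(out_dir, "reference.fasta"),
             truth_vcf = file.path(out_dir, "truth.vcf"),
             tracts = file.path(out_dir, "tracts.tsv"))
  write_fasta(truth$assembly, paths[["reference"]])
  write_vcf(truth$variants, paths[["truth_vcf"]], asm = truth$assembly,
            genotypes = truth_genotypes(truth))
  readr::write_tsv(truth$tracts, paths[["tracts"]])
  if (!is.null(reads)) {
    paths <- c(paths, fastq = file.path(out_dir, "reads.fastq"),
               sam = file.path(out_dir, "alignments.sam"),
               errors = file.path(out_dir, "errors.tsv"))
    write_fastq(reads$reads, paths[["fastq"]])
    write_sam(reads$reads, truth$assembly, paths[["sam"]])
    readr::write_tsv(reads$errors, paths[["errors"]])
  }
  invisible(paths)
}
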