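#' Partition variant sites into discoverer categories A/B/C
#'
#' Category C is all sites; category B excludes sites discovered only in the
#' inbred reference individual; category A additionally excludes sites
#' discovered only in the inbred individual and/or the wildcat. A site is in
#' A exactly when its discoverer set contains at least one ordinary domestic
#' individual, so A is a subset of B is a subset of C.
#'
#' @param sites Merged site tibble from [merge_sites()] (needs a
#'   `discoverers` list column).
#' @param inbred Name of the inbred reference individual (default
#'   `"Cinnamon"`).
#' @param wildcat Name of the wildcat (default `"Nancy"`).
#' @param individuals Optional character vector of all known individual
#'   names; defaults to the union of discoverers. Unknown `inbred`/`wildcat`
#'   names are an error.
#' @return `sites` with logical columns `cat_A`, `cat_B`, `cat_C`.
#' @export
categorize <- function(sites, inbred = "Cinnamon", wildcat = "Nancy",
                       individuals = NULL) {
  if (!"discoverers" %in% names(sites)) {
    abort("sites must carry a discoverers list column (see merge_sites())")
  }
  if (nrow(sites) > 0 && any(lengths(sites$discoverers) == 0)) {
    abort("every site must have a non-empty discoverer set")
  }
  known <- individuals %||% unique(unlist(sites$discoverers))
  if (nrow(sites) > 0) {
    missing <- setdiff(c(inbred, wildcat), known)
    if (length(missing) > 0) {
      abort(paste0("unknown individual name(s): ", paste(missing, collapse = ", ")))
    }
  }
  special <- c(inbred, wildcat)
  sites$cat_A <- map_lgl(sites$discoverers, function(d) any(!d %in% special))
  sites$cat_B <- map_lgl(sites$discoverers, function(d) any(!d %in% inbred))
  sites$cat_C <- TRUE
  sites
}

#' Average spacing between SNPs (bases per SNP)
#'
#' Integer average spacing, rounded half up, as printed in SNP resource
#' tables. Zero SNP counts give `NA` (the spacing is undefined).
#'
#' @param non_n_bases Count(s) of non-N bases.
#' @param snp_count SNP count(s).
#' @return Numeric vector of rounded spacings.
#' @examples
#' bases_per_snp(164170763, 77824)  # 2110
#' @export
bases_per_snp <- function(non_n_bases, snp_count) {
  if (any(non_n_bases < 0) || any(snp_count < 0)) {
    abort("counts must be non-negative")
  }
  out <- rep(NA_real_, length(snp_count))
  ok <- snp_count > 0
  out[ok] <- round_half_up(non_n_bases[ok] / snp_count[ok])
  out
}

#' Per-chromosome category counts and spacing table
#'
#' Summarises categorized sites into the standard per-chromosome resource
#' table: non-N bases, SNP counts in categories A/B/C, and bases-per-SNP for
#' each category, with a genome-wide Total row.
#'
#' @param sites Categorized sites from [categorize()].
#' @param asm Reference [assembly()].
#' @param types Variant types to count (default `"SNP"`).
#' @return Tibble with one row per chromosome plus `"Total"`.
#' @export
category_table <- function(sites, asm, types = "SNP") {
  stopifnot(inherits(asm, "assembly"))
  sites <- sites[sites$type %in% types, , drop = FALSE]
  per <- purrr::map(asm$seqinfo$chrom, function(cn) {
    s <- sites[sites$chrom == cn, ]
    tibble(chrom = cn,
           non_n_bases = asm$seqinfo$non_n[asm$seqinfo$chrom == cn],
           A = sum(s$cat_A), B = sum(s$cat_B), C = sum(s$cat_C))
  })
  out <- bind_rows(per)
  out <- bind_rows(out, tibble(chrom = "Total",
                               non_n_bases = sum(out$non_n_bases),
                               A = sum(out$A), B = sum(out$B), C = sum(out$C)))
  mutate(out,
         bases_per_snp_A = bases_per_snp(.data$non_n_bases, .data$A),
         bases_per_snp_B = bases_per_snp(.data$non_n_bases, .data$B),
         bases_per_snp_C = bases_per_snp(.data$non_n_bases, .data$C))
}

#' SNP density in fixed windows along chromosomes
#'
#' Tiles each chromosome with half-open windows of `window` bases (the final
#' partial window is kept), counts sites per window, and flags windows with
#' no non-N sequence as undetermined (their density cannot be measured).
#'
#' @param sites Variant-site tibble (any tibble with `chrom` and `pos`).
#' @param asm Reference [assembly()].
#' @param window Window size in bases (default 1 Mb).
#' @param low_threshold Windows with fewer sites than this are tallied in
#'   [glance()] (default 100, the conventional sparse-window cutoff).
#' @return A `window_table`: tibble with `chrom`, `start`, `end`, `non_n`,
#'   `n_snps`, `undetermined`.
#' @export
window_density <- function(sites, asm, window = 1e6, low_threshold = 100) {
  stopifnot(inherits(asm, "assembly"))
  if (window <= 0) abort("window must be positive")
  per <- purrr::map(seq_len(nrow(asm$seqinfo)), function(ci) {
    cn <- asm$seqinfo$chrom[ci]
    L <- asm$seqinfo$length[ci]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    runs <- asm$n_runs[asm$n_runs$chrom == cn, ]
    n_overlap <- rep(0, length(starts))
    if (nrow(runs) > 0) {
      wir <- IRanges::IRanges(start = starts + 1, end = ends)
      nir <- IRanges::IRanges(start = runs$start + 1, end = runs$end)
      ov <- IRanges::findOverlaps(wir, nir)
      if (length(ov) > 0) {
        inter <- IRanges::pintersect(wir[S4Vectors::queryHits(ov)],
                                     nir[S4Vectors::subjectHits(ov)])
        n_overlap <- n_overlap +
          as.vector(tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)[
            as.character(seq_along(starts))])
        n_overlap[is.na(n_overlap)] <- 0
      }
    }
    p <- sites$pos[sites$chrom == cn]
    cnt <- tabulate(floor(p / window) + 1, nbins = length(starts))
    tibble(chrom = cn, start = starts, end = ends,
           non_n = (ends - starts) - n_overlap,
           n_snps = cnt, undetermined = (ends - starts) - n_overlap == 0)
  })
  out <- bind_rows(per)
  attr(out, "window") <- window
  attr(out, "low_threshold") <- low_threshold
  class(out) <- c("window_table", class(out))
  out
}

#' @export
glance.window_table <- function(x, ...) {
  thr <- attr(x, "low_threshold")
  det <- !x$undetermined
  tibble(window = attr(x, "window"),
         n_windows = nrow(x),
         n_determined = sum(det),
         n_undetermined = sum(!det),
         n_below_threshold = sum(det & x$n_snps < thr),
         low_threshold = thr,
         total_snps = sum(x$n_snps))
}

#' Fraction of windows holding at least one SNP, by window size
#'
#' For each window size, chromosomes are tiled with half-open windows and
#' the fraction of windows containing one or more sites is reported. By
#' default windows with no non-N sequence are excluded from the denominator
#' (their occupancy cannot be determined); `include_unmapped = TRUE` keeps
#' them.
#'
#' @param sites Variant-site tibble (`chrom`, `pos`).
#' @param asm Reference [assembly()].
#' @param window_sizes Numeric vector of window sizes in bases (non-empty).
#' @param include_unmapped Keep fully-N windows in the denominator?
#' @param category Optional label copied into a `category` column (handy
#'   when binding curves for several site categories).
#' @return An `occupancy_curve` tibble: `window_size`, `n_windows`,
#'   `n_determined`, `n_occupied`, `fraction`.
#' @export
occupancy_curve <- function(sites, asm, window_sizes,
                            include_unmapped = FALSE, category = NULL) {
  if (length(window_sizes) == 0) abort("window_sizes must be non-empty")
  per <- purrr::map(window_sizes, function(w) {
    wt <- window_density(sites, asm, window = w)
    det <- if (include_unmapped) rep(TRUE, nrow(wt)) else !wt$undetermined
    tibble(window_size = w,
           n_windows = nrow(wt),
           n_determined = sum(det),
           n_occupied = sum(det & wt$n_snps > 0),
           fraction = if (sum(det) > 0) sum(det & wt$n_snps > 0) / sum(det) else 0)
  })
  out <- bind_rows(per)
  if (!is.null(category)) out$category <- category
  class(out) <- c("occupancy_curve", class(out))
  out
}

#' Informative-marker fraction from validation genotypes
#'
#' Markers are only informative for association mapping with minor allele
#' frequency of at least ~5%; with only a handful of genotyped animals, the
#' proxy is whether the alternate allele was observed in more than one
#' individual. Variants whose alternate allele is seen in exactly one cat are
#' counted as singletons (possibly rare), the rest as multi-cat (likely
#' informative); the multi-cat percentage (rounded to a whole percent, which
#' is how the extrapolation is conventionally quoted) may be projected onto a
#' larger SNP resource via `extrapolation_base`.
#'
#' @param genotypes Validation genotype tibble: columns `ref`, `alt`, one
#'   observed-genotype column per cat (strings like `"A/G"`; `"."` for no
#'   call), and optionally `discovered_in` (list or comma-separated string)
#'   and `amplimer`.
#' @param cat_cols Character vector naming the per-cat genotype columns;
#'   defaults to every column not among the recognised metadata columns.
#' @param restrict_to Optional character vector: keep only variants whose
#'   `discovered_in` set intersects it (e.g. the six domestic breed cats).
#' @param extrapolation_base Optional SNP-resource size to extrapolate the
#'   informative count onto.
#' @return One-row tibble: `n_scored`, `n_singleton`, `n_multi`,
#'   `singleton_pct`, `multi_pct` (whole percents), and
#'   `extrapolated_informative` (rounded to the nearest thousand; `NA`
#'   without a base).
#' @export
informative_fraction <- function(genotypes, cat_cols = NULL,
                                 restrict_to = NULL,
                                 extrapolation_base = NULL) {
  if (nrow(genotypes) == 0) abort("empty genotype table")
  meta <- c("site_id", "chrom", "pos", "type", "ref", "alt", "discovered_in",
            "amplimer", "confirmed")
  cat_cols <- cat_cols %||% setdiff(names(genotypes), meta)
  if (length(cat_cols) == 0) abort("no per-cat genotype columns found")
  g <- genotypes
  if (!is.null(restrict_to)) {
    disc <- discovered_sets(g)
    g <- g[map_lgl(disc, function(d) length(intersect(d, restrict_to)) > 0), ,
           drop = FALSE]
  }
  carriers <- vapply(seq_len(nrow(g)), function(i) {
    alt <- g$alt[i]
    sum(vapply(cat_cols, function(cc) {
      obs <- g[[cc]][i]
      !is.na(obs) && alt %in% strsplit(obs, "[/|]")[[1]]
    }, logical(1)))
  }, integer(1))
  scored <- carriers >= 1
  n <- sum(scored)
  if (n == 0) abort("no variant with an observed alternate allele")
  n1 <- sum(carriers[scored] == 1)
  nm <- sum(carriers[scored] >= 2)
  multi_pct <- round_half_up(100 * nm / n)
  extrap <- NA_real_
  if (!is.null(extrapolation_base)) {
    extrap <- round_half_up(multi_pct / 100 * extrapolation_base / 1000) * 1000
  }
  tibble(n_scored = n, n_singleton = n1, n_multi = nm,
         singleton_pct = round_half_up(100 * n1 / n),
         multi_pct = multi_pct,
         extrapolated_informative = extrap)
}

discovered_sets <- function(g) {
  if (!"discovered_in" %in% names(g)) {
    abort("genotype table has no discovered_in column")
  }
  if (is.list(g$discovered_in)) g$discovered_in
  else strsplit(g$discovered_in, ",", fixed = TRUE)
}

#' Estimate an individual's homozygous-tract genome fraction from calls
#'
#' Segments the genome by the individual's discovered variant sites: sites
#' closer than `max_gap` are merged into heterozygous segments (each segment
#' extended by `max_gap / 2` at both ends to account for the undetected
#' margin beyond its outermost site), and the homozygous fraction is the
#' genome fraction outside all such segments. This density-based
#' segmentation is nearly unbiased when tracts are much longer than the
#' typical detected-site spacing, unlike all-or-nothing binning, whose
#' boundary bins bias the fraction downward.
#'
#' @param sites Merged sites (with `discoverers`) or per-read records (with
#'   `individual`).
#' @param individual Individual name.
#' @param asm Reference [assembly()].
#' @param max_gap Largest gap (bases) between consecutive sites still joined
#'   into one heterozygous segment. Default 6 kb, a few times the detected
#'   het-site spacing under light coverage of a 1-per-600-bp mosaic.
#' @param chroms Optional chromosome subset (e.g. autosomes only).
#' @return One-row tibble: `individual`, `max_gap`, `n_sites`, `n_segments`,
#'   `het_bases`, `hom_fraction`.
#' @export
tract_homozygosity <- function(sites, individual, asm, max_gap = 6000,
                               chroms = NULL) {
  stopifnot(inherits(asm, "assembly"))
  if ("discoverers" %in% names(sites)) {
    keep <- map_lgl(sites$discoverers, function(d) individual %in% d)
  } else {
    keep <- sites$individual == individual
  }
  s <- sites[keep, , drop = FALSE]
  info <- asm$seqinfo
  if (!is.null(chroms)) {
    info <- info[info$chrom %in% chroms, , drop = FALSE]
    s <- s[s$chrom %in% chroms, , drop = FALSE]
  }
  het_bases <- 0
  n_segments <- 0L
  for (ci in seq_len(nrow(info))) {
    cn <- info$chrom[ci]
    L <- info$length[ci]
    pos <- sort(unique(s$pos[s$chrom == cn]))
    if (length(pos) == 0) next
    brk <- which(diff(pos) > max_gap)
    seg_start <- pmax(pos[c(1L, brk + 1L)] - max_gap / 2, 0)
    seg_end <- pmin(pos[c(brk, length(pos))] + max_gap / 2, L)
    het_bases <- het_bases + sum(seg_end - seg_start)
    n_segments <- n_segments + length(seg_start)
  }
  genome <- sum(info$length)
  tibble(individual = individual, max_gap = max_gap,
         n_sites = nrow(s), n_segments = n_segments,
         het_bases = het_bases,
         hom_fraction = 1 - het_bases / genome)
}
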