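#' Randomly sample candidate sites for empirical validation
#'
#' Uniform sample without replacement from the sites whose discoverer set
#' intersects `restrict_to` (e.g. the six domestic breed cats), deterministic
#' for a fixed seed.
#'
#' @param sites Merged site tibble (needs `discoverers`).
#' @param n Sample size; must not exceed the eligible site count.
#' @param restrict_to Optional character vector of individuals; `NULL` keeps
#'   all sites eligible.
#' @param seed Integer seed.
#' @return Tibble of `n` sampled sites (original row order preserved).
#' @export
sample_candidates <- function(sites, n, restrict_to = NULL, seed) {
  if (missing(seed) || is.null(seed)) abort("seed is required")
  eligible <- sites
  if (!is.null(restrict_to)) {
    keep <- map_lgl(sites$discoverers,
                    function(d) length(intersect(d, restrict_to)) > 0)
    eligible <- sites[keep, , drop = FALSE]
  }
  if (n > nrow(eligible)) {
    abort(paste0("requested ", n, " candidates but only ", nrow(eligible),
                 " site(s) are eligible"))
  }
  idx <- withr::with_seed(seed, sample.int(nrow(eligible), n))
  eligible[sort(idx), , drop = FALSE]
}

#' Keep sites far enough from assembly gaps to be testable
#'
#' Sites within `min_distance` bases of an N run or a contig end are
#' excluded (flanking sequence there is too uncertain for assay/primer
#' design). The bound is inclusive: a site exactly `min_distance` bases from
#' the nearest gap is kept. Distance is measured from the site position to
#' the nearest N character (or just past the contig terminus), so a site
#' immediately adjacent to a gap has distance 1.
#'
#' @param sites Site tibble (`chrom`, `pos`).
#' @param asm Reference [assembly()].
#' @param min_distance Minimum gap distance in bases (default 750).
#' @return The filtered site tibble.
#' @export
filter_gap_distance <- function(sites, asm, min_distance = 750) {
  if (nrow(sites) == 0) return(sites)
  d <- gap_distance(asm, sites$chrom, sites$pos)
  sites[d >= min_distance, , drop = FALSE]
}

#' Empirical confirmation rate of validated variants
#'
#' SNP mode excludes low-quality amplimers (and untested records) from the
#' denominator: the rate is confirmed / assayable. DIP mode keeps every
#' record falling in an amplicon in the denominator, including untested
#' ones — the two conventions intentionally differ, mirroring how such
#' validation experiments are conventionally reported. Percentages are
#' rounded to a whole percent.
#'
#' @param records Validation record tibble: `type` (`"SNP"`/`"DIP"`),
#'   `amplimer` (`"ok"`, `"low_quality"`, `"not_tested"`), `confirmed`
#'   (logical; the alternate allele was observed in the discovering cat).
#' @param kind `"SNP"` or `"DIP"`.
#' @return One-row tibble: `kind`, `n_confirmed`, `denominator`,
#'   `rate_percent`.
#' @export
confirmation_rate <- function(records, kind = c("SNP", "DIP")) {
  kind <- match.arg(kind)
  r <- records[records$type == kind, , drop = FALSE]
  if (nrow(r) == 0) abort(paste0("no ", kind, " validation records"))
  if (kind == "SNP") {
    denom <- sum(r$amplimer == "ok")
    num <- sum(r$amplimer == "ok" & r$confirmed %in% TRUE)
  } else {
    denom <- nrow(r)
    num <- sum(r$confirmed %in% TRUE)
  }
  if (denom == 0) abort("no assayable records in denominator")
  tibble(kind = kind, n_confirmed = num, denominator = denom,
         rate_percent = round_half_up(100 * num / denom))
}

#' Build validation records by error-free re-sequencing of truth genotypes
#'
#' Emulates the wet-lab confirmation step on synthetic data: every sampled
#' site is re-typed directly from the truth genotypes, so a true site is
#' confirmed exactly when its discovering individual really carries the
#' alternate allele. Injecting known-false sites (e.g. sequencing-error
#' calls) therefore yields a confirmation rate of true/(true + false).
#'
#' @param sampled Sampled site tibble (needs `discoverers`).
#' @param truth A `truth_set`.
#' @return Validation record tibble suitable for [confirmation_rate()].
#' @export
resequence_against_truth <- function(sampled, truth) {
  stopifnot(inherits(truth, "truth_set"))
  key <- paste(truth$variants$chrom, truth$variants$pos, truth$variants$alt)
  confirmed <- vapply(seq_len(nrow(sampled)), function(i) {
    j <- match(paste(sampled$chrom[i], sampled$pos[i], sampled$alt[i]), key)
    if (is.na(j)) return(FALSE)
    disc <- sampled$discoverers[[i]]
    cols <- match(disc, colnames(truth$carry1))
    cols <- cols[!is.na(cols)]
    any(truth$carry1[j, cols] | truth$carry2[j, cols])
  }, logical(1))
  tibble(chrom = sampled$chrom, pos = sampled$pos, type = sampled$type,
         alt = sampled$alt, amplimer = "ok", confirmed = confirmed)
}

#' Synthetic validation genotype table with the survey's marginal counts
#'
#' A stand-in, constructed in code, for a published 94-variant PCR validation
#' genotype table that is not redistributed here: 94 SNP records (92
#' confirmed, 1 low-quality amplimer, 1 unconfirmed) of which, among the 92
#' scored, 24 are singletons and 68 multi-cat, with the domestic-discovered
#' subset (57) holding 50 multi-cat variants; plus 45 DIP records (43
#' validated, 1 not tested, 1 failed). Only these marginal counts are
#' reproduced; individual rows are synthetic.
#'
#' @param cats Character vector of genotyped cat names (first six are
#'   treated as the domestic breed cats).
#' @return Tibble with one row per validated variant: `site_id`, `type`,
#'   `ref`, `alt`, `discovered_in`, `amplimer`, `confirmed`, and one
#'   observed-genotype column per cat.
#' @export
example_validation_table <- function(cats = default_individuals()$name) {
  domestic <- cats[1:6]
  special <- setdiff(cats, domestic)
  ref <- "A"; alt <- "G"
  rows <- list()
  add <- function(n, discovered, carriers, amplimer, confirmed) {
    for (k in seq_len(n)) {
      obs <- setNames(rep("A/A", length(cats)), cats)
      carrier_cats <- carriers(k)
      obs[carrier_cats] <- "A/G"
      rows[[length(rows) + 1L]] <<- c(
        list(type = "SNP", ref = ref, alt = alt,
             discovered_in = paste(discovered(k), collapse = ","),
             amplimer = amplimer, confirmed = confirmed),
        as.list(obs))
    }
  }
  # domestic-discovered, scored: 7 singleton + 50 multi = 57
  add(7, function(k) domestic[(k - 1) %% 6 + 1],
      function(k) domestic[(k - 1) %% 6 + 1], "ok", TRUE)
  add(50, function(k) domestic[(k - 1) %% 6 + 1],
      function(k) domestic[c((k - 1) %% 6 + 1, k %% 6 + 1)], "ok", TRUE)
  # discovered only in the inbred and/or wildcat, scored: 17 singleton + 18 multi
  add(17, function(k) special[(k - 1) %% 2 + 1],
      function(k) special[(k - 1) %% 2 + 1], "ok", TRUE)
  add(18, function(k) special[(k - 1) %% 2 + 1],
      function(k) c(special[(k - 1) %% 2 + 1], domestic[(k - 1) %% 6 + 1]),
      "ok", TRUE)
  # the low-quality amplimer (wildcat) and the unconfirmed ragdoll variant
  add(1, function(k) special[1], function(k) character(0), "low_quality", FALSE)
  add(1, function(k) domestic[4], function(k) character(0), "ok", FALSE)
  snps <- bind_rows(purrr::map(rows, as_tibble))
  dip_status <- c(rep(list(c("ok", TRUE)), 43), list(c("not_tested", FALSE)),
                  list(c("ok", FALSE)))
  dips <- bind_rows(purrr::map(seq_along(dip_status), function(k) {
    obs <- setNames(rep(list("."), length(cats)), cats)
    as_tibble(c(list(type = "DIP", ref = "AG", alt = "A",
                     discovered_in = domestic[(k - 1) %% 6 + 1],
                     amplimer = dip_status[[k]][1],
                     confirmed = as.logical(dip_status[[k]][2])),
                obs))
  }))
  out <- bind_rows(snps, dips)
  out$site_id <- sprintf("var%03d", seq_len(nrow(out)))
  select(out, "site_id", dplyr::everything())
}
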