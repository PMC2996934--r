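#' Simulate a population and its truth variant catalog
#'
#' Generates a consensus reference with N-gap runs, then lays down three
#' classes of polymorphic sites on the non-N sequence: shared domestic sites
#' (population allele frequency drawn from a discretized symmetric
#' Beta(0.5, 0.5) spectrum, genotypes sampled per haplotype), divergent sites
#' fixed in the wildcat, and private heterozygous sites for the inbred
#' individual confined to the heterozygous tracts of a two-state
#' (homozygous/heterozygous) tract process. Site densities are calibrated so
#' a domestic cat's expected heterozygosity equals `domestic_het_rate` and
#' the inbred mosaic's stationary homozygous fraction equals
#' `inbred_homozygous_fraction`. A configurable fraction of sites are short
#' indels (DIPs) instead of SNPs.
#'
#' Each individual's genotypes are drawn from an individual-keyed random
#' stream, so adding or removing an individual never perturbs the others.
#'
#' @param model A [population_model()].
#' @param seed Integer seed; runs are byte-reproducible for a fixed seed.
#' @return An object of class `truth_set`: the reference [assembly()], the
#'   individual table, a `variants` tibble (`chrom`, `pos` 0-based, `type`,
#'   `ref`, `alt`, `class`, `freq`), per-haplotype carrier matrices, and the
#'   inbred tract table.
#' @export
simulate_population <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  if (missing(seed) || is.null(seed)) abort("seed is required")
  sp <- freq_spectrum(model$freq_grid_size)
  inds <- model$individuals
  chrs <- model$chromosomes
  has_wildcat <- any(inds$class == "wildcat")
  inbred_names <- inds$name[inds$class == "inbred"]
  BASES <- c("A", "C", "G", "T")

  seqs <- setNames(vector("list", nrow(chrs)), chrs$name)
  site_list <- list()
  tract_list <- list()

  withr::with_seed(child_seed(seed, "population"), {
    for (ci in seq_len(nrow(chrs))) {
      cn <- chrs$name[ci]
      L <- as.integer(chrs$length[ci])
      chars <- sample(BASES, L, replace = TRUE)

      ng <- rpois(1, L * model$gap_start_prob)
      if (ng > 0) {
        gs <- sample.int(L, min(ng, L))
        gl <- rgeom(length(gs), 1 / model$gap_mean_length) + 1L
        ir <- IRanges::reduce(IRanges::IRanges(start = gs, width = gl))
        ir <- IRanges::restrict(ir, start = 1L, end = L)
        for (k in seq_along(ir)) {
          chars[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- "N"
        }
      }
      nonN <- which(chars != "N")

      # inbred tract mosaic (shared by all inbred individuals if several)
      tr <- sim_tracts(L, model$inbred_homozygous_fraction,
                       model$inbred_tract_mean_length)
      tract_list[[cn]] <- mutate(tr, chrom = cn, .before = 1)

      # site positions by class (1-based for now)
      s_shared <- model$domestic_het_rate / sp$e_het
      n_sh <- rpois(1, s_shared * length(nonN))
      pos_sh <- sample(nonN, min(n_sh, length(nonN)))
      pos_wc <- integer(0)
      if (has_wildcat && model$wildcat_extra_rate > 0) {
        n_wc <- rpois(1, model$wildcat_extra_rate * length(nonN))
        pos_wc <- sample(nonN, min(n_wc, length(nonN)))
      }
      pos_ib <- integer(0)
      if (length(inbred_names) > 0 && model$domestic_het_rate > 0) {
        het_tr <- tr[tr$state == "het", ]
        if (nrow(het_tr) > 0) {
          idx <- findInterval(nonN - 1L, het_tr$start)
          elig <- nonN[idx >= 1 & (nonN - 1L) < het_tr$end[pmax(idx, 1L)]]
          n_ib <- rpois(1, model$domestic_het_rate * length(elig))
          if (length(elig) > 0) pos_ib <- sample(elig, min(n_ib, length(elig)))
        }
      }
      cls <- c(rep("shared", length(pos_sh)),
               rep("wildcat_private", length(pos_wc)),
               rep("inbred_private", length(pos_ib)))
      pos <- c(pos_sh, pos_wc, pos_ib)
      keep <- !duplicated(pos)
      pos <- pos[keep]; cls <- cls[keep]
      o <- order(pos)
      pos <- pos[o]; cls <- cls[o]
      ns <- length(pos)
      if (ns == 0) {
        seqs[[cn]] <- paste(chars, collapse = "")
        next
      }

      # SNP vs DIP; DIPs need isolation from neighbours and from N
      is_dip <- runif(ns) < model$dip_fraction
      dlen <- pmin(rgeom(ns, 0.6) + 1L, 5L)
      is_ins <- runif(ns) < 0.5
      nb_dist <- pmin(c(diff(pos), Inf), c(Inf, diff(pos)))
      ok_dip <- is_dip & nb_dist > 11 & (pos + dlen) <= L
      del_hits_n <- vapply(which(ok_dip & !is_ins), function(i) {
        any(chars[(pos[i] + 1L):(pos[i] + dlen[i])] == "N")
      }, logical(1))
      ok_dip[which(ok_dip & !is_ins)[del_hits_n]] <- FALSE
      type <- ifelse(ok_dip, "DIP", "SNP")

      ref <- chars[pos]
      alt <- character(ns)
      snp_i <- which(type == "SNP")
      alt[snp_i] <- vapply(snp_i, function(i)
        sample(setdiff(BASES, chars[pos[i]]), 1), character(1))
      for (i in which(type == "DIP")) {
        if (is_ins[i]) {
          alt[i] <- paste0(ref[i], paste(sample(BASES, dlen[i], TRUE), collapse = ""))
        } else {
          ref[i] <- paste(chars[pos[i]:(pos[i] + dlen[i])], collapse = "")
          alt[i] <- chars[pos[i]]
        }
      }
      fr <- rep(NA_real_, ns)
      sh_i <- cls == "shared"
      fr[sh_i] <- sample(sp$f, sum(sh_i), replace = TRUE, prob = sp$p)

      site_list[[cn]] <- tibble(chrom = cn, pos = pos - 1L, type = type,
                                ref = ref, alt = alt, class = cls, freq = fr)
      seqs[[cn]] <- paste(chars, collapse = "")
    }
  })

  variants <- bind_rows(site_list)
  if (nrow(variants) == 0) {
    variants <- tibble(chrom = character(), pos = integer(), type = character(),
                       ref = character(), alt = character(), class = character(),
                       freq = double())
  }
  nv <- nrow(variants)
  nind <- nrow(inds)
  carry1 <- matrix(FALSE, nv, nind, dimnames = list(NULL, inds$name))
  carry2 <- matrix(FALSE, nv, nind, dimnames = list(NULL, inds$name))
  is_x_chrom <- chrs$name[chrs$is_X]
  site_on_x <- variants$chrom %in% is_x_chrom

  for (j in seq_len(nind)) {
    nm <- inds$name[j]
    cl <- inds$class[j]
    haploid <- site_on_x & inds$sex[j] == "M"
    withr::with_seed(child_seed(seed, paste0("genotype:", nm)), {
      sh <- which(variants$class == "shared")
      if (length(sh) > 0 && cl != "inbred") {
        f <- variants$freq[sh]
        carry1[sh, j] <- runif(length(sh)) < f
        c2 <- runif(length(sh)) < f
        carry2[sh, j] <- c2 & !haploid[sh]
      }
      if (cl == "wildcat") {
        wp <- which(variants$class == "wildcat_private")
        carry1[wp, j] <- TRUE
        carry2[wp, j] <- !haploid[wp]
      }
      if (cl == "inbred") {
        ip <- which(variants$class == "inbred_private")
        if (length(ip) > 0) {
          on1 <- runif(length(ip)) < 0.5
          carry1[ip, j] <- on1 | haploid[ip]
          carry2[ip, j] <- (!on1) & !haploid[ip]
        }
      }
    })
  }

  # consensus-from: substitute the donor's first haplotype as the reference
  if (!is.null(model$consensus_from) && nv > 0) {
    dj <- match(model$consensus_from, inds$name)
    donor_haploid <- site_on_x & inds$sex[dj] == "M"
    # move donor hap1 DIPs to hap2 (the consensus absorbs no indels)
    dip_i <- which(variants$type == "DIP" & carry1[, dj])
    for (i in dip_i) {
      if (donor_haploid[i]) {
        carry1[i, dj] <- FALSE
      } else {
        carry2[i, dj] <- TRUE
        carry1[i, dj] <- FALSE
      }
    }
    sw <- which(variants$type == "SNP" & carry1[, dj])
    if (length(sw) > 0) {
      old_ref <- variants$ref[sw]
      variants$ref[sw] <- variants$alt[sw]
      variants$alt[sw] <- old_ref
      for (cn in unique(variants$chrom[sw])) {
        ii <- sw[variants$chrom[sw] == cn]
        s <- strsplit(seqs[[cn]], "", fixed = TRUE)[[1]]
        s[variants$pos[ii] + 1L] <- variants$ref[ii]
        seqs[[cn]] <- paste(s, collapse = "")
      }
      for (j in seq_len(nind)) {
        haploid <- site_on_x & inds$sex[j] == "M"
        carry1[sw, j] <- xor(carry1[sw, j], TRUE)
        nh <- sw[!haploid[sw]]
        carry2[nh, j] <- xor(carry2[nh, j], TRUE)
      }
    }
  }

  # keep only sites where some haplotype differs from the (final) reference
  poly <- rowSums(carry1) + rowSums(carry2) > 0
  variants <- variants[poly, , drop = FALSE]
  carry1 <- carry1[poly, , drop = FALSE]
  carry2 <- carry2[poly, , drop = FALSE]

  tracts <- bind_rows(tract_list)
  out <- list(
    assembly = assembly(unlist(seqs)),
    individuals = inds,
    chromosomes = chrs,
    variants = as_tibble(variants),
    carry1 = carry1,
    carry2 = carry2,
    tracts = tracts,
    model = model,
    seed = seed
  )
  class(out) <- "truth_set"
  out
}

# Alternating exponential homozygous/heterozygous tracts with stationary
# homozygous probability f and mean homozygous tract length mean_hom.
sim_tracts <- function(L, f, mean_hom) {
  if (f >= 1) return(tibble(start = 0L, end = as.integer(L), state = "hom"))
  if (f <= 0) return(tibble(start = 0L, end = as.integer(L), state = "het"))
  mean_het <- mean_hom * (1 - f) / f
  state <- if (runif(1) < f) "hom" else "het"
  pos <- 0L
  starts <- integer(0); ends <- integer(0); states <- character(0)
  while (pos < L) {
    m <- if (state == "hom") mean_hom else mean_het
    len <- max(1L, as.integer(ceiling(stats::rexp(1, 1 / m))))
    e <- min(L, pos + len)
    starts <- c(starts, pos); ends <- c(ends, e); states <- c(states, state)
    pos <- e
    state <- if (state == "hom") "het" else "hom"
  }
  tibble(start = starts, end = as.integer(ends), state = states)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", nrow(x$individuals), " individual(s), ",
      format(sum(x$assembly$seqinfo$length), big.mark = ","), " bp, ",
      format(nrow(x$variants), big.mark = ","), " truth variant(s) (",
      sum(x$variants$type == "SNP"), " SNP / ", sum(x$variants$type == "DIP"),
      " DIP)\n", sep = "")
  invisible(x)
}

#' Per-individual truth genotype strings
#'
#' @param truth A `truth_set`.
#' @return Tibble (one row per truth variant) of phased genotype strings,
#'   one column per individual; hemizygous calls are single-allele (`"1"`).
#' @export
truth_genotypes <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  inds <- truth$individuals
  if (nrow(truth$variants) == 0) {
    return(as_tibble(setNames(rep(list(character(0)), nrow(inds)), inds$name)))
  }
  is_x <- truth$variants$chrom %in% truth$chromosomes$name[truth$chromosomes$is_X]
  out <- purrr::map(seq_len(nrow(inds)), function(j) {
    haploid <- is_x & inds$sex[j] == "M"
    g <- paste0(as.integer(truth$carry1[, j]), "|",
                as.integer(truth$carry2[, j]))
    g[haploid] <- as.character(as.integer(truth$carry1[haploid, j]))
    g
  })
  names(out) <- inds$name
  as_tibble(out)
}

#' Number of haplotypes an individual carries on a chromosome
#'
#' @param truth A `truth_set`.
#' @param individual Individual name.
#' @param chrom Chromosome name.
#' @return 1 (male X) or 2.
#' @export
n_haplotypes <- function(truth, individual, chrom) {
  j <- match(individual, truth$individuals$name)
  if (is.na(j)) abort(paste0("unknown individual: ", individual))
  ci <- match(chrom, truth$chromosomes$name)
  if (is.na(ci)) abort(paste0("unknown chromosome: ", chrom))
  if (truth$chromosomes$is_X[ci] && truth$individuals$sex[j] == "M") 1L else 2L
}

# Variant table (0-based pos, ref, alt, type) carried by one haplotype of one
# individual on one chromosome, sorted by position.
haplotype_variants <- function(truth, individual, chrom, hap) {
  j <- match(individual, truth$individuals$name)
  if (is.na(j)) abort(paste0("unknown individual: ", individual))
  if (hap > n_haplotypes(truth, individual, chrom)) {
    abort(paste0(individual, " has no haplotype ", hap, " on ", chrom))
  }
  carry <- if (hap == 1) truth$carry1[, j] else truth$carry2[, j]
  v <- truth$variants[carry & truth$variants$chrom == chrom, , drop = FALSE]
  arrange(v, .data$pos)
}

#' Reconstruct one haplotype sequence
#'
#' Applies the haplotype's truth variants to the reference chromosome.
#' Requesting the second haplotype of a male on chromosome X is an error
#' (hemizygosity: exactly one X haplotype exists).
#'
#' @param truth A `truth_set`.
#' @param individual Individual name.
#' @param chrom Chromosome name.
#' @param hap Haplotype index (1 or 2).
#' @return A character string.
#' @export
haplotype_sequence <- function(truth, individual, chrom, hap = 1) {
  v <- haplotype_variants(truth, individual, chrom, hap)
  refseq <- truth$assembly$sequences[[chrom]]
  apply_variants(refseq, v)$seq
}

# Apply sorted variants to a reference substring [s0, e0) (0-based half-open,
# defaults to the whole sequence); returns the edited sequence and CIGAR.
apply_variants <- function(refseq, v, s0 = 0L, e0 = nchar(refseq)) {
  if (nrow(v) > 0) {
    rlen <- nchar(v$ref)
    keep <- v$pos >= s0 & (v$pos + pmax(rlen, 1L)) <= (e0 - 1L + (v$type == "SNP"))
    # SNPs may sit on the final base; DIPs must leave >= 1 reference base after
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) == 0) {
    return(list(seq = substr(refseq, s0 + 1L, e0), cigar = paste0(e0 - s0, "M")))
  }
  pieces <- character(0)
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len == 0) return()
    k <- length(ops)
    if (k > 0 && ops[k] == op) {
      lens[k] <<- lens[k] + len
    } else {
      ops <<- c(ops, op); lens <<- c(lens, len)
    }
  }
  cur <- s0
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    pre <- p - cur
    if (pre > 0) pieces <- c(pieces, substr(refseq, cur + 1L, p))
    push("M", pre)
    if (v$type[i] == "SNP") {
      pieces <- c(pieces, v$alt[i])
      push("M", 1L)
      cur <- p + 1L
    } else if (nchar(v$ref[i]) > 1L) {       # deletion: anchor kept
      pieces <- c(pieces, v$alt[i])
      push("M", 1L)
      push("D", nchar(v$ref[i]) - 1L)
      cur <- p + nchar(v$ref[i])
    } else {                                  # insertion after anchor
      pieces <- c(pieces, v$alt[i])
      push("M", 1L)
      push("I", nchar(v$alt[i]) - 1L)
      cur <- p + 1L
    }
  }
  if (cur < e0) {
    pieces <- c(pieces, substr(refseq, cur + 1L, e0))
    push("M", e0 - cur)
  }
  list(seq = paste(pieces, collapse = ""), cigar = cigar_string(ops, lens))
}

#' Realized fraction of the genome inside homozygous tracts
#'
#' @param truth A `truth_set`.
#' @return Fraction in `[0, 1]`.
#' @export
truth_hom_fraction <- function(truth) {
  tr <- truth$tracts
  sum(tr$end[tr$state == "hom"] - tr$start[tr$state == "hom"]) /
    sum(tr$end - tr$start)
}
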