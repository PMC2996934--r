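#' Pipeline configuration
#'
#' Bundles every stage's parameters with a single global seed and output
#' directory. The configuration round-trips through YAML unchanged
#' ([write_config()] / [read_config()]), so a run is fully described by one
#' file plus the seed.
#'
#' @param seed Global integer seed; stages and individuals derive child
#'   seeds from it by stable hashing.
#' @param out_dir Output directory.
#' @param population A [population_model()].
#' @param reads A [read_model()].
#' @param nqs An [nqs_params()].
#' @param window_sizes Window sizes (bases) for the occupancy curve.
#' @param density_window Window (bases) for the density table (default 1 Mb
#'   scaled is usually too coarse for a desk genome; default here 100 kb).
#' @param panel_spacing Panel window spacing in bases.
#' @param panel_backfill Backfill A-less panel windows from B/C?
#' @param validation_n Number of candidate sites to sample for validation.
#' @param min_gap_distance Gap-distance filter for validation candidates.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("lightsnp_run_"),
                            population = population_model(),
                            reads = read_model(),
                            nqs = nqs_params(),
                            window_sizes = c(5e3, 15e3, 50e3, 150e3),
                            density_window = 1e5,
                            panel_spacing = 15000,
                            panel_backfill = TRUE,
                            validation_n = 94,
                            min_gap_distance = 750,
                            log_level = c("info", "quiet")) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 population = population, reads = reads, nqs = nqs,
                 window_sizes = window_sizes, density_window = density_window,
                 panel_spacing = panel_spacing, panel_backfill = panel_backfill,
                 validation_n = validation_n,
                 min_gap_distance = min_gap_distance,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$population <- unclass(x$population)
  x$population$chromosomes <- as.list(as.data.frame(x$population$chromosomes))
  x$population$individuals <- as.list(as.data.frame(x$population$individuals))
  x$reads <- unclass(x$reads)
  x$nqs <- unclass(x$nqs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pop <- x$population
  pop$chromosomes <- as_tibble(as.data.frame(pop$chromosomes))
  pop$individuals <- as_tibble(as.data.frame(pop$individuals))
  population <- do.call(population_model,
                        pop[intersect(names(pop), names(formals(population_model)))])
  rm_args <- x$reads[intersect(names(x$reads), names(formals(read_model)))]
  nqs_args <- x$nqs[intersect(names(x$nqs), names(formals(nqs_params)))]
  pipeline_config(seed = x$seed, out_dir = x$out_dir,
                  population = population,
                  reads = do.call(read_model, rm_args),
                  nqs = do.call(nqs_params, nqs_args),
                  window_sizes = unlist(x$window_sizes),
                  density_window = x$density_window,
                  panel_spacing = x$panel_spacing,
                  panel_backfill = x$panel_backfill,
                  validation_n = x$validation_n,
                  min_gap_distance = x$min_gap_distance,
                  log_level = x$log_level)
}

#' Run the full discovery pipeline: simulate, call, summarise, design, validate
#'
#' Executes the stages in order — population and read simulation, NQS
#' variant calling, non-redundant merging and categorization, resource
#' statistics (rate table, category table, window densities, occupancy
#' curves), panel design, and truth-based validation of a random candidate
#' sample — writing every artifact to `config$out_dir`. Outputs are
#' byte-identical across runs with the same configuration and seed (no
#' timestamps are embedded). Any stage failure aborts with the stage name.
#'
#' Written files: `reference.fasta`, `truth.vcf`, `tracts.tsv`,
#' `reads.fastq`, `alignments.sam`, `errors.tsv`, `calls.vcf`, `rates.tsv`,
#' `category_table.tsv`, `windows.bedgraph`, `occupancy.tsv`, `panel.bed`,
#' `panel_summary.tsv`, `validation.tsv`, `summary.tsv`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_report`: per-stage timings plus the main
#'   result objects (truth, callset, sites, tables, panel, validation rates).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_info <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    log_info("stage %-10s %8.2fs", name, timings[[name]])
    out
  }

  truth <- stage("simulate", simulate_population(config$population, config$seed))
  rs <- stage("reads", simulate_reads(truth, config$reads, config$seed))
  stage("write_truth", write_truth(truth, config$out_dir, rs))

  cs <- stage("call", call_variants(rs$reads, truth$assembly, config$nqs))
  sites <- stage("merge", merge_sites(cs))

  inbred <- truth$individuals$name[truth$individuals$class == "inbred"]
  wildcat <- truth$individuals$name[truth$individuals$class == "wildcat"]
  sites <- stage("categorize", categorize(
    sites,
    inbred = if (length(inbred)) inbred[1] else "Cinnamon",
    wildcat = if (length(wildcat)) wildcat[1] else "Nancy",
    individuals = truth$individuals$name))

  stats <- stage("stats", {
    rates <- snp_rate_table(cs, rs$reads, truth$assembly)
    ctab <- category_table(sites, truth$assembly)
    wt <- window_density(sites[sites$type == "SNP", ], truth$assembly,
                         window = config$density_window)
    occ <- bind_rows(
      occupancy_curve(sites[sites$cat_A & sites$type == "SNP", ], truth$assembly,
                      config$window_sizes, category = "A"),
      occupancy_curve(sites[sites$cat_B & sites$type == "SNP", ], truth$assembly,
                      config$window_sizes, category = "B"),
      occupancy_curve(sites[sites$type == "SNP", ], truth$assembly,
                      config$window_sizes, category = "C"))
    list(rates = rates, ctab = ctab, windows = wt, occupancy = occ)
  })

  panel <- stage("panel", design_panel(sites[sites$type == "SNP", ],
                                       truth$assembly,
                                       spacing = config$panel_spacing,
                                       backfill = config$panel_backfill))

  validation <- stage("validate", {
    # as in the original survey, candidates are drawn from sites discovered
    # in the ordinary domestic individuals
    domestic <- truth$individuals$name[truth$individuals$class == "domestic"]
    snp_sites <- sites[sites$type == "SNP", ]
    if (length(domestic) > 0) {
      elig <- map_lgl(snp_sites$discoverers,
                      function(d) length(intersect(d, domestic)) > 0)
      snp_sites <- snp_sites[elig, , drop = FALSE]
    }
    n <- min(config$validation_n, nrow(snp_sites))
    if (n > 0) {
      cand <- sample_candidates(snp_sites, n, seed = child_seed(config$seed, "validate"))
      cand <- filter_gap_distance(cand, truth$assembly, config$min_gap_distance)
    } else {
      cand <- snp_sites
    }
    dip_sites <- sites[sites$type == "DIP", ]
    recs <- bind_rows(
      if (nrow(cand) > 0) resequence_against_truth(cand, truth),
      if (nrow(dip_sites) > 0) {
        nd <- min(45, nrow(dip_sites))
        dcand <- sample_candidates(dip_sites, nd,
                                   seed = child_seed(config$seed, "validate_dips"))
        resequence_against_truth(dcand, truth)
      })
    if (nrow(recs) == 0) {
      recs <- tibble(chrom = character(), pos = integer(), type = character(),
                     alt = character(), amplimer = character(),
                     confirmed = logical())
    }
    rates <- bind_rows(
      if (any(recs$type == "SNP")) confirmation_rate(recs, "SNP"),
      if (any(recs$type == "DIP")) confirmation_rate(recs, "DIP"))
    list(records = recs, rates = rates)
  })

  stage("write", {
    out <- config$out_dir
    write_vcf(sites, file.path(out, "calls.vcf"), asm = truth$assembly)
    readr::write_tsv(stats$rates, file.path(out, "rates.tsv"))
    readr::write_tsv(stats$ctab, file.path(out, "category_table.tsv"))
    bed <- stats$windows
    writeLines(sprintf("%s\t%d\t%d\t%d", bed$chrom, bed$start, bed$end,
                       bed$n_snps),
               file.path(out, "windows.bedgraph"))
    readr::write_tsv(as_tibble(stats$occupancy), file.path(out, "occupancy.tsv"))
    write_panel_bed(panel, file.path(out, "panel.bed"))
    readr::write_tsv(panel_summary(panel), file.path(out, "panel_summary.tsv"))
    readr::write_tsv(validation$records, file.path(out, "validation.tsv"))
    summary_tbl <- tibble(
      metric = c("n_truth_variants", "n_records", "n_sites", "n_sites_A",
                 "n_sites_B", "n_sites_C", "panel_assays",
                 "panel_covered_fraction",
                 paste0("snps_", stats$rates$individual)),
      value = c(nrow(truth$variants), nrow(cs$records), nrow(sites),
                sum(sites$cat_A), sum(sites$cat_B), sum(sites$cat_C),
                nrow(panel$selected), panel$covered_fraction,
                stats$rates$snp_count))
    readr::write_tsv(summary_tbl, file.path(out, "summary.tsv"))
  })

  report <- list(config = config, timings = timings, truth = truth,
                 reads = rs, callset = cs, sites = sites, stats = stats,
                 panel = panel, validation = validation)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$config$seed, ", out_dir ", x$config$out_dir,
      "\n", sep = "")
  cat("  truth variants: ", nrow(x$truth$variants),
      "; call records: ", nrow(x$callset$records),
      "; non-redundant sites: ", nrow(x$sites), "\n", sep = "")
  cat("  categories A/B/C: ", sum(x$sites$cat_A), "/", sum(x$sites$cat_B),
      "/", sum(x$sites$cat_C), "; panel assays: ", nrow(x$panel$selected),
      " (covered ", sprintf("%.2f", x$panel$covered_fraction), ")\n", sep = "")
  if (nrow(x$validation$rates) > 0) {
    cat("  validation: ",
        paste(sprintf("%s %d/%d = %d%%", x$validation$rates$kind,
                      x$validation$rates$n_confirmed,
                      x$validation$rates$denominator,
                      x$validation$rates$rate_percent), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
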