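#' Design a spacing-based genotyping panel
#'
#' Tiles the genome into windows of `spacing` bases and, in each window,
#' selects the category-A site nearest the window midpoint (ties break to
#' the smaller coordinate). Windows lacking an A site are, with
#' `backfill = TRUE`, filled with the nearest-midpoint category-B site, then
#' category-C. The covered fraction counts windows with an A selection over
#' determined windows (windows with any non-N sequence), so it equals the
#' A-site window occupancy at the same window size. A greedy minimum-distance
#' walk over A sites is available with `method = "greedy"`.
#'
#' Because selection is windowed, two sites selected in adjacent windows can
#' be closer than `spacing`; the mean inter-selection gap still approaches
#' genome length / selections on evenly covered input.
#'
#' @param sites Categorized sites from [categorize()].
#' @param asm Reference [assembly()].
#' @param spacing Window size in bases (default 15,000).
#' @param backfill Fill A-less windows from categories B then C?
#' @param method `"window"` (default) or `"greedy"`.
#' @return A `panel_design`: list with `selected` (tibble: site columns plus
#'   `window`, `source` category), `spacing`, `covered_fraction`, `counts`
#'   (named: A, backfill_B, backfill_C), `n_windows`, `n_determined`.
#' @export
design_panel <- function(sites, asm, spacing = 15000, backfill = TRUE,
                         method = c("window", "greedy")) {
  stopifnot(inherits(asm, "assembly"))
  method <- match.arg(method)
  if (spacing <= 0) abort("spacing must be positive")
  if (!all(c("cat_A", "cat_B", "cat_C") %in% names(sites))) {
    abort("sites must be categorized (see categorize())")
  }
  wt <- window_density(sites[0, ], asm, window = spacing)
  n_windows <- nrow(wt)
  n_det <- sum(!wt$undetermined)

  if (method == "greedy") {
    sel <- list()
    a <- arrange(sites[sites$cat_A, , drop = FALSE], .data$chrom, .data$pos)
    for (cn in unique(a$chrom)) {
      p <- a[a$chrom == cn, ]
      last <- -Inf
      keep <- logical(nrow(p))
      for (i in seq_len(nrow(p))) {
        if (p$pos[i] - last >= spacing) {
          keep[i] <- TRUE
          last <- p$pos[i]
        }
      }
      sel[[cn]] <- p[keep, ]
    }
    selected <- bind_rows(sel)
    selected$window <- floor(selected$pos / spacing)
    selected$source <- "A"
    covered <- if (n_det > 0) {
      length(unique(paste(selected$chrom, selected$window))) / n_det
    } else 0
    out <- list(selected = selected, spacing = spacing, method = method,
                covered_fraction = min(covered, 1),
                counts = c(A = nrow(selected), backfill_B = 0L, backfill_C = 0L),
                n_windows = n_windows, n_determined = n_det)
    class(out) <- "panel_design"
    return(out)
  }

  s <- sites
  s$category <- ifelse(s$cat_A, "A", ifelse(s$cat_B, "B", "C"))
  if (!backfill) s <- s[s$cat_A, , drop = FALSE]
  if (nrow(s) == 0) {
    selected <- mutate(s, window = integer(0), source = character(0))
  } else {
    lens <- asm$seqinfo$length[match(s$chrom, asm$seqinfo$chrom)]
    s$window <- floor(s$pos / spacing)
    win_start <- s$window * spacing
    win_end <- pmin(win_start + spacing, lens)
    mid <- (win_start + win_end) / 2
    s$mid_dist <- abs(s$pos - mid)
    selected <- s |>
      mutate(cat_rank = match(.data$category, c("A", "B", "C"))) |>
      group_by(.data$chrom, .data$window) |>
      arrange(.data$cat_rank, .data$mid_dist, .data$pos, .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      arrange(.data$chrom, .data$pos) |>
      mutate(source = .data$category) |>
      select(-"cat_rank", -"mid_dist")
  }
  n_a <- sum(selected$source == "A")
  out <- list(
    selected = selected, spacing = spacing, method = method,
    covered_fraction = if (n_det > 0) n_a / n_det else 0,
    counts = c(A = n_a,
               backfill_B = sum(selected$source == "B"),
               backfill_C = sum(selected$source == "C")),
    n_windows = n_windows, n_determined = n_det)
  class(out) <- "panel_design"
  out
}

#' Summarise a panel design
#'
#' @param design A `panel_design` from [design_panel()].
#' @return One-row tibble: `n_assays`, `n_A`, `n_backfilled`,
#'   `covered_fraction`, `mean_gap` (mean distance between consecutive
#'   selections on a chromosome; `NA` with fewer than two selections).
#' @export
panel_summary <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  sel <- arrange(design$selected, .data$chrom, .data$pos)
  gaps <- unlist(purrr::map(split(sel$pos, sel$chrom), diff))
  tibble(n_assays = nrow(sel),
         n_A = unname(design$counts[["A"]]),
         n_backfilled = unname(design$counts[["backfill_B"]] +
                                 design$counts[["backfill_C"]]),
         covered_fraction = if (nrow(sel) > 0) design$covered_fraction else 0,
         mean_gap = if (length(gaps) > 0) mean(gaps) else NA_real_)
}

#' @export
print.panel_design <- function(x, ...) {
  cat("<panel_design> spacing ", format(x$spacing, big.mark = ","), " bp (",
      x$method, "): ", nrow(x$selected), " assay(s), ",
      unname(x$counts[["A"]]), " from category A, covered fraction ",
      sprintf("%.3f", x$covered_fraction), "\n", sep = "")
  invisible(x)
}

#' Write selected panel sites to BED (0-based half-open)
#'
#' @param design A `panel_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(design, path) {
  sel <- arrange(design$selected, .data$chrom, .data$pos)
  lines <- sprintf("%s\t%d\t%d\t%s_%s", sel$chrom, sel$pos, sel$pos + 1L,
                   sel$source, sel$alt)
  writeLines(lines, path)
  invisible(path)
}
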