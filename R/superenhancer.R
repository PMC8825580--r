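# ROSE-style super-enhancer identification: TSS-filtered stitching of
# H3K27ac peaks, background-subtracted signal, rank-curve inflection cutoff
# and proximity-based gene assignment.

#' Super-enhancer calling parameters
#'
#' @param stitch_gap Maximum gap (bp) bridged when stitching peaks into
#'   enhancer domains (default 12500).
#' @param tss_exclusion Half-width (bp) of the TSS exclusion zone; peaks
#'   fully inside `tss +/- tss_exclusion` are dropped before stitching
#'   (default 2500).
#' @param gene_window Proximity window (bp) for assigning active genes to
#'   super-enhancers (default 50000).
#' @return A list of class `se_params`.
#' @export
se_params <- function(stitch_gap = 12500L, tss_exclusion = 2500L,
                      gene_window = 50000L) {
  if (any(c(stitch_gap, tss_exclusion, gene_window) <= 0)) {
    abort("all se_params fields must be strictly positive")
  }
  structure(list(stitch_gap = as.integer(stitch_gap),
                 tss_exclusion = as.integer(tss_exclusion),
                 gene_window = as.integer(gene_window)),
            class = "se_params")
}

#' Stitch enhancer peaks into domains
#'
#' Drops peaks fully contained in a TSS exclusion zone, then transitively
#' merges remaining same-chromosome peaks whose gap is at most
#' `params$stitch_gap`. Peaks only partially overlapping an exclusion zone
#' are kept intact.
#'
#' @param peaks Normalized interval tibble (e.g. H3K27ac peaks).
#' @param promoters TSS exclusion intervals (see [tss_exclusion_zones()]);
#'   `NULL` disables the exclusion.
#' @param params [se_params()].
#' @return Tibble of disjoint stitched regions: `chrom`, `start`, `end`,
#'   `n_constituents` and a `constituents` list-column of the source peaks.
#' @export
stitch_enhancers <- function(peaks, promoters = NULL, params = se_params()) {
  validate_intervals(peaks, "peaks")
  if (nrow(peaks) == 0) {
    warn("empty peak set; no enhancers to stitch")
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_constituents = integer(), constituents = list()))
  }
  peaks <- normalize_intervals(peaks)
  if (!is.null(promoters) && nrow(promoters) > 0) {
    inside <- IRanges::overlapsAny(as_granges(peaks),
                                         as_granges(promoters),
                                         type = "within")
    peaks <- peaks[!inside, , drop = FALSE]
    if (nrow(peaks) == 0) {
      warn("all peaks fell inside TSS exclusion zones")
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    n_constituents = integer(), constituents = list()))
    }
  }
  gr <- as_granges(peaks)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = params$stitch_gap + 1L,
                                  with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  out <- granges_to_tbl(merged)
  out$n_constituents <- lengths(revmap)
  out$constituents <- lapply(revmap, function(i) {
    peaks[i, intersect(c("chrom", "start", "end", "score", "name"),
                       names(peaks)), drop = FALSE]
  })
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Score stitched enhancers from coverage
#'
#' Fills per-domain treatment and input signal (sum of per-bp coverage over
#' the region) and the background-subtracted `net_signal = max(treat -
#' input, 0)`.
#'
#' @param stitched Output of [stitch_enhancers()].
#' @param treat_cov Coverage tibble for the mark.
#' @param input_cov Optional input coverage; `NULL` means `net_signal =
#'   treat_signal`.
#' @return `stitched` with `treat_signal`, `input_signal` and `net_signal`
#'   columns added.
#' @export
score_enhancers <- function(stitched, treat_cov, input_cov = NULL) {
  if (nrow(stitched) == 0) {
    return(mutate(stitched, treat_signal = numeric(), input_signal = numeric(),
                  net_signal = numeric()))
  }
  if (any(treat_cov$value < 0) ||
      (!is.null(input_cov) && any(input_cov$value < 0))) {
    abort("coverage values must be >= 0")
  }
  gr <- as_granges(stitched)
  treat <- binned_coverage(treat_cov, gr) * GenomicRanges::width(gr)
  input <- if (is.null(input_cov)) numeric(length(gr))
           else binned_coverage(input_cov, gr) * GenomicRanges::width(gr)
  if (any(treat == 0)) {
    warn("some stitched regions have no treatment coverage; scored as 0")
  }
  mutate(stitched, treat_signal = treat, input_signal = input,
         net_signal = pmax(treat - input, 0))
}

#' Rank-curve inflection cutoff for super-enhancers
#'
#' Sorts signals ascending, rescales ranks and signals to \[0, 1\] and
#' locates the discrete inflection of the hockey-stick curve: the rank at
#' which the one-point forward-difference slope of the scaled curve is
#' largest, among ranks whose slope exceeds 1 (the average slope of the
#' whole curve). Ties take the lowest rank. Enhancers with signal strictly
#' above the cutoff signal are super. If no slope exceeds 1 — an exactly
#' linear ramp — there are no super-enhancers.
#'
#' @param net_signals Numeric vector of non-negative enhancer signals; at
#'   least 3 values with at least 2 distinct.
#' @return List with `cutoff_value`, `cutoff_index` (rank in the ascending
#'   order at the inflection; `NA` if the slope never exceeds 1) and
#'   `is_super`, a logical vector aligned with `net_signals`.
#' @export
find_se_cutoff <- function(net_signals) {
  if (length(net_signals) < 3) abort("need >= 3 enhancers")
  if (any(net_signals < 0)) abort("signals must be >= 0")
  if (length(unique(net_signals)) < 2) {
    warn("all enhancer signals equal; no super-enhancer cutoff")
    return(list(cutoff_value = NA_real_, cutoff_index = NA_integer_,
                is_super = rep(FALSE, length(net_signals))))
  }
  s <- sort(net_signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  slope <- diff(y) / diff(x) # forward differences, length n - 1
  # the slope must rise above the curve's average slope of 1; the small
  # tolerance keeps an exactly linear ramp (slope identically 1 up to
  # rounding) from yielding supers
  if (max(slope) <= 1 + 1e-8) {
    return(list(cutoff_value = max(s), cutoff_index = NA_integer_,
                is_super = rep(FALSE, length(net_signals))))
  }
  cutoff_index <- which.max(slope) # ties -> lowest rank
  cutoff_value <- s[cutoff_index]
  list(cutoff_value = cutoff_value, cutoff_index = cutoff_index,
       is_super = net_signals > cutoff_value)
}

#' Rank enhancers and flag super-enhancers
#'
#' Applies [find_se_cutoff()] to scored, stitched enhancers and returns the
#' full ranking. Optionally demotes super-enhancers lacking support from a
#' second evidence track (e.g. H3K4me1 peaks).
#'
#' @param scored Output of [score_enhancers()].
#' @param require_overlap Optional interval tibble; super-enhancers with no
#'   overlap with it are demoted to typical enhancers.
#' @return An object of class `se_ranking`: list with `enhancers` (tibble
#'   sorted by ascending `net_signal`, with `rank` and `is_super`),
#'   `cutoff_value` and `cutoff_index`.
#' @export
se_ranking <- function(scored, require_overlap = NULL) {
  cut <- find_se_cutoff(scored$net_signal)
  enh <- scored |>
    mutate(is_super = cut$is_super) |>
    arrange(.data$net_signal) |>
    mutate(rank = row_number())
  if (!is.null(require_overlap) && any(enh$is_super)) {
    sup <- filter(enh, .data$is_super)
    ok <- IRanges::overlapsAny(as_granges(sup),
                                     as_granges(require_overlap))
    demote <- sup[!ok, c("chrom", "start", "end")]
    if (nrow(demote) > 0) {
      key <- paste(enh$chrom, enh$start, enh$end)
      enh$is_super[key %in% paste(demote$chrom, demote$start, demote$end)] <- FALSE
    }
  }
  structure(list(enhancers = enh, cutoff_value = cut$cutoff_value,
                 cutoff_index = cut$cutoff_index),
            class = "se_ranking")
}

#' @export
print.se_ranking <- function(x, ...) {
  cat("Super-enhancer ranking:", nrow(x$enhancers), "enhancers,",
      sum(x$enhancers$is_super), "super |",
      "signal cutoff:", format(x$cutoff_value, digits = 4), "\n")
  invisible(x)
}

#' Assign active genes to super-enhancers
#'
#' A gene is assigned to a super-enhancer when its TSS lies within the SE
#' region extended by `params$gene_window` on both sides and the gene is in
#' the active set. Genes may map to multiple SEs; SEs may have zero genes.
#'
#' @param ranking An `se_ranking` object (or a tibble of regions).
#' @param genes Gene tibble.
#' @param active_gene_ids Character vector of transcriptionally active gene
#'   ids.
#' @param params [se_params()] (supplies `gene_window`).
#' @param supers_only Restrict assignment to flagged super-enhancers
#'   (default `TRUE`).
#' @return Tibble with one row per SE-gene pair: SE coordinates, `gene_id`,
#'   `tss`.
#' @export
assign_genes <- function(ranking, genes, active_gene_ids,
                         params = se_params(), supers_only = TRUE) {
  regions <- if (inherits(ranking, "se_ranking")) ranking$enhancers else ranking
  if (supers_only && "is_super" %in% names(regions)) {
    regions <- filter(regions, .data$is_super)
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), tss = integer())
  if (nrow(regions) == 0) return(empty)
  active <- filter(genes, .data$gene_id %in% active_gene_ids)
  if (nrow(active) == 0) return(empty)
  ext <- tibble(chrom = regions$chrom,
                start = pmax(0L, regions$start - params$gene_window),
                end = regions$end + params$gene_window)
  tss_gr <- GenomicRanges::GRanges(active$chrom,
                                   IRanges::IRanges(active$tss + 1L,
                                                    active$tss + 1L))
  hits <- GenomicRanges::findOverlaps(as_granges(ext), tss_gr)
  tibble(chrom = regions$chrom[S4Vectors::queryHits(hits)],
         start = regions$start[S4Vectors::queryHits(hits)],
         end = regions$end[S4Vectors::queryHits(hits)],
         gene_id = active$gene_id[S4Vectors::subjectHits(hits)],
         tss = active$tss[S4Vectors::subjectHits(hits)]) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Which genes count as transcriptionally active
#'
#' Activity is defined as normalized expression above a quantile of the
#' sample's expression distribution.
#'
#' @param expr Named numeric vector of per-gene expression for one sample.
#' @param quantile_cut Quantile threshold (default 0.5).
#' @return Character vector of active gene ids.
#' @export
active_genes <- function(expr, quantile_cut = 0.5) {
  names(expr)[expr > stats::quantile(expr, quantile_cut)]
}
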