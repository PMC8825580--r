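# Gene models, promoter windows, midpoint-priority peak annotation and
# TSS-anchored log-ratio profiles.

#' Build a gene model tibble
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param strand `+1` / `-1` integer strand.
#' @param tx_start,tx_end Transcript span, 0-based half-open.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` and the derived `tss` (`tx_start` on `+`, `tx_end - 1` on `-`).
#' @export
gene_tbl <- function(gene_id, chrom, strand, tx_start, tx_end) {
  x <- tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
              strand = as.integer(strand),
              tx_start = as.integer(tx_start), tx_end = as.integer(tx_end))
  if (any(duplicated(x$gene_id))) abort("gene ids must be unique")
  if (!all(x$strand %in% c(-1L, 1L))) abort("strand must be +1 or -1")
  if (any(x$tx_start >= x$tx_end)) abort("need tx_start < tx_end")
  x$tss <- ifelse(x$strand == 1L, x$tx_start, x$tx_end - 1L)
  x
}

#' Promoter windows around gene TSSs
#'
#' Strand-aware window: `upstream` bases before and `downstream` bases after
#' the TSS in the direction of transcription.
#'
#' @param genes Gene tibble from [gene_tbl()].
#' @param upstream,downstream Window half-sizes in bp (defaults 3000/3000,
#'   the convention of standard annotation tools).
#' @return Interval tibble with a `gene_id` column.
#' @export
promoter_windows <- function(genes, upstream = 3000L, downstream = 3000L) {
  start <- ifelse(genes$strand == 1L, genes$tss - upstream,
                  genes$tss - downstream)
  end <- ifelse(genes$strand == 1L, genes$tss + downstream + 1L,
                genes$tss + upstream + 1L)
  tibble(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
         end = as.integer(end), gene_id = genes$gene_id) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' TSS exclusion zones
#'
#' Symmetric `tss +/- size` windows used to drop promoter-proximal peaks
#' before enhancer stitching.
#'
#' @param genes Gene tibble.
#' @param size Half-width in bp (default 2500).
#' @return Interval tibble with `gene_id`.
#' @export
tss_exclusion_zones <- function(genes, size = 2500L) {
  tibble(chrom = genes$chrom,
         start = pmax(0L, genes$tss - as.integer(size)),
         end = genes$tss + as.integer(size) + 1L,
         gene_id = genes$gene_id) |>
    arrange(.data$chrom, .data$start, .data$end)
}

feature_levels <- c("promoter", "five_prime_utr", "three_prime_utr",
                    "exon", "intron", "downstream", "distal_intergenic")

#' Annotate peaks with genomic features
#'
#' Each peak is assigned exactly one feature, decided at the peak midpoint,
#' by the priority promoter > 5'UTR > 3'UTR > exon > intron > downstream >
#' distal intergenic. UTRs are scored only when the gene table carries
#' `utr5_len` / `utr3_len` columns; exon/intron resolution requires an
#' `exon_table` (without one, a transcript is treated as a single exon).
#'
#' @param peaks Normalized interval tibble.
#' @param genes Gene tibble from [gene_tbl()]; must be non-empty.
#' @param exon_table Optional interval tibble of exons with a `gene_id`
#'   column.
#' @param tss_window Length-2 vector: promoter window upstream/downstream of
#'   the TSS in bp (default `c(3000, 3000)`).
#' @param downstream_len Bases past the transcript end counted as
#'   `downstream` (default 3000).
#' @return A tibble with one row per peak: coordinates, `midpoint`,
#'   `feature` (factor with the priority levels), `gene_id` of the nearest
#'   TSS and the signed `distance_to_tss` (positive downstream of the TSS
#'   in the gene's direction of transcription).
#' @seealso [feature_proportions()]
#' @export
annotate_peaks <- function(peaks, genes, exon_table = NULL,
                           tss_window = c(3000L, 3000L),
                           downstream_len = 3000L) {
  validate_intervals(peaks, "peaks")
  if (is.null(genes) || nrow(genes) == 0) abort("`genes` must be non-empty")
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  midpoint = integer(),
                  feature = factor(character(), levels = feature_levels),
                  gene_id = character(), distance_to_tss = integer()))
  }
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  in_set <- function(tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(logical(length(mid)))
    IRanges::overlapsAny(mid_gr, as_granges(tbl))
  }

  prom <- promoter_windows(genes, tss_window[1], tss_window[2])
  body <- tibble(chrom = genes$chrom, start = genes$tx_start,
                 end = genes$tx_end)
  down <- tibble(
    chrom = genes$chrom,
    start = as.integer(ifelse(genes$strand == 1L, genes$tx_end,
                              pmax(0L, genes$tx_start - downstream_len))),
    end = as.integer(ifelse(genes$strand == 1L, genes$tx_end + downstream_len,
                            genes$tx_start)))
  down <- filter(down, .data$start < .data$end)

  utr5 <- utr3 <- NULL
  if (all(c("utr5_len", "utr3_len") %in% names(genes))) {
    utr5 <- tibble(
      chrom = genes$chrom,
      start = as.integer(ifelse(genes$strand == 1L, genes$tx_start,
                                genes$tx_end - genes$utr5_len)),
      end = as.integer(ifelse(genes$strand == 1L,
                              genes$tx_start + genes$utr5_len, genes$tx_end)))
    utr3 <- tibble(
      chrom = genes$chrom,
      start = as.integer(ifelse(genes$strand == 1L,
                                genes$tx_end - genes$utr3_len, genes$tx_start)),
      end = as.integer(ifelse(genes$strand == 1L, genes$tx_end,
                              genes$tx_start + genes$utr3_len)))
    utr5 <- filter(utr5, .data$start < .data$end)
    utr3 <- filter(utr3, .data$start < .data$end)
  }

  is_prom <- in_set(prom)
  is_u5 <- in_set(utr5)
  is_u3 <- in_set(utr3)
  is_body <- in_set(body)
  is_exon <- if (is.null(exon_table)) is_body else (is_body & in_set(exon_table))
  is_down <- in_set(down)

  feature <- rep("distal_intergenic", length(mid))
  feature[is_down] <- "downstream"
  feature[is_body] <- "intron"
  feature[is_exon] <- "exon"
  feature[is_u3] <- "three_prime_utr"
  feature[is_u5] <- "five_prime_utr"
  feature[is_prom] <- "promoter"

  # nearest TSS (signed, transcription-oriented distance)
  tss_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1L,
                                                    genes$tss + 1L))
  nearest_idx <- GenomicRanges::nearest(mid_gr, tss_gr)
  gene_id <- genes$gene_id[nearest_idx]
  dist <- (mid - genes$tss[nearest_idx]) * genes$strand[nearest_idx]
  gene_id[is.na(nearest_idx)] <- NA_character_
  dist[is.na(nearest_idx)] <- NA_integer_

  tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
         midpoint = mid,
         feature = factor(feature, levels = feature_levels),
         gene_id = gene_id, distance_to_tss = as.integer(dist))
}

#' Feature proportions from a peak annotation
#'
#' @param annotation Output of [annotate_peaks()].
#' @return Tibble with `feature`, `n` and `proportion` (summing to 1) for
#'   every feature level, including empty ones.
#' @export
feature_proportions <- function(annotation) {
  counts <- table(annotation$feature)
  tibble(feature = factor(names(counts), levels = feature_levels),
         n = as.integer(counts),
         proportion = as.integer(counts) / max(1L, nrow(annotation)))
}

# mean per-bp coverage of arbitrary windows, from run-length coverage tibble
binned_coverage <- function(cov, windows_gr) {
  out <- numeric(length(windows_gr))
  if (is.null(cov) || nrow(cov) == 0) return(out)
  cgr <- as_granges(cov)
  hits <- GenomicRanges::findOverlaps(windows_gr, cgr)
  if (length(hits) == 0) return(out)
  ov <- GenomicRanges::pintersect(windows_gr[S4Vectors::queryHits(hits)],
                                  cgr[S4Vectors::subjectHits(hits)])
  contrib <- GenomicRanges::width(ov) * cov$value[S4Vectors::subjectHits(hits)]
  sums <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out / GenomicRanges::width(windows_gr)
}

#' TSS-anchored log2-ratio signal profile
#'
#' Builds a genes x bins matrix of `log2((treat + c) / (input + c))` around
#' every TSS, with rows oriented 5' to 3' (minus-strand rows reversed), the
#' layout consumed by TSS heatmaps and average profiles.
#'
#' @param treat Coverage tibble (see [coverage_tbl()]) for the
#'   histone-mark track.
#' @param input Optional coverage tibble for the input/control track
#'   (missing regions count as 0; `NULL` means an all-zero input).
#' @param genes Gene tibble.
#' @param flank Half-window around the TSS in bp (default 5000); must be a
#'   multiple of `bin`.
#' @param bin Bin width in bp (default 50).
#' @param pseudo Pseudo-count `c > 0` (default 1).
#' @return Numeric matrix with `nrow(genes)` rows (named by gene id) and
#'   `2 * flank / bin` columns. Bins that fall off the chromosome start are
#'   `NA`.
#' @export
tss_profile <- function(treat, input = NULL, genes, flank = 5000L, bin = 50L,
                        pseudo = 1) {
  if (flank %% bin != 0) abort("`flank` must be divisible by `bin`")
  if (pseudo <= 0) abort("`pseudo` must be > 0")
  n_bins <- as.integer(2 * flank / bin)
  offsets <- seq(-flank, flank - bin, by = bin)
  # bins laid left to right in genomic coordinates for every gene
  starts <- rep(genes$tss, each = n_bins) + rep(offsets, times = nrow(genes))
  bins <- tibble(chrom = rep(genes$chrom, each = n_bins),
                 start = as.integer(starts),
                 end = as.integer(starts + bin))
  off_edge <- bins$start < 0
  bins$start[off_edge] <- 0L
  bins$end[off_edge] <- 1L
  bgr <- as_granges(bins)
  tmat <- matrix(binned_coverage(treat, bgr), ncol = n_bins, byrow = TRUE)
  imat <- matrix(binned_coverage(input, bgr), ncol = n_bins, byrow = TRUE)
  m <- log2((tmat + pseudo) / (imat + pseudo))
  m[matrix(off_edge, ncol = n_bins, byrow = TRUE)] <- NA_real_
  flip <- genes$strand == -1L
  m[flip, ] <- m[flip, n_bins:1, drop = FALSE]
  rownames(m) <- genes$gene_id
  colnames(m) <- paste0("bin", seq_len(n_bins))
  m
}
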