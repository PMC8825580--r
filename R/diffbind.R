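# Consensus peaks, region x sample counts, occupancy/affinity sample
# correlation and a transparent moderated-t differential-binding contrast
# on logCPM between two phenotype groups.

#' Consensus peaks across samples
#'
#' Merges the union of all peak sets into disjoint regions and keeps those
#' overlapped by peaks from at least `min_overlap` distinct samples.
#'
#' @param peaksets Named list of normalized interval tibbles (one per
#'   sample), or a single tibble with a `sample` column. At least 2
#'   samples.
#' @param min_overlap Minimum number of supporting samples (default 2).
#' @return Object of class `consensus_peaks`: tibble `chrom`, `start`,
#'   `end`, `support`, with `min_overlap` and the sample names stored as
#'   attributes.
#' @export
consensus_peaks <- function(peaksets, min_overlap = 2L) {
  if (is.data.frame(peaksets)) {
    if (!"sample" %in% names(peaksets)) {
      abort("a single tibble input needs a `sample` column")
    }
    peaksets <- split(peaksets, peaksets$sample)
  }
  if (length(peaksets) < 2) abort("need >= 2 peak sets")
  if (min_overlap > length(peaksets)) {
    abort("`min_overlap` exceeds the number of samples")
  }
  samples <- names(peaksets) %||% as.character(seq_along(peaksets))
  all_peaks <- imap(peaksets, function(p, s) mutate(p, sample = s)) |>
    list_rbind()
  merged <- union_intervals(all_peaks[c("chrom", "start", "end")])
  if (nrow(merged) == 0) {
    out <- mutate(merged, support = integer())
  } else {
    mgr <- as_granges(merged)
    support <- rep(0L, nrow(merged))
    for (s in samples) {
      hit <- IRanges::overlapsAny(mgr, as_granges(peaksets[[s]]))
      support <- support + as.integer(hit)
    }
    out <- filter(mutate(merged, support = support),
                  .data$support >= min_overlap)
  }
  structure(out, class = c("consensus_peaks", class(out)),
            min_overlap = as.integer(min_overlap), samples = samples)
}

#' Region x sample count matrix from coverage
#'
#' Counts are the summed per-bp coverage over each consensus region
#' (uniform 1x coverage yields the region length); library sizes are the
#' per-sample totals over the whole coverage track.
#'
#' @param consensus Output of [consensus_peaks()] (or any interval tibble).
#' @param coverages Named list of coverage tibbles, one per sample.
#' @return List with `counts` (integer regions x samples matrix, rows named
#'   `chrom:start-end`) and `library_sizes` (named numeric vector).
#' @export
count_matrix <- function(consensus, coverages) {
  if (length(coverages) < 1) abort("need >= 1 coverage track")
  gr <- as_granges(consensus)
  w <- GenomicRanges::width(gr)
  counts <- vapply(coverages, function(cov) {
    if (any(cov$value < 0)) abort("coverage values must be >= 0")
    round(binned_coverage(cov, gr) * w)
  }, numeric(length(gr)))
  counts <- matrix(as.integer(counts), nrow = length(gr),
                   dimnames = list(paste0(consensus$chrom, ":",
                                          consensus$start, "-",
                                          consensus$end),
                                   names(coverages)))
  lib <- vapply(coverages, function(cov)
    sum((cov$end - cov$start) * cov$value), 0)
  list(counts = counts, library_sizes = lib)
}

#' Sample-sample correlation with clustering order
#'
#' Pearson correlation between sample columns — on the 0/1 occupancy
#' matrix, or on `log2(count + 1)` for affinity data — with
#' average-linkage hierarchical clustering on `1 - r`.
#'
#' @param data Regions x samples matrix: 0/1 occupancy or counts.
#' @param method `"occupancy"` or `"affinity"`.
#' @return List with `correlation` (symmetric, unit diagonal) and `order`
#'   (dendrogram leaf order). Constant columns get correlation 0 with a
#'   warning.
#' @export
sample_correlation <- function(data, method = c("occupancy", "affinity")) {
  method <- match.arg(method)
  if (ncol(data) < 2) abort("need >= 2 samples")
  m <- if (method == "affinity") log2(data + 1) else (data > 0) + 0
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(stats::cor(m))
  if (any(sds == 0)) {
    warn("constant sample columns; their correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  hc <- hclust(as.dist(1 - r), method = "average")
  list(correlation = r, order = hc$order, hclust = hc)
}

#' Differential binding between two groups
#'
#' Normalizes counts to log2 counts-per-million with pseudo-count 0.5, then
#' tests every region with a Welch t-test whose per-group variances are
#' floored at the trimmed mean (trim 0.25) of that group's per-region
#' variances — a simple variance moderation that stabilizes low-count
#' regions — followed by BH adjustment.
#'
#' @param counts Regions x samples count matrix.
#' @param groups Binary labels, one per sample (any two values); at least
#'   2 samples per group.
#' @param fdr_threshold Regions at `fdr <= fdr_threshold` are flagged
#'   `significant` (default 0.05).
#' @param library_sizes Optional per-sample totals; defaults to column
#'   sums.
#' @return Tibble with one row per region: `region`, group means on the
#'   logCPM scale, `log2_fc` (group A minus group B, A = first level),
#'   `t`, `p`, `fdr`, `direction`
#'   (`enriched_in_A` / `enriched_in_B`), `significant`; sorted by `fdr`.
#' @export
differential_regions <- function(counts, groups, fdr_threshold = 0.05,
                                 library_sizes = NULL) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) abort("`groups` must take exactly two values")
  if (any(table(g) < 2)) abort("need >= 2 samples per group")
  if (length(groups) != ncol(counts)) {
    abort("one group label per sample column required")
  }
  lib <- library_sizes %||% colSums(counts)
  logcpm <- log2(t((t(counts) + 0.5) / (lib + 1) * 1e6))
  a <- logcpm[, g == levels(g)[1], drop = FALSE]
  b <- logcpm[, g == levels(g)[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  floor1 <- mean(v1, trim = 0.25); floor2 <- mean(v2, trim = 0.25)
  v1f <- pmax(v1, floor1); v2f <- pmax(v2, floor2)
  se2 <- v1f / n1 + v2f / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1f / n1)^2 / (n1 - 1) + (v2f / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df = df)
  fdr <- bh_adjust(p)
  out <- tibble(region = rownames(counts) %||%
                  as.character(seq_len(nrow(counts))),
                mean_a = m1, mean_b = m2, log2_fc = m1 - m2,
                t = tstat, p = p, fdr = fdr,
                direction = ifelse(m1 - m2 >= 0, "enriched_in_A",
                                   "enriched_in_B"),
                significant = fdr <= fdr_threshold)
  arrange(out, .data$fdr, .data$p)
}

#' Restrict differential regions to gene promoters
#'
#' Keeps regions overlapping a promoter by at least 1 bp and annotates the
#' gene id (one row per region-promoter pair).
#'
#' @param diff Output of [differential_regions()] whose `region` column is
#'   `chrom:start-end`.
#' @param promoters Interval tibble with `gene_id`.
#' @return `diff` subset with `gene_id` added.
#' @export
promoter_subset <- function(diff, promoters) {
  if (nrow(diff) == 0) return(mutate(diff, gene_id = character()))
  parts <- stringr::str_match(diff$region, "^(.+):(\\d+)-(\\d+)$")
  regions <- tibble(chrom = parts[, 2],
                    start = as.integer(parts[, 3]),
                    end = as.integer(parts[, 4]))
  hits <- GenomicRanges::findOverlaps(as_granges(regions),
                                      as_granges(promoters))
  out <- diff[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- promoters$gene_id[S4Vectors::subjectHits(hits)]
  arrange(out, .data$fdr, .data$p)
}
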