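# Genomic-interval data model. Intervals travel as plain tibbles with columns
# chrom / start / end (0-based half-open, the BED dialect) plus optional
# score, name, sample and mark columns. GenomicRanges does the heavy lifting
# behind this surface; coordinates are shifted to 1-based closed on the way
# in and back on the way out.

#' Build an interval tibble
#'
#' Constructs and validates a tibble of genomic intervals in 0-based
#' half-open (BED) coordinates.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer base positions, `0 <= start < end`, end exclusive.
#' @param score Optional non-negative numeric signal per interval.
#' @param name Optional label per interval.
#' @param sample,mark Optional sample id and histone-mark label attached as
#'   columns (recycled to length).
#' @param normalize Sort and deduplicate (default `TRUE`).
#'
#' @return A tibble with columns `chrom`, `start`, `end` and any optional
#'   columns supplied, sorted by (chrom, start, end, name) with exact
#'   duplicates removed when `normalize = TRUE`.
#' @export
#' @examples
#' interval_tbl(c("chr1", "chr1"), c(100L, 0L), c(200L, 50L))
interval_tbl <- function(chrom, start, end, score = NULL, name = NULL,
                         sample = NULL, mark = NULL, normalize = TRUE) {
  x <- tibble(chrom = as.character(chrom),
              start = as.integer(start),
              end = as.integer(end))
  if (!is.null(score)) x$score <- as.numeric(score)
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(sample)) x$sample <- as.character(sample)
  if (!is.null(mark)) x$mark <- as.character(mark)
  validate_intervals(x)
  if (normalize) normalize_intervals(x) else x
}

validate_intervals <- function(x, arg = "x") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("`", arg, "` must have columns ",
                 paste(need, collapse = ", "), "; missing: ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort("chromosome names must be non-empty strings")
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(paste0("invalid intervals (need 0 <= start < end) at rows: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if ("score" %in% names(x) && any(x$score < 0, na.rm = TRUE)) {
    abort("interval scores must be >= 0")
  }
  invisible(x)
}

#' Normalize an interval tibble
#'
#' Sorts by (chrom, start, end, name) and drops rows that are exact
#' duplicates across all columns. All set-level operations in the package
#' expect (and return) normalized input.
#'
#' @param x Interval tibble.
#' @return The normalized tibble.
#' @export
normalize_intervals <- function(x) {
  validate_intervals(x)
  keys <- intersect(c("chrom", "start", "end", "name"), names(x))
  x |>
    distinct() |>
    arrange(across(dplyr::all_of(keys)))
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tbl <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Merge overlapping or bookended intervals into a disjoint union
#'
#' @param x Interval tibble.
#' @param min_gap Gaps of at most `min_gap` bases between intervals are
#'   bridged (default 0: only touching/overlapping intervals merge).
#' @return Normalized tibble of disjoint intervals.
#' @export
union_intervals <- function(x, min_gap = 0L) {
  if (nrow(x) == 0) return(interval_tbl(character(), integer(), integer()))
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = min_gap + 1L)
  normalize_intervals(granges_to_tbl(gr))
}

#' Base-pair intersection of two interval sets
#'
#' Returns the genomic regions covered by both sets, as disjoint intervals.
#' Commutative up to normalization.
#'
#' @param a,b Normalized interval tibbles.
#' @return Normalized tibble of disjoint intervals covered by both inputs.
#' @export
#' @examples
#' a <- interval_tbl("chr1", 0L, 100L)
#' b <- interval_tbl("chr1", 50L, 150L)
#' intersect_intervals(a, b) # chr1:50-100
intersect_intervals <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(interval_tbl(character(), integer(), integer()))
  }
  # disjoint chromosome sets are a legitimate input; silence the seqlevel
  # merge notice
  gr <- suppressWarnings(
    GenomicRanges::intersect(as_granges(a), as_granges(b),
                             ignore.strand = TRUE))
  normalize_intervals(granges_to_tbl(gr))
}

#' Fraction of query intervals overlapping a subject set
#'
#' Counts query intervals whose total overlap with the base-pair union of
#' the subject reaches `min_bp`, divided by the number of query intervals.
#' This is the "fraction of peaks commonly found" statistic used to compare
#' peak repertoires between sample panels.
#'
#' @param query,subject Normalized interval tibbles.
#' @param min_bp Minimum total overlapping bases (>= 1) with the subject
#'   union for a query interval to count as found.
#' @return A single number in \[0, 1\]. An empty query returns 0 with a
#'   warning.
#' @export
overlap_fraction <- function(query, subject, min_bp = 1L) {
  validate_intervals(query, "query"); validate_intervals(subject, "subject")
  if (min_bp < 1) abort("`min_bp` must be >= 1")
  if (nrow(query) == 0) {
    warn("empty query set; overlap_fraction defined as 0")
    return(0)
  }
  if (nrow(subject) == 0) return(0)
  qgr <- as_granges(query)
  sgr <- GenomicRanges::reduce(as_granges(subject))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qgr, sgr))
  if (length(hits) == 0) return(0)
  ov <- GenomicRanges::pintersect(qgr[S4Vectors::queryHits(hits)],
                                  sgr[S4Vectors::subjectHits(hits)])
  per_query <- tapply(GenomicRanges::width(ov),
                      S4Vectors::queryHits(hits), sum)
  sum(per_query >= min_bp) / nrow(query)
}

#' Total bases covered by an interval set
#'
#' @param x Interval tibble.
#' @return Total width of the base-pair union of `x`.
#' @export
total_bp <- function(x) {
  u <- union_intervals(x)
  sum(u$end - u$start)
}
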