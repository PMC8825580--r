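# Bivalent repressive domains: promoters co-occupied by H3K9me3 and
# H3K27me3, and their recurrence across a sample panel.

#' Promoters co-marked by two repressive marks
#'
#' Default mode (`"both"`): a gene is returned when its promoter overlaps
#' at least `min_bp` bases of an H3K9me3 peak and at least `min_bp` bases
#' of an H3K27me3 peak. Strict mode (`"strict"`): additionally the
#' base-pair intersection of the two marks must itself cover `min_bp`
#' bases of the promoter (the marks co-localize, not merely co-occur).
#'
#' @param h3k9me3,h3k27me3 Normalized interval tibbles of peaks.
#' @param promoters Interval tibble with a `gene_id` column (see
#'   [promoter_windows()]); must be non-empty.
#' @param min_bp Minimum overlap in bases (default 1).
#' @param mode `"both"` (default) or `"strict"`.
#' @return Tibble with `gene_id`, sorted.
#' @export
promoter_comark <- function(h3k9me3, h3k27me3, promoters, min_bp = 1L,
                            mode = c("both", "strict")) {
  mode <- match.arg(mode)
  if (is.null(promoters) || nrow(promoters) == 0) {
    abort("`promoters` must be non-empty")
  }
  if (min_bp < 1) abort("`min_bp` must be >= 1")
  hit_genes <- function(marks) {
    if (nrow(marks) == 0) return(character())
    pgr <- as_granges(promoters)
    mgr <- GenomicRanges::reduce(as_granges(marks))
    hits <- GenomicRanges::findOverlaps(pgr, mgr)
    if (length(hits) == 0) return(character())
    ov <- GenomicRanges::pintersect(pgr[S4Vectors::queryHits(hits)],
                                    mgr[S4Vectors::subjectHits(hits)])
    per <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    unique(promoters$gene_id[as.integer(names(per))[per >= min_bp]])
  }
  genes <- intersect(hit_genes(h3k9me3), hit_genes(h3k27me3))
  if (mode == "strict" && length(genes) > 0) {
    both <- intersect_intervals(h3k9me3, h3k27me3)
    genes <- intersect(genes, hit_genes(both))
  }
  tibble(gene_id = sort(genes))
}

#' Recurrence of co-marked promoters across samples
#'
#' @param per_sample A tibble with columns `sample` and `gene_id` (one row
#'   per sample-gene membership), or a named list of per-sample gene-id
#'   vectors.
#' @return Tibble with `gene_id`, `recurrence` and a `samples` list-column,
#'   sorted by descending recurrence with ties broken by `gene_id`.
#' @export
comark_recurrence <- function(per_sample) {
  if (is.list(per_sample) && !is.data.frame(per_sample)) {
    if (length(per_sample) == 0) abort("need >= 1 sample")
    per_sample <- imap(per_sample, function(g, s) {
      tibble(sample = s, gene_id = as.character(g))
    }) |> list_rbind()
  }
  if (length(unique(per_sample$sample)) < 1) abort("need >= 1 sample")
  per_sample |>
    distinct(.data$sample, .data$gene_id) |>
    group_by(.data$gene_id) |>
    summarise(recurrence = dplyr::n(),
              samples = list(sort(.data$sample)), .groups = "drop") |>
    arrange(desc(.data$recurrence), .data$gene_id)
}
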