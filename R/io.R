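# Text I/O: BED3/5/6 peaks, 6-column gene tables, bedGraph coverage,
# expression matrices and survival tables. All readers return tibbles in
# 0-based half-open coordinates (native BED, no shift).

#' Read a BED file of peaks
#'
#' Accepts BED3/BED5/BED6 (tab- or whitespace-separated). Column 4 is taken
#' as `name` and column 5 as `score` when present. Lines starting with
#' `track`, `browser` or `#` are skipped. Malformed lines raise an error
#' naming their line numbers.
#'
#' @param path Path to the BED file.
#' @param sample,mark Optional sample id and histone-mark label recorded as
#'   columns on every interval.
#' @return A normalized interval tibble (see [interval_tbl()]).
#' @export
read_bed <- function(path, sample = NULL, mark = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    warn(paste0("no intervals in ", path, "; returning empty set"))
    return(interval_tbl(character(), integer(), integer(),
                        sample = if (!is.null(sample)) character(),
                        mark = if (!is.null(mark)) character()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("lines with fewer than 3 columns in ", path, ": ",
                 paste(head(idx[nf < 3], 5), collapse = ", ")))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad_num <- is.na(start) | is.na(end)
  if (any(bad_num)) {
    abort(paste0("non-integer coordinates in ", path, " at lines: ",
                 paste(head(idx[bad_num], 5), collapse = ", ")))
  }
  bad_ord <- start >= end | start < 0
  if (any(bad_ord)) {
    abort(paste0("invalid coordinates (need 0 <= start < end) in ", path,
                 " at lines: ", paste(head(idx[bad_ord], 5), collapse = ", ")))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5, vapply(fields, function(f) f[min(5L, length(f))], ""),
                      NA_character_)))
  x <- tibble(chrom = chrom, start = start, end = end)
  if (any(nf >= 4)) x$name <- name
  if (any(nf >= 5)) x$score <- ifelse(is.na(score), 0, score)
  if (!is.null(sample)) x$sample <- sample
  if (!is.null(mark)) x$mark <- mark
  validate_intervals(x)
  normalize_intervals(x)
}

#' Write intervals as BED
#'
#' Writes BED3 plus `name`/`score` columns when present (BED5/6 layout with
#' `.` placeholders as needed).
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, x$start, x$end)
  if ("name" %in% names(x) || "score" %in% names(x)) {
    cols <- c(cols, list(x$name %||% rep(".", nrow(x))))
  }
  if ("score" %in% names(x)) cols <- c(cols, list(x$score))
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a gene table
#'
#' Two layouts are accepted. `format = "tsv"`: a header line then columns
#' `gene_id, chrom, strand, tx_start, tx_end, tss` (strand as `+`/`-` or
#' `1`/`-1`). `format = "bed6"`: BED6 with `name` = gene id and the TSS
#' derived from the strand (start on `+`, end-1 on `-`).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"bed6"`.
#' @return A gene tibble as produced by [gene_tbl()].
#' @export
read_genes <- function(path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("gene file not found: ", path))
  if (format == "bed6") {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 6) abort("BED6 gene file needs 6 columns")
    strand <- ifelse(d[[6]] == "-", -1L, 1L)
    return(gene_tbl(gene_id = d[[4]], chrom = d[[1]], strand = strand,
                    tx_start = d[[2]], tx_end = d[[3]]))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(d))) {
    abort(paste0("gene TSV needs columns: ", paste(need, collapse = ", ")))
  }
  strand <- if (is.character(d$strand)) ifelse(d$strand == "-", -1L, 1L)
            else as.integer(sign(d$strand))
  gene_tbl(gene_id = d$gene_id, chrom = d$chrom, strand = strand,
           tx_start = d$tx_start, tx_end = d$tx_end)
}

#' Read bedGraph-like coverage
#'
#' Four whitespace-separated columns: chrom, start, end, value. Values must
#' be non-negative.
#'
#' @param path Path to the coverage file.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("coverage file not found: ", path))
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4) abort("bedGraph needs 4 columns: chrom start end value")
  coverage_tbl(d[[1]], d[[2]], d[[3]], d[[4]])
}

#' Build a coverage tibble
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param value Non-negative per-interval coverage value (per-bp depth).
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
coverage_tbl <- function(chrom, start, end, value) {
  x <- tibble(chrom = as.character(chrom), start = as.integer(start),
              end = as.integer(end), value = as.numeric(value))
  validate_intervals(x)
  if (any(x$value < 0)) abort("coverage values must be >= 0")
  arrange(x, .data$chrom, .data$start, .data$end)
}

#' Read an expression matrix
#'
#' TSV with a header of sample/patient ids and gene ids in the first column.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Read a survival table
#'
#' TSV with columns `patient_id`, `time` (months, > 0) and `event` (0/1).
#'
#' @param path Path to the TSV.
#' @return Tibble with those three columns.
#' @export
read_survival_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(d))) {
    abort(paste0("survival TSV needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(d$time <= 0)) abort("survival times must be > 0")
  if (!all(d$event %in% c(0, 1))) abort("event must be 0/1")
  as_tibble(d[need])
}
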