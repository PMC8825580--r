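# Brute-force oracles, independent of the package's interval engine
# (GenomicRanges) and of the cumulative-sum maxstat scan. All are direct
# transcriptions of the definitions, quadratic where the package is not.

# random interval tibble
rand_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e5,
                           max_len = 500) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  normalize_intervals(tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len))
}

# pairwise overlap width of one interval with a set (same chrom assumed
# handled by caller)
o_overlap_bp <- function(qs, qe, ss, se) {
  pmax(0L, pmin(qe, se) - pmax(qs, ss))
}

# fraction of query intervals with >= min_bp overlap of the subject union
o_overlap_fraction <- function(query, subject, min_bp = 1L) {
  if (nrow(query) == 0) return(0)
  su <- o_union(subject)
  hits <- vapply(seq_len(nrow(query)), function(i) {
    s <- su[su$chrom == query$chrom[i], , drop = FALSE]
    if (nrow(s) == 0) return(FALSE)
    sum(o_overlap_bp(query$start[i], query$end[i], s$start, s$end)) >= min_bp
  }, TRUE)
  mean(hits)
}

# union by sweep (independent of GenomicRanges::reduce)
o_union <- function(x, gap = 0L) {
  if (nrow(x) == 0) return(x[0, c("chrom", "start", "end")])
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- list()
  cur <- x[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(x))[-1]) {
    if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end + gap) {
      cur$end <- max(cur$end, x$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- x[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1]] <- cur
  dplyr::bind_rows(out)
}

# base-pair intersection via all pairs
o_intersect <- function(a, b) {
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    bb <- b[b$chrom == a$chrom[i], , drop = FALSE]
    if (nrow(bb) == 0) next
    s <- pmax(a$start[i], bb$start); e <- pmin(a$end[i], bb$end)
    keep <- s < e
    if (any(keep)) {
      pieces[[length(pieces) + 1]] <-
        tibble::tibble(chrom = a$chrom[i], start = s[keep], end = e[keep])
    }
  }
  if (length(pieces) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  o_union(dplyr::bind_rows(pieces))
}

# transitive stitch by iterated pairwise merging to a fixpoint
o_stitch <- function(x, gap) {
  cur <- x[order(x$chrom, x$start, x$end), c("chrom", "start", "end")]
  repeat {
    merged <- o_union(cur, gap = gap)
    if (nrow(merged) == nrow(cur)) return(merged)
    cur <- merged
  }
}

# per-region support: number of peaksets overlapping each region
o_support <- function(regions, peaksets) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(vapply(peaksets, function(p) {
      pp <- p[p$chrom == regions$chrom[i], , drop = FALSE]
      any(o_overlap_bp(regions$start[i], regions$end[i],
                       pp$start, pp$end) > 0)
    }, TRUE))
  }, 0L)
}

# exhaustive maxstat: re-derives scores and scans every candidate split
o_maxstat <- function(time, event, x, eps = c(0.1, 0.9)) {
  n <- length(time)
  ut <- sort(unique(time))
  d <- vapply(ut, function(u) sum(event[time == u]), 0)
  nr <- vapply(ut, function(u) sum(time >= u), 0)
  lam <- cumsum(d / nr)
  a <- event - lam[match(time, ut)]
  best_cut <- NA_real_; best_z <- 0
  for (mu in sort(unique(x))) {
    m <- sum(x <= mu)
    if (m == n) next
    pr <- m / n
    if (pr < eps[1] || pr > eps[2]) next
    S <- sum(a[x <= mu])
    V <- m * (n - m) / (n * (n - 1)) * sum(a^2)
    z <- S / sqrt(V)
    if (abs(z) > abs(best_z) + 1e-12) { best_cut <- mu; best_z <- z }
  }
  list(cutpoint = best_cut, max_statistic = abs(best_z))
}

# hand product-limit KM over distinct event times
o_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1; out <- numeric(0)
  for (u in ut) {
    nr <- sum(time >= u); d <- sum(event[time == u])
    s <- s * (1 - d / nr)
    out <- c(out, s)
  }
  tibble::tibble(time = ut, survival = out)
}

interval_key <- function(x) paste(x$chrom, x$start, x$end)
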