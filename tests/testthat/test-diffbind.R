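test_that("consensus peaks honour min_overlap and match the support oracle", {
  p1 <- interval_tbl("chr1", c(0L, 1000L), c(100L, 1100L))
  p2 <- interval_tbl("chr1", c(50L, 5000L), c(150L, 5100L))
  cons <- consensus_peaks(list(A = p1, B = p2), min_overlap = 2)
  expect_equal(nrow(cons), 1) # only the 0-150 merged region is shared
  expect_equal(cons$support, 2L)

  # identical peaksets: consensus is the normalized set with full support
  same <- consensus_peaks(list(A = p1, B = p1, C = p1), min_overlap = 2)
  expect_equal(same$start, p1$start)
  expect_equal(same$support, c(3L, 3L))
  expect_error(consensus_peaks(list(A = p1), 1), ">= 2")
  expect_error(consensus_peaks(list(A = p1, B = p2), 3), "exceeds")

  set.seed(51)
  sets <- purrr::map(1:6, ~ rand_intervals(80, span = 2e4, max_len = 400))
  names(sets) <- paste0("S", 1:6)
  for (mo in c(2L, 4L)) {
    got <- consensus_peaks(sets, min_overlap = mo)
    merged <- o_union(dplyr::bind_rows(sets))
    support <- o_support(merged, sets)
    want <- merged[support >= mo, ]
    expect_equal(interval_key(got), interval_key(want))
    expect_equal(got$support, support[support >= mo])
  }
  # raising min_overlap never increases the region count
  expect_lte(nrow(consensus_peaks(sets, 4)), nrow(consensus_peaks(sets, 2)))
})

test_that("count matrix accumulates coverage exactly", {
  cons <- consensus_peaks(list(A = interval_tbl("chr1", 0L, 100L),
                               B = interval_tbl("chr1", 10L, 90L)))
  zero <- coverage_tbl("chr1", 0L, 200L, 0)
  uni <- coverage_tbl("chr1", 0L, 200L, 1)
  cm0 <- count_matrix(cons, list(A = zero, B = zero))
  expect_true(all(cm0$counts == 0))
  cm1 <- count_matrix(cons, list(A = uni, B = uni))
  expect_true(all(cm1$counts == 100)) # region length at 1x/bp
  expect_equal(unname(cm1$library_sizes), c(200, 200))
  set.seed(52)
  bins <- tibble::tibble(start = seq(0L, 190L, 10L), end = seq(10L, 200L, 10L),
                         value = rpois(20, 5))
  cov <- coverage_tbl("chr1", bins$start, bins$end, bins$value)
  cm2 <- count_matrix(cons, list(A = cov))
  want <- sum(bins$value[bins$start < 100] * 10)
  expect_equal(unname(cm2$counts[1, 1]), want)
})

test_that("sample correlation separates planted clusters", {
  set.seed(53)
  # duplicated sample: r = 1
  m <- matrix(rpois(200 * 4, 20), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "a2")))
  m[, "a2"] <- m[, "a"]
  sc <- sample_correlation(m, method = "affinity")
  expect_equal(sc$correlation["a", "a2"], 1)
  expect_true(isSymmetric(sc$correlation))
  expect_true(all(diag(sc$correlation) == 1))

  # two occupancy clusters with distinct repertoires
  occ <- cbind(matrix(rep(c(1, 0), c(50, 50)), 100, 4),
               matrix(rep(c(0, 1), c(50, 50)), 100, 4))
  occ <- occ * matrix(rbinom(100 * 8, 1, 0.9), 100, 8)
  colnames(occ) <- paste0("s", 1:8)
  so <- sample_correlation(occ, method = "occupancy")
  cl <- cutree(so$hclust, k = 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])

  # small instance equals the direct Pearson formula
  m2 <- matrix(c(1, 4, 2, 7, 3, 5, 8, 2), ncol = 2,
               dimnames = list(NULL, c("x", "y")))
  sa <- sample_correlation(m2, method = "affinity")
  lx <- log2(m2 + 1)
  want <- sum(scale(lx[, 1]) * scale(lx[, 2])) / 3
  expect_equal(sa$correlation["x", "y"], want)

  m3 <- cbind(m2, z = rep(4, 4))
  expect_warning(s3 <- sample_correlation(m3, "affinity"), "constant")
  expect_equal(s3$correlation["z", "x"], 0)
})

test_that("differential regions control the null and recover planted fold-changes", {
  set.seed(54)
  # permuted-label null on homogeneous counts: few flags, ~uniform p
  flagged <- replicate(10, {
    cnt <- matrix(rpois(2000 * 16, 50), nrow = 2000)
    rownames(cnt) <- paste0("chr1:", seq_len(2000), "-", seq_len(2000) + 1L)
    d <- differential_regions(cnt, sample(rep(c("A", "B"), each = 8)))
    mean(d$significant)
  })
  expect_lte(mean(flagged), 0.05)
  cnt0 <- matrix(rpois(2000 * 16, 50), nrow = 2000)
  rownames(cnt0) <- paste0("chr1:", seq_len(2000), "-", seq_len(2000) + 1L)
  d0 <- differential_regions(cnt0, sample(rep(c("A", "B"), each = 8)))
  ks <- suppressWarnings(stats::ks.test(d0$p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)

  # planted 4x in 100 of 2000 regions
  set.seed(55)
  base <- exp(rnorm(2000, 4, 1))
  cnt <- matrix(rpois(2000 * 16, base), nrow = 2000)
  cnt[1:100, 9:16] <- rpois(100 * 8, base[1:100] * 4)
  rownames(cnt) <- paste0("chr1:", seq_len(2000), "-", seq_len(2000) + 1L)
  d <- differential_regions(cnt, rep(c("A", "B"), each = 8))
  planted_regions <- paste0("chr1:", 1:100, "-", 2:101)
  hit <- d$region[d$significant]
  expect_gte(sum(planted_regions %in% hit), 80)
  planted_rows <- d[d$region %in% planted_regions, ]
  expect_true(all(planted_rows$direction[planted_rows$significant] ==
                    "enriched_in_B"))

  # label swap flips every direction and preserves p
  d_sw <- differential_regions(cnt, rep(c("B", "A"), each = 8))
  d_sw <- d_sw[match(d$region, d_sw$region), ]
  expect_equal(d$p, d_sw$p, tolerance = 1e-12)
  expect_true(all(d$direction != d_sw$direction |
                    abs(d$log2_fc) < 1e-12))
  # common library-size scaling leaves directions unchanged wherever the
  # contrast is non-degenerate (the 0.5 pseudo-count can flip the sign of
  # fold changes that are numerically ~0)
  d_sc <- differential_regions(cnt * 2L, rep(c("A", "B"), each = 8))
  d_sc <- d_sc[match(d$region, d_sc$region), ]
  stable <- d$significant | abs(d$log2_fc) > 0.1
  expect_equal(d$direction[stable], d_sc$direction[stable])
  expect_error(differential_regions(cnt, rep(c("A", "B"), c(15, 1))),
               ">= 2")
})

test_that("promoter subsetting annotates overlapping regions", {
  diff <- tibble::tibble(region = c("chr1:100-200", "chr1:5000-5100"),
                         mean_a = 1, mean_b = 0, log2_fc = 1, t = 2,
                         p = 0.01, fdr = 0.02,
                         direction = "enriched_in_A", significant = TRUE)
  proms <- tibble::tibble(chrom = "chr1", start = 150L, end = 400L,
                          gene_id = "gX")
  got <- promoter_subset(diff, proms)
  expect_equal(got$region, "chr1:100-200")
  expect_equal(got$gene_id, "gX")
  set.seed(56)
  regs <- rand_intervals(100, chroms = "chr1", span = 5e4)
  dd <- tibble::tibble(region = paste0(regs$chrom, ":", regs$start, "-",
                                       regs$end),
                       mean_a = 0, mean_b = 0, log2_fc = 0, t = 0, p = 1,
                       fdr = 1, direction = "enriched_in_A",
                       significant = FALSE)
  pr <- rand_intervals(20, chroms = "chr1", span = 5e4)
  pr$gene_id <- paste0("g", seq_len(nrow(pr)))
  got2 <- promoter_subset(dd, pr)
  keep <- vapply(seq_len(nrow(regs)), function(i)
    any(o_overlap_bp(regs$start[i], regs$end[i], pr$start, pr$end) > 0),
    TRUE)
  expect_setequal(unique(got2$region), dd$region[keep])
})
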