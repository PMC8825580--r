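make_cohort <- function(seed, n_genes = 200, n = 300, planted = NULL) {
  cfg <- sim_config(seed = seed,
                    survival = utils::modifyList(
                      list(n_patients = n),
                      if (is.null(planted)) list() else list(planted = planted)))
  ex <- make_expression(cfg, gene_ids = paste0("g", seq_len(n_genes)),
                        sample_ids = sprintf("P%04d", seq_len(n)))
  sv <- make_survival_cohort(cfg, ex$expr)
  sv
}

test_that("differential expression finds planted shifts and flips with groups", {
  cfg <- sim_config(seed = 31, expression = list(n_genes = 500L,
                                                 planted_frac = 0.1,
                                                 planted_fold = 4))
  groups <- rep(c("A", "B"), each = 20)
  ex <- make_expression(cfg, sample_ids = sprintf("s%02d", 1:40),
                        groups = groups)
  a <- ex$expr[, groups == "A"]; b <- ex$expr[, groups == "B"]
  # planted genes are shifted UP in B: test B over A
  res <- diff_expression(b, a, alternative = "over")
  hit <- res$gene_id[res$q <= 0.05]
  planted <- ex$truth$gene_id[ex$truth$planted]
  expect_gte(sum(planted %in% hit), 45)
  expect_lte(sum(!hit %in% planted), 5)
  # swapping groups flips over/under exactly
  res2 <- diff_expression(a, b, alternative = "under")
  expect_equal(res$p, res2$p, tolerance = 1e-12)
  # identical groups: one-sided p >= 0.5
  res0 <- diff_expression(a, a, alternative = "over")
  expect_true(all(res0$p >= 0.5))
  expect_error(diff_expression(a[, 1:2], b), ">= 3")
})

test_that("no prognostic genes are selected when survival is independent", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 400 + s,
                      survival = list(n_patients = 300,
                                      planted = list(n_genes = 1, beta = 0,
                                                     cut_quantile = 0.5)))
    ex <- make_expression(cfg, gene_ids = paste0("g", 1:200),
                          sample_ids = sprintf("P%04d", 1:300))
    sv <- make_survival_cohort(cfg, ex$expr)
    nrow(select_prognostic(sv$cohort, rownames(ex$expr), direction = "any"))
  }, 0)
  expect_gte(mean(hits == 0), 0.8)
})

test_that("planted prognostic genes are selected with correct betas", {
  # complete follow-up keeps the per-gene signal sharp for this unit check;
  # the marginal effect of each planted gene is still attenuated by the
  # combined hazard of the other nine, so recovery is high but not total
  recovered <- false_sel <- 0
  for (s in c(37, 38, 39)) {
    cfg <- sim_config(seed = s,
                      survival = list(n_patients = 600, censoring_rate = 0))
    ex <- make_expression(cfg, gene_ids = paste0("g", 1:200),
                          sample_ids = sprintf("P%04d", 1:600))
    sv <- make_survival_cohort(cfg, ex$expr)
    sel <- select_prognostic(sv$cohort, rownames(ex$expr), direction = "any")
    recovered <- recovered + sum(sel$gene_id %in% sv$truth$gene_id)
    false_sel <- false_sel + sum(!sel$gene_id %in% sv$truth$gene_id)
  }
  expect_gte(recovered, 21) # mean >= 7 of 10 per cohort
  expect_lte(false_sel, 3)
  cfg <- sim_config(seed = 37,
                    survival = list(n_patients = 600, censoring_rate = 0))
  ex <- make_expression(cfg, gene_ids = paste0("g", 1:200),
                        sample_ids = sprintf("P%04d", 1:600))
  sv <- make_survival_cohort(cfg, ex$expr)
  # adverse_high keeps only beta > 0 (all planted effects are adverse-high)
  sel_hi <- select_prognostic(sv$cohort, rownames(ex$expr),
                              direction = "adverse_high")
  expect_true(all(sel_hi$beta > 0))
  expect_true(all(sel_hi$q_value <= 0.05))
  expect_true(all(sel_hi$prop_above > 0 & sel_hi$prop_above < 1))
  expect_error(select_prognostic(sv$cohort, character()), "non-empty")
  expect_error(select_prognostic(sv$cohort, "nope"), "absent")
})

test_that("score arithmetic matches the +/-1-weighted beta sum", {
  mod <- risk_model(tibble::tibble(gene_id = c("a", "b"),
                                   beta = c(0.5, -0.3),
                                   cutpoint = c(1, 1),
                                   prop_above = c(0.5, 0.5)))
  e <- matrix(c(2, 2, 0, 0, 2, 0, 1, 1), nrow = 2,
              dimnames = list(c("a", "b"), paste0("p", 1:4)))
  sc <- score_patients(e, mod)
  expect_equal(sc$score, c(0.2, -0.2, 0.8, -0.2)) # equality codes below
  sc_above <- score_patients(e, mod, ties = "above")
  expect_equal(sc_above$score[4], 0.2)
  expect_error(score_patients(e[1, , drop = FALSE], mod), "missing")
})

test_that("scores are invariant to gene order and move by 2*beta across a cutpoint", {
  set.seed(9)
  genes <- tibble::tibble(gene_id = paste0("g", 1:6),
                          beta = rnorm(6), cutpoint = runif(6, 1, 2),
                          prop_above = 0.5)
  mod <- risk_model(genes)
  mod_shuffled <- risk_model(genes[sample.int(6), ])
  e <- matrix(runif(6 * 10, 0, 3), nrow = 6,
              dimnames = list(genes$gene_id, paste0("p", 1:10)))
  expect_equal(score_patients(e, mod)$score,
               score_patients(e, mod_shuffled)$score)
  # zero-beta gene changes nothing
  mod0 <- risk_model(dplyr::bind_rows(
    genes, tibble::tibble(gene_id = "z", beta = 0, cutpoint = 1,
                          prop_above = 0.5)))
  e0 <- rbind(e, z = runif(10, 0, 3))
  expect_equal(score_patients(e0, mod0)$score, score_patients(e, mod)$score)
  # crossing one cutpoint moves the score by exactly 2 * beta
  e2 <- e
  e2["g3", 1] <- genes$cutpoint[3] + 10 # force above
  e["g3", 1] <- genes$cutpoint[3] - 1   # force below
  d <- score_patients(e2, mod)$score[1] - score_patients(e, mod)$score[1]
  expect_equal(d, 2 * genes$beta[3])
})

test_that("score cutoff matches the exhaustive scan and splits the cohort", {
  sv <- make_cohort(41, n = 300)
  sel <- tibble::tibble(gene_id = sv$truth$gene_id,
                        beta = sv$truth$beta,
                        cutpoint = sv$truth$cutpoint, prop_above = 0.5)
  mod <- risk_model(sel)
  sc <- score_patients(sv$cohort$expression, mod)
  split <- fit_score_cutoff(sc, sv$cohort)
  want <- o_maxstat(sv$cohort$patients$time, sv$cohort$patients$event,
                    sc$score)
  expect_equal(split$score_cutoff, want$cutpoint)
  expect_equal(glance(split)$n_high + glance(split)$n_low, 300)
  expect_lt(split$logrank$p_value, 0.001)
  # permuting patient order leaves the cutoff unchanged
  perm <- sample.int(nrow(sc))
  split2 <- fit_score_cutoff(sc[perm, ], sv$cohort)
  expect_equal(split2$score_cutoff, split$score_cutoff)
  expect_error(fit_score_cutoff(dplyr::mutate(sc, score = 1), sv$cohort),
               "constant")
})

test_that("model transfer quantile-matches cutpoints and copies betas", {
  m <- risk_model(tibble::tibble(gene_id = "g", beta = 1, cutpoint = 99,
                                 prop_above = 0.4),
                  score_cutoff = -1.5)
  ve <- matrix(1:10, nrow = 1, dimnames = list("g", paste0("p", 1:10)))
  tm <- transfer_model(m, ve)
  expect_equal(tm$genes$cutpoint, 6) # 7..10 above: fraction 0.4
  expect_equal(tm$genes$achieved_prop_above, 0.4)
  expect_equal(tm$genes$beta, m$genes$beta)
  expect_equal(tm$score_cutoff, -1.5)

  # identity transfer: training matrix reproduces training dichotomies
  set.seed(10)
  e <- matrix(runif(3 * 50), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("p", 1:50)))
  genes <- tibble::tibble(gene_id = c("a", "b", "c"), beta = c(1, -1, 0.5),
                          cutpoint = apply(e, 1, median),
                          prop_above = apply(e > apply(e, 1, median), 1,
                                             mean))
  m2 <- risk_model(genes)
  t2 <- transfer_model(m2, e)
  above_orig <- e > genes$cutpoint
  above_new <- e > t2$genes$cutpoint
  expect_equal(above_new, above_orig)
  expect_error(transfer_model(m2, e[1:2, ]), "missing")
})

test_that("transfer approximately preserves the above-cutpoint fraction", {
  sv <- make_cohort(43, n = 200)
  genes <- tibble::tibble(gene_id = rownames(sv$cohort$expression)[1:20],
                          beta = 1, cutpoint = 0, prop_above = 0)
  for (i in 1:20) {
    xg <- sv$cohort$expression[genes$gene_id[i], ]
    genes$cutpoint[i] <- unname(quantile(xg, 0.6))
    genes$prop_above[i] <- mean(xg > genes$cutpoint[i])
  }
  valid <- make_cohort(44, n = 150)
  t3 <- transfer_model(risk_model(genes), valid$cohort$expression)
  gap <- abs(t3$genes$achieved_prop_above - genes$prop_above)
  expect_true(all(gap <= 1 / 150 + 1e-9))
})

test_that("score-response correlation matches the textbook formula", {
  s <- c(1, 2, 3, 4, 5); r <- c(2.1, 3.9, 6.2, 8.1, 9.7)
  got <- correlate_score_response(s, r)
  rr <- sum((s - mean(s)) * (r - mean(r))) /
    sqrt(sum((s - mean(s))^2) * sum((r - mean(r))^2))
  tt <- rr * sqrt(3 / (1 - rr^2))
  expect_equal(got$r, rr)
  expect_equal(got$r_squared, rr^2)
  expect_equal(got$p, 2 * pt(-abs(tt), df = 3))
  # exact linear response
  lin <- correlate_score_response(s, 2 - 3 * s)
  expect_equal(lin$r_squared, 1)
  expect_warning(na <- correlate_score_response(c(s, 9), c(r, NA)),
                 "missing")
  expect_equal(na$n, 5)
  expect_error(correlate_score_response(s, rep(1, 5)), "variance")
  expect_error(correlate_score_response(s[1:3], r[1:3]), ">= 4")
})

test_that("risk models round-trip through TSV", {
  genes <- tibble::tibble(gene_id = c("a", "b"), beta = c(0.123456789, -2),
                          cutpoint = c(pi, exp(1)), prop_above = c(0.4, 0.6),
                          q_value = c(0.01, 0.04))
  m <- risk_model(genes, score_cutoff = -3.45)
  f <- withr::local_tempfile()
  write_risk_model(m, f)
  m2 <- read_risk_model(f)
  expect_equal(m2$genes$beta, m$genes$beta)
  expect_equal(m2$genes$cutpoint, m$genes$cutpoint)
  expect_equal(m2$score_cutoff, m$score_cutoff)
})
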