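# Prognostic gene selection and the +/-1-weighted Cox-beta risk score:
# per-gene maxstat dichotomies with BH control, Cox betas on the
# dichotomies, per-patient score = sum(beta_g * w_g) with w_g = +1 when
# expression exceeds the gene's cutpoint (ties code as below, -1), a
# maxstat cutoff on the score itself, and quantile-matched transfer of
# cutpoints to a validation cohort.

#' Assemble a survival cohort
#'
#' @param patients Tibble with `patient_id`, `time` (> 0, months) and
#'   `event` (0/1).
#' @param expression Genes x patients numeric matrix; column names must
#'   match `patient_id` (order is aligned here).
#' @return Object of class `survival_cohort`: list with `patients` and
#'   `expression` aligned column-wise.
#' @export
survival_cohort <- function(patients, expression) {
  check_surv(patients$time, patients$event)
  if (is.null(colnames(expression)) ||
      !all(patients$patient_id %in% colnames(expression))) {
    abort("expression columns must cover all patient ids")
  }
  expression <- expression[, patients$patient_id, drop = FALSE]
  structure(list(patients = as_tibble(patients), expression = expression),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("Survival cohort:", nrow(x$patients), "patients,",
      nrow(x$expression), "genes,", sum(x$patients$event), "events\n")
  invisible(x)
}

#' Per-gene differential expression between two sample groups
#'
#' One-sided two-sample Wilcoxon rank-sum test per gene with BH adjustment:
#' `alternative = "over"` tests for higher expression in `expr_a` than in
#' `expr_b`, `"under"` the reverse.
#'
#' @param expr_a,expr_b Genes x samples matrices with identical row order;
#'   at least 3 samples per group.
#' @param alternative `"over"` or `"under"`.
#' @return Tibble: `gene_id`, `statistic` (Wilcoxon W), `p`, `q`.
#' @export
diff_expression <- function(expr_a, expr_b, alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  if (!identical(rownames(expr_a), rownames(expr_b))) {
    abort("expr_a and expr_b must share the same gene index")
  }
  if (ncol(expr_a) < 3 || ncol(expr_b) < 3) {
    abort("need >= 3 samples per group")
  }
  alt <- if (alternative == "over") "greater" else "less"
  res <- apply(cbind(expr_a, expr_b), 1, function(v) {
    a <- v[seq_len(ncol(expr_a))]
    b <- v[-seq_len(ncol(expr_a))]
    w <- suppressWarnings(wilcox.test(a, b, alternative = alt, exact = FALSE))
    c(w$statistic, w$p.value)
  })
  tibble(gene_id = rownames(expr_a), statistic = res[1, ], p = res[2, ],
         q = bh_adjust(res[2, ]))
}

#' Select prognostic genes by maxstat + BH
#'
#' For every candidate gene: maxstat cutpoint and selection-adjusted p on
#' the cohort; BH across candidates; genes at `q <= fdr` are dichotomized
#' at their cutpoint and a univariate Cox beta fitted (above cutpoint coded
#' 1). A direction filter keeps genes whose beta sign matches the expected
#' adverse direction.
#'
#' @param cohort A [survival_cohort()].
#' @param candidates Character vector of candidate gene ids (subset of the
#'   cohort's genes); must be non-empty.
#' @param fdr BH threshold (default 0.05).
#' @param direction `"adverse_high"` (high expression adverse, beta > 0),
#'   `"adverse_low"`, or `"any"`.
#' @param eps Maxstat quantile window (default `c(0.1, 0.9)`).
#' @return Tibble of selected risk genes: `gene_id`, `beta`, `se`,
#'   `cutpoint`, `prop_above` (training fraction strictly above the
#'   cutpoint), `max_statistic`, `p`, `q_value`, `separation`.
#' @export
select_prognostic <- function(cohort, candidates, fdr = 0.05,
                              direction = c("adverse_high", "adverse_low",
                                            "any"),
                              eps = c(0.1, 0.9)) {
  direction <- match.arg(direction)
  if (length(candidates) == 0) abort("`candidates` must be non-empty")
  miss <- setdiff(candidates, rownames(cohort$expression))
  if (length(miss)) {
    abort(paste0("candidate genes absent from cohort: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  tm <- cohort$patients$time
  ev <- cohort$patients$event
  scan <- map(candidates, function(g) {
    ms <- maxstat_cutpoint(tm, ev, cohort$expression[g, ], eps = eps)
    tibble(gene_id = g, cutpoint = ms$cutpoint,
           max_statistic = ms$max_statistic, p = ms$p_value)
  }) |> list_rbind()
  scan$q_value <- bh_adjust(scan$p)
  kept <- filter(scan, .data$q_value <= fdr)
  if (nrow(kept) == 0) {
    return(mutate(kept, beta = numeric(), se = numeric(),
                  prop_above = numeric(), separation = logical()))
  }
  fits <- map(seq_len(nrow(kept)), function(i) {
    g <- kept$gene_id[i]
    xg <- cohort$expression[g, ]
    above <- as.numeric(xg > kept$cutpoint[i])
    fit <- cox_beta_binary(tm, ev, above)
    tibble(beta = fit$beta, se = fit$se, separation = !fit$converged,
           prop_above = mean(above))
  }) |> list_rbind()
  out <- as_tibble(cbind(kept, fits))
  out <- switch(direction,
                adverse_high = filter(out, .data$beta > 0),
                adverse_low = filter(out, .data$beta < 0),
                any = out)
  select(out, "gene_id", "beta", "se", "cutpoint", "prop_above",
         "max_statistic", "p", "q_value", "separation")
}

#' Build a risk-score model
#'
#' @param genes Tibble of risk genes as returned by [select_prognostic()]
#'   (needs at least `gene_id`, `beta`, `cutpoint`, `prop_above`).
#' @param score_cutoff Optional global score cutoff (filled by
#'   [fit_score_cutoff()]).
#' @param training_meta Optional list of cohort name, n, seed.
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(genes, score_cutoff = NULL, training_meta = list()) {
  need <- c("gene_id", "beta", "cutpoint", "prop_above")
  if (!all(need %in% names(genes))) {
    abort(paste0("`genes` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(genes) == 0) abort("risk model needs >= 1 gene")
  structure(list(genes = as_tibble(genes),
                 score_cutoff = score_cutoff,
                 training_meta = training_meta),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Risk-score model:", nrow(x$genes), "genes | score range [",
      format(-sum(abs(x$genes$beta)), digits = 4), ",",
      format(sum(abs(x$genes$beta)), digits = 4), "] | cutoff:",
      if (is.null(x$score_cutoff)) "unset"
      else format(x$score_cutoff, digits = 4), "\n")
  invisible(x)
}

#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) x$genes

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         score_cutoff = x$score_cutoff %||% NA_real_,
         max_abs_score = sum(abs(x$genes$beta)))
}

#' Score patients with a risk model
#'
#' `score(patient) = sum_g beta_g w_g` with `w_g = +1` if the patient's
#' expression of gene g is strictly above the gene's cutpoint, else `-1`
#' (equality codes as below).
#'
#' @param expr Genes x patients matrix containing every model gene.
#' @param model A [risk_model()].
#' @param ties `"below"` (default: equality at the cutpoint weights -1) or
#'   `"above"`.
#' @return Tibble: `patient_id`, `score`.
#' @export
score_patients <- function(expr, model, ties = c("below", "above")) {
  ties <- match.arg(ties)
  miss <- setdiff(model$genes$gene_id, rownames(expr))
  if (length(miss)) {
    abort(paste0("genes missing from expression matrix: ",
                 paste(miss, collapse = ", ")))
  }
  e <- expr[model$genes$gene_id, , drop = FALSE]
  above <- if (ties == "below") e > model$genes$cutpoint
           else e >= model$genes$cutpoint
  w <- ifelse(above, 1, -1)
  tibble(patient_id = colnames(expr),
         score = as.numeric(colSums(w * model$genes$beta)))
}

#' Maxstat cutoff on the risk score
#'
#' Applies [maxstat_cutpoint()] to the per-patient score, splits the cohort
#' into high-risk (`score > cutoff`) and low-risk groups, and tests the
#' split with the log-rank test.
#'
#' @param scores Tibble `patient_id`, `score` (from [score_patients()]).
#' @param cohort A [survival_cohort()] covering the same patients;
#'   at least 20.
#' @param eps Maxstat window (default `c(0.1, 0.9)`).
#' @return Object of class `score_split`: list with `score_cutoff`,
#'   `groups` (tibble `patient_id`, `score`, `risk_group`), `logrank`
#'   (one-row tibble), `maxstat` and per-group Kaplan-Meier curves `km`
#'   (tibble with `risk_group` column).
#' @export
fit_score_cutoff <- function(scores, cohort, eps = c(0.1, 0.9)) {
  pat <- inner_join(cohort$patients, scores, by = "patient_id")
  if (nrow(pat) < 20) abort("need >= 20 patients")
  if (length(unique(pat$score)) < 2) abort("scores are constant")
  ms <- maxstat_cutpoint(pat$time, pat$event, pat$score, eps = eps)
  groups <- pat |>
    mutate(risk_group = ifelse(.data$score > ms$cutpoint, "high", "low")) |>
    select("patient_id", "score", "risk_group")
  lr <- logrank_test(pat$time, pat$event,
                     ifelse(pat$score > ms$cutpoint, "high", "low"))
  km <- map(c("high", "low"), function(gp) {
    idx <- groups$risk_group == gp
    mutate(km_estimate(pat$time[idx], pat$event[idx]), risk_group = gp)
  }) |> list_rbind()
  structure(list(score_cutoff = ms$cutpoint, groups = groups, logrank = lr,
                 maxstat = ms, km = km),
            class = "score_split")
}

#' @export
print.score_split <- function(x, ...) {
  tab <- table(x$groups$risk_group)
  cat("Score split at", format(x$score_cutoff, digits = 4), "| high:",
      tab[["high"]], "low:", tab[["low"]], "| log-rank p =",
      format(x$logrank$p_value, digits = 3), "\n")
  invisible(x)
}

#' @method glance score_split
#' @export
glance.score_split <- function(x, ...) {
  tab <- table(factor(x$groups$risk_group, levels = c("high", "low")))
  tibble(score_cutoff = x$score_cutoff, n_high = as.integer(tab[["high"]]),
         n_low = as.integer(tab[["low"]]),
         chi_square = x$logrank$chi_square, p_value = x$logrank$p_value)
}

#' Transfer a risk model to a validation cohort
#'
#' For each model gene the validation cutpoint is the largest observed
#' validation value `v` such that the fraction of validation patients with
#' expression strictly above `v` is at least the training `prop_above`
#' (quantile matching). Betas and the global score cutoff are copied
#' unchanged.
#'
#' @param model A [risk_model()].
#' @param validation_expr Genes x patients matrix containing every model
#'   gene.
#' @return A new `risk_model` with validation cutpoints and an added
#'   `achieved_prop_above` column.
#' @export
transfer_model <- function(model, validation_expr) {
  miss <- setdiff(model$genes$gene_id, rownames(validation_expr))
  if (length(miss)) {
    abort(paste0("genes missing from validation expression: ",
                 paste(miss, collapse = ", ")))
  }
  genes <- model$genes
  new_cut <- map_dbl(seq_len(nrow(genes)), function(i) {
    v <- sort(unique(validation_expr[genes$gene_id[i], ]))
    frac_above <- vapply(v, function(u)
      mean(validation_expr[genes$gene_id[i], ] > u), 0)
    ok <- v[frac_above >= genes$prop_above[i]]
    if (length(ok) == 0) {
      warn(paste0("no validation value achieves prop_above for ",
                  genes$gene_id[i], "; using the minimum"))
      return(v[1])
    }
    max(ok)
  })
  genes$cutpoint <- new_cut
  genes$achieved_prop_above <- map_dbl(seq_len(nrow(genes)), function(i)
    mean(validation_expr[genes$gene_id[i], ] > genes$cutpoint[i]))
  risk_model(genes, score_cutoff = model$score_cutoff,
             training_meta = c(model$training_meta, list(transferred = TRUE)))
}

#' Correlate risk scores with a drug-response readout
#'
#' Pearson correlation between per-sample scores and a continuous response
#' (e.g. IC50), with the two-sided t-test p-value. Pairs with missing
#' response are dropped with a warning.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param response Numeric response, same length; may contain `NA`.
#' @return One-row tibble: `r`, `r_squared`, `p`, `n`.
#' @export
correlate_score_response <- function(scores, response) {
  if (length(scores) != length(response)) {
    abort("scores and response lengths differ")
  }
  keep <- !is.na(scores) & !is.na(response)
  if (any(!keep)) warn(paste0("dropping ", sum(!keep), " pairs with missing values"))
  s <- scores[keep]; r <- response[keep]
  if (length(s) < 4) abort("need >= 4 paired samples")
  if (sd(s) == 0 || sd(r) == 0) abort("zero variance in scores or response")
  ct <- cor.test(s, r, method = "pearson")
  tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p = ct$p.value, n = length(s))
}

#' Serialize / read a risk model as TSV
#'
#' The gene table is written as TSV with a `# score_cutoff=` header line;
#' the round trip is lossless.
#'
#' @param model A [risk_model()].
#' @param path Output / input path.
#' @return `write_risk_model()`: `path`, invisibly. `read_risk_model()`:
#'   the `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  cutoff <- if (is.null(model$score_cutoff)) "NA"
            else format(model$score_cutoff, digits = 17)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# score_cutoff=", cutoff), con)
  utils::write.table(model$genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  header <- readLines(path, n = 1)
  cutoff <- as.numeric(sub("^# score_cutoff=", "", header))
  genes <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  risk_model(as_tibble(genes),
             score_cutoff = if (is.na(cutoff)) NULL else cutoff)
}
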