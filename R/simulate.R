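# Seeded synthetic-data generators. Every generator is a pure function of
# a sim_config (including its seed): identical configs give identical
# output, and each generator draws from its own deterministically derived
# seed so changing one config field does not perturb the others. Planted
# ground truth is returned alongside every dataset, in the same tabular
# shapes the analysis functions consume.

#' Simulation configuration
#'
#' Defaults emulate the statistical shape of a 16-sample histone-mark cell
#' line panel with a large newly-diagnosed patient cohort: log-normal
#' expression, exponential survival whose log-hazard is a sum of planted
#' binary gene effects, an exponential enhancer-signal bulk with a small
#' high-signal super-enhancer tail, and IC50s linear in a planted score.
#'
#' @param seed Integer master seed.
#' @param genome List: `n_chroms`, `chrom_length`, `n_genes`,
#'   `gene_length` (min/max), `n_exons`, `min_gap` (minimum intergenic
#'   clearance, keeping neighbouring promoter/downstream windows disjoint).
#' @param n_samples Number of ChIP-seq samples in the panel.
#' @param peaks List: `n_peaks` per sample and mark, `width`, `marks`,
#'   `proportions` (named, over promoter/exon/intron/downstream/
#'   distal_intergenic; a single vector shared by all marks or a named
#'   list per mark), `tss_window`, `comark` (list `n_genes`, `n_samples`
#'   planting promoters carrying both repressive marks).
#' @param enhancers List: `n`, `super_fraction` (in (0, 0.5)),
#'   `bulk_mean`, `super_multiplier`, `peak_width`, `max_constituents`.
#' @param expression List: `n_genes`, `meanlog`, `sdlog_gene` (between-gene
#'   spread of log means), `sdlog` (within-gene noise), `planted_frac`,
#'   `planted_fold` (fold-change planted in group B samples).
#' @param survival List: `n_patients`, `baseline_hazard` (events per
#'   month), `planted` (list `n_genes`, `beta`, `cut_quantile`),
#'   `censoring_rate`.
#' @param response List: `intercept`, `slope`, `sd` linking IC50 to score.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = list(),
                       n_samples = 16,
                       peaks = list(),
                       enhancers = list(),
                       expression = list(),
                       survival = list(),
                       response = list()) {
  merge_defaults <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    genome = merge_defaults(genome, list(
      n_chroms = 4L, chrom_length = 3e7, n_genes = 300L,
      gene_length = c(8000L, 20000L), n_exons = 3L, min_gap = 10000L)),
    peaks = merge_defaults(peaks, list(
      n_peaks = 2000L, width = 500L,
      marks = c("H3K9me3", "H3K27me3"),
      proportions = c(promoter = 0.10, exon = 0.05, intron = 0.354,
                      downstream = 0.042, distal_intergenic = 0.454),
      tss_window = c(3000L, 3000L),
      comark = list(n_genes = 30L, n_samples = NULL))),
    enhancers = merge_defaults(enhancers, list(
      n = 1000L, super_fraction = 0.05, bulk_mean = 10,
      super_multiplier = 20, peak_width = 1000L, max_constituents = 3L)),
    expression = merge_defaults(expression, list(
      n_genes = 500L, meanlog = 5, sdlog_gene = 1, sdlog = 0.5,
      planted_frac = 0.1, planted_fold = 4)),
    survival = merge_defaults(survival, list(
      n_patients = 674L, baseline_hazard = 0.01,
      planted = list(n_genes = 10L, beta = 0.7, cut_quantile = 0.5),
      censoring_rate = 0.6)),
    response = merge_defaults(response, list(
      intercept = 10, slope = -0.5, sd = 0.5)))
  props <- cfg$peaks$proportions
  check_props <- function(p) {
    if (any(p < 0 | p > 1) || sum(p) > 1 + 1e-9) {
      abort("peak feature proportions must lie in [0,1] and sum to <= 1")
    }
  }
  if (is.list(props)) lapply(props, check_props) else check_props(props)
  sf <- cfg$enhancers$super_fraction
  if (sf <= 0 || sf >= 0.5) abort("super_fraction must be in (0, 0.5)")
  structure(cfg, class = "sim_config")
}

# per-generator derived seeds (kept well below 2^31)
sim_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% .Machine$integer.max

#' Generate a synthetic genome of non-overlapping genes
#'
#' Genes are placed uniformly along the chromosomes without overlap, with
#' Bernoulli(0.5) strands and a fixed relative exon layout (first, middle
#' and last slices of the transcript).
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (a [gene_tbl()]), `exons` (interval tibble
#'   with `gene_id`) and `chrom_lengths` (named vector).
#' @export
make_genome <- function(cfg) {
  g <- cfg$genome
  if (g$n_genes < 1) abort("n_genes must be >= 1")
  withr::with_seed(sim_seed(cfg, 101L), {
    chroms <- paste0("chr", seq_len(g$n_chroms))
    per_chrom <- diff(floor(seq(0, g$n_genes, length.out = g$n_chroms + 1)))
    rows <- map(seq_len(g$n_chroms), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      len <- round(runif(k, g$gene_length[1], g$gene_length[2]))
      # genes keep >= min_gap bp of clearance so that promoter/downstream
      # windows of neighbours never swallow each other's planted features
      slack <- g$chrom_length - sum(len) - (g$min_gap + 1) * k
      if (slack <= 0) abort("genes cannot fit on the configured chromosomes")
      gaps <- diff(c(0, sort(runif(k, 0, slack))))
      starts <- cumsum(gaps + g$min_gap + 1) + cumsum(c(0, len[-k]))
      tibble(chrom = chroms[ci], tx_start = round(starts),
             tx_end = round(starts) + len)
    }) |> list_rbind()
    rows$gene_id <- sprintf("g%04d", seq_len(nrow(rows)))
    rows$strand <- ifelse(runif(nrow(rows)) < 0.5, 1L, -1L)
    genes <- gene_tbl(rows$gene_id, rows$chrom, rows$strand,
                      rows$tx_start, rows$tx_end)
    # exons: fixed relative slices [0,.1], [.45,.55], [.9,1] of the body
    rel <- list(c(0, 0.1), c(0.45, 0.55), c(0.9, 1))[seq_len(min(3, g$n_exons))]
    exons <- map(rel, function(r) {
      tibble(chrom = genes$chrom,
             start = as.integer(genes$tx_start +
                                  floor(r[1] * (genes$tx_end - genes$tx_start))),
             end = as.integer(genes$tx_start +
                                ceiling(r[2] * (genes$tx_end - genes$tx_start))),
             gene_id = genes$gene_id)
    }) |> list_rbind() |> arrange(.data$chrom, .data$start)
    list(genes = genes,
         exons = exons,
         chrom_lengths = setNames(rep(g$chrom_length, g$n_chroms), chroms))
  })
}

# intergenic space at >= margin from any gene, as an interval tibble
intergenic_space <- function(genome, margin) {
  genes <- genome$genes
  chrom_len <- genome$chrom_lengths
  buffered <- union_intervals(tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tx_start - as.integer(margin)),
    end = genes$tx_end + as.integer(margin)))
  map(names(chrom_len), function(ch) {
    used <- filter(buffered, .data$chrom == ch)
    bounds <- c(0L, rbind(used$start, used$end), as.integer(chrom_len[[ch]]))
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    tibble(chrom = ch, start = as.integer(starts), end = as.integer(ends))
  }) |> list_rbind() |> filter(.data$end > .data$start)
}

#' Generate per-sample, per-mark peak sets with planted features
#'
#' Peak feature labels are drawn from the configured proportions and
#' placed so that the midpoint-priority annotation rule recovers them. A
#' configured subset of promoters additionally receives both H3K9me3 and
#' H3K27me3 peaks in a configured subset of samples; background promoter
#' peaks of those two marks are drawn from disjoint gene pools so the
#' planted co-marked set is exactly the recoverable one.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [make_genome()].
#' @return List with `peaks` (tibble with `sample` and `mark` columns),
#'   `truth_features` (tibble `sample`, `mark`, `feature`, peak
#'   coordinates) and `truth_comark` (tibble `gene_id`, `sample`).
#' @export
make_peaks <- function(cfg, genome) {
  p <- cfg$peaks
  genes <- genome$genes
  withr::with_seed(sim_seed(cfg, 202L), {
    samples <- sprintf("S%02d", seq_len(cfg$n_samples))
    distal_space <- intergenic_space(genome, margin = max(p$tss_window) +
                                       3000L + p$width) |>
      filter(.data$end - .data$start > 3L * p$width)
    half <- p$width %/% 2L

    # eligible genes per feature placement
    glen <- genes$tx_end - genes$tx_start
    comark_genes <- if (p$comark$n_genes > 0)
      sample(genes$gene_id, p$comark$n_genes) else character()
    bg <- setdiff(genes$gene_id, comark_genes)
    # disjoint background promoter pools for the two repressive marks
    pool <- list(H3K9me3 = bg[seq_along(bg) %% 2L == 0L],
                 H3K27me3 = bg[seq_along(bg) %% 2L == 1L])

    all_peaks <- map(samples, function(s) {
      map(p$marks, function(mk) {
        props <- if (is.list(p$proportions)) p$proportions[[mk]]
                 else p$proportions
        counts <- as.vector(stats::rmultinom(1, p$n_peaks, props))
        names(counts) <- names(props)
        feats <- map(names(counts), function(ft) {
          k <- counts[[ft]]
          if (k == 0) return(NULL)
          if (ft == "distal_intergenic") {
            w <- distal_space$end - distal_space$start
            pick <- sample.int(nrow(distal_space), k, replace = TRUE,
                               prob = w)
            mids <- distal_space$start[pick] +
              floor(runif(k, half + 1, pmax(half + 2, w[pick] - half - 1)))
            tibble(chrom = distal_space$chrom[pick],
                   midpoint = as.integer(mids), feature = ft)
          } else {
            gi <- switch(ft,
                         promoter = {
                           ids <- if (mk %in% names(pool)) pool[[mk]]
                                  else genes$gene_id
                           match(sample(ids, k, replace = TRUE),
                                 genes$gene_id)
                         },
                         sample.int(nrow(genes), k, replace = TRUE))
            mids <- switch(
              ft,
              promoter = genes$tss[gi] +
                as.integer(floor(runif(k, -p$tss_window[1] + half + 1,
                                       p$tss_window[2] - half - 1))) *
                genes$strand[gi],
              exon = genes$tx_start[gi] + floor(glen[gi] * runif(k, 0.46, 0.54)),
              intron = {
                rel <- runif(k, 0.60, 0.84)
                as.integer(ifelse(genes$strand[gi] == 1L,
                                  genes$tx_start[gi] + floor(glen[gi] * rel),
                                  genes$tx_end[gi] - floor(glen[gi] * rel)))
              },
              downstream = {
                d <- floor(runif(k, 500 + half, 2500 - half))
                as.integer(ifelse(genes$strand[gi] == 1L,
                                  genes$tx_end[gi] + d,
                                  genes$tx_start[gi] - d))
              })
            tibble(chrom = genes$chrom[gi], midpoint = as.integer(mids),
                   feature = ft)
          }
        }) |> list_rbind()
        if (nrow(feats) == 0) return(NULL)
        mutate(feats, sample = s, mark = mk)
      }) |> list_rbind()
    }) |> list_rbind()

    # planted co-marked promoters
    comark_samples <- p$comark$n_samples %||% cfg$n_samples
    use_samples <- samples[seq_len(min(comark_samples, cfg$n_samples))]
    comark <- NULL
    if (length(comark_genes) > 0 &&
        all(c("H3K9me3", "H3K27me3") %in% p$marks)) {
      gi <- match(comark_genes, genes$gene_id)
      comark <- map(use_samples, function(s) {
        map(c("H3K9me3", "H3K27me3"), function(mk) {
          tibble(chrom = genes$chrom[gi], midpoint = genes$tss[gi],
                 feature = "promoter", sample = s, mark = mk)
        }) |> list_rbind()
      }) |> list_rbind()
      all_peaks <- bind_rows(all_peaks, comark)
    }

    if (is.null(all_peaks) || nrow(all_peaks) == 0) {
      empty <- tibble(chrom = character(), start = integer(),
                      end = integer(), sample = character(),
                      mark = character())
      return(list(peaks = empty,
                  truth_features = mutate(empty, feature = character()),
                  truth_comark = tibble(gene_id = character(),
                                        sample = character())))
    }
    peaks <- all_peaks |>
      mutate(start = pmax(0L, .data$midpoint - half),
             end = .data$midpoint - half + p$width) |>
      select("chrom", "start", "end", "sample", "mark", "feature")

    truth_comark <- if (is.null(comark)) {
      tibble(gene_id = character(), sample = character())
    } else {
      tidyr::expand_grid(gene_id = sort(comark_genes), sample = use_samples)
    }

    list(peaks = select(peaks, -"feature") |>
           arrange(.data$sample, .data$mark, .data$chrom, .data$start),
         truth_features = peaks,
         truth_comark = truth_comark)
  })
}

#' Generate an enhancer landscape with a planted super-enhancer tail
#'
#' Enhancer loci are placed in intergenic space, far from every TSS and
#' from each other (farther than the stitch gap, so each planted locus
#' survives stitching as one domain). Bulk locus signals are
#' Exponential(`bulk_mean`); a planted fraction are super-enhancers at
#' `super_multiplier` times the bulk mean. Signal is spread uniformly over
#' the locus' constituent peaks as per-bp coverage.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [make_genome()].
#' @param params [se_params()] used for spacing guarantees.
#' @return List with `peaks` (constituent H3K27ac peaks), `coverage`
#'   (coverage tibble) and `truth` (tibble `enhancer_id`, locus span,
#'   `signal`, `is_super`, `n_constituents`).
#' @export
make_enhancer_landscape <- function(cfg, genome, params = se_params()) {
  e <- cfg$enhancers
  withr::with_seed(sim_seed(cfg, 303L), {
    margin <- params$tss_exclusion + 5000L
    space <- intergenic_space(genome, margin = margin)
    span_max <- e$max_constituents * (e$peak_width + 10000L)
    slot <- span_max + params$stitch_gap + 5000L
    slots <- map(seq_len(nrow(space)), function(i) {
      n_slot <- (space$end[i] - space$start[i]) %/% slot
      if (n_slot < 1) return(NULL)
      tibble(chrom = space$chrom[i],
             start = space$start[i] + (seq_len(n_slot) - 1L) * slot)
    }) |> list_rbind()
    if (nrow(slots) < e$n) {
      abort("not enough intergenic space for the configured enhancer count")
    }
    pick <- slots[sample.int(nrow(slots), e$n), ]
    n_super <- max(1L, floor(e$n * e$super_fraction))
    is_super <- c(rep(TRUE, n_super), rep(FALSE, e$n - n_super))[
      sample.int(e$n)]
    signal <- ifelse(is_super,
                     e$super_multiplier * e$bulk_mean * runif(e$n, 0.9, 1.1),
                     rexp(e$n, rate = 1 / e$bulk_mean))
    k <- sample.int(e$max_constituents, e$n, replace = TRUE)
    loci <- map(seq_len(e$n), function(i) {
      gaps <- if (k[i] > 1) floor(runif(k[i] - 1, 2000, 10000)) else integer()
      starts <- pick$start[i] + cumsum(c(0L, gaps + e$peak_width))
      peaks <- tibble(chrom = pick$chrom[i], start = as.integer(starts),
                      end = as.integer(starts + e$peak_width),
                      enhancer_id = i)
      peaks
    }) |> list_rbind()
    # spread each locus' signal uniformly over its constituent bases
    loci <- loci |>
      group_by(.data$enhancer_id) |>
      mutate(value = signal[.data$enhancer_id[1]] /
               sum(.data$end - .data$start)) |>
      ungroup()
    truth <- loci |>
      group_by(.data$enhancer_id) |>
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                end = max(.data$end), n_constituents = dplyr::n(),
                .groups = "drop") |>
      mutate(signal = signal[.data$enhancer_id],
             is_super = is_super[.data$enhancer_id]) |>
      arrange(.data$chrom, .data$start)
    list(peaks = normalize_intervals(select(loci, "chrom", "start", "end")),
         coverage = coverage_tbl(loci$chrom, loci$start, loci$end,
                                 loci$value),
         truth = truth)
  })
}

#' Generate a log-normal expression matrix with planted group effects
#'
#' Per-gene log means are drawn once; samples add independent log-normal
#' noise. When `groups` is supplied, a planted fraction of genes is shifted
#' up by `planted_fold` in the second group level.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Gene identifiers (default `g1..gN` from the config).
#' @param sample_ids Sample identifiers (default `P0001..` sized from the
#'   survival config).
#' @param groups Optional two-level factor over samples enabling planted
#'   differential expression.
#' @return List with `expr` (genes x samples matrix) and `truth` (tibble
#'   `gene_id`, `planted`, `fold`).
#' @export
make_expression <- function(cfg, gene_ids = NULL, sample_ids = NULL,
                            groups = NULL) {
  ex <- cfg$expression
  gene_ids <- gene_ids %||% paste0("g", seq_len(ex$n_genes))
  sample_ids <- sample_ids %||%
    sprintf("P%04d", seq_len(cfg$survival$n_patients))
  withr::with_seed(sim_seed(cfg, 404L), {
    ng <- length(gene_ids); ns <- length(sample_ids)
    mu <- rnorm(ng, ex$meanlog, ex$sdlog_gene)
    expr <- exp(matrix(rnorm(ng * ns, mean = mu, sd = ex$sdlog),
                       nrow = ng, dimnames = list(gene_ids, sample_ids)))
    planted <- rep(FALSE, ng)
    if (!is.null(groups)) {
      g <- as.factor(groups)
      if (nlevels(g) != 2 || length(g) != ns) {
        abort("`groups` must be a two-level factor over the samples")
      }
      n_planted <- round(ex$planted_frac * ng)
      planted[sample.int(ng, n_planted)] <- TRUE
      expr[planted, g == levels(g)[2]] <-
        expr[planted, g == levels(g)[2]] * ex$planted_fold
    }
    list(expr = expr,
         truth = tibble(gene_id = gene_ids, planted = planted,
                        fold = ifelse(planted, ex$planted_fold, 1)))
  })
}

#' Generate a survival cohort with planted prognostic genes
#'
#' Each patient's hazard is `h0 * exp(sum_g beta_g 1[expr_g > cut_g])`
#' over the planted genes, with exponential event times and independent
#' uniform censoring calibrated to the configured censoring rate.
#'
#' @param cfg A [sim_config()].
#' @param expression Genes x patients matrix (e.g. from
#'   [make_expression()]).
#' @param planted_genes Optional gene ids to plant; default draws
#'   `cfg$survival$planted$n_genes` of them (seeded).
#' @return List with `cohort` (a [survival_cohort()]) and `truth` (tibble
#'   `gene_id`, `beta`, `cutpoint`).
#' @export
make_survival_cohort <- function(cfg, expression, planted_genes = NULL) {
  sv <- cfg$survival
  withr::with_seed(sim_seed(cfg, 505L), {
    n <- ncol(expression)
    pl <- sv$planted
    planted_genes <- planted_genes %||%
      sample(rownames(expression), pl$n_genes)
    if (!all(planted_genes %in% rownames(expression))) {
      abort("planted genes must be present in the expression matrix")
    }
    beta <- rep_len(pl$beta, length(planted_genes))
    cut <- vapply(planted_genes, function(g)
      unname(quantile(expression[g, ], pl$cut_quantile)), 0)
    lp <- rep(0, n)
    for (i in seq_along(planted_genes)) {
      lp <- lp + beta[i] * (expression[planted_genes[i], ] > cut[i])
    }
    hazard <- sv$baseline_hazard * exp(lp)
    t_lat <- rexp(n, rate = hazard)
    if (sv$censoring_rate <= 0) {
      time <- t_lat; event <- rep(1, n)
    } else {
      f <- function(tau) mean(pmin(t_lat, tau) / tau) - sv$censoring_rate
      tau <- stats::uniroot(f, c(min(t_lat) * 1e-3, max(t_lat) * 1e3))$root
      cens <- runif(n, 0, tau)
      event <- as.numeric(t_lat <= cens)
      time <- pmin(t_lat, cens)
    }
    patients <- tibble(patient_id = colnames(expression), time = time,
                       event = event)
    list(cohort = survival_cohort(patients, expression),
         truth = tibble(gene_id = planted_genes, beta = beta,
                        cutpoint = unname(cut)))
  })
}

#' Generate IC50 drug response linear in a planted score
#'
#' @param cfg A [sim_config()].
#' @param scores Named numeric vector of per-sample scores (>= 4 samples).
#' @return List with `response` (tibble `sample`, `ic50`) and `truth`
#'   (list `intercept`, `slope`, `sd`).
#' @export
make_drug_response <- function(cfg, scores) {
  if (length(scores) < 4) abort("need >= 4 samples")
  rs <- cfg$response
  withr::with_seed(sim_seed(cfg, 606L), {
    ic50 <- rs$intercept + rs$slope * scores + rnorm(length(scores), 0, rs$sd)
    list(response = tibble(sample = names(scores) %||%
                             as.character(seq_along(scores)),
                           ic50 = as.numeric(ic50)),
         truth = list(intercept = rs$intercept, slope = rs$slope,
                      sd = rs$sd))
  })
}
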