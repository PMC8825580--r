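# Maximally selected rank statistics for survival cutpoints.
#
# For a continuous covariate x, every observed value mu inside the
# eps-quantile window defines a dichotomy {x <= mu} vs {x > mu}. The
# statistic at mu is the standardized log-rank (Savage/Nelson-Aalen score)
# statistic of that split under the permutation distribution:
#
#   a_i = event_i - Lambda(t_i)   (cumulative hazard scores, Breslow-style;
#                                  events precede censoring at tied times)
#   S(mu) = sum_{x_i <= mu} a_i,  E = 0,  V = m (N - m) / (N (N - 1)) sum a^2
#   Z(mu) = S(mu) / sqrt(V)
#
# The reported cutpoint maximizes |Z| (ties -> smaller cutpoint). The
# selection-adjusted p-value uses the improved-Bonferroni approximation of
# Lausen & Schumacher for maximally selected rank statistics, or a
# permutation of the (time, event) pairs against x.

logrank_scores <- function(time, event) {
  # Nelson-Aalen cumulative hazard at each subject's own time
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  n <- length(t_s)
  # distinct times, events and at-risk counts
  ut <- unique(t_s)
  d <- vapply(ut, function(u) sum(e_s[t_s == u]), 0)
  n_risk <- vapply(ut, function(u) sum(t_s >= u), 0)
  lam <- cumsum(d / n_risk)
  Lambda_at <- lam[match(t_s, ut)]
  a <- numeric(n)
  a[ord] <- e_s - Lambda_at
  a
}

# Lausen-Schumacher improved Bonferroni approximation.
# b: observed max |Z|; m: ordered group sizes (# below cutpoint) of the
# candidate splits; N: sample size.
p_lausen_schumacher <- function(b, N, m) {
  if (b <= 0) return(1)
  m <- sort(unique(m))
  if (length(m) < 2) return(min(1, 2 * pnorm(-b)))
  m1 <- m[-length(m)]
  m2 <- m[-1]
  t <- sqrt(1 - m1 * (N - m2) / ((N - m1) * m2))
  D <- sum(exp(-b^2 / 2) / pi * (t - (b^2 / 4 - 1) * t^3 / 6))
  p <- 2 * pnorm(-b) + D
  # never below the single-split (unadjusted) two-sided normal p
  max(min(p, 1), 2 * pnorm(-b))
}

#' Maximally selected rank statistic cutpoint
#'
#' Finds the expression cutpoint maximizing the standardized log-rank
#' statistic over all observed values inside the `eps` quantile window,
#' with a selection-adjusted p-value.
#'
#' @param time,event Survival times (> 0) and 0/1 event indicators;
#'   at least 10 observations.
#' @param x Continuous covariate (e.g. one gene's expression).
#' @param eps Length-2 proportion window: candidate cutpoints must leave a
#'   fraction of observations in `[eps[1], eps[2]]` below or at the
#'   cutpoint (default `c(0.1, 0.9)`).
#' @param method `"approx"` (Lausen-Schumacher improved Bonferroni,
#'   default) or `"permutation"`.
#' @param B Number of permutations for `method = "permutation"`.
#' @param seed Optional seed for the permutation method.
#' @return Object of class `maxstat_cut`: list with `cutpoint`,
#'   `max_statistic` (max |Z|), `z` (signed, for the low group),
#'   `p_value`, `eps`, `method`, `n` and `candidates` (tibble of every
#'   candidate cutpoint with its `n_below` and signed `z`).
#' @export
maxstat_cutpoint <- function(time, event, x, eps = c(0.1, 0.9),
                             method = c("approx", "permutation"),
                             B = 1000, seed = NULL) {
  method <- match.arg(method)
  check_surv(time, event)
  n <- length(time)
  if (n < 10) abort("need >= 10 observations for maxstat")
  if (length(x) != n) abort("`x` must match time/event length")
  if (length(unique(x)) < 2) abort("`x` is constant")
  if (length(eps) != 2 || eps[1] <= 0 || eps[2] >= 1 || eps[1] >= eps[2]) {
    abort("`eps` must satisfy 0 < eps[1] < eps[2] < 1")
  }

  a <- logrank_scores(time, event)
  ssq <- sum(a^2)
  ord <- order(x)
  xs <- x[ord]
  as_cum <- cumsum(a[ord])
  # candidates: largest index of each distinct x value (complete groups)
  last_of_value <- which(xs != c(xs[-1], NA) | seq_len(n) == n)
  last_of_value <- last_of_value[last_of_value < n] # need both groups
  m <- last_of_value
  prop <- m / n
  keep <- prop >= eps[1] & prop <= eps[2]
  m <- m[keep]
  if (length(m) < 2) {
    abort("fewer than 2 distinct candidate cutpoints inside the eps window")
  }
  S <- as_cum[m]
  V <- m * (n - m) / (n * (n - 1)) * ssq
  z <- S / sqrt(V)
  cand <- tibble(cutpoint = xs[m], n_below = m, z = z)
  best <- which.max(abs(z)) # ties: which.max takes the first = smaller cutpoint
  b <- abs(z[best])

  p <- if (method == "approx") {
    p_lausen_schumacher(b, n, m)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) {
          if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    # permuting the scores against the x-sorted order is equivalent to
    # permuting the (time, event) pairs against x
    perm_max <- vapply(seq_len(B), function(i) {
      Sp <- cumsum(sample(a))[m]
      max(abs(Sp / sqrt(V)))
    }, 0)
    (1 + sum(perm_max >= b - 1e-12)) / (B + 1)
  }

  structure(list(cutpoint = cand$cutpoint[best], max_statistic = b,
                 z = z[best], p_value = p, eps = eps, method = method,
                 n = n, candidates = cand),
            class = "maxstat_cut")
}

#' @export
print.maxstat_cut <- function(x, ...) {
  cat("Maxstat cutpoint:", format(x$cutpoint, digits = 4),
      "| max |Z| =", format(x$max_statistic, digits = 4),
      "| p =", format(x$p_value, digits = 4),
      paste0("(", x$method, ")"), "\n")
  invisible(x)
}

#' @method tidy maxstat_cut
#' @export
tidy.maxstat_cut <- function(x, ...) x$candidates

#' @method glance maxstat_cut
#' @export
glance.maxstat_cut <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, max_statistic = x$max_statistic, z = x$z,
         p_value = x$p_value, eps_low = x$eps[1], eps_high = x$eps[2],
         method = x$method, n = x$n)
}
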