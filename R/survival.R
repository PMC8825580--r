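# Survival primitives: Kaplan-Meier, log-rank with a signed Z, univariate
# Cox for a binary covariate, and Benjamini-Hochberg adjustment. The fits
# are delegated to the survival package (Breslow ties everywhere); this
# file owns the contracts, degenerate-input handling and tidy surfaces.

check_surv <- function(time, event) {
  if (length(time) != length(event)) abort("time and event lengths differ")
  if (length(time) < 1) abort("need >= 1 observation")
  if (any(is.na(time)) || any(is.na(event))) abort("missing times/events")
  if (any(time <= 0)) abort("survival times must be > 0")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (1 = death).
#' @return Tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`. `S(0) = 1` implicitly;
#'   `survival` is non-increasing.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 0))
km_estimate <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected with hypergeometric variance summed over
#' distinct event times. The signed `z` is computed for the second group
#' level (positive when that group has more events than expected), so
#' swapping labels negates `z` and leaves `chi_square` and `p` unchanged.
#'
#' @param time,event As in [km_estimate()].
#' @param group Binary group labels (any two values).
#' @return One-row tibble: `chi_square`, `p_value`, `z`, `n1`, `n2`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("`group` must take exactly two values")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  v <- if (is.matrix(sd$var)) sd$var[2, 2] else sd$var[2]
  z <- if (v > 0) (sd$obs[2] - sd$exp[2]) / sqrt(v) else 0
  chi <- z^2
  tibble(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
         z = z, n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2]))
}

#' Univariate Cox model for a binary covariate
#'
#' Partial-likelihood fit (Newton-Raphson, Breslow tie handling) of
#' `h(t) = h0(t) exp(beta x)` for binary `x`. Monotone likelihood
#' (separation) is flagged when `|beta| > 10`; the coefficient is clamped
#' at +/-10 and `converged` set to `FALSE`.
#'
#' @param time,event As in [km_estimate()].
#' @param x Binary covariate taking both values.
#' @return Object of class `cox_fit`: list with `beta` (log hazard ratio
#'   for `x = 1` vs `x = 0`), `se`, `converged`, `n_iter`, `n`, `n_event`.
#' @export
cox_beta_binary <- function(time, event, x) {
  check_surv(time, event)
  if (length(unique(x)) != 2) abort("`x` must take exactly two values")
  if (sum(event) < 1) abort("need >= 1 event")
  xb <- as.numeric(x == sort(unique(x))[2])
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ xb,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)))
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  converged <- is.finite(beta) && abs(beta) <= 10
  if (!converged) beta <- sign(beta) * 10
  structure(list(beta = beta, se = se, converged = converged,
                 n_iter = fit$iter, n = length(time), n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit: beta =", format(x$beta, digits = 4),
      "(se", paste0(format(x$se, digits = 3), ")"),
      if (!x$converged) "[separation: clamped, not converged]", "\n")
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(term = "x", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se,
         p.value = 2 * pnorm(-abs(x$beta / x$se)))
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(beta = x$beta, se = x$se, converged = x$converged,
         n_iter = x$n_iter, n = x$n, n_event = x$n_event)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
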