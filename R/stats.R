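# Rare-event inference for permeation counts: currents and conductance from
# mean event counts, the exact (conditional binomial) test for equality of
# Poisson rates, rate ratios with exact Clopper-Pearson-inverted confidence
# intervals, and percentile bootstrap CIs of mean counts.

#' Ionic current from a mean permeation count
#'
#' `I = mean_events * charge / duration`, in pA. The default charge is the
#' exact +2e; pass `charge = 3.2e-19` to follow the common rounding of the
#' elementary charge to 1.6e-19 C.
#'
#' @param mean_events Mean number of permeation events per trajectory.
#' @param duration Trajectory duration in ns.
#' @param charge Transported charge per event, C.
#' @return Current in pA.
#' @examples
#' events_to_current(0.40, 60)  # ~2.13 pA
#' @export
events_to_current <- function(mean_events, duration, charge = .ca_charge) {
  stopifnot(duration > 0)
  mean_events * charge / (duration * 1e-9) * 1e12
}

#' Channel conductance from current and voltage
#'
#' `g = |I / V|` in pS.
#'
#' @param current Current in pA.
#' @param voltage Transmembrane voltage in mV (non-zero).
#' @return Conductance in pS.
#' @examples
#' conductance(2.13, -400)  # ~5.33 pS
#' @export
conductance <- function(current, voltage) {
  if (any(voltage == 0)) stop("conductance is undefined at zero voltage")
  abs(current / (voltage / 1e3))
}

#' Exact test for equality of two Poisson rates
#'
#' Conditions on the total count `n = c1 + c2`: under the null of equal
#' rates (per unit exposure), `c1 ~ Binomial(n, rho/(1+rho))` with `rho` the
#' exposure ratio (1/2 for equal exposure). The two-sided p-value doubles the
#' smaller tail, capped at 1.
#'
#' @param c1,c2 Total event counts in the two conditions.
#' @param exposure_ratio Exposure of condition 1 over condition 2.
#' @return p-value in `[0, 1]` (1 with a warning when both totals are 0).
#' @examples
#' exact_poisson_test(16, 2)  # 0.0013
#' exact_poisson_test(4, 2)   # 0.6875
#' @export
exact_poisson_test <- function(c1, c2, exposure_ratio = 1) {
  stopifnot(c1 >= 0, c2 >= 0, c1 == round(c1), c2 == round(c2),
            exposure_ratio > 0)
  n <- c1 + c2
  if (n == 0) {
    warning("both totals are zero; the conditional test is degenerate")
    return(1)
  }
  p0 <- exposure_ratio / (1 + exposure_ratio)
  lo <- stats::pbinom(c1, n, p0)
  hi <- stats::pbinom(c1 - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Rate ratio with exact confidence interval
#'
#' Effect size for two Poisson counts: `RR = (c1/E1) / (c2/E2)`, with an
#' exact CI by Clopper-Pearson inversion of the conditional binomial
#' proportion `pi = c1/(c1+c2)`: `pi_L = qbeta(alpha/2; c1, c2+1)`,
#' `pi_U = qbeta(1-alpha/2; c1+1, c2)`, mapped to the rate-ratio scale by
#' `RR = pi/(1-pi) * E2/E1`. A zero `c2` gives an infinite upper bound.
#'
#' @inheritParams exact_poisson_test
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @return Object of class `rate_inference` with `rate_ratio`, `ci`,
#'   `p_value`, `alpha`, `counts` and `exposure_ratio`.
#' @examples
#' rate_ratio_ci(16, 2)  # RR = 8, CI ~ [1.88, 71.72]
#' @export
rate_ratio_ci <- function(c1, c2, exposure_ratio = 1, alpha = 0.05) {
  stopifnot(c1 >= 0, c2 >= 0, exposure_ratio > 0, alpha > 0, alpha < 1)
  if (c1 == 0 && c2 == 0)
    stop("rate ratio is undefined when both totals are zero")
  rr <- if (c2 > 0) (c1 / c2) / exposure_ratio else Inf
  pi_l <- if (c1 > 0) stats::qbeta(alpha / 2, c1, c2 + 1) else 0
  pi_u <- if (c2 > 0) stats::qbeta(1 - alpha / 2, c1 + 1, c2) else 1
  ci <- c(lower = pi_l / (1 - pi_l) / exposure_ratio,
          upper = if (pi_u < 1) pi_u / (1 - pi_u) / exposure_ratio else Inf)
  structure(list(rate_ratio = rr, ci = ci,
                 p_value = exact_poisson_test(c1, c2, exposure_ratio),
                 alpha = alpha, counts = c(c1 = c1, c2 = c2),
                 exposure_ratio = exposure_ratio,
                 method = "conditional binomial, Clopper-Pearson inversion"),
            class = "rate_inference")
}

#' @export
print.rate_inference <- function(x, ...) {
  up <- if (is.finite(x$ci[2])) sprintf("%.2f", x$ci[2]) else "Inf"
  cat(sprintf("Rate ratio %.4g (counts %d vs %d), %g%% CI [%.2f, %s]\n",
              x$rate_ratio, x$counts[1], x$counts[2], 100 * (1 - x$alpha),
              x$ci[1], up))
  cat(sprintf("  exact Poisson test (two-sided conditional binomial): p = %.4g\n",
              x$p_value))
  invisible(x)
}

#' Percentile bootstrap CI of a mean count
#'
#' Resamples the per-trajectory counts with replacement and returns the
#' percentile interval of the resampled means.
#'
#' @param counts Integer per-trajectory event counts (length >= 2).
#' @param n_resamples Number of bootstrap resamples.
#' @param alpha Two-sided level.
#' @param seed Optional RNG seed for reproducibility.
#' @return `c(lower, upper)` with attribute `mean`.
#' @examples
#' bootstrap_ci_mean(c(0, 0, 0, 1, 1), seed = 1)  # ~[0.0, 0.8]
#' @export
bootstrap_ci_mean <- function(counts, n_resamples = 10000, alpha = 0.05,
                              seed = NULL) {
  stopifnot(length(counts) >= 2, n_resamples >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(counts)
  means <- colMeans(matrix(sample(counts, n * n_resamples, replace = TRUE),
                           nrow = n))
  ci <- unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2)))
  structure(ci, mean = mean(counts))
}

#' Integer count vector matching a printed mean and SD
#'
#' Recovers per-trajectory counts when only their mean and sample SD are
#' printed: searches all non-negative integer vectors of the given length
#' (bounded totals) and returns those matching both summaries to the printed
#' precision.
#'
#' @param mean_count,sd_count Printed mean and sample SD.
#' @param n Number of trajectories.
#' @param digits Printed precision.
#' @param max_count Largest count considered per trajectory.
#' @return Matrix with one matching (sorted) count vector per row.
#' @export
counts_from_summary <- function(mean_count, sd_count, n = 5, digits = 2,
                                max_count = 10) {
  grid <- do.call(expand.grid, rep(list(0:max_count), n))
  grid <- as.matrix(grid[apply(grid, 1, function(r) !is.unsorted(r)), ,
                         drop = FALSE])
  m <- rowMeans(grid)
  s <- apply(grid, 1, stats::sd)
  hit <- round(m, digits) == round(mean_count, digits) &
    round(s, digits) == round(sd_count, digits)
  out <- grid[hit, , drop = FALSE]
  dimnames(out) <- NULL
  out
}
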