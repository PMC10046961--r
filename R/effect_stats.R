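#' Percent change from baseline
#'
#' Per-well percent change of the peak number between the baseline window
#' and the post-treatment window: `100 * (post - baseline) / baseline`.
#' Wells with a zero baseline peak number carry no defined change and are
#' excluded with reason `"zero baseline"`. Complete cessation gives exactly
#' -100.
#'
#' @param baseline,post Peak numbers (pulses/10 min), both >= 0.
#' @return A list with `delta_pct` (numeric or `NA`), `excluded` (flag) and
#'   `reason` (`NA` or text).
#' @examples
#' percent_change(20, 42)$delta_pct  # +110
#' percent_change(10, 0)$delta_pct   # -100
#' percent_change(0, 5)$reason
#' @export
percent_change <- function(baseline, post) {
  if (length(baseline) != 1L || length(post) != 1L)
    stop("percent_change is scalar; use it per well")
  if (is.na(baseline) || is.na(post) || baseline < 0 || post < 0)
    stop("peak numbers must be non-negative")
  if (baseline == 0)
    return(list(delta_pct = NA_real_, excluded = TRUE,
                reason = "zero baseline"))
  list(delta_pct = 100 * (post - baseline) / baseline, excluded = FALSE,
       reason = NA_character_)
}

#' Two-sample Wilcoxon rank-sum test against vehicle
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p-value comparing a compound's
#' per-well percent changes to the same-plate vehicle wells. The exact null
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used. Identical constant samples give p = 1.
#'
#' @param drug_deltas,dmso_deltas Non-empty numeric vectors of percent
#'   changes.
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_vs_dmso(c(1, 2, 3), c(10, 11, 12))  # exact: 0.1
#' @export
wilcoxon_vs_dmso <- function(drug_deltas, dmso_deltas) {
  x <- as.numeric(drug_deltas)
  y <- as.numeric(dmso_deltas)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples contain NA")
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && m + n <= 20) {
    # exact: the U distribution is symmetric about m*n/2
    p <- if (u > m * n / 2)
      stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
    else
      stats::pwilcox(u, m, n)
    return(min(1, 2 * p))
  }
  nties <- table(pooled)
  mu <- m * n / 2
  sigma2 <- (m * n / 12) *
    ((m + n + 1) - sum(nties^3 - nties) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Nonparametric tolerance interval from order statistics
#'
#' Two-sided distribution-free tolerance interval covering at least a
#' proportion `coverage` of the population with the stated confidence, built
#' from symmetric order statistics: among pairs (r, s = n - r + 1) it picks
#' the largest r (narrowest interval) whose coverage - which follows a
#' Beta(s - r, n - s + r + 1) law - reaches the target confidence. The
#' defaults (80% coverage, 95% confidence) require n >= 22 even at the
#' sample extremes; smaller samples are rejected with the minimal feasible
#' size.
#'
#' @param samples Numeric vector of observations (e.g. vehicle percent
#'   changes).
#' @param coverage Population proportion to cover, in (0, 1). Default 0.80.
#' @param confidence Target confidence level, in (0, 1). Default 0.95.
#' @return A list of class `calosc_tolerance_interval`: `lower`, `upper`,
#'   `coverage`, `confidence_target`, `confidence_achieved`, `r`, `s`, `n`.
#' @examples
#' tolerance_interval(rnorm(30))
#' @export
tolerance_interval <- function(samples, coverage = 0.80, confidence = 0.95) {
  x <- as.numeric(samples)
  if (anyNA(x)) stop("samples contain NA")
  n <- length(x)
  if (coverage <= 0 || coverage >= 1 || confidence <= 0 || confidence >= 1)
    stop("coverage and confidence must be in (0, 1)")
  conf_at <- function(r, n) 1 - stats::pbeta(coverage, n - 2 * r + 1, 2 * r)
  if (n < 2 || conf_at(1, n) < confidence) {
    n_min <- 2
    while (conf_at(1, n_min) < confidence) n_min <- n_min + 1
    stop(sprintf(paste0("n = %d is infeasible for coverage %.2f at ",
                        "confidence %.2f; minimal feasible n is %d"),
                 n, coverage, confidence, n_min))
  }
  r <- 1L
  while (2 * (r + 1) <= n && conf_at(r + 1, n) >= confidence) r <- r + 1L
  s <- n - r + 1L
  xs <- sort(x)
  structure(list(lower = xs[r], upper = xs[s], coverage = coverage,
                 confidence_target = confidence,
                 confidence_achieved = conf_at(r, n),
                 r = r, s = s, n = n),
            class = "calosc_tolerance_interval")
}

#' @export
print.calosc_tolerance_interval <- function(x, ...) {
  cat(sprintf(paste0("<tolerance interval> [%.3g, %.3g] (order stats %d/%d ",
                     "of n = %d): covers %.0f%% of the population with ",
                     "achieved confidence %.3f\n"),
              x$lower, x$upper, x$r, x$s, x$n, 100 * x$coverage,
              x$confidence_achieved))
  invisible(x)
}

#' Summarize one drug concentration on a plate
#'
#' Mean and SD of the per-well percent changes for one drug at one
#' concentration, with the rank-sum p-value against the same-plate vehicle
#' wells. The dose is significant when p < `alpha`; the direction is the
#' sign of the mean change when significant, `none` otherwise.
#'
#' @param observations Percent-change observations for the dose: either a
#'   numeric vector or a data.frame with columns `delta_pct` and `excluded`
#'   (excluded wells are dropped), optionally `treatment` and
#'   `concentration` carried into the result.
#' @param dmso Vehicle observations in the same two forms.
#' @param alpha Significance level (default 0.05).
#' @return A one-row data.frame: `treatment`, `concentration`, `n_wells`,
#'   `mean_delta_pct`, `sd_delta_pct`, `p_value`, `significant`, `direction`.
#' @export
summarize_dose <- function(observations, dmso, alpha = 0.05) {
  pull <- function(obs) {
    if (is.data.frame(obs)) {
      if (!is.null(obs$excluded)) obs <- obs[!obs$excluded, , drop = FALSE]
      obs$delta_pct
    } else as.numeric(obs)
  }
  treatment <- if (is.data.frame(observations) &&
                   !is.null(observations$treatment))
    observations$treatment[1] else NA_character_
  concentration <- if (is.data.frame(observations) &&
                       !is.null(observations$concentration))
    observations$concentration[1] else NA_real_
  x <- pull(observations)
  y <- pull(dmso)
  if (!length(x)) stop("all wells excluded for this dose")
  if (!length(y)) stop("no vehicle wells available")
  p <- wilcoxon_vs_dmso(x, y)
  sig <- p < alpha
  m <- mean(x)
  data.frame(
    treatment = treatment, concentration = concentration,
    n_wells = length(x), mean_delta_pct = m,
    sd_delta_pct = stats::sd(x), p_value = p, significant = sig,
    direction = if (!sig || m == 0) "none" else if (m > 0) "up" else "down"
  )
}
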