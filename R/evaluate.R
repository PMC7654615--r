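#' Convergence classification for a fitted method
#'
#' A fit counts as a convergence failure when the fitter itself signaled an
#' error or non-convergence, or when the estimated treatment odds ratio or
#' its standard error exceeds 1000 in absolute value (a symptom of
#' separation or a degenerate likelihood even when the optimizer reports
#' success).
#'
#' @param fit A \code{fit_result}, or a data frame row with columns
#'   \code{converged}, \code{log_or}, \code{se}.
#' @return \code{TRUE} if the fit is usable, \code{FALSE} otherwise.
#' @export
classify_convergence <- function(fit) {
  ok <- isTRUE(fit$converged) &&
    is.finite(fit$log_or) && is.finite(fit$se) &&
    exp(abs(fit$log_or)) <= 1000 && fit$se <= 1000
  ok
}

#' Summarize replicate fits of one method under one scenario
#'
#' Computes the per-scenario performance measures over the converged
#' replicates only: the rejection rate of the two-sided 5% Wald test (type I
#' error under a null scenario, power otherwise), the mean odds ratio
#' (exponentiated mean log odds ratio), the coverage of the 95% CI with
#' respect to the method-appropriate truth (conditional for the
#' random-intercept and Mantel-Haenszel methods, marginal for the others),
#' and the convergence rate among non-prescreened replicates. Each measure
#' carries a Monte Carlo standard error: binomial for proportions, delta
#' method on the log scale for the mean odds ratio.
#'
#' When fewer than \code{min_converged} replicates converge the estimates
#' are reported as \code{NA} (the convergence rate is still reported): a
#' handful of surviving fits would give a noisy and selection-biased
#' summary.
#'
#' @param fits List of \code{fit_result}s (or the long data frame from
#'   [run_scenario()] filtered to one method), one per analyzed replicate.
#' @param truth_conditional,truth_marginal True conditional and marginal
#'   odds ratios of the scenario.
#' @param n_generated Total replicates generated (default: analyzed count).
#' @param n_prescreen_excluded Replicates dropped by [prescreen_trial()].
#' @param alpha_level Two-sided significance level (default 0.05).
#' @param min_converged Minimum converged replicates for reporting
#'   estimates (default 50).
#' @return One-row data frame: method, counts, \code{rejection_rate},
#'   \code{mean_or}, \code{coverage}, \code{convergence_rate} (percent),
#'   their MCSEs, and \code{truth_used}.
#' @export
summarize_fits <- function(fits, truth_conditional = 1, truth_marginal = 1,
                           n_generated = NULL, n_prescreen_excluded = 0,
                           alpha_level = 0.05, min_converged = 50) {
  df <- if (is.data.frame(fits)) fits else fits_to_df(fits)
  stopifnot(nrow(df) >= 1)
  method <- unique(df$method)
  if (length(method) != 1) stop("summarize_fits() expects a single method")
  estimand <- unique(df$estimand)
  if (is.null(n_generated)) n_generated <- nrow(df) + n_prescreen_excluded
  conv <- vapply(seq_len(nrow(df)), function(i) classify_convergence(df[i, ]),
                 logical(1))
  m <- sum(conv)
  n_analyzed <- n_generated - n_prescreen_excluded
  conv_rate <- 100 * m / n_analyzed
  truth <- if (estimand == "conditional") truth_conditional else truth_marginal
  prop_mcse <- function(p) sqrt(p * (1 - p) / m)
  if (m >= min_converged) {
    d <- df[conv, ]
    rejection <- mean(d$p_value < alpha_level)
    mean_log <- mean(d$log_or)
    mean_or <- exp(mean_log)
    coverage <- mean(d$ci_low <= log(truth) & log(truth) <= d$ci_high)
    mcse_rejection <- prop_mcse(rejection)
    mcse_coverage <- prop_mcse(coverage)
    mcse_mean <- mean_or * stats::sd(d$log_or) / sqrt(m)
  } else {
    rejection <- mean_or <- coverage <- NA_real_
    mcse_rejection <- mcse_coverage <- mcse_mean <- NA_real_
  }
  data.frame(method = method, estimand = estimand,
             n_generated = n_generated,
             n_prescreen_excluded = n_prescreen_excluded,
             n_converged = m,
             rejection_rate = rejection, mcse_rejection = mcse_rejection,
             mean_or = mean_or, mcse_mean = mcse_mean,
             coverage = coverage, mcse_coverage = mcse_coverage,
             convergence_rate = conv_rate,
             truth_used = truth,
             stringsAsFactors = FALSE)
}
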