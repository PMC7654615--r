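#' Per-center 2x2 event tables
#'
#' Collapses a subject-level trial table into one 2x2 table per center:
#' \code{a} treated with event, \code{b} treated without, \code{c} control
#' with event, \code{d} control without, \code{n = a+b+c+d}.
#'
#' @inheritParams fit_unadjusted
#' @return Data frame of class \code{"stratum_table"} with columns
#'   \code{center_id, a, b, c, d, n}, ordered by center id.
#' @examples
#' cfg <- scenario_config(100, 4, icc = 0, p0 = 0.2, true_or = 2,
#'                        size_distribution = "balanced")
#' tabulate_strata(generate_trial(cfg, seed = 1))
#' @export
tabulate_strata <- function(data) {
  data <- validate_trial(data)
  ids <- sort(unique(data$center_id))
  tabs <- lapply(ids, function(j) {
    d <- data[data$center_id == j, ]
    data.frame(center_id = j,
               a = sum(d$arm == 1 & d$outcome == 1),
               b = sum(d$arm == 1 & d$outcome == 0),
               c = sum(d$arm == 0 & d$outcome == 1),
               d = sum(d$arm == 0 & d$outcome == 0))
  })
  out <- do.call(rbind, tabs)
  out$n <- out$a + out$b + out$c + out$d
  class(out) <- c("stratum_table", "data.frame")
  out
}

#' Mantel-Haenszel common odds ratio across center strata
#'
#' Point estimate
#' \deqn{OR_{MH} = \frac{\sum_j a_j d_j / n_j}{\sum_j b_j c_j / n_j},}
#' standard error of the log odds ratio by the Robins-Breslow-Greenland
#' variance, and p-value from the Mantel-Haenszel chi-square test (with a
#' continuity correction by default, matching the behavior of standard
#' contingency-table routines). Strata with \eqn{a_j d_j = b_j c_j = 0}
#' contribute nothing to the estimate, so their subjects are effectively
#' excluded; the count of subjects in informative strata is reported in
#' \code{extras$n_informative}.
#'
#' Non-convergence, mirroring what the paper's rule would record from a
#' standard software run, occurs when (i) any stratum has fewer than 2
#' subjects (the common-table test cannot be formed and standard routines
#' error), or (ii) either the numerator or the denominator of
#' \eqn{OR_{MH}} is zero, leaving the estimate undefined or degenerate.
#'
#' @param strata A \code{stratum_table} (or a subject-level trial table,
#'   which is tabulated first).
#' @param correct Apply the continuity correction to the chi-square
#'   statistic (default \code{TRUE}).
#' @param conf_level Confidence level for the RBG interval (default 0.95).
#' @return A \code{fit_result} with \code{estimand = "conditional"}.
#' @examples
#' tab <- data.frame(center_id = 1:2, a = c(2, 3), b = c(8, 7),
#'                   c = c(1, 2), d = c(9, 8))
#' tab$n <- rowSums(tab[, c("a", "b", "c", "d")])
#' class(tab) <- c("stratum_table", "data.frame")
#' exp(mh_common_or(tab)$log_or)  # 2.1/1.1
#' @export
mh_common_or <- function(strata, correct = TRUE, conf_level = 0.95) {
  if (!inherits(strata, "stratum_table")) strata <- tabulate_strata(strata)
  if (nrow(strata) < 1) stop("need >= 1 stratum")
  a <- strata$a; b <- strata$b; cc <- strata$c; d <- strata$d; n <- strata$n
  informative <- a * d > 0 | b * cc > 0
  n_informative <- sum(n[informative])
  extras <- list(n_informative = n_informative,
                 n_strata = nrow(strata),
                 n_strata_informative = sum(informative))
  if (any(n < 2)) {
    res <- nonconverged_result("mantel_haenszel", "conditional",
                               n_analyzed = n_informative,
                               reason = "stratum with fewer than 2 subjects")
    res$extras <- c(res$extras, extras)
    return(res)
  }
  R <- a * d / n; S <- b * cc / n
  sR <- sum(R); sS <- sum(S)
  if (sR == 0 || sS == 0) {
    res <- nonconverged_result("mantel_haenszel", "conditional",
                               n_analyzed = n_informative,
                               reason = "undefined or degenerate common OR")
    res$extras <- c(res$extras, extras)
    return(res)
  }
  log_or <- log(sR / sS)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / n; Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sR^2) +
    sum(P * S + Q * R) / (2 * sR * sS) +
    sum(Q * S) / (2 * sS^2)
  se <- sqrt(v)
  # Mantel-Haenszel chi-square test on sum(a)
  e_a <- (a + b) * (a + cc) / n
  v_a <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  delta <- abs(sum(a) - sum(e_a))
  if (correct) delta <- max(0, delta - 0.5)
  stat <- delta^2 / sum(v_a)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  fit_result("mantel_haenszel", log_or, se, p,
             log_or - crit * se, log_or + crit * se,
             converged = is.finite(log_or) && is.finite(se),
             estimand = "conditional", n_analyzed = n_informative,
             extras = c(extras, list(statistic = stat)))
}

#' @rdname mh_common_or
#' @param data Subject-level trial table.
#' @export
fit_mantel_haenszel <- function(data, correct = TRUE, conf_level = 0.95) {
  mh_common_or(tabulate_strata(data), correct = correct,
               conf_level = conf_level)
}
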