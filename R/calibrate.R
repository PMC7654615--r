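#' Convert a conditional log odds ratio to its marginal counterpart
#'
#' With a normal random intercept of variance \eqn{\sigma^2} on the logit
#' scale, population-averaging attenuates regression coefficients by the
#' factor \eqn{\sqrt{1 + c^2\sigma^2}} with \eqn{c = 16\sqrt{3}/(15\pi)}
#' (the classic logit-normal approximation). At the ICC values 0.025 and
#' 0.075 the divisors are 1.0145 and 1.0451, so the marginal odds ratio is
#' only slightly closer to 1 than the conditional one.
#'
#' @param beta_c Conditional log odds ratio.
#' @param sigma2 Between-center variance on the logit scale (>= 0).
#' @return \code{conditional_to_marginal}: the marginal log odds ratio
#'   \eqn{\beta_m = \beta_c / \sqrt{1 + c^2\sigma^2}};
#'   \code{attenuation_divisor}: the divisor itself.
#' @examples
#' attenuation_divisor(icc_to_sigma2(0.025))
#' exp(conditional_to_marginal(log(2.08), icc_to_sigma2(0.025)))
#' @export
conditional_to_marginal <- function(beta_c, sigma2) {
  beta_c / attenuation_divisor(sigma2)
}

#' @rdname conditional_to_marginal
#' @export
attenuation_divisor <- function(sigma2) {
  stopifnot(sigma2 >= 0)
  cc <- 16 * sqrt(3) / (15 * pi)
  sqrt(1 + cc^2 * sigma2)
}

# Intercept alpha such that E_u[expit(alpha + u)] = p0 for u ~ N(0, sigma2),
# by 1-D root finding with Gauss-Hermite integration (25 nodes).
marginal_intercept <- function(p0, sigma2, n_quad = 25) {
  if (sigma2 < 1e-12) return(stats::qlogis(p0))
  gh <- gauss_hermite(n_quad)
  w <- gh$weights / sqrt(pi)           # weights for u = sqrt(2*sigma2)*z
  zs <- sqrt(2 * sigma2) * gh$nodes
  f <- function(a) sum(w * stats::plogis(a + zs)) - p0
  lo <- stats::qlogis(p0) - 3 * sqrt(sigma2) - 1
  hi <- stats::qlogis(p0) + 3 * sqrt(sigma2) + 1
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Normal-approximation initializer: conditional OR giving roughly the target
# power for a two-sided 5% Wald test of the log odds ratio, ignoring centers.
analytic_or_for_power <- function(n_total, icc, p0, target_power = 0.80,
                                  alpha_level = 0.05) {
  div <- attenuation_divisor(icc_to_sigma2(icc))
  za <- stats::qnorm(1 - alpha_level / 2)
  f <- function(log_or_c) {
    bm <- log_or_c / div
    p1 <- stats::plogis(stats::qlogis(p0) + bm)
    se <- sqrt(2 / n_total * (1 / (p1 * (1 - p1)) + 1 / (p0 * (1 - p0))))
    stats::pnorm(abs(bm) / se - za) - target_power
  }
  exp(stats::uniroot(f, c(1e-4, log(100)), tol = 1e-6)$root)
}

#' Solve for the conditional odds ratio giving a target power
#'
#' Finds, by monotone bisection on the log odds ratio, the true conditional
#' odds ratio under which a chosen analysis method attains a target power in
#' the simulated design (total sample size, number of centers, ICC,
#' control-arm event probability, size distribution). Power at each
#' candidate is estimated by simulating \code{replicates} trials with common
#' random numbers across candidates, so the power curve is monotone in the
#' candidate and the bisection is well behaved. A normal-approximation
#' initializer brackets the root to keep the number of power evaluations
#' small.
#'
#' @inheritParams scenario_config
#' @param target_power Target power in (alpha_level, 1); default 0.80.
#' @param method Analysis method used to define power; one of
#'   \code{"unadjusted"}, \code{"random_intercept"}, \code{"mantel_haenszel"},
#'   \code{"gee"}, \code{"gee_fg"}. Default \code{"unadjusted"}.
#' @param replicates Simulated trials per power evaluation (default 2000).
#' @param seed Integer seed controlling all randomness.
#' @param tol Bisection tolerance on the odds-ratio scale (default 0.01,
#'   i.e. the solved OR is reported to about two decimals).
#' @param or_max Upper bound of the search interval (default 100).
#' @param alpha_level Two-sided significance level (default 0.05).
#' @return List of class \code{"or_solution"}: \code{or} (solved conditional
#'   odds ratio), \code{power} and \code{mcse} (estimated power and its Monte
#'   Carlo SE at the solution), \code{replicates}, \code{evaluations}.
#' @examples
#' \donttest{
#' sol <- solve_or_for_power(400, 4, icc = 0, p0 = 0.2, target_power = 0.8,
#'                           replicates = 300, seed = 1)
#' sol$or
#' }
#' @export
solve_or_for_power <- function(n_total, n_centers, icc, p0,
                               target_power = 0.80, method = "unadjusted",
                               size_distribution = "balanced",
                               replicates = 2000, seed = 1, tol = 0.01,
                               or_max = 100, alpha_level = 0.05) {
  stopifnot(target_power > 0, target_power < 1)
  if (target_power <= alpha_level) {
    stop("target power must exceed the significance level; at OR = 1 the ",
         "rejection rate equals the test size")
  }
  fitfun <- method_registry(method)
  seeds <- replicate_seeds(seed, replicates)
  power_at <- function(log_or) {
    cfg <- scenario_config(n_total, n_centers, icc = icc, p0 = p0,
                           true_or = exp(log_or),
                           size_distribution = size_distribution)
    rej <- vapply(seeds, function(s) {
      trial <- generate_trial(cfg, seed = s)
      if (prescreen_trial(trial) != "retain") return(NA)
      fit <- tryCatch(fitfun(trial), error = function(e) NULL)
      if (is.null(fit) || !classify_convergence(fit)) return(NA)
      fit$p_value < alpha_level
    }, logical(1))
    mean(rej, na.rm = TRUE)
  }
  n_eval <- 0L
  pw <- function(b) { n_eval <<- n_eval + 1L; power_at(b) }

  init <- tryCatch(analytic_or_for_power(n_total, icc, p0, target_power,
                                         alpha_level),
                   error = function(e) NA_real_)
  lo <- log(1 + 1e-4); hi <- log(or_max)
  if (is.finite(init)) {
    lo0 <- max(lo, log(init / 1.6)); hi0 <- min(hi, log(init * 1.6))
    if (pw(lo0) < target_power) lo <- lo0
    if (pw(hi0) > target_power) hi <- hi0
  }
  if (pw(hi) < target_power) {
    stop(sprintf("target power %.2f unreachable at OR <= %g", target_power, or_max))
  }
  while (exp(hi) - exp(lo) > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) < target_power) lo <- mid else hi <- mid
  }
  root <- (lo + hi) / 2
  p_hat <- power_at(root)
  structure(list(or = exp(root), power = p_hat,
                 mcse = sqrt(p_hat * (1 - p_hat) / replicates),
                 replicates = replicates, evaluations = n_eval),
            class = "or_solution")
}

#' @export
print.or_solution <- function(x, ...) {
  cat(sprintf("Solved conditional OR = %.3f (power %.3f, MCSE %.4f, m = %d)\n",
              x$or, x$power, x$mcse, x$replicates))
  invisible(x)
}
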