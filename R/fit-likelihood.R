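#' Center-unadjusted logistic regression
#'
#' Fits \code{logit(pi_ij) = alpha + beta_trt * X_ij} by maximum likelihood,
#' ignoring centers. The estimand is a marginal (population-averaged) odds
#' ratio. Inference is Wald-z on the log odds-ratio scale.
#'
#' @param data Trial table with columns \code{center_id}, \code{arm},
#'   \code{outcome}.
#' @param conf_level Confidence level (default 0.95).
#' @return A \code{fit_result}.
#' @examples
#' cfg <- scenario_config(200, 5, icc = 0.025, p0 = 0.10, true_or = 2,
#'                        size_distribution = "balanced")
#' fit_unadjusted(generate_trial(cfg, seed = 1))
#' @export
fit_unadjusted <- function(data, conf_level = 0.95) {
  data <- validate_trial(data)
  if (length(unique(data$arm)) < 2) stop("both arms must be present")
  fit <- suppressWarnings(
    stats::glm(outcome ~ arm, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- stats::coef(fit)[["arm"]]
  se <- sqrt(stats::vcov(fit)["arm", "arm"])
  ok <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se)
  wald_fit("unadjusted", beta, se, estimand = "marginal",
           n_analyzed = nrow(data), converged = ok, conf_level = conf_level,
           extras = list(alpha = stats::coef(fit)[["(Intercept)"]]))
}

#' Random-intercept logistic regression (adaptive Gauss-Hermite)
#'
#' Fits \code{logit(pi_ij) = alpha + beta_trt * X_ij + u_j} with
#' \eqn{u_j \sim N(0, \sigma^2)} by maximum likelihood, the per-center
#' integrals approximated by adaptive Gauss-Hermite quadrature with
#' \code{n_quad} nodes (default 9). The estimand is the conditional
#' (within-center) odds ratio. A variance estimate on the \eqn{\sigma = 0}
#' boundary (singular fit) is a legitimate optimum and is reported as
#' converged; optimizer failures and non-finite curvature are not.
#'
#' @inheritParams fit_unadjusted
#' @param n_quad Number of adaptive Gauss-Hermite quadrature nodes.
#' @return A \code{fit_result}; \code{extras$sigma} holds \eqn{\hat\sigma}.
#' @seealso [aghq_loglik()] for direct evaluation of the marginal
#'   log-likelihood that is being maximized.
#' @examples
#' cfg <- scenario_config(500, 5, icc = 0.075, p0 = 0.10, true_or = 2,
#'                        size_distribution = "balanced")
#' fit_random_intercept(generate_trial(cfg, seed = 1))
#' @export
fit_random_intercept <- function(data, n_quad = 9, conf_level = 0.95) {
  data <- validate_trial(data)
  if (length(unique(data$center_id)) < 2) stop("need >= 2 centers")
  warn_nonconv <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(outcome ~ arm + (1 | center_id),
                  family = stats::binomial(), data = data, nAGQ = n_quad),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        warn_nonconv <<- TRUE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (is.null(fit)) {
    return(nonconverged_result("random_intercept", "conditional",
                               n_analyzed = nrow(data), reason = "fit error"))
  }
  beta <- lme4::fixef(fit)[["arm"]]
  # vcov may fall back to an approximate Hessian with a warning; the
  # resulting SE is still policed by the convergence rule downstream
  se <- tryCatch(suppressWarnings(sqrt(as.matrix(stats::vcov(fit))["arm", "arm"])),
                 error = function(e) NA_real_)
  sigma_hat <- sqrt(as.numeric(lme4::VarCorr(fit)$center_id[1, 1]))
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  ok <- !warn_nonconv && opt_ok && is.finite(beta) && is.finite(se)
  wald_fit("random_intercept", beta, se, estimand = "conditional",
           n_analyzed = nrow(data), converged = ok, conf_level = conf_level,
           extras = list(sigma = sigma_hat,
                         alpha = lme4::fixef(fit)[["(Intercept)"]],
                         logLik = as.numeric(stats::logLik(fit))))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates
#' \deqn{\ell(\alpha,\beta,\sigma) = \sum_j \log \int \prod_i
#'   \mathrm{Bern}(y_{ij};\, \mathrm{expit}(\alpha + \beta x_{ij} + u))\,
#'   \phi(u; 0, \sigma^2)\, du}
#' with each center's integral approximated by adaptive Gauss-Hermite
#' quadrature: the rule is centered at the center-specific posterior mode of
#' \eqn{u} (found by Newton iterations) and scaled by the curvature there.
#' With \eqn{\sigma} near 0 the integral collapses to the Bernoulli
#' log-likelihood at \eqn{u = 0}.
#'
#' @inheritParams fit_unadjusted
#' @param alpha,beta,sigma Model parameters (\eqn{\sigma \ge 0}).
#' @param n_quad Number of quadrature nodes (default 9).
#' @return The marginal log-likelihood (scalar).
#' @export
aghq_loglik <- function(data, alpha, beta, sigma, n_quad = 9) {
  stopifnot(sigma >= 0)
  data <- validate_trial(data)
  gh <- gauss_hermite(n_quad)
  centers <- split(seq_len(nrow(data)), data$center_id)
  sum(vapply(centers, function(idx) {
    y <- data$outcome[idx]
    eta0 <- alpha + beta * data$arm[idx]
    if (sigma < 1e-10) {
      return(sum(y * eta0 - log1pexp(eta0)))
    }
    # log integrand g(u) = sum_i [y*eta - log(1+e^eta)] - u^2/(2 sigma^2)
    # Newton search for the posterior mode
    u <- 0
    for (it in seq_len(50)) {
      mu <- stats::plogis(eta0 + u)
      g1 <- sum(y - mu) - u / sigma^2
      g2 <- -sum(mu * (1 - mu)) - 1 / sigma^2
      step <- g1 / g2
      u <- u - step
      if (abs(step) < 1e-10) break
    }
    mu <- stats::plogis(eta0 + u)
    tau <- 1 / sqrt(sum(mu * (1 - mu)) + 1 / sigma^2)
    uk <- u + sqrt(2) * tau * gh$nodes
    log_terms <- vapply(seq_along(uk), function(k) {
      eta <- eta0 + uk[k]
      log(gh$weights[k]) + gh$nodes[k]^2 +
        sum(y * eta - log1pexp(eta)) +
        stats::dnorm(uk[k], 0, sigma, log = TRUE)
    }, numeric(1))
    log(sqrt(2) * tau) + log_sum_exp(log_terms)
  }, numeric(1)))
}
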