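#' Between-center variance implied by an intra-class correlation
#'
#' On the latent logistic scale the residual variance is fixed at
#' \eqn{\pi^2/3}, so an intra-class correlation coefficient
#' \eqn{\rho = \sigma_c^2 / (\sigma_c^2 + \pi^2/3)} pins down the
#' between-center variance \eqn{\sigma_c^2 = \rho/(1-\rho) \cdot \pi^2/3}.
#'
#' @param icc Intra-class correlation on the logit scale, in \code{[0, 1)}.
#' @return Between-center variance \eqn{\sigma_c^2} (logit scale).
#' @seealso [sigma2_to_icc()] for the inverse mapping.
#' @examples
#' icc_to_sigma2(0.025)
#' sigma2_to_icc(icc_to_sigma2(0.075))
#' @export
icc_to_sigma2 <- function(icc) {
  if (!is.numeric(icc) || anyNA(icc) || any(icc < 0) || any(icc >= 1)) {
    stop("'icc' must lie in [0, 1)")
  }
  icc / (1 - icc) * pi^2 / 3
}

#' @rdname icc_to_sigma2
#' @param sigma2 Between-center variance on the logit scale, >= 0.
#' @export
sigma2_to_icc <- function(sigma2) {
  if (!is.numeric(sigma2) || anyNA(sigma2) || any(sigma2 < 0)) {
    stop("'sigma2' must be >= 0")
  }
  sigma2 / (sigma2 + pi^2 / 3)
}

#' Scenario configuration for the trial simulator
#'
#' Bundles one cell of a simulation design grid: total sample size, target
#' number of centers, intra-class correlation, control-arm event probability,
#' true conditional odds ratio, and how participants are spread over centers.
#'
#' @param n_total Total number of participants randomized.
#' @param n_centers Target number of centers. With a skewed size
#'   distribution the realized number of non-empty centers can be smaller.
#' @param icc Intra-class correlation coefficient on the logit scale,
#'   in \code{[0, 1)}.
#' @param p0 Control-arm event probability, in \code{(0, 1)}.
#' @param true_or True conditional odds ratio for treatment (> 0); 1 gives a
#'   null scenario.
#' @param size_distribution \code{"balanced"} (equal center sizes) or
#'   \code{"skewed"} (one equal-probability multinomial draw per trial).
#' @param block_size Permuted block size for the stratified randomization;
#'   must be even for 1:1 allocation. Default 4.
#' @param calibrate_intercept \code{"conditional"} sets the intercept to
#'   \code{qlogis(p0)} so that \code{p0} is the event probability in the
#'   median (u = 0) center; \code{"marginal"} solves for the intercept so the
#'   population-averaged control-arm probability equals \code{p0}.
#' @return An object of class \code{"scenario_config"}.
#' @examples
#' cfg <- scenario_config(200, 5, icc = 0.025, p0 = 0.10, true_or = 1,
#'                        size_distribution = "skewed")
#' cfg
#' @export
scenario_config <- function(n_total, n_centers, icc, p0, true_or = 1,
                            size_distribution = c("balanced", "skewed"),
                            block_size = 4,
                            calibrate_intercept = c("conditional", "marginal")) {
  size_distribution <- match.arg(size_distribution)
  calibrate_intercept <- match.arg(calibrate_intercept)
  stopifnot(n_total >= 1, n_centers >= 1, p0 > 0, p0 < 1, true_or > 0)
  if (block_size %% 2 != 0) stop("'block_size' must be even for 1:1 allocation")
  sigma2 <- icc_to_sigma2(icc)
  alpha <- if (calibrate_intercept == "conditional") {
    stats::qlogis(p0)
  } else {
    marginal_intercept(p0, sigma2)
  }
  structure(
    list(n_total = as.integer(n_total), n_centers = as.integer(n_centers),
         icc = icc, p0 = p0, true_or = true_or,
         size_distribution = size_distribution,
         block_size = as.integer(block_size),
         calibrate_intercept = calibrate_intercept,
         alpha = alpha, beta_trt = log(true_or), sigma2 = sigma2),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Multicenter trial scenario\n")
  cat(sprintf("  n = %d across %d centers (%s sizes), block size %d\n",
              x$n_total, x$n_centers, x$size_distribution, x$block_size))
  cat(sprintf("  ICC = %g (sigma^2 = %.4f), control event prob = %g (%s intercept %.4f)\n",
              x$icc, x$sigma2, x$p0, x$calibrate_intercept, x$alpha))
  cat(sprintf("  true conditional OR = %g\n", x$true_or))
  invisible(x)
}

#' Allocate participants to centers
#'
#' Balanced mode gives every center the same size (a remainder of
#' \code{n_total} modulo \code{n_centers} is assigned one-per-center to the
#' lowest-indexed centers). Skewed mode draws the sizes once from a
#' multinomial distribution with equal cell probabilities \code{1/n_centers};
#' centers drawn with zero participants are dropped, so the realized number
#' of centers can fall below the target when \code{n_total} is small relative
#' to \code{n_centers}.
#'
#' @inheritParams scenario_config
#' @param mode \code{"balanced"} or \code{"skewed"}.
#' @return Integer vector of positive per-center sizes summing to
#'   \code{n_total}; its length is the realized number of centers.
#' @examples
#' assign_center_sizes(500, 5, "balanced")
#' set.seed(1); assign_center_sizes(500, 5, "skewed")
#' @export
assign_center_sizes <- function(n_total, n_centers,
                                mode = c("balanced", "skewed")) {
  mode <- match.arg(mode)
  stopifnot(n_total >= 1, n_centers >= 1)
  if (mode == "balanced") {
    sizes <- rep(n_total %/% n_centers, n_centers)
    rem <- n_total %% n_centers
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  } else {
    sizes <- as.integer(stats::rmultinom(1, n_total, rep(1 / n_centers, n_centers)))
  }
  as.integer(sizes[sizes > 0])
}

#' Stratified permuted-block randomization
#'
#' Within each center, arms are assigned by concatenating independently
#' permuted blocks containing \code{block_size/2} subjects of each arm
#' (1:1 allocation); a final incomplete block is a fresh permuted block
#' truncated to the remaining count. At any enrollment-order prefix within a
#' center the arm imbalance is therefore at most \code{block_size/2}.
#'
#' @param center_sizes Integer vector of per-center sizes.
#' @param block_size Even block size (default 4).
#' @return List of integer 0/1 vectors, one per center, in enrollment order.
#' @examples
#' set.seed(1)
#' permuted_block_randomize(c(8, 6))
#' @export
permuted_block_randomize <- function(center_sizes, block_size = 4) {
  if (block_size %% 2 != 0) stop("'block_size' must be even")
  half <- block_size / 2
  lapply(center_sizes, function(n) {
    n_blocks <- ceiling(n / block_size)
    arms <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(c(0L, 1L), each = half))
    }), use.names = FALSE)
    arms[seq_len(n)]
  })
}

#' Simulate one multicenter trial
#'
#' Generates subject-level data from a latent-variable threshold model: for
#' subject i in center j,
#' \deqn{Y^*_{ij} = \alpha + \beta_{trt} X_{ij} + u_j + \epsilon_{ij},}
#' with \eqn{u_j \sim N(0, \sigma^2)}, \eqn{\sigma^2} set by the ICC on the
#' logit scale, \eqn{\epsilon_{ij}} standard logistic, and
#' \eqn{Y_{ij} = 1\{Y^*_{ij} > 0\}}. Equivalently
#' \eqn{P(Y_{ij}=1 \mid X_{ij}, u_j) = \mathrm{expit}(\alpha + \beta_{trt} X_{ij} + u_j)},
#' so \eqn{\beta_{trt}} is a conditional (within-center) log odds ratio.
#' Treatment is assigned by [permuted_block_randomize()] stratified by
#' center; center sizes come from [assign_center_sizes()].
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer; when given, \code{set.seed(seed)} is called
#'   first so that identical \code{(config, seed)} yield identical data.
#' @return A \code{data.frame} of class \code{"trial_data"} with integer
#'   columns \code{center_id}, \code{arm}, \code{outcome}, and attributes
#'   \code{n_centers_realized} and \code{config}.
#' @examples
#' cfg <- scenario_config(200, 5, icc = 0.025, p0 = 0.10, true_or = 1,
#'                        size_distribution = "skewed")
#' trial <- generate_trial(cfg, seed = 7)
#' head(trial)
#' attr(trial, "n_centers_realized")
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- assign_center_sizes(config$n_total, config$n_centers,
                               config$size_distribution)
  J <- length(sizes)
  arms <- permuted_block_randomize(sizes, config$block_size)
  center_id <- rep.int(seq_len(J), sizes)
  arm <- unlist(arms, use.names = FALSE)
  u <- stats::rnorm(J, 0, sqrt(config$sigma2))
  eps <- stats::rlogis(config$n_total)
  ystar <- config$alpha + config$beta_trt * arm + u[center_id] + eps
  out <- data.frame(center_id = center_id, arm = arm,
                    outcome = as.integer(ystar > 0))
  attr(out, "n_centers_realized") <- J
  attr(out, "config") <- config
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Prescreen a simulated trial before analysis
#'
#' Trials in which no subject has an event, or in which every event falls in
#' a single arm, are uninformative for an odds ratio and break most fitters;
#' they are excluded from analysis (and tallied) rather than fitted.
#'
#' @param data A trial table with columns \code{arm} and \code{outcome}.
#' @return One of \code{"retain"}, \code{"exclude_no_events"},
#'   \code{"exclude_one_arm_only"}.
#' @export
prescreen_trial <- function(data) {
  ev <- data$outcome == 1
  if (!any(ev)) return("exclude_no_events")
  arms_with_events <- unique(data$arm[ev])
  if (length(arms_with_events) < 2) return("exclude_one_arm_only")
  "retain"
}

#' Read or write a subject-level trial table
#'
#' The on-disk format is delimited text with header
#' \code{center_id,arm,outcome}, one row per subject, integer-coded; the same
#' format is accepted by every fitting function.
#'
#' @param data A trial \code{data.frame}.
#' @param path File path.
#' @return \code{read_trial} returns a \code{"trial_data"} data frame;
#'   \code{write_trial} invisibly returns \code{path}.
#' @export
write_trial <- function(data, path) {
  utils::write.csv(data[, c("center_id", "arm", "outcome")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  out <- utils::read.csv(path)
  validate_trial(out)
}

# Coerce/validate a user-supplied trial table; used by all fitters.
validate_trial <- function(data) {
  need <- c("center_id", "arm", "outcome")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(data$outcome %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary 'outcome' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!(data$arm %in% c(0, 1)))
  if (length(bad)) {
    stop("'arm' must be coded 0/1; offending row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (nrow(data) == 0) stop("empty trial table")
  if (is.null(attr(data, "n_centers_realized"))) {
    attr(data, "n_centers_realized") <- length(unique(data$center_id))
  }
  if (!inherits(data, "trial_data")) class(data) <- c("trial_data", class(data))
  data
}
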