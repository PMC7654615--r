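#' Deterministic per-replicate seeds
#'
#' Derives \code{m} child seeds from one root seed so that each replicate
#' has its own reproducible random stream: results are identical regardless
#' of execution order or number of parallel workers, and any single
#' replicate can be regenerated in isolation.
#'
#' @param seed Integer root seed.
#' @param m Number of replicates.
#' @return Integer vector of length \code{m}.
#' @export
replicate_seeds <- function(seed, m) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, m)
}

#' Run one simulation scenario
#'
#' Generates \code{replicates} trials from \code{config}, prescreens them
#' (trials with no events or all events in one arm are excluded before any
#' fitting), fits the requested methods to each retained trial, applies the
#' convergence classification, and summarizes each method's performance.
#' Fitter errors in a replicate are caught and recorded as non-convergence;
#' they never abort the run.
#'
#' @param config A [scenario_config()]; its \code{true_or} is the true
#'   conditional odds ratio, from which the marginal truth used to score
#'   marginal methods is derived via [conditional_to_marginal()].
#' @param replicates Number of trials to generate.
#' @param methods Character vector of methods to fit; any of
#'   \code{"unadjusted"}, \code{"random_intercept"}, \code{"mantel_haenszel"},
#'   \code{"gee"}, \code{"gee_fg"}.
#' @param seed Root seed; replicate r uses a deterministically derived child
#'   seed.
#' @param cores Number of worker processes (forked; default 1). Results are
#'   independent of this value.
#' @param min_converged Passed to [summarize_fits()].
#' @return List of class \code{"scenario_result"}:
#'   \code{summary} (one row per method), \code{replicates} (long data
#'   frame, one row per replicate x method, prescreen-excluded replicates
#'   flagged), \code{n_generated}, \code{n_prescreen_excluded},
#'   \code{mean_realized_centers}.
#' @examples
#' cfg <- scenario_config(200, 5, icc = 0.025, p0 = 0.10, true_or = 1,
#'                        size_distribution = "skewed")
#' res <- run_scenario(cfg, replicates = 20, methods = "unadjusted", seed = 1)
#' res$summary
#' @export
run_scenario <- function(config, replicates,
                         methods = mctsim_methods(),
                         seed = 1, cores = 1, min_converged = 50) {
  stopifnot(inherits(config, "scenario_config"), replicates >= 1)
  methods <- match.arg(methods, mctsim_methods(), several.ok = TRUE)
  seeds <- replicate_seeds(seed, replicates)

  one_replicate <- function(r) {
    trial <- generate_trial(config, seed = seeds[r])
    screen <- prescreen_trial(trial)
    if (screen != "retain") {
      return(list(screen = screen, centers = attr(trial, "n_centers_realized"),
                  fits = NULL))
    }
    gee_fit <- NULL
    fits <- lapply(methods, function(mth) {
      f <- tryCatch({
        if (mth == "gee_fg" && !is.null(gee_fit)) {
          fay_graubard_correct(gee_fit)
        } else {
          method_registry(mth)(trial)
        }
      }, error = function(e) {
        nonconverged_result(mth,
                            if (mth %in% c("random_intercept", "mantel_haenszel"))
                              "conditional" else "marginal",
                            n_analyzed = nrow(trial),
                            reason = conditionMessage(e))
      })
      if (mth == "gee") gee_fit <<- f
      f
    })
    list(screen = "retain", centers = attr(trial, "n_centers_realized"),
         fits = fits)
  }

  reps <- if (cores > 1) {
    parallel::mclapply(seq_len(replicates), one_replicate, mc.cores = cores)
  } else {
    lapply(seq_len(replicates), one_replicate)
  }

  screens <- vapply(reps, `[[`, character(1), "screen")
  n_excluded <- sum(screens != "retain")
  long <- do.call(rbind, lapply(seq_along(reps), function(r) {
    if (is.null(reps[[r]]$fits)) {
      data.frame(replicate = r, prescreen = screens[r], method = methods,
                 estimand = NA_character_, log_or = NA_real_, or = NA_real_,
                 se = NA_real_, p_value = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, converged = NA, n_analyzed = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      cbind(replicate = r, prescreen = "retain", fits_to_df(reps[[r]]$fits))
    }
  }))
  rownames(long) <- NULL

  truth_c <- config$true_or
  truth_m <- exp(conditional_to_marginal(log(truth_c), config$sigma2))
  summary <- do.call(rbind, lapply(methods, function(mth) {
    d <- long[long$method == mth & long$prescreen == "retain", ]
    summarize_fits(d, truth_conditional = truth_c, truth_marginal = truth_m,
                   n_generated = replicates,
                   n_prescreen_excluded = n_excluded,
                   min_converged = min_converged)
  }))
  structure(list(summary = summary, replicates = long,
                 n_generated = replicates,
                 n_prescreen_excluded = n_excluded,
                 mean_realized_centers =
                   mean(vapply(reps, `[[`, numeric(1), "centers")),
                 config = config, seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario result: %d replicates (%d prescreen-excluded), mean %.1f centers\n",
              x$n_generated, x$n_prescreen_excluded, x$mean_realized_centers))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Define and run a scenario grid
#'
#' \code{grid_spec()} builds the cartesian product of design factors;
#' \code{run_grid()} runs every scenario and stacks the per-method
#' summaries. Scenario \code{s} uses a child seed deterministically derived
#' from the root seed, so any scenario can be reproduced alone.
#'
#' @param n_total,n_centers,icc,p0,size_distribution Vectors of design
#'   factor levels, crossed.
#' @param true_or True conditional odds ratio(s); recycle along the grid or
#'   supply one value (1 for null scenarios). Solved values from
#'   [solve_or_for_power()] can be supplied directly.
#' @param replicates Replicates per scenario (default 5000).
#' @param methods Methods to fit in every scenario.
#' @return \code{grid_spec}: a data frame with one row per scenario.
#' @examples
#' spec <- grid_spec(n_total = c(200, 500), n_centers = 5, icc = 0.025,
#'                   p0 = 0.10, size_distribution = "skewed")
#' res <- run_grid(spec, replicates = 10, methods = "unadjusted", seed = 1)
#' @export
grid_spec <- function(n_total = c(200, 500, 1000, 5000),
                      n_centers = c(5, 50, 100),
                      icc = c(0.025, 0.075),
                      p0 = c(0.02, 0.05, 0.10),
                      size_distribution = c("balanced", "skewed"),
                      true_or = 1) {
  g <- expand.grid(n_total = n_total, n_centers = n_centers, icc = icc,
                   p0 = p0, size_distribution = size_distribution,
                   true_or = true_or, stringsAsFactors = FALSE)
  g$scenario <- seq_len(nrow(g))
  g[, c("scenario", setdiff(names(g), "scenario"))]
}

#' @rdname grid_spec
#' @param spec A \code{grid_spec()} data frame (columns \code{n_total},
#'   \code{n_centers}, \code{icc}, \code{p0}, \code{size_distribution},
#'   \code{true_or}).
#' @inheritParams run_scenario
#' @param seed Root seed for the whole grid.
#' @return \code{run_grid}: a data frame of per-scenario, per-method
#'   performance summaries (the scenario factors are prepended).
#' @export
run_grid <- function(spec, replicates = 5000, methods = mctsim_methods(),
                     seed = 1, cores = 1, min_converged = 50) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1)
  scen_seeds <- replicate_seeds(seed, nrow(spec))
  out <- lapply(seq_len(nrow(spec)), function(s) {
    row <- spec[s, ]
    cfg <- scenario_config(row$n_total, row$n_centers, icc = row$icc,
                           p0 = row$p0, true_or = row$true_or,
                           size_distribution = row$size_distribution)
    res <- run_scenario(cfg, replicates = replicates, methods = methods,
                        seed = scen_seeds[s], cores = cores,
                        min_converged = min_converged)
    cbind(scenario = if ("scenario" %in% names(spec)) row$scenario else s,
          row[setdiff(names(row), "scenario")], res$summary,
          mean_realized_centers = res$mean_realized_centers,
          row.names = NULL)
  })
  do.call(rbind, out)
}

#' Analyze a user-supplied multicenter trial table
#'
#' Applied entry point: reads a subject-level trial table (columns
#' \code{center_id}, \code{arm}, \code{outcome}) and fits the requested
#' methods. Tables with more than two arms are analyzed pairwise: each
#' non-reference arm is compared with the named reference arm on the subset
#' of subjects in those two arms. Analyzed-subject counts are reported per
#' method, which exposes the participants that the Mantel-Haenszel
#' estimator effectively drops from uninformative centers.
#'
#' @param x Path to a delimited trial table, or a data frame.
#' @param methods Methods to fit.
#' @param reference_arm For multi-arm tables, the value of \code{arm} to use
#'   as the reference group (required when more than two arms are present;
#'   for 0/1-coded two-arm tables the control arm 0 is the reference).
#' @return Data frame with one row per (comparison arm, method): odds ratio,
#'   CI, p-value, convergence flag, and analyzed-subject count.
#' @export
analyze_dataset <- function(x, methods = mctsim_methods(),
                            reference_arm = NULL) {
  methods <- match.arg(methods, mctsim_methods(), several.ok = TRUE)
  data <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  need <- c("center_id", "arm", "outcome")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(data$outcome %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary 'outcome' at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  arms <- sort(unique(data$arm))
  if (length(arms) < 2) stop("need >= 2 arms")
  if (length(arms) == 2 && is.null(reference_arm) && all(arms %in% c(0, 1))) {
    reference_arm <- 0
  }
  if (is.null(reference_arm)) {
    stop("multi-arm table: supply 'reference_arm'")
  }
  if (!reference_arm %in% arms) {
    stop("reference arm '", reference_arm, "' not present; arms found: ",
         paste(arms, collapse = ", "))
  }
  comparisons <- setdiff(arms, reference_arm)
  out <- lapply(comparisons, function(trt) {
    d <- data[data$arm %in% c(reference_arm, trt), ]
    d$arm <- as.integer(d$arm == trt)
    d <- validate_trial(d[, need])
    rows <- lapply(methods, function(mth) {
      f <- tryCatch(method_registry(mth)(d), error = function(e) {
        nonconverged_result(mth,
                            if (mth %in% c("random_intercept", "mantel_haenszel"))
                              "conditional" else "marginal",
                            n_analyzed = nrow(d),
                            reason = conditionMessage(e))
      })
      cbind(comparison = paste(trt, "vs", reference_arm),
            n_subset = nrow(d), as.data.frame(f))
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
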