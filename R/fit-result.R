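# Container for one method's treatment-effect estimate on one trial.
# All estimates live on the log odds-ratio scale; `estimand` records whether
# the method targets a within-center (conditional) or population-averaged
# (marginal) odds ratio.
fit_result <- function(method, log_or, se, p_value, ci_low, ci_high,
                       converged, estimand, n_analyzed, extras = list()) {
  structure(
    list(method = method, log_or = log_or, se = se, p_value = p_value,
         ci_low = ci_low, ci_high = ci_high, converged = converged,
         estimand = estimand, n_analyzed = n_analyzed, extras = extras),
    class = "fit_result")
}

# Placeholder for a fit that errored or is undefined.
nonconverged_result <- function(method, estimand, n_analyzed = NA_integer_,
                                reason = NA_character_) {
  fit_result(method, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
             converged = FALSE, estimand = estimand,
             n_analyzed = n_analyzed, extras = list(reason = reason))
}

# Wald inference on the log odds-ratio scale. `df = Inf` gives the normal
# reference; finite df gives a t reference.
wald_fit <- function(method, log_or, se, estimand, n_analyzed,
                     converged = TRUE, df = Inf, conf_level = 0.95,
                     extras = list()) {
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  z <- log_or / se
  p <- 2 * stats::pt(-abs(z), df = df)
  fit_result(method, log_or, se, p, log_or - crit * se, log_or + crit * se,
             converged, estimand, n_analyzed, extras)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit (%s estimand)>\n", x$method, x$estimand))
  if (isTRUE(x$converged)) {
    cat(sprintf("  OR = %.4f (95%% CI %.4f to %.4f), log-OR SE = %.4f, p = %.4g\n",
                exp(x$log_or), exp(x$ci_low), exp(x$ci_high), x$se, x$p_value))
  } else {
    cat("  did not converge\n")
  }
  cat(sprintf("  analyzed subjects: %s\n",
              ifelse(is.na(x$n_analyzed), "NA", x$n_analyzed)))
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, ...) {
  data.frame(method = x$method, estimand = x$estimand,
             log_or = x$log_or, or = exp(x$log_or), se = x$se,
             p_value = x$p_value, ci_low = x$ci_low, ci_high = x$ci_high,
             converged = x$converged, n_analyzed = x$n_analyzed,
             stringsAsFactors = FALSE)
}

# Stack a list of fit_result objects into a long data frame.
fits_to_df <- function(fits) {
  do.call(rbind, lapply(fits, as.data.frame))
}

# Map a method name to its fitting function (trial table -> fit_result).
method_registry <- function(method) {
  switch(method,
         unadjusted = fit_unadjusted,
         random_intercept = fit_random_intercept,
         mantel_haenszel = fit_mantel_haenszel,
         gee = fit_gee_exchangeable,
         gee_fg = fit_gee_fg,
         stop("unknown method: ", method))
}

#' @keywords internal
mctsim_methods <- function() {
  c("unadjusted", "random_intercept", "mantel_haenszel", "gee", "gee_fg")
}
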