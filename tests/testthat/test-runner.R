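test_that("scenario runs are deterministic given the root seed", {
  cfg <- scenario_config(150, 5, icc = 0.025, p0 = 0.15, true_or = 1,
                         size_distribution = "skewed")
  r1 <- run_scenario(cfg, replicates = 15, seed = 3,
                     methods = c("unadjusted", "mantel_haenszel"))
  r2 <- run_scenario(cfg, replicates = 15, seed = 3,
                     methods = c("unadjusted", "mantel_haenszel"))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$replicates, r2$replicates)
  r3 <- run_scenario(cfg, replicates = 15, seed = 4, methods = "unadjusted")
  expect_false(identical(
    r1$replicates$log_or[r1$replicates$method == "unadjusted"],
    r3$replicates$log_or))
})

test_that("every replicate appears exactly once per method in the long output", {
  cfg <- scenario_config(120, 4, icc = 0.025, p0 = 0.05, true_or = 1,
                         size_distribution = "skewed")
  res <- run_scenario(cfg, replicates = 25, seed = 5,
                      methods = c("unadjusted", "gee"))
  tab <- table(res$replicates$replicate, res$replicates$method)
  expect_true(all(tab == 1))
  expect_equal(nrow(res$replicates), 25 * 2)
  # prescreen-excluded replicates are present but carry no estimates
  excl <- res$replicates[res$replicates$prescreen != "retain", ]
  expect_equal(nrow(excl) / 2, res$n_prescreen_excluded)
  expect_true(all(is.na(excl$log_or)))
})

test_that("fitter failures are recorded as non-convergence, not errors", {
  # 100 centers on 200 subjects: nearly every replicate has a size-1 center,
  # so the Mantel-Haenszel estimator almost never converges
  cfg <- scenario_config(200, 100, icc = 0.025, p0 = 0.10, true_or = 1,
                         size_distribution = "skewed")
  res <- run_scenario(cfg, replicates = 10, seed = 6,
                      methods = "mantel_haenszel")
  s <- res$summary
  expect_lt(s$convergence_rate, 10)
  expect_true(is.na(s$rejection_rate))
})

test_that("grid runs stack per-scenario summaries with their design factors", {
  spec <- grid_spec(n_total = c(120, 240), n_centers = 4, icc = 0.025,
                    p0 = 0.10, size_distribution = "skewed")
  expect_equal(nrow(spec), 2)
  out <- run_grid(spec, replicates = 8, methods = c("unadjusted", "gee"),
                  seed = 10)
  expect_equal(nrow(out), 4)  # 2 scenarios x 2 methods
  expect_setequal(unique(out$n_total), c(120, 240))
  expect_true(all(c("rejection_rate", "coverage", "convergence_rate",
                    "mean_realized_centers") %in% names(out)))
  out2 <- run_grid(spec, replicates = 8, methods = c("unadjusted", "gee"),
                   seed = 10)
  expect_identical(out, out2)
})

test_that("analyze_dataset fits a two-arm table and reports analyzed counts", {
  cfg <- scenario_config(300, 4, icc = 0.05, p0 = 0.2, true_or = 2,
                         size_distribution = "balanced")
  trial <- generate_trial(cfg, seed = 12)
  res <- analyze_dataset(trial, methods = c("unadjusted", "mantel_haenszel",
                                            "gee"))
  expect_equal(nrow(res), 3)
  expect_true(all(res$n_subset == 300))
  expect_true(all(res$converged))
})

test_that("MH analyzed count drops subjects from uninformative centers", {
  cfg <- scenario_config(200, 4, icc = 0.05, p0 = 0.2, true_or = 2,
                         size_distribution = "balanced")
  trial <- generate_trial(cfg, seed = 13)
  # append a center whose subjects are all in arm 1: uninformative for MH
  extra <- data.frame(center_id = 99L, arm = 1L,
                      outcome = c(1L, 0L, 0L, 1L, 0L, 0L))
  combined <- rbind(as.data.frame(trial), extra)
  res <- analyze_dataset(combined,
                         methods = c("unadjusted", "mantel_haenszel"))
  n_mh <- res$n_analyzed[res$method == "mantel_haenszel"]
  n_un <- res$n_analyzed[res$method == "unadjusted"]
  expect_equal(n_un, 206)
  expect_equal(n_mh, 200)
  # the oracle for the exclusion: subjects in strata with a zero cross-product
  tab <- tabulate_strata(validate_trial(combined))
  informative <- tab$a * tab$d > 0 | tab$b * tab$c > 0
  expect_equal(n_mh, sum(tab$n[informative]))
})

test_that("multi-arm tables are analyzed pairwise against the reference", {
  set.seed(14)
  multi <- data.frame(
    center_id = rep(1:4, each = 30),
    arm = rep(c("ctrl", "a", "b"), 40),
    outcome = rbinom(120, 1, 0.25))
  res <- analyze_dataset(multi, methods = "unadjusted",
                         reference_arm = "ctrl")
  expect_equal(sort(unique(res$comparison)), c("a vs ctrl", "b vs ctrl"))
  expect_true(all(res$n_subset == 80))
  expect_error(analyze_dataset(multi, methods = "unadjusted"),
               "reference_arm")
  expect_error(analyze_dataset(multi, methods = "unadjusted",
                               reference_arm = "zzz"), "not present")
  bad <- multi; bad$outcome[5] <- 3
  expect_error(analyze_dataset(bad, reference_arm = "ctrl"), "non-binary")
})

test_that("derived replicate seeds are reproducible and leave the RNG alone", {
  s1 <- replicate_seeds(42, 10)
  set.seed(1); x <- runif(1)
  s2 <- replicate_seeds(42, 10)
  y <- runif(1)
  expect_identical(s1, s2)
  set.seed(1)
  expect_identical(c(x, y), runif(2))  # RNG state restored by replicate_seeds
  expect_equal(length(unique(s1)), 10)
})
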