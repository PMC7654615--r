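test_that("ICC maps to between-center variance and back", {
  expect_equal(icc_to_sigma2(0), 0)
  expect_equal(icc_to_sigma2(0.5), pi^2 / 3)
  expect_equal(icc_to_sigma2(0.025), 0.025 / 0.975 * pi^2 / 3)
  for (icc in c(0, 0.01, 0.025, 0.075, 0.3, 0.9)) {
    expect_equal(sigma2_to_icc(icc_to_sigma2(icc)), icc, tolerance = 1e-12)
  }
  expect_error(icc_to_sigma2(1), "icc")
  expect_error(icc_to_sigma2(-0.1), "icc")
  expect_error(sigma2_to_icc(-1), "sigma2")
})

test_that("center sizes sum to n in both modes; skewed mode drops empty cells", {
  expect_identical(assign_center_sizes(500, 5, "balanced"),
                   rep(100L, 5))
  expect_identical(assign_center_sizes(7, 3, "balanced"), c(3L, 2L, 2L))
  set.seed(11)
  for (i in 1:20) {
    s <- assign_center_sizes(200, 100, "skewed")
    expect_equal(sum(s), 200)
    expect_true(all(s >= 1))
    expect_lte(length(s), 100)
  }
})

test_that("mean realized center count matches the occupancy formula", {
  set.seed(3)
  counts <- replicate(2000, length(assign_center_sizes(200, 100, "skewed")))
  analytic <- 100 * (1 - 0.99^200)
  expect_lt(abs(mean(counts) - analytic), 3 * sd(counts) / sqrt(2000))
})

test_that("permuted blocks bound arm imbalance at every enrollment prefix", {
  set.seed(21)
  arms8 <- permuted_block_randomize(8, block_size = 4)[[1]]
  expect_equal(sum(arms8), 4)
  treated6 <- replicate(200, sum(permuted_block_randomize(6, 4)[[1]]))
  expect_true(all(treated6 %in% 2:4))
  for (i in 1:50) {
    n <- sample(1:23, 1)
    a <- permuted_block_randomize(n, 4)[[1]]
    imbalance <- abs(cumsum(2 * a - 1))
    expect_lte(max(imbalance), 2)
  }
  expect_error(permuted_block_randomize(10, 3), "even")
})

test_that("trial generation is reproducible and respects the threshold model", {
  cfg <- scenario_config(200, 5, icc = 0.025, p0 = 0.10, true_or = 1.5,
                         size_distribution = "skewed")
  t1 <- generate_trial(cfg, seed = 99)
  t2 <- generate_trial(cfg, seed = 99)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 200)
  expect_equal(length(unique(t1$center_id)), attr(t1, "n_centers_realized"))

  # sigma = 0, beta = 0: control event proportion converges to p0
  cfg0 <- scenario_config(60000, 6, icc = 0, p0 = 0.10, true_or = 1,
                          size_distribution = "balanced")
  tr <- generate_trial(cfg0, seed = 1)
  p_hat <- mean(tr$outcome[tr$arm == 0])
  expect_lt(abs(p_hat - 0.10), 3 * sqrt(0.1 * 0.9 / sum(tr$arm == 0)))

  # sigma = 0, OR = 3, p0 = 0.10: treated event probability is exactly
  # expit(logit(0.1) + log 3) = 0.25
  cfg3 <- scenario_config(60000, 6, icc = 0, p0 = 0.10, true_or = 3,
                          size_distribution = "balanced")
  tr3 <- generate_trial(cfg3, seed = 2)
  p1 <- mean(tr3$outcome[tr3$arm == 1])
  expect_lt(abs(p1 - 0.25), 3 * sqrt(0.25 * 0.75 / sum(tr3$arm == 1)))
})

test_that("marginal intercept calibration hits the population-averaged rate", {
  cfg <- scenario_config(1000, 10, icc = 0.3, p0 = 0.05, true_or = 1,
                         size_distribution = "balanced",
                         calibrate_intercept = "marginal")
  expect_lt(cfg$alpha, qlogis(0.05))  # must compensate for averaging over u
  # independent oracle: adaptive numerical integration over the random effect
  p_marg <- integrate(function(u) plogis(cfg$alpha + u) *
                        dnorm(u, 0, sqrt(cfg$sigma2)),
                      -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(p_marg, 0.05, tolerance = 1e-7)
  # conditional calibration, by contrast, sets the median-center rate
  cfg_c <- scenario_config(1000, 10, icc = 0.3, p0 = 0.05, true_or = 1,
                           size_distribution = "balanced")
  expect_equal(cfg_c$alpha, qlogis(0.05))
})

test_that("prescreening classifies trials by event pattern", {
  base <- data.frame(center_id = rep(1:2, each = 4),
                     arm = rep(c(0L, 1L), 4), outcome = 0L)
  expect_equal(prescreen_trial(base), "exclude_no_events")
  one_arm <- base; one_arm$outcome[one_arm$arm == 1][1:3] <- 1L
  expect_equal(prescreen_trial(one_arm), "exclude_one_arm_only")
  both <- one_arm; both$outcome[both$arm == 0][1] <- 1L
  expect_equal(prescreen_trial(both), "retain")
})

test_that("trial tables survive a text round trip and are validated on read", {
  cfg <- scenario_config(60, 3, icc = 0.025, p0 = 0.2, true_or = 1,
                         size_distribution = "balanced")
  tr <- generate_trial(cfg, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(back$center_id, tr$center_id)
  expect_equal(back$arm, tr$arm)
  expect_equal(back$outcome, tr$outcome)

  bad <- tr; bad$outcome[3] <- 2L
  bad_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_trial(bad_path), "row")
})
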