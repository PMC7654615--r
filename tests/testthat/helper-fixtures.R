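# Fixtures and independent oracles shared across test files.

# Subject-level data for a single collapsed 2x2 table:
# treated a events / b non-events, control c events / d non-events.
toy_2x2_trial <- function(a, b, c, d, center = 1L) {
  data.frame(
    center_id = center,
    arm = c(rep(1L, a + b), rep(0L, c + d)),
    outcome = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)))
}

# Fixed toy dataset: 3 centers x 6 subjects, both arms and both outcomes
# represented in every center. Deterministic by construction.
toy_gee_trial <- function() {
  data.frame(
    center_id = rep(1:3, each = 6),
    arm       = rep(c(0L, 0L, 0L, 1L, 1L, 1L), 3),
    outcome   = c(0L, 1L, 0L, 1L, 1L, 0L,
                  1L, 0L, 0L, 0L, 1L, 1L,
                  0L, 0L, 1L, 1L, 0L, 1L))
}

# Literal dense-matrix evaluation of the exchangeable-GEE sandwich and the
# Fay-Graubard corrected sandwich at given (beta, rho, phi): builds every
# n_i x n_i working covariance explicitly and evaluates the display
# equations term by term. Independent of the fitting code's closed-form
# inverse.
dense_gee_matrices <- function(data, beta, rho, phi, b = 0.75) {
  X <- cbind(1, data$arm)
  mu <- plogis(drop(X %*% beta))
  A <- mu * (1 - mu)
  r <- data$outcome - mu
  ids <- unique(data$center_id)
  H_list <- list(); g_list <- list()
  for (j in seq_along(ids)) {
    ii <- which(data$center_id == ids[j])
    n_c <- length(ii)
    R <- matrix(rho, n_c, n_c); diag(R) <- 1
    V <- phi * diag(sqrt(A[ii]), n_c) %*% R %*% diag(sqrt(A[ii]), n_c)
    D <- A[ii] * X[ii, , drop = FALSE]
    Vinv <- solve(V)
    H_list[[j]] <- t(D) %*% Vinv %*% D
    g_list[[j]] <- drop(t(D) %*% Vinv %*% r[ii])
  }
  Omega <- solve(Reduce(`+`, H_list))
  meat <- Reduce(`+`, lapply(g_list, tcrossprod))
  V_rob <- Omega %*% meat %*% Omega
  C_list <- lapply(H_list, function(H) {
    diag(1 / sqrt(1 - pmin(b, diag(H %*% Omega))), nrow(Omega))
  })
  meat_fg <- Reduce(`+`, Map(function(C, g) tcrossprod(drop(C %*% g)),
                             C_list, g_list))
  V_fg <- Omega %*% meat_fg %*% Omega
  U <- Reduce(`+`, g_list)
  list(Omega = Omega, V = V_rob, V_fg = V_fg, U = U,
       H_list = H_list, g_list = g_list, C_list = C_list)
}

# Brute-force random-intercept marginal log-likelihood: trapezoid rule over
# u on [-8*sigma, 8*sigma] with n_grid points, per center.
trapezoid_loglik <- function(data, alpha, beta, sigma, n_grid = 1e4) {
  u <- seq(-8 * sigma, 8 * sigma, length.out = n_grid)
  du <- u[2] - u[1]
  sum(vapply(split(seq_len(nrow(data)), data$center_id), function(idx) {
    y <- data$outcome[idx]
    eta0 <- alpha + beta * data$arm[idx]
    f <- vapply(u, function(uu) {
      eta <- eta0 + uu
      exp(sum(y * eta - log1p(exp(eta)))) * dnorm(uu, 0, sigma)
    }, numeric(1))
    log(sum((f[-1] + f[-n_grid]) / 2) * du)
  }, numeric(1)))
}

# A priori acceptance tolerance: both the reported value (m replicates here)
# and the reference value (5000 replicates) are Monte Carlo proportions, so
# compare at 3 combined binomial MCSEs.
tol3 <- function(p, m, m_ref = 5000) {
  3 * sqrt(p * (1 - p) * (1 / m + 1 / m_ref))
}
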