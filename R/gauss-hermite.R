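#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int f(x) e^{-x^2} dx \approx \sum_k w_k f(z_k)}
#' (physicists' convention), computed by the Golub-Welsch eigenvalue method
#' on the Jacobi matrix of the Hermite recurrence.
#'
#' @param n Number of nodes (>= 1).
#' @return List with \code{nodes} (ascending) and \code{weights}.
#' @examples
#' gh <- gauss_hermite(2)  # nodes +-1/sqrt(2), weights sqrt(pi)/2
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}
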