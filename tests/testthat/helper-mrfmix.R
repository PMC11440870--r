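# Shared fixtures for the test suite.  Everything is generated in code;
# no binary fixtures are used anywhere.

# A small blurred Poisson scene for sampler tests (square PSF matrix).
small_scene <- function(rows = 5, cols = 6, kernel_sd = 0.8, seed = 42) {
  truth <- matrix(10, rows, cols)
  truth[2:3, 2:3] <- 60
  sim <- simulate_observation(truth, kernel_sd = kernel_sd, seed = seed)
  list(truth = truth, y = sim$y, A = sim$A, lambda = sim$lambda,
       rows = rows, cols = cols)
}

# An empty-observation system matrix (flat likelihood) over m pixels.
flat_system <- function(m) {
  Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                       dims = c(0L, m))
}

# Midpoint-rule quadrature oracle for the 2-pixel homogeneous posterior
# with identity system matrix: returns normalized cell weights and the
# grid of cell centres.  Independent of the package's density code.
quad2_oracle <- function(y, tau, potential, upper = 25, n = 1000) {
  h <- upper / n
  gx <- h * (seq_len(n) - 0.5)
  loglik <- outer(y[1] * log(gx) - gx - lgamma(y[1] + 1),
                  y[2] * log(gx) - gx - lgamma(y[2] + 1), "+")
  d <- outer(gx, gx, "-")
  logpr <- if (potential == "laplace") -abs(d) / tau else -d^2 / (2 * tau^2)
  lp <- loglik + logpr
  w <- exp(lp - max(lp))
  list(w = w / sum(w), gx = gx, h = h)
}
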