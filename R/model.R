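#' Neighbour pairs of the first-order lattice graph
#'
#' Unordered 4-neighbourhood pairs (up/down/left/right, clipped at the
#' borders) in row-major pixel indexing.  Each unordered pair appears
#' exactly once.
#'
#' @param rows,cols Grid dimensions.
#' @return A two-column integer matrix of pixel index pairs (j, t), j < t.
#' @export
neighbour_pairs <- function(rows, cols) {
  idx <- matrix(seq_len(rows * cols), rows, cols, byrow = TRUE)
  horiz <- if (cols > 1) cbind(as.vector(idx[, -cols]), as.vector(idx[, -1]))
           else matrix(integer(), 0, 2)
  vert <- if (rows > 1) cbind(as.vector(idx[-rows, ]), as.vector(idx[-1, ]))
          else matrix(integer(), 0, 2)
  rbind(horiz, vert)
}

#' Adjacency list of the first-order lattice graph
#' @param rows,cols Grid dimensions.
#' @return A list of integer vectors; element j holds the neighbours of
#'   pixel j (row-major indexing).
#' @export
neighbour_list <- function(rows, cols) {
  p <- neighbour_pairs(rows, cols)
  nb <- vector("list", rows * cols)
  for (k in seq_len(nrow(p))) {
    nb[[p[k, 1]]] <- c(nb[[p[k, 1]]], p[k, 2])
    nb[[p[k, 2]]] <- c(nb[[p[k, 2]]], p[k, 1])
  }
  nb
}

phi_ <- function(d, potential) {
  switch(potential, absolute = abs(d), quadratic = d^2,
         stop("potential must be 'absolute' or 'quadratic'", call. = FALSE))
}

#' Markov random field energy
#'
#' Global energy `sum_j Phi_j(x)` with local energies
#' `Phi_j(x) = sum_{t in neighbours(j)} 0.5 * phi(x_j - x_t)`; with the
#' pair weight 0.5 each unordered neighbour pair contributes `phi` once.
#'
#' @param x Image matrix.
#' @param potential `"absolute"` (Laplace MRF) or `"quadratic"`
#'   (Gaussian MRF).
#' @return Nonnegative scalar energy.
#' @export
prior_energy <- function(x, potential = c("absolute", "quadratic")) {
  potential <- match.arg(potential)
  x <- unclass_image(x)
  r <- nrow(x); c <- ncol(x)
  e <- 0
  if (c > 1) e <- e + sum(phi_(x[, -1, drop = FALSE] - x[, -c, drop = FALSE], potential))
  if (r > 1) e <- e + sum(phi_(x[-1, , drop = FALSE] - x[-r, , drop = FALSE], potential))
  e
}

# Per-pixel local energies Phi_j (weight 0.5), for both potentials at once.
local_energies_ <- function(x) {
  x <- unclass_image(x)
  r <- nrow(x); c <- ncol(x)
  ea <- matrix(0, r, c); eq <- matrix(0, r, c)
  if (c > 1) {
    dh <- x[, -1, drop = FALSE] - x[, -c, drop = FALSE]
    ea[, -c] <- ea[, -c] + 0.5 * abs(dh); ea[, -1] <- ea[, -1] + 0.5 * abs(dh)
    eq[, -c] <- eq[, -c] + 0.5 * dh^2;    eq[, -1] <- eq[, -1] + 0.5 * dh^2
  }
  if (r > 1) {
    dv <- x[-1, , drop = FALSE] - x[-r, , drop = FALSE]
    ea[-r, ] <- ea[-r, ] + 0.5 * abs(dv); ea[-1, ] <- ea[-1, ] + 0.5 * abs(dv)
    eq[-r, ] <- eq[-r, ] + 0.5 * dv^2;    eq[-1, ] <- eq[-1, ] + 0.5 * dv^2
  }
  list(absolute = ea, quadratic = eq)
}

#' Poisson log-likelihood of an image
#'
#' `sum_i (y_i log lambda_i - lambda_i - log y_i!)` with
#' `lambda = A x`; returns `-Inf` (not an error) when some `lambda_i = 0`
#' with `y_i > 0`, and uses the `0 * log 0 = 0` convention.
#'
#' @param x Image matrix or pixel vector.
#' @param A System matrix.
#' @param y Integer count vector.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(x, A, y) {
  if (length(y) == 0) return(0)
  lambda <- project(A, x)
  if (length(lambda) != length(y))
    stop("length(y) != nrow(A)", call. = FALSE)
  sum(stats::dpois(y, lambda, log = TRUE))
}

#' Homogeneous MRF log prior
#'
#' Laplace: `-E_abs(x)/tau - m log(2 tau)`; Gaussian (sd `tau`):
#' `-E_quad(x)/(2 tau^2) - m log(sqrt(2 pi) tau)`, where `E` is
#' [prior_energy()].  The pseudo-independent per-pixel normalisers stand in
#' for the intractable Gibbs normalising constant, making scale updates
#' well defined; support truncation constants for `x >= 0` are omitted (they
#' cancel in Metropolis ratios).
#'
#' @param x Image matrix.
#' @param potential `"absolute"`/`"laplace"` or `"quadratic"`/`"gaussian"`.
#' @param tau Positive scale parameter (prior conditional scale, `1/B`).
#' @return Scalar log-density (unnormalised).
#' @export
log_prior_homogeneous <- function(x, potential, tau) {
  potential <- normalize_potential_(potential)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  m <- length(unclass_image(x))
  if (potential == "absolute")
    -prior_energy(x, "absolute") / tau - m * log(2 * tau)
  else
    -prior_energy(x, "quadratic") / (2 * tau^2) - m * log(sqrt(2 * pi) * tau)
}

normalize_potential_ <- function(potential) {
  switch(tolower(potential),
         absolute = , laplace = "absolute",
         quadratic = , gaussian = "quadratic",
         stop("unknown potential: ", potential, call. = FALSE))
}

#' Scale-invariant hyperprior on a positive scale, log density
#'
#' The weakly informative `pi(tau) proportional to 1/tau` prior (uniform on
#' `log tau`), unnormalised.
#' @param tau Positive scalar.
#' @return `-log(tau)`.
#' @export
log_hyperprior_tau <- function(tau) {
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  -log(tau)
}

#' Locally adaptive Laplace/Gaussian mixture log prior
#'
#' Per-pixel mixture in which the binary spatial factor `theta_j` selects
#' the local term: `theta_j = 1` gives the edge-preserving Laplace term
#' with scale `tau_l`, `theta_j = 0` the smoothing Gaussian term with
#' scale `tau_g`.  Local energies use the pair weight 0.5, so with all
#' labels equal the mixture reduces exactly to the homogeneous prior.
#'
#' @param x Image matrix.
#' @param theta Binary vector/matrix of length m (row-major).
#' @param tau_l,tau_g Positive scales of the Laplace and Gaussian terms.
#' @return Scalar log-density (unnormalised).
#' @export
log_mixture_prior <- function(x, theta, tau_l, tau_g) {
  if (tau_l <= 0 || tau_g <= 0) stop("scales must be > 0", call. = FALSE)
  th <- as_theta_vector_(theta, x)
  le <- local_energies_(x)
  ea <- as_pixel_vector(le$absolute); eq <- as_pixel_vector(le$quadratic)
  sum(th * (-ea / tau_l - log(2 * tau_l)) +
        (1 - th) * (-eq / (2 * tau_g^2) - log(sqrt(2 * pi) * tau_g)))
}

as_theta_vector_ <- function(theta, x) {
  th <- if (is.matrix(theta)) as_pixel_vector(theta) else as.numeric(theta)
  if (length(th) != length(unclass_image(x)))
    stop("theta length != number of pixels", call. = FALSE)
  if (!all(th %in% c(0, 1))) stop("theta must be binary", call. = FALSE)
  th
}

#' Gaussian hyperpriors on the mixture scales, log density
#'
#' Independent Gaussian hyperpriors centred at 100 (Laplace scale) and 10
#' (Gaussian scale), both with standard deviation 1, reflecting the prior
#' expectation that high-contrast neighbourhoods show much larger pixel
#' differences than smooth ones.
#'
#' @param tau_l,tau_g Positive scales.
#' @param mean_l,mean_g,sd_l,sd_g Hyperprior means and standard deviations.
#' @return Scalar log-density.
#' @export
log_hyperprior_scales <- function(tau_l, tau_g, mean_l = 100, mean_g = 10,
                                  sd_l = 1, sd_g = 1) {
  if (tau_l <= 0 || tau_g <= 0) stop("scales must be > 0", call. = FALSE)
  stats::dnorm(tau_l, mean_l, sd_l, log = TRUE) +
    stats::dnorm(tau_g, mean_g, sd_g, log = TRUE)
}

#' Bernoulli log prior of the spatial factor
#'
#' `sum_j theta_j log(rho) + (1 - theta_j) log(1 - rho)`; returns `-Inf`
#' when `rho` is 0 or 1 and some label conflicts.
#'
#' @param theta Binary vector/matrix.
#' @param rho Edge probability in `[0, 1]`.
#' @return Scalar log-probability.
#' @export
log_prior_theta <- function(theta, rho) {
  th <- if (is.matrix(theta)) as_pixel_vector(theta) else as.numeric(theta)
  if (!all(th %in% c(0, 1))) stop("theta must be binary", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  s <- sum(th); m <- length(th)
  term <- function(k, p) if (k == 0) 0 else k * log(p)  # 0 * log 0 = 0
  term(s, rho) + term(m - s, 1 - rho)
}

#' Beta hyperprior on the edge probability, log density
#'
#' `Beta(alpha, beta)` log density; the default `alpha = beta = 0.5` is
#' U-shaped, favouring decisive (near 0 or 1) edge probabilities.  Returns
#' `-Inf` outside the open unit interval.
#'
#' @param rho Probability (vectorised).
#' @param alpha,beta Positive shape parameters.
#' @return Log-density, one value per element of `rho`.
#' @export
log_hyperprior_rho <- function(rho, alpha = 0.5, beta = 0.5) {
  if (alpha <= 0 || beta <= 0) stop("alpha, beta must be > 0", call. = FALSE)
  out <- rep(-Inf, length(rho))
  ok <- rho > 0 & rho < 1
  out[ok] <- stats::dbeta(rho[ok], alpha, beta, log = TRUE)
  out
}

#' Joint log posterior of the homogeneous model
#'
#' `log_likelihood + log_prior_homogeneous + log_hyperprior_tau`
#' (unnormalised).
#'
#' @inheritParams log_prior_homogeneous
#' @param A System matrix.
#' @param y Count vector (may be empty for a flat likelihood).
#' @return Scalar log-density.
#' @export
log_posterior_homogeneous <- function(x, tau, potential, A, y) {
  log_likelihood(x, A, y) + log_prior_homogeneous(x, potential, tau) +
    log_hyperprior_tau(tau)
}

#' Joint log posterior of the mixture model
#'
#' Likelihood, mixture prior, scale hyperpriors, Bernoulli label prior and
#' Beta hyperprior on the edge probability, summed on the log scale
#' (unnormalised).
#'
#' @inheritParams log_mixture_prior
#' @param rho Edge probability.
#' @param A System matrix.
#' @param y Count vector.
#' @param hyper Hyperprior constants, see [hyperprior_spec()].
#' @return Scalar log-density.
#' @export
log_posterior_mixture <- function(x, theta, tau_l, tau_g, rho, A, y,
                                  hyper = hyperprior_spec()) {
  log_likelihood(x, A, y) +
    log_mixture_prior(x, theta, tau_l, tau_g) +
    log_hyperprior_scales(tau_l, tau_g, hyper$mean_l, hyper$mean_g,
                          hyper$sd_l, hyper$sd_g) +
    log_prior_theta(theta, rho) +
    log_hyperprior_rho(rho, hyper$alpha, hyper$beta)
}

#' Hyperprior constants of the mixture model
#'
#' @param mean_l,mean_g Gaussian hyperprior means of the Laplace and
#'   Gaussian scales (defaults 100 and 10).
#' @param sd_l,sd_g Hyperprior standard deviations (default 1).
#' @param alpha,beta Beta hyperprior shapes for the edge probability
#'   (default 0.5, 0.5).
#' @return A list of class `"hyperprior_spec"`.
#' @export
hyperprior_spec <- function(mean_l = 100, mean_g = 10, sd_l = 1, sd_g = 1,
                            alpha = 0.5, beta = 0.5) {
  stopifnot(mean_l > 0, mean_g > 0, sd_l > 0, sd_g > 0, alpha > 0, beta > 0)
  structure(list(mean_l = mean_l, mean_g = mean_g, sd_l = sd_l, sd_g = sd_g,
                 alpha = alpha, beta = beta),
            class = "hyperprior_spec")
}

#' Full conditional probability of a spatial-factor label
#'
#' `P(theta_j = 1 | x, tau_l, tau_g, rho)` computed in log space:
#' `rho L_j / (rho L_j + (1 - rho) G_j)` with `L_j`, `G_j` the local
#' Laplace and Gaussian terms at pixel j.  Given the image, the labels are
#' conditionally independent, so the result is vectorised over pixels.
#'
#' @param x Image matrix.
#' @param tau_l,tau_g Positive scales.
#' @param rho Edge probability in `[0, 1]`.
#' @param j Optional pixel indices (row-major); default all pixels.
#' @return Vector of probabilities.
#' @export
theta_conditional_prob <- function(x, tau_l, tau_g, rho, j = NULL) {
  if (tau_l <= 0 || tau_g <= 0) stop("scales must be > 0", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  le <- local_energies_(x)
  ea <- as_pixel_vector(le$absolute); eq <- as_pixel_vector(le$quadratic)
  if (!is.null(j)) { ea <- ea[j]; eq <- eq[j] }
  if (rho == 0) return(rep(0, length(ea)))
  if (rho == 1) return(rep(1, length(ea)))
  log_l <- -ea / tau_l - log(2 * tau_l)
  log_g <- -eq / (2 * tau_g^2) - log(sqrt(2 * pi) * tau_g)
  stats::plogis(log(rho) - log1p(-rho) + log_l - log_g)
}
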