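#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs samplers.  Proposal standard
#' deviations are adapted every `adapt_interval` iterations *during
#' burn-in only* toward the asymptotically optimal acceptance rate 0.234;
#' adaptation is frozen afterwards so the post-burn-in chain is a fixed
#' Markov kernel.
#'
#' @param iterations Total iterations (default 5000).
#' @param burn_in Iterations discarded before summaries (default 100).
#' @param adapt_interval Iterations between proposal-scale updates
#'   (default 10).
#' @param target_rate Target acceptance rate (default 0.234).
#' @param sd_pixel,sd_tau,sd_tau_l,sd_tau_g,sd_rho Initial random-walk
#'   proposal standard deviations per update block.
#' @param thin Keep every `thin`-th stored sample (default 1 = all).
#' @param store_x,store_theta Whether to store thinned image / label
#'   samples (posterior means are always accumulated exactly).
#' @param theta_mode `"gibbs"` (exact conditional draw, default) or
#'   `"metropolis"` (single-flip proposals) for the spatial factor.
#' @param rho_mode `"gibbs"` (conjugate Beta draw, default) or
#'   `"metropolis"` for the edge probability.
#' @param seed Optional integer seed; fixed seeds give bit-identical chains.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 5000, burn_in = 100, adapt_interval = 10,
                        target_rate = 0.234, sd_pixel = 10, sd_tau = 10,
                        sd_tau_l = 1, sd_tau_g = 1, sd_rho = 0.05,
                        thin = 1, store_x = TRUE, store_theta = TRUE,
                        theta_mode = c("gibbs", "metropolis"),
                        rho_mode = c("gibbs", "metropolis"), seed = NULL) {
  theta_mode <- match.arg(theta_mode)
  rho_mode <- match.arg(rho_mode)
  stopifnot(iterations > burn_in, burn_in >= 0, adapt_interval >= 1,
            target_rate > 0, target_rate < 1, sd_pixel > 0, sd_tau > 0,
            sd_tau_l > 0, sd_tau_g > 0, sd_rho > 0, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 adapt_interval = as.integer(adapt_interval),
                 target_rate = target_rate, sd_pixel = sd_pixel,
                 sd_tau = sd_tau, sd_tau_l = sd_tau_l, sd_tau_g = sd_tau_g,
                 sd_rho = sd_rho, thin = as.integer(thin),
                 store_x = store_x, store_theta = store_theta,
                 theta_mode = theta_mode, rho_mode = rho_mode, seed = seed),
            class = "mcmc_config")
}

#' Proposal-scale adaptation rule
#'
#' `scale_new = 0.5 * scale * (1 + r / target_rate)`: the scale is halved
#' when nothing was accepted, unchanged at the target rate, and grows when
#' acceptance is high.
#'
#' @param scale Current proposal standard deviation (> 0).
#' @param r Observed acceptance rate in `[0, 1]`.
#' @param target_rate Target acceptance rate (default 0.234).
#' @return The updated scale.
#' @export
adapt_scale <- function(scale, r, target_rate = 0.234) {
  stopifnot(scale > 0, r >= 0, r <= 1)
  0.5 * scale * (1 + r / target_rate)
}

csc_parts_ <- function(A) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  list(p = A@p, i = A@i, x = A@x, n = nrow(A), m = ncol(A))
}

#' One Metropolis sweep over all pixels
#'
#' Random-walk update of every pixel in raster order with outright
#' rejection of negative proposals.  The acceptance ratio uses only the
#' likelihood rows touched by the pixel and the local prior terms; pass
#' `theta`, `tau_l`, `tau_g` for the mixture prior, or `tau` with a
#' `potential` for the homogeneous prior.  Intended for toy problems and
#' verification; full-length chains run through [run_homogeneous()] /
#' [run_mixture()].
#'
#' @param x Current image matrix (nonnegative).
#' @param y Count vector.
#' @param A System matrix.
#' @param proposal_sd Random-walk standard deviation.
#' @param potential `"laplace"` or `"gaussian"` (homogeneous prior).
#' @param tau Homogeneous prior scale.
#' @param theta,tau_l,tau_g Mixture prior state (used when `theta` given).
#' @return A list with the updated image `x` and the `accepted` count.
#' @export
pixel_sweep <- function(x, y, A, proposal_sd, potential = "laplace",
                        tau = NULL, theta = NULL, tau_l = NULL, tau_g = NULL) {
  x <- unclass_image(x)
  rows <- nrow(x); cols <- ncol(x)
  v <- as_pixel_vector(x)
  lambda <- as.numeric(A %*% v)
  nb <- neighbour_list(rows, cols)
  mixture <- !is.null(theta)
  if (mixture) {
    th <- as_theta_vector_(theta, x)
    stopifnot(tau_l > 0, tau_g > 0)
  } else {
    potential <- normalize_potential_(potential)
    stopifnot(tau > 0)
  }
  accepted <- 0L
  for (j in seq_along(v)) {
    xp <- v[j] + stats::rnorm(1, 0, proposal_sd)
    if (xp < 0) next
    a_col <- A[, j]
    nz <- which(a_col != 0)
    lam_new <- lambda[nz] + a_col[nz] * (xp - v[j])
    dll <- sum(stats::dpois(y[nz], lam_new, log = TRUE)) -
           sum(stats::dpois(y[nz], lambda[nz], log = TRUE))
    dn <- xp - v[nb[[j]]]; dold <- v[j] - v[nb[[j]]]
    if (mixture) {
      wl <- 0.5 * (th[j] + th[nb[[j]]])
      wg <- 0.5 * ((1 - th[j]) + (1 - th[nb[[j]]]))
      dpr <- sum(wl * (abs(dn) - abs(dold))) / tau_l +
             sum(wg * (dn^2 - dold^2)) / (2 * tau_g^2)
    } else if (potential == "absolute") {
      dpr <- sum(abs(dn) - abs(dold)) / tau
    } else {
      dpr <- sum(dn^2 - dold^2) / (2 * tau^2)
    }
    if (log(stats::runif(1)) < dll - dpr) {
      lambda[nz] <- lam_new
      v[j] <- xp
      accepted <- accepted + 1L
    }
  }
  list(x = as_image(v, rows, cols), accepted = accepted)
}

#' One Metropolis update of the homogeneous prior scale
#'
#' Targets `pi(x | tau) pi(tau)` with the scale-invariant `1/tau`
#' hyperprior; nonpositive proposals are rejected.
#'
#' @param x Image matrix.
#' @param tau Current scale (> 0).
#' @param potential `"laplace"` or `"gaussian"`.
#' @param proposal_sd Random-walk standard deviation.
#' @return A list with the updated `tau` and logical `accepted`.
#' @export
sample_tau <- function(x, tau, potential, proposal_sd) {
  stopifnot(tau > 0, proposal_sd > 0)
  target <- function(t) log_prior_homogeneous(x, potential, t) +
    log_hyperprior_tau(t)
  tp <- tau + stats::rnorm(1, 0, proposal_sd)
  accepted <- FALSE
  if (tp > 0 && log(stats::runif(1)) < target(tp) - target(tau)) {
    tau <- tp; accepted <- TRUE
  }
  list(tau = tau, accepted = accepted)
}

#' Metropolis updates of the two mixture scales
#'
#' Given the labels, the Laplace scale `tau_l` and Gaussian scale `tau_g`
#' are conditionally independent (each sees only its own pixel subset and
#' hyperprior), so the two updates share no state and their order is
#' irrelevant.
#'
#' @param x Image matrix.
#' @param theta Binary label vector/matrix.
#' @param tau_l,tau_g Current scales.
#' @param proposal_sd_l,proposal_sd_g Random-walk standard deviations.
#' @param hyper Hyperprior constants, see [hyperprior_spec()].
#' @return List with updated `tau_l`, `tau_g` and logical acceptance flags.
#' @export
sample_scales <- function(x, theta, tau_l, tau_g, proposal_sd_l = 1,
                          proposal_sd_g = 1, hyper = hyperprior_spec()) {
  th <- as_theta_vector_(theta, x)
  le <- local_energies_(x)
  ea <- as_pixel_vector(le$absolute); eq <- as_pixel_vector(le$quadratic)
  S_l <- sum(ea[th == 1]); n_l <- sum(th == 1)
  S_g <- sum(eq[th == 0]); n_g <- sum(th == 0)
  tgt_l <- function(t) -S_l / t - n_l * log(2 * t) +
    stats::dnorm(t, hyper$mean_l, hyper$sd_l, log = TRUE)
  tgt_g <- function(t) -S_g / (2 * t^2) - n_g * log(sqrt(2 * pi) * t) +
    stats::dnorm(t, hyper$mean_g, hyper$sd_g, log = TRUE)
  acc_l <- acc_g <- FALSE
  tp <- tau_l + stats::rnorm(1, 0, proposal_sd_l)
  if (tp > 0 && log(stats::runif(1)) < tgt_l(tp) - tgt_l(tau_l)) {
    tau_l <- tp; acc_l <- TRUE
  }
  tp <- tau_g + stats::rnorm(1, 0, proposal_sd_g)
  if (tp > 0 && log(stats::runif(1)) < tgt_g(tp) - tgt_g(tau_g)) {
    tau_g <- tp; acc_g <- TRUE
  }
  list(tau_l = tau_l, tau_g = tau_g, accepted_l = acc_l, accepted_g = acc_g)
}

#' One update sweep of the spatial factor
#'
#' Default `"gibbs"` mode draws every label exactly from its full
#' conditional [theta_conditional_prob()] (the labels are conditionally
#' independent given the image); `"metropolis"` mode proposes single-label
#' flips instead.
#'
#' @param x Image matrix.
#' @param theta Current binary labels.
#' @param tau_l,tau_g Scales.
#' @param rho Edge probability.
#' @param mode `"gibbs"` or `"metropolis"`.
#' @return List with updated `theta` (vector, row-major) and `accepted`
#'   flip count (Metropolis mode only).
#' @export
sample_theta <- function(x, theta, tau_l, tau_g, rho,
                         mode = c("gibbs", "metropolis")) {
  mode <- match.arg(mode)
  th <- as_theta_vector_(theta, x)
  p <- theta_conditional_prob(x, tau_l, tau_g, rho)
  if (mode == "gibbs") {
    th <- as.integer(stats::runif(length(th)) < p)
    return(list(theta = th, accepted = NA_integer_))
  }
  accepted <- 0L
  for (j in seq_along(th)) {
    z <- stats::qlogis(p[j])                    # log odds of theta_j = 1
    lr <- if (th[j] == 1) -z else z             # flip proposal
    if (log(stats::runif(1)) < lr) {
      th[j] <- 1L - th[j]; accepted <- accepted + 1L
    }
  }
  list(theta = th, accepted = accepted)
}

#' One update of the edge probability
#'
#' Default `"gibbs"` mode draws from the conjugate posterior
#' `Beta(alpha + sum(theta), beta + m - sum(theta))`; `"metropolis"` mode
#' uses a random walk with proposals outside (0, 1) rejected.
#'
#' @param theta Binary labels.
#' @param alpha,beta Beta hyperprior shapes.
#' @param mode `"gibbs"` or `"metropolis"`.
#' @param rho Current value (Metropolis mode).
#' @param proposal_sd Random-walk standard deviation (Metropolis mode).
#' @return List with updated `rho` and logical `accepted`.
#' @export
sample_rho <- function(theta, alpha = 0.5, beta = 0.5,
                       mode = c("gibbs", "metropolis"), rho = NULL,
                       proposal_sd = 0.05) {
  mode <- match.arg(mode)
  th <- if (is.matrix(theta)) as_pixel_vector(theta) else as.numeric(theta)
  s <- sum(th); m <- length(th)
  if (mode == "gibbs")
    return(list(rho = stats::rbeta(1, alpha + s, beta + m - s),
                accepted = NA))
  stopifnot(!is.null(rho), rho > 0, rho < 1)
  tgt <- function(p) (alpha - 1 + s) * log(p) + (beta - 1 + m - s) * log1p(-p)
  rp <- rho + stats::rnorm(1, 0, proposal_sd)
  accepted <- FALSE
  if (rp > 0 && rp < 1 && log(stats::runif(1)) < tgt(rp) - tgt(rho)) {
    rho <- rp; accepted <- TRUE
  }
  list(rho = rho, accepted = accepted)
}

default_x0_ <- function(y, A, rows, cols, x0) {
  if (!is.null(x0)) return(as_pixel_vector(unclass_image(x0)))
  if (nrow(A) == ncol(A)) return(as.numeric(y))
  rep(max(mean(y), 1), rows * cols)
}

#' Run the homogeneous-prior sampler
#'
#' Metropolis-within-Gibbs chain for the Poisson likelihood with a
#' homogeneous Laplace or Gaussian MRF prior: one Metropolis sweep over
#' the pixels per iteration, followed (when `tau` is not fixed) by a
#' Metropolis update of the scale under the `1/tau` hyperprior.  Proposal
#' scales adapt toward the 0.234 rate during burn-in.
#'
#' @param y Integer count vector (length `rows * cols` for a square PSF
#'   system matrix).
#' @param A System matrix.
#' @param rows,cols Image dimensions.
#' @param potential `"laplace"` or `"gaussian"`.
#' @param tau `NULL` to estimate the scale (default), or a fixed positive
#'   value.
#' @param config An [mcmc_config()].
#' @param x0 Optional initial image; defaults to the observed counts.
#' @return An object of class `"mrf_chain"`.
#' @export
run_homogeneous <- function(y, A, rows, cols,
                            potential = c("laplace", "gaussian"),
                            tau = NULL, config = mcmc_config(), x0 = NULL) {
  potential <- match.arg(potential)
  stopifnot(inherits(config, "mcmc_config"), all(y >= 0))
  csc <- csc_parts_(A)
  if (length(y) != csc$n || rows * cols != csc$m)
    stop("dimension mismatch between y, A and the grid", call. = FALSE)
  x0v <- default_x0_(y, A, rows, cols, x0)
  estimate_tau <- is.null(tau)
  tau0 <- if (estimate_tau) 100 else tau
  stopifnot(tau0 > 0)
  res <- with_seed_(config$seed,
    run_homogeneous_cpp(as.integer(y), csc$p, csc$i, csc$x, rows, cols,
                        if (potential == "laplace") 0L else 1L,
                        estimate_tau, tau0, x0v,
                        config$iterations, config$burn_in,
                        config$adapt_interval, config$target_rate,
                        config$sd_pixel, config$sd_tau, config$thin,
                        config$store_x))
  structure(c(res, list(model = potential, mixture = FALSE,
                        estimate_tau = estimate_tau, rows = rows, cols = cols,
                        config = config, seed = config$seed)),
            class = "mrf_chain")
}

#' Run the mixture-prior sampler
#'
#' Full Metropolis-within-Gibbs chain for the locally adaptive
#' Laplace/Gaussian mixture model.  Per iteration: pixel sweep, label
#' update (Gibbs by default), the two conditionally independent scale
#' updates, and the edge-probability update (conjugate Beta by default).
#'
#' @inheritParams run_homogeneous
#' @param hyper Hyperprior constants, see [hyperprior_spec()].
#' @param theta0 Optional initial labels; defaults to thresholding the
#'   maximum neighbour difference of the initial image at 50.
#' @param fix_scales Optional `c(tau_l, tau_g)` to hold the scales fixed.
#' @param fix_rho Optional fixed edge probability.
#' @return An object of class `"mrf_chain"` with label traces and
#'   post-burn-in inclusion frequencies `theta_freq`.
#' @export
run_mixture <- function(y, A, rows, cols, hyper = hyperprior_spec(),
                        config = mcmc_config(), x0 = NULL, theta0 = NULL,
                        fix_scales = NULL, fix_rho = NULL) {
  stopifnot(inherits(config, "mcmc_config"), all(y >= 0))
  csc <- csc_parts_(A)
  if (length(y) != csc$n || rows * cols != csc$m)
    stop("dimension mismatch between y, A and the grid", call. = FALSE)
  x0v <- default_x0_(y, A, rows, cols, x0)
  if (is.null(theta0)) {
    d <- neighbour_max_diff(as_image(x0v, rows, cols))
    theta0 <- as.integer(as_pixel_vector(d) > 50)
  } else {
    theta0 <- as.integer(as_theta_vector_(theta0, as_image(x0v, rows, cols)))
  }
  estimate_scales <- is.null(fix_scales)
  tau_l0 <- if (estimate_scales) hyper$mean_l else fix_scales[1]
  tau_g0 <- if (estimate_scales) hyper$mean_g else fix_scales[2]
  estimate_rho <- is.null(fix_rho)
  rho0 <- if (estimate_rho) 0.5 else fix_rho
  stopifnot(tau_l0 > 0, tau_g0 > 0, rho0 >= 0, rho0 <= 1)
  res <- with_seed_(config$seed,
    run_mixture_cpp(as.integer(y), csc$p, csc$i, csc$x, rows, cols, x0v,
                    theta0, tau_l0, tau_g0, rho0,
                    c(hyper$mean_l, hyper$mean_g, hyper$sd_l, hyper$sd_g,
                      hyper$alpha, hyper$beta),
                    estimate_scales, estimate_rho,
                    if (config$theta_mode == "gibbs") 0L else 1L,
                    if (config$rho_mode == "gibbs") 0L else 1L,
                    config$iterations, config$burn_in, config$adapt_interval,
                    config$target_rate, config$sd_pixel, config$sd_tau_l,
                    config$sd_tau_g, config$sd_rho, config$thin,
                    config$store_x, config$store_theta))
  structure(c(res, list(model = "mixture", mixture = TRUE, hyper = hyper,
                        rows = rows, cols = cols, config = config,
                        seed = config$seed)),
            class = "mrf_chain")
}

#' @export
#' @method print mrf_chain
print.mrf_chain <- function(x, ...) {
  cat("<mrf_chain>", x$model, "model,", x$rows, "x", x$cols, "grid\n")
  cat("  iterations:", x$config$iterations, " burn-in:", x$config$burn_in, "\n")
  post <- seq(x$config$burn_in + 1L, x$config$iterations)
  cat("  mean pixel acceptance (post burn-in):",
      round(mean(x$accept_pixel[post]), 3), "\n")
  if (x$mixture) {
    cat("  posterior mean tau_l:", round(mean(x$tau_l[post]), 2),
        " tau_g:", round(mean(x$tau_g[post]), 2),
        " rho:", round(mean(x$rho[post]), 3), "\n")
  } else if (x$estimate_tau) {
    cat("  posterior mean tau:", round(mean(x$tau[post]), 2), "\n")
  }
  invisible(x)
}

#' Posterior mean image of a chain
#' @param chain An `"mrf_chain"`.
#' @return Numeric matrix (exact mean over all post-burn-in iterations).
#' @export
posterior_mean_image <- function(chain) {
  stopifnot(inherits(chain, "mrf_chain"))
  as_image(chain$x_mean, chain$rows, chain$cols)
}
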