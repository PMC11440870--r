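post_indices_ <- function(chain) {
  seq(chain$config$burn_in + 1L, chain$config$iterations)
}

#' Pixelwise posterior summary of a chain
#'
#' Posterior mean image (exact, accumulated over every post-burn-in
#' iteration) and equal-tailed credible-interval images at the given level
#' (from the stored, possibly thinned, post-burn-in samples).
#'
#' @param chain An `"mrf_chain"`.
#' @param level Credible level (default 0.95).
#' @return An object of class `"mrf_summary"`: list with matrices `mean`,
#'   `lower`, `upper` and the `level`.
#' @export
posterior_summary <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "mrf_chain"), level > 0, level < 1)
  if (is.null(chain$x_samples))
    stop("chain stores no image samples (store_x = FALSE)", call. = FALSE)
  keep <- chain$kept_iterations > chain$config$burn_in
  if (!any(keep)) stop("no post-burn-in samples stored", call. = FALSE)
  xs <- chain$x_samples[keep, , drop = FALSE]
  a <- (1 - level) / 2
  qs <- apply(xs, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  structure(list(mean = posterior_mean_image(chain),
                 lower = as_image(qs[1, ], chain$rows, chain$cols),
                 upper = as_image(qs[2, ], chain$rows, chain$cols),
                 level = level),
            class = "mrf_summary")
}

#' Mean squared error over a pixel mask
#'
#' @param estimate,truth Numeric matrices of identical shape.
#' @param mask Optional logical matrix selecting pixels (default: all).
#' @return Nonnegative scalar.
#' @export
mse <- function(estimate, truth, mask = NULL) {
  estimate <- unclass_image(estimate); truth <- unclass_image(truth)
  if (!identical(dim(estimate), dim(truth)))
    stop("estimate and truth shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(truth), ncol(truth))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  mean((estimate[mask] - truth[mask])^2)
}

roi_mask_list_ <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  out <- list(global = rois$global)
  for (k in sort(unique(rois$labels[rois$labels > 0])))
    out[[paste0("roi", k)]] <- rois$labels == k
  out
}

#' Sensitivity sweep of the MSE over the prior scale
#'
#' For every scale on `tau_grid` and every requested potential, runs a
#' fixed-scale homogeneous chain, takes the posterior mean image, and
#' records the MSE against the truth globally and within each numbered
#' RoI.  The attribute `"optimum"` tabulates the arg-min scale per
#' potential and region.
#'
#' @param y Count vector.
#' @param A System matrix.
#' @param truth Ground-truth image.
#' @param rois An `"roi_set"` from [make_roi_masks()].
#' @param tau_grid Strictly increasing positive scales.
#' @param potentials Character vector among `"laplace"`, `"gaussian"`.
#' @param config An [mcmc_config()]; image storage is disabled internally.
#' @return A tibble of class `"tau_sweep"` with columns `potential`,
#'   `tau`, `roi`, `mse`.
#' @export
tau_sweep <- function(y, A, truth, rois, tau_grid,
                      potentials = c("laplace", "gaussian"),
                      config = mcmc_config(iterations = 1000)) {
  stopifnot(all(tau_grid > 0), !is.unsorted(tau_grid, strictly = TRUE))
  potentials <- match.arg(potentials, several.ok = TRUE)
  truth <- unclass_image(truth)
  masks <- roi_mask_list_(rois)
  config$store_x <- FALSE
  rows_out <- list(); idx <- 1L
  for (pot in potentials) {
    for (tv in tau_grid) {
      ch <- run_homogeneous(y, A, nrow(truth), ncol(truth), potential = pot,
                            tau = tv, config = config)
      est <- posterior_mean_image(ch)
      for (rn in names(masks)) {
        rows_out[[idx]] <- tibble::tibble(potential = pot, tau = tv, roi = rn,
                                          mse = mse(est, truth, masks[[rn]]))
        idx <- idx + 1L
      }
    }
  }
  out <- do.call(rbind, rows_out)
  opt <- do.call(rbind, lapply(split(out, list(out$potential, out$roi)),
    function(d) d[which.min(d$mse), c("potential", "roi", "tau", "mse")]))
  rownames(opt) <- NULL
  structure(out, optimum = tibble::as_tibble(opt),
            class = c("tau_sweep", class(out)))
}

#' Arg-min scales of a sensitivity sweep
#' @param sweep A `"tau_sweep"`.
#' @return Tibble with the optimal `tau` and minimal `mse` per potential
#'   and region.
#' @export
sweep_optimum <- function(sweep) attr(sweep, "optimum")

#' Classify pixels from the posterior of the spatial factor
#'
#' Labels a pixel as hot/high-contrast (1) when its post-burn-in inclusion
#' frequency of `theta_j = 1` exceeds `threshold`.
#'
#' @param chain A mixture `"mrf_chain"`.
#' @param threshold Frequency threshold (default 0.5).
#' @return An object of class `"classification_map"`: list with the binary
#'   `labels` matrix and `source = "theta-posterior"`.
#' @export
classify_theta <- function(chain, threshold = 0.5) {
  stopifnot(inherits(chain, "mrf_chain"))
  if (!isTRUE(chain$mixture))
    stop("theta classification needs a mixture chain", call. = FALSE)
  labels <- as_image(as.integer(chain$theta_freq > threshold),
                     chain$rows, chain$cols)
  structure(list(labels = labels, source = "theta-posterior",
                 threshold = threshold),
            class = "classification_map")
}

#' Intensity k-means baseline classification
#'
#' Lloyd's algorithm ([stats::kmeans()]) on the pixel intensities with
#' `nstart` seeded restarts; the cluster with the higher centroid is
#' labelled 1, so the labelling does not depend on initialisation order.
#'
#' @param estimate Image matrix with at least `k` distinct values.
#' @param k Number of clusters (default 2).
#' @param nstart Random restarts (default 10).
#' @param seed Optional seed for the restarts.
#' @return A `"classification_map"` with `source = "k-means"`.
#' @export
kmeans_baseline <- function(estimate, k = 2, nstart = 10, seed = NULL) {
  estimate <- unclass_image(estimate)
  v <- as_pixel_vector(estimate)
  if (length(unique(v)) < k)
    stop("fewer distinct intensity values than clusters", call. = FALSE)
  km <- with_seed_(seed, stats::kmeans(v, centers = k, nstart = nstart))
  hi <- which.max(km$centers)
  labels <- as_image(as.integer(km$cluster == hi), nrow(estimate),
                     ncol(estimate))
  structure(list(labels = labels, source = "k-means",
                 centers = sort(as.numeric(km$centers))),
            class = "classification_map")
}

#' Agreement between a classification map and a reference mask
#'
#' @param map A `"classification_map"` (or a binary matrix).
#' @param reference Binary/logical matrix of the same shape.
#' @return Fraction of agreeing pixels, in `[0, 1]`.
#' @export
classification_agreement <- function(map, reference) {
  labels <- if (inherits(map, "classification_map")) map$labels
            else unclass_image(map)
  reference <- unclass_image(reference) * 1
  if (!identical(dim(labels), dim(reference)))
    stop("shape mismatch between map and reference", call. = FALSE)
  mean((labels * 1) == reference)
}

#' Extract a row or column profile for plotting
#'
#' Returns the values of a 1-based row or column of the posterior summary
#' (and optionally the truth) as an ordered table, e.g. the 20th row or
#' 36th column of a 29 x 58 restoration.
#'
#' @param summary An `"mrf_summary"`, or a plain image matrix.
#' @param axis `"row"` or `"column"`.
#' @param index 1-based row/column index.
#' @param truth Optional ground-truth matrix.
#' @return A tibble with columns `position`, `mean`, `lower`, `upper`
#'   (the latter two only for summaries) and `truth` if supplied.
#' @export
extract_profile <- function(summary, axis = c("row", "column"), index,
                            truth = NULL) {
  axis <- match.arg(axis)
  pick <- function(mat) {
    mat <- unclass_image(mat)
    if (axis == "row") {
      if (index < 1 || index > nrow(mat)) stop("row index out of range",
                                               call. = FALSE)
      mat[index, ]
    } else {
      if (index < 1 || index > ncol(mat)) stop("column index out of range",
                                               call. = FALSE)
      mat[, index]
    }
  }
  if (inherits(summary, "mrf_summary")) {
    out <- tibble::tibble(position = seq_along(pick(summary$mean)),
                          mean = pick(summary$mean),
                          lower = pick(summary$lower),
                          upper = pick(summary$upper))
  } else {
    out <- tibble::tibble(position = seq_along(pick(summary)),
                          mean = pick(summary))
  }
  if (!is.null(truth)) out$truth <- pick(truth)
  out
}
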