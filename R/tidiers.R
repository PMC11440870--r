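#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter traces of a chain
#'
#' @param x An `"mrf_chain"`.
#' @param ... Unused.
#' @return A long tibble with columns `iteration`, `parameter`, `value`
#'   covering the scale/probability traces and the pixel acceptance rate.
#' @export
tidy.mrf_chain <- function(x, ...) {
  iters <- seq_len(x$config$iterations)
  pars <- if (x$mixture)
    list(tau_l = x$tau_l, tau_g = x$tau_g, rho = x$rho,
         accept_pixel = x$accept_pixel)
  else
    list(tau = x$tau, accept_pixel = x$accept_pixel)
  do.call(rbind, lapply(names(pars), function(nm)
    tibble::tibble(iteration = iters, parameter = nm, value = pars[[nm]])))
}

#' One-row summary of a chain
#'
#' @param x An `"mrf_chain"`.
#' @param ... Unused.
#' @return A one-row tibble: model, iterations, burn-in, post-burn-in
#'   pixel acceptance rate, and posterior means of the scale parameters.
#' @export
glance.mrf_chain <- function(x, ...) {
  post <- post_indices_(x)
  out <- tibble::tibble(model = x$model,
                        iterations = x$config$iterations,
                        burn_in = x$config$burn_in,
                        accept_pixel = mean(x$accept_pixel[post]))
  if (x$mixture) {
    out$tau_l <- mean(x$tau_l[post])
    out$tau_g <- mean(x$tau_g[post])
    out$rho <- mean(x$rho[post])
  } else if (isTRUE(x$estimate_tau)) {
    out$tau <- mean(x$tau[post])
  }
  out
}

#' Image matrix as a tidy pixel table
#' @param x Numeric matrix.
#' @param value Column name for the pixel value.
#' @return Tibble with columns `row`, `col` and the value column.
#' @export
image_to_tibble <- function(x, value = "value") {
  x <- unclass_image(x)
  out <- tibble::tibble(row = rep(seq_len(nrow(x)), ncol(x)),
                        col = rep(seq_len(ncol(x)), each = nrow(x)))
  out[[value]] <- as.vector(x)
  out
}

need_ggplot_ <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Plot an image matrix
#' @param x Numeric matrix.
#' @param title Optional title.
#' @return A ggplot raster plot (row 1 at the top).
#' @export
plot_image <- function(x, title = NULL) {
  need_ggplot_()
  d <- image_to_tibble(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::scale_fill_viridis_c()
}

#' Trace plots of a chain
#' @param object An `"mrf_chain"`.
#' @param ... Unused.
#' @return A ggplot with one facet per traced parameter.
#' @exportS3Method ggplot2::autoplot
autoplot.mrf_chain <- function(object, ...) {
  need_ggplot_()
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$config$burn_in,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}

#' Posterior mean image plot
#' @param object An `"mrf_summary"`.
#' @param ... Unused.
#' @return A ggplot raster of the posterior mean.
#' @exportS3Method ggplot2::autoplot
autoplot.mrf_summary <- function(object, ...) {
  plot_image(object$mean, title = "posterior mean")
}

#' MSE sensitivity curves of a scale sweep
#' @param object A `"tau_sweep"`.
#' @param ... Unused.
#' @return A ggplot of MSE against the prior scale (log axis), one facet
#'   per region, coloured by potential.
#' @exportS3Method ggplot2::autoplot
autoplot.tau_sweep <- function(object, ...) {
  need_ggplot_()
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$mse,
                                       colour = .data$potential)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = expression(tau), y = "MSE")
}

#' Profile plot with credible band
#' @param profile_tbl Output of [extract_profile()].
#' @return A ggplot of the posterior mean and interval along the profile,
#'   with the truth overlaid when present.
#' @export
plot_profile <- function(profile_tbl) {
  need_ggplot_()
  p <- ggplot2::ggplot(profile_tbl,
                       ggplot2::aes(x = .data$position, y = .data$mean))
  if (all(c("lower", "upper") %in% names(profile_tbl)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80")
  p <- p + ggplot2::geom_line(colour = "steelblue")
  if ("truth" %in% names(profile_tbl))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$truth),
                                colour = "red", linetype = "dashed")
  p + ggplot2::labs(x = "pixel", y = "value")
}
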