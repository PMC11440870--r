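#' Reference phantom geometry
#'
#' Fixed layout of the package's reference simulation phantom on a 29 x 58
#' pixel grid: one large circular hot region toward the right, a small
#' irregular region at the circle's lower right, and two rectangular hot
#' regions toward the left.  The layout is frozen so that every simulation
#' in the package runs on the same ground truth.
#'
#' @return A list describing the grid size and the hot-region shapes.
#' @export
reference_geometry <- function() {
  list(
    rows = 29L, cols = 58L,
    circle = list(center = c(14, 40), radius = 8),
    blob = list(centers = list(c(24, 49), c(26, 51), c(25, 52)), radius = 2),
    rect1 = c(5L, 10L, 8L, 20L),   # row1, row2, col1, col2
    rect2 = c(18L, 24L, 10L, 18L)
  )
}

hot_mask_from_geometry <- function(geom) {
  rows <- geom$rows; cols <- geom$cols
  rc <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  mask <- matrix(FALSE, rows, cols)
  disc <- function(center, radius) {
    (rc$row - center[1])^2 + (rc$col - center[2])^2 <= radius^2
  }
  in_bounds <- function(r1, r2, c1, c2) {
    if (r1 < 1 || c1 < 1 || r2 > rows || c2 > cols)
      stop("phantom geometry region exceeds grid bounds", call. = FALSE)
  }
  if (!is.null(geom$circle)) {
    ctr <- geom$circle$center; rad <- geom$circle$radius
    in_bounds(ctr[1] - rad, ctr[1] + rad, ctr[2] - rad, ctr[2] + rad)
    mask[disc(ctr, rad)] <- TRUE
  }
  if (!is.null(geom$blob)) {
    for (ctr in geom$blob$centers) {
      rad <- geom$blob$radius
      in_bounds(ctr[1] - rad, ctr[1] + rad, ctr[2] - rad, ctr[2] + rad)
      mask[disc(ctr, rad)] <- TRUE
    }
  }
  for (nm in c("rect1", "rect2")) {
    if (!is.null(geom[[nm]])) {
      rc4 <- geom[[nm]]
      in_bounds(rc4[1], rc4[2], rc4[3], rc4[4])
      mask[rc4[1]:rc4[2], rc4[3]:rc4[4]] <- TRUE
    }
  }
  mask
}

#' Generate a piecewise-constant simulation phantom
#'
#' Builds a nonnegative image with hot regions at `hot_value` on a constant
#' background, on the frozen reference layout (29 x 58; see
#' [reference_geometry()]) or a user-supplied geometry list.
#'
#' @param geometry `"reference"` (aliases `"paper1"`, `"paper2"`), or a
#'   geometry list in the format of [reference_geometry()].
#' @param hot_value Pixel value inside the hot regions; must satisfy
#'   `hot_value >= background_value`.
#' @param background_value Pixel value elsewhere (default 0).
#' @return A numeric matrix (the phantom) with attribute `"hot_mask"`, the
#'   logical matrix of hot pixels.
#' @examples
#' x <- make_phantom(hot_value = 1099, background_value = 0)
#' mean(x[attr(x, "hot_mask")])
#' @export
make_phantom <- function(geometry = "reference", hot_value,
                         background_value = 0) {
  if (is.character(geometry)) {
    if (!geometry %in% c("reference", "paper1", "paper2"))
      stop("unknown phantom geometry: ", geometry, call. = FALSE)
    geometry <- reference_geometry()
  }
  if (!is.numeric(hot_value) || !is.numeric(background_value) ||
      hot_value < background_value || background_value < 0)
    stop("need hot_value >= background_value >= 0", call. = FALSE)
  mask <- hot_mask_from_geometry(geometry)
  x <- matrix(background_value, geometry$rows, geometry$cols)
  x[mask] <- hot_value
  attr(x, "hot_mask") <- mask
  x
}

#' The two frozen study phantoms
#'
#' Phantom 1 is the hard-edge case (hot 1099 on background 0); phantom 2
#' starts from base values 400 (hot) / 75 (background) and is smoothed with
#' a Gaussian kernel (`kernel_sd` = 1.5 px) so that its edges are soft.
#'
#' @param which 1 (hard-edge) or 2 (smoothed).
#' @param kernel_sd Bandwidth of the smoothing kernel for phantom 2.
#' @return A numeric matrix with a `"hot_mask"` attribute (for phantom 2 the
#'   mask of the unsmoothed base phantom).
#' @export
reference_phantom <- function(which = 1, kernel_sd = 1.5) {
  which <- match.arg(as.character(which), c("1", "2"))
  if (which == "1") return(make_phantom("reference", 1099, 0))
  base <- make_phantom("reference", 400, 75)
  out <- smooth_phantom(base, kernel_sd)
  attr(out, "hot_mask") <- attr(base, "hot_mask")
  out
}

gaussian_kernel_1d <- function(kernel_sd, radius = ceiling(3 * kernel_sd)) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * kernel_sd^2))
  k / sum(k)
}

#' 2-D Gaussian kernel on a truncated stencil
#'
#' Sampled at integer offsets on a (2r+1) x (2r+1) stencil with
#' r = `ceiling(3 * kernel_sd)` and normalised to sum to one.
#' @param kernel_sd Kernel standard deviation in pixels (> 0).
#' @param radius Stencil radius; defaults to 3 standard deviations.
#' @return A numeric matrix summing to 1.
#' @export
gaussian_kernel_2d <- function(kernel_sd, radius = ceiling(3 * kernel_sd)) {
  if (kernel_sd <= 0) stop("kernel_sd must be > 0", call. = FALSE)
  k1 <- gaussian_kernel_1d(kernel_sd, radius)
  outer(k1, k1)
}

# 1-D convolution along dim 1 of a matrix, with reflect or truncate boundary.
conv_cols_1d <- function(x, k1, boundary) {
  radius <- (length(k1) - 1L) / 2L
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (off in seq(-radius, radius)) {
    w <- k1[off + radius + 1L]
    src <- seq_len(n) + off
    if (boundary == "reflect") {
      # reflect without repeating the border pixel (2 - i for i < 1)
      src <- ifelse(src < 1L, 2L - src, src)
      src <- ifelse(src > n, 2L * n - src, src)
      out <- out + w * x[src, , drop = FALSE]
    } else {
      keep <- src >= 1L & src <= n
      out[keep, ] <- out[keep, ] + w * x[src[keep], , drop = FALSE]
    }
  }
  out
}

#' Smooth an image with a normalised Gaussian kernel
#'
#' Separable 2-D Gaussian convolution.  With the default `"reflect"`
#' boundary the global pixel sum is (approximately) conserved; with
#' `"truncate"` the kernel mass falling off-grid is dropped, matching the
#' boundary policy of [psf_system_matrix()].
#'
#' @param grid Numeric matrix (nonnegative image).
#' @param kernel_sd Kernel standard deviation in pixels (> 0).
#' @param boundary `"reflect"` (default) or `"truncate"`.
#' @return The smoothed matrix.
#' @export
smooth_phantom <- function(grid, kernel_sd, boundary = c("reflect", "truncate")) {
  boundary <- match.arg(boundary)
  if (kernel_sd <= 0) stop("kernel_sd must be > 0", call. = FALSE)
  k1 <- gaussian_kernel_1d(kernel_sd)
  out <- conv_cols_1d(unclass_image(grid), k1, boundary)
  out <- t(conv_cols_1d(t(out), k1, boundary))
  out
}

#' Strip phantom attributes from an image
#'
#' Returns the plain numeric matrix underlying a phantom, dropping the
#' `"hot_mask"` attribute.
#'
#' @param x Numeric matrix, possibly with phantom attributes.
#' @return A plain numeric matrix.
#' @export
unclass_image <- function(x) {
  x <- as.matrix(x)
  attr(x, "hot_mask") <- NULL
  x
}

#' Maximum absolute first-order neighbour difference per pixel
#'
#' For each pixel, the largest absolute difference to any of its 4-connected
#' neighbours (up, down, left, right, clipped at the borders).
#'
#' @param x Numeric matrix.
#' @return A numeric matrix of the same shape.
#' @export
neighbour_max_diff <- function(x) {
  x <- unclass_image(x)
  r <- nrow(x); c <- ncol(x)
  d <- matrix(0, r, c)
  if (r > 1) {
    dv <- abs(x[-1, , drop = FALSE] - x[-r, , drop = FALSE])
    d[-r, ] <- pmax(d[-r, ], dv)
    d[-1, ] <- pmax(d[-1, ], dv)
  }
  if (c > 1) {
    dh <- abs(x[, -1, drop = FALSE] - x[, -c, drop = FALSE])
    d[, -c] <- pmax(d[, -c], dh)
    d[, -1] <- pmax(d[, -1], dh)
  }
  d
}

# The eight fixed RoI windows (row1, row2, col1, col2), identical for both
# study phantoms.  1,2: hot-region high-contrast edges; 3,4: hot interiors;
# 5,6: smooth background; 7,8: background-side high-contrast edges.
roi_windows <- function() {
  w <- rbind(
    c(11, 17, 31, 34),
    c( 9, 11,  9, 19),
    c(11, 17, 37, 43),
    c(19, 23, 11, 17),
    c( 2,  6, 24, 30),
    c(24, 28, 30, 36),
    c(11, 17, 49, 52),
    c(17, 25,  7,  9)
  )
  colnames(w) <- c("row1", "row2", "col1", "col2")
  w
}

#' Regions of interest and smooth/high-contrast pixel classification
#'
#' Classifies pixels of a ground-truth image by their maximum absolute
#' first-order neighbour difference — below `smooth_thresh` they are
#' "smooth", above `contrast_thresh` they are "high-contrast" — and labels
#' the eight fixed evaluation sub-windows used for localized error
#' assessment.  Window positions are identical for both study phantoms.
#'
#' @param truth Numeric matrix (a phantom).
#' @param smooth_thresh Upper bound on neighbour variation for a pixel to
#'   count as smooth (default 50).
#' @param contrast_thresh Lower bound for a pixel to count as
#'   high-contrast (default 500).
#' @return An object of class `"roi_set"`: a list with integer matrix
#'   `labels` (0 = unlabeled, 1-8 = window id), logical matrices `smooth`,
#'   `contrast` and `global`, and the `windows` table.
#' @export
make_roi_masks <- function(truth, smooth_thresh = 50, contrast_thresh = 500) {
  if (smooth_thresh <= 0 || contrast_thresh <= 0 ||
      smooth_thresh >= contrast_thresh)
    stop("need 0 < smooth_thresh < contrast_thresh", call. = FALSE)
  truth <- unclass_image(truth)
  d <- neighbour_max_diff(truth)
  labels <- matrix(0L, nrow(truth), ncol(truth))
  w <- roi_windows()
  for (k in seq_len(nrow(w))) {
    if (w[k, 2] > nrow(truth) || w[k, 4] > ncol(truth))
      stop("RoI window exceeds grid bounds", call. = FALSE)
    labels[w[k, 1]:w[k, 2], w[k, 3]:w[k, 4]] <- k
  }
  structure(
    list(labels = labels,
         smooth = d < smooth_thresh,
         contrast = d > contrast_thresh,
         global = matrix(TRUE, nrow(truth), ncol(truth)),
         windows = w),
    class = "roi_set")
}

#' Mouse-like assessment phantom
#'
#' A synthetic small-animal planar phantom: an elongated body ellipse on a
#' low background with three hot organ-like foci (29 x 58 grid).  Used to
#' exercise the latent-label classification against a k-means baseline;
#' it is not derived from any acquired scan.
#'
#' @return A numeric matrix with a `"hot_mask"` attribute marking the foci.
#' @export
make_mouse_phantom <- function() {
  rows <- 29L; cols <- 58L
  rc <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  x <- matrix(5, rows, cols)
  body <- ((rc$row - 15) / 10)^2 + ((rc$col - 29) / 24)^2 <= 1
  x[body] <- 60
  foci <- matrix(FALSE, rows, cols)
  add_focus <- function(center, radius) {
    (rc$row - center[1])^2 + (rc$col - center[2])^2 <= radius^2
  }
  foci[add_focus(c(10, 14), 3)] <- TRUE
  foci[add_focus(c(16, 30), 4)] <- TRUE
  foci[add_focus(c(18, 44), 3)] <- TRUE
  x[foci] <- 400
  attr(x, "hot_mask") <- foci
  x
}
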