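#' Row-major flattening of an image
#'
#' Images are stored as `rows x cols` matrices; vectors aligned to the
#' system matrix use row-major pixel order (pixel j = (r-1)*cols + c).
#'
#' @param x Numeric matrix.
#' @return Numeric vector of length `rows * cols`.
#' @export
as_pixel_vector <- function(x) {
  as.vector(t(unclass_image(x)))
}

#' Reshape a row-major pixel vector back to an image
#' @param v Numeric vector of length `rows * cols`.
#' @param rows,cols Grid dimensions.
#' @return Numeric matrix.
#' @export
as_image <- function(v, rows, cols) {
  if (length(v) != rows * cols) stop("length(v) != rows*cols", call. = FALSE)
  matrix(v, rows, cols, byrow = TRUE)
}

#' Point-spread-function system matrix
#'
#' Builds the sparse `n x m` system matrix `A` (here `n = m = rows*cols`)
#' whose row i holds a normalised Gaussian kernel centred at pixel i, in
#' row-major pixel order.  The kernel is normalised on its full truncated
#' stencil before off-grid entries are dropped, so interior rows sum to 1
#' and rows near the border sum to less than 1 (counts falling off the
#' detector are lost).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param kernel_sd PSF standard deviation in pixels (> 0).
#' @param radius Stencil truncation radius (default 3 standard deviations).
#' @return A [Matrix::sparseMatrix()] (`dgCMatrix`) of size `m x m`.
#' @export
psf_system_matrix <- function(rows, cols, kernel_sd,
                              radius = ceiling(3 * kernel_sd)) {
  if (rows < 1 || cols < 1) stop("rows, cols must be >= 1", call. = FALSE)
  if (kernel_sd <= 0) stop("kernel_sd must be > 0", call. = FALSE)
  m <- rows * cols
  k <- gaussian_kernel_2d(kernel_sd, radius)
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))  # row-major order
  ii <- jj <- xx <- vector("list", (2 * radius + 1)^2)
  idx <- 1L
  for (dr in seq(-radius, radius)) {
    for (dc in seq(-radius, radius)) {
      w <- k[dr + radius + 1L, dc + radius + 1L]
      if (w <= 0) next
      r2 <- rc$row + dr; c2 <- rc$col + dc
      keep <- r2 >= 1L & r2 <= rows & c2 >= 1L & c2 <= cols
      if (!any(keep)) next
      i <- which(keep)                       # detector row = centre pixel
      j <- (r2[keep] - 1L) * cols + c2[keep] # source pixel, row-major
      ii[[idx]] <- i; jj[[idx]] <- j; xx[[idx]] <- rep(w, length(i))
      idx <- idx + 1L
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(m, m))
}

#' Forward projection
#'
#' Expected counts `lambda_i = sum_j a_ij x_j` for image `x` under system
#' matrix `A`.
#'
#' @param A System matrix (`n x m`), dense or sparse.
#' @param x Image matrix (flattened row-major) or a length-`m` vector.
#' @return Numeric vector of expected counts (length `n`).
#' @export
project <- function(A, x) {
  v <- if (is.matrix(x)) as_pixel_vector(x) else as.numeric(x)
  if (ncol(A) != length(v))
    stop("dimension mismatch: ncol(A) != number of pixels", call. = FALSE)
  if (any(v < 0)) stop("image values must be nonnegative", call. = FALSE)
  as.numeric(A %*% v)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a Poisson count observation
#'
#' Independent Poisson draws with means `lambda`; with a fixed `seed` the
#' draw is reproducible and the caller's RNG state is left untouched.
#'
#' @param lambda Nonnegative expected-count vector.
#' @param seed Optional integer seed.
#' @return Integer vector of counts, same length as `lambda`.
#' @export
sample_observation <- function(lambda, seed = NULL) {
  if (any(lambda < 0)) stop("lambda must be nonnegative", call. = FALSE)
  with_seed_(seed, as.integer(stats::rpois(length(lambda), lambda)))
}

#' Simulate a degraded observation of a phantom
#'
#' Convenience wrapper: blur `truth` through the PSF system matrix and add
#' Poisson counting noise.
#'
#' @param truth Phantom matrix.
#' @param kernel_sd PSF standard deviation (default 1 px, the package's
#'   reference detector blur).
#' @param seed Optional integer seed.
#' @param A Optional pre-built system matrix (overrides `kernel_sd`).
#' @return A list with elements `y` (integer counts, length m), `A`
#'   (system matrix), `lambda` (expected counts), `rows`, `cols`.
#' @export
simulate_observation <- function(truth, kernel_sd = 1, seed = NULL, A = NULL) {
  truth <- unclass_image(truth)
  if (is.null(A)) A <- psf_system_matrix(nrow(truth), ncol(truth), kernel_sd)
  lambda <- project(A, truth)
  list(y = sample_observation(lambda, seed), A = A, lambda = lambda,
       rows = nrow(truth), cols = ncol(truth))
}
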