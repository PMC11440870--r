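#' Write a numeric image matrix to disk
#'
#' CSV (comma-separated numeric grid, the canonical human-diffable
#' interchange), 16-bit single-page TIFF, or plain-text PGM (P2, integer
#' images only); the format follows the file extension.
#'
#' @param x Numeric matrix.
#' @param path Output path ending in `.csv`, `.tif`/`.tiff` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  x <- unclass_image(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(x, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output", call. = FALSE)
    if (any(x < 0) || any(x > 65535))
      stop("TIFF output needs values in [0, 65535]", call. = FALSE)
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  } else if (ext == "pgm") {
    if (any(x < 0) || any(x != round(x)))
      stop("PGM output needs nonnegative integers", call. = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", paste(ncol(x), nrow(x)), format(max(x, 1))), con)
    utils::write.table(x, con, sep = " ", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported matrix format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read a numeric image matrix from disk
#'
#' Counterpart of [write_matrix()].  Integer grids round-trip losslessly
#' through every format; CSV keeps floats at full printed precision.
#'
#' @param path Input path (`.csv`, `.tif`/`.tiff`, `.pgm`).
#' @param type `"image"` (nonnegative reals) or `"counts"` (nonnegative
#'   integers; violations are reported with their position).
#' @return Numeric matrix.
#' @export
read_matrix <- function(path, type = c("image", "counts")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    lines <- readLines(path)
    fields <- strsplit(lines, ",", fixed = TRUE)
    len <- lengths(fields)
    if (length(unique(len)) != 1)
      stop("ragged CSV: row ", which(len != len[1])[1], " has ",
           len[which(len != len[1])[1]], " fields, expected ", len[1],
           call. = FALSE)
    x <- matrix(as.numeric(unlist(fields)), nrow = length(lines),
                byrow = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input", call. = FALSE)
    x <- round(tiff::readTIFF(path) * 65535)
  } else if (ext == "pgm") {
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (toks[1] != "P2") stop("only plain (P2) PGM supported", call. = FALSE)
    dims <- as.integer(toks[2:3])  # width height
    vals <- as.numeric(toks[-(1:4)])
    x <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  } else stop("unsupported matrix format: .", ext, call. = FALSE)
  if (anyNA(x)) stop("non-numeric entries in ", path, call. = FALSE)
  if (type == "counts") {
    bad <- which(x < 0 | x != round(x), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("count matrix has a non-count value at row ", bad[1, 1],
           ", column ", bad[1, 2], call. = FALSE)
    storage.mode(x) <- "integer"
  }
  x
}

#' Write a sparse system matrix as text triplets
#'
#' Plain-text coordinate format: a header line `n m nnz` followed by one
#' `i j value` triplet per line (1-based indices).
#'
#' @param A Sparse (or dense) matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparse_matrix <- function(A, path) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::summary(A)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(nrow(A), ncol(A), nrow(tr)), con)
  utils::write.table(data.frame(tr$i, tr$j, tr$x), con, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sparse system matrix from text triplets
#' @param path Input path in the format of [write_sparse_matrix()].
#' @return A `dgCMatrix`.
#' @export
read_sparse_matrix <- function(path) {
  hdr <- scan(path, what = integer(), n = 3, quiet = TRUE)
  tr <- utils::read.table(path, skip = 1,
                          col.names = c("i", "j", "x"))
  if (any(tr$x < 0)) stop("system matrix entries must be >= 0", call. = FALSE)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(hdr[1], hdr[2]))
}

#' Write a chain to a plain-text archive directory
#'
#' Columnar on-disk layout: `config.yaml` (model, dimensions, seed and the
#' full sampler configuration — enough to regenerate the run), `traces.csv`
#' (per-iteration parameter and acceptance traces), `x_mean.csv`, and for
#' mixture chains `theta_freq.csv`.  Stored image/label samples are *not*
#' archived; rerun with the embedded config and seed to recover them.
#'
#' @param chain An `"mrf_chain"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "mrf_chain"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for chain archives", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- chain$config
  meta <- list(model = chain$model, mixture = chain$mixture,
               rows = chain$rows, cols = chain$cols,
               seed = if (is.null(chain$seed)) NA else chain$seed,
               estimate_tau = isTRUE(chain$estimate_tau),
               config = cfg[setdiff(names(cfg), "seed")],
               version = as.character(utils::packageVersion("mrfmix")))
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  tr <- if (chain$mixture)
    data.frame(iteration = seq_along(chain$tau_l), tau_l = chain$tau_l,
               tau_g = chain$tau_g, rho = chain$rho,
               accept_pixel = chain$accept_pixel, sd_pixel = chain$sd_pixel)
  else
    data.frame(iteration = seq_along(chain$tau), tau = chain$tau,
               accept_pixel = chain$accept_pixel,
               accept_tau = chain$accept_tau, sd_pixel = chain$sd_pixel,
               sd_tau = chain$sd_tau)
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  write_matrix(posterior_mean_image(chain), file.path(dir, "x_mean.csv"))
  if (chain$mixture)
    write_matrix(as_image(chain$theta_freq, chain$rows, chain$cols),
                 file.path(dir, "theta_freq.csv"))
  invisible(dir)
}

#' Read a chain archive written by [write_chain()]
#'
#' Restores the traces and posterior summaries (not the raw image
#' samples).
#'
#' @param dir Archive directory.
#' @return An `"mrf_chain"` (with `x_samples = NULL`).
#' @export
read_chain <- function(dir) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for chain archives", call. = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  tr <- utils::read.csv(file.path(dir, "traces.csv"))
  cfg <- do.call(mcmc_config, c(meta$config,
                                list(seed = if (is.na(meta$seed)) NULL
                                            else meta$seed)))
  xm <- read_matrix(file.path(dir, "x_mean.csv"))
  out <- list(model = meta$model, mixture = meta$mixture,
              estimate_tau = meta$estimate_tau,
              rows = meta$rows, cols = meta$cols, config = cfg,
              seed = cfg$seed, x_mean = as_pixel_vector(xm),
              accept_pixel = tr$accept_pixel, sd_pixel = tr$sd_pixel,
              x_samples = NULL, kept_iterations = NULL, restored = TRUE)
  if (meta$mixture) {
    out$tau_l <- tr$tau_l; out$tau_g <- tr$tau_g; out$rho <- tr$rho
    out$theta_freq <- as_pixel_vector(
      read_matrix(file.path(dir, "theta_freq.csv")))
  } else {
    out$tau <- tr$tau; out$accept_tau <- tr$accept_tau; out$sd_tau <- tr$sd_tau
  }
  structure(out, class = "mrf_chain")
}

#' Read a run configuration file
#'
#' YAML key-value run description: phantom spec, forward-model spec
#' (`psf_sd` or `matrix_path`), model choice, scale handling, sampler
#' settings, output directory and seed.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"` with validated fields.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$phantom <- cfg$phantom %||% "paper1"
  cfg$model <- cfg$model %||% "laplace"
  if (!cfg$model %in% c("laplace", "gaussian", "mixture"))
    stop("model must be laplace, gaussian or mixture", call. = FALSE)
  cfg$psf_sd <- cfg$psf_sd %||% 1
  if (!is.null(cfg$tau_grid) && length(cfg$tau_grid) < 1)
    stop("sweep requires a non-empty tau_grid", call. = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
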