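# Shared I/O: trajectory CSV, parameter/report JSON, kymograph CSV and
# mask movies. Units are explicit everywhere: positions um, times s.

#' Write / read trajectory CSV
#'
#' The standard trajectory format: one row per sample, columns `cell_id`,
#' `t_s`, `x_um`, `y_um`. On reading, the sampling interval is inferred
#' and validated as uniform.
#'
#' @param traj trajectory data frame
#' @param path CSV path
#' @return `read_trajectories` returns the data frame with attribute
#'   `delta_t`.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj[, c("cell_id", "t_s", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  traj <- utils::read.csv(path)
  need <- c("cell_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(traj)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  attr(traj, "delta_t") <- traj_delta_t(traj)
  traj
}

#' Write / read GLE parameter JSON
#'
#' Parameter sets and fit reports as JSON with keys `alpha`, `beta`,
#' `gamma`, `sigma`, `sigma_x` plus the derived eigen-structure
#' (`lambda_plus`, `lambda_minus`, `phi_plus`, `phi_minus`) and, when
#' available, `mse`.
#'
#' @param params a [gle_params] object
#' @param path JSON path
#' @export
write_gle_params <- function(params, path) {
  eig <- gle_eigen(params)
  obj <- c(params[c("alpha", "beta", "gamma", "sigma")],
           list(sigma_x = params$sigma_x,
                lambda_plus = eig$lambda_plus,
                lambda_minus = eig$lambda_minus,
                phi_plus = eig$phi_plus, phi_minus = eig$phi_minus))
  if (!is.null(attr(params, "mse"))) obj$mse <- attr(params, "mse")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gle_params
#' @export
read_gle_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  gle_params(o$alpha, o$beta, o$gamma, o$sigma,
             if (is.null(o$sigma_x)) 0 else o$sigma_x)
}

#' Write a kymograph matrix as CSV
#'
#' Rows are boundary indices 1..n, columns are frames.
#'
#' @param mat numeric matrix
#' @param path CSV path
#' @export
write_kymograph <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) as.matrix(utils::read.csv(path))

#' Write / read a binary mask movie as multi-page TIFF
#'
#' Requires the `tiff` package. Masks are stored as 0/1 single-channel
#' pages.
#'
#' @param masks list of logical matrices
#' @param path TIFF path
#' @export
write_mask_movie <- function(masks, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  tiff::writeTIFF(lapply(masks, function(m) {
    storage.mode(m) <- "double"
    m
  }), path)
  invisible(path)
}

#' @rdname write_mask_movie
#' @export
read_mask_movie <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p > 0.5
  })
}
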