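# Elliptic Fourier shape descriptors, power-spectrum PCA and
# deformation-velocity mode coupling.

#' Elliptic Fourier descriptor of a cell mask
#'
#' Traces the boundary pixel chain of the mask, samples 160 equally spaced
#' points along it, rescales by the factor `3000 * A / (160 * L)` (A = mask
#' pixel count, L = chain length in px), removes the 160-point mean so the
#' origin sits at the contour centroid, and takes the discrete Fourier
#' transform of the complex coordinates `z = x + iy`:
#' \deqn{\tilde q_k = \sum_{i=0}^{159} e^{-2\pi i k j/160} \hat q_j,
#'       \qquad S_k = |\tilde q_k|^2.}
#' Signed modes use the convention `C_n = qtilde_n` (n >= 1) and
#' `C_{-n} = qtilde_{160-n}`.
#'
#' @param mask binary matrix, single foreground component
#' @param n_points number of contour samples (default 160)
#' @param rescale `"printed"` for the `3000 A / (160 L)` factor, `"unit"`
#'   to normalize the contour scale out entirely (divide by `L`)
#' @return An object of class `shape_spectrum`: list with `q_hat` (complex
#'   contour samples, centred), `q_tilde` (complex DFT), `S` (power
#'   spectrum, length `n_points`), `L` (chain length, px), `A` (pixel
#'   count), `n_points`.
#' @export
elliptic_fourier <- function(mask, n_points = 160,
                             rescale = c("printed", "unit")) {
  rescale <- match.arg(rescale)
  check_single_component(mask)
  chain <- extract_contour(mask)
  L <- polygon_length(chain)
  A <- sum(mask != 0)
  pts <- resample_closed(chain, n_points)
  fac <- if (rescale == "printed") 3000 * A / (n_points * L) else 1 / L
  z <- complex(real = pts[, 1], imaginary = pts[, 2]) * fac
  z <- z - mean(z)
  q_tilde <- fft(z)
  structure(list(q_hat = z, q_tilde = q_tilde, S = Mod(q_tilde)^2,
                 L = L, A = A, n_points = n_points),
            class = "shape_spectrum")
}

#' Signed Fourier mode of a shape spectrum
#'
#' @param spectrum a [elliptic_fourier()] result
#' @param n signed mode index (nonzero integer; negative n maps to
#'   `q_tilde[n_points - |n|]`)
#' @return Complex mode amplitude `C_n`.
#' @export
shape_mode <- function(spectrum, n) {
  stopifnot(inherits(spectrum, "shape_spectrum"), n != 0)
  np <- spectrum$n_points
  k <- if (n > 0) n else np + n
  spectrum$q_tilde[k + 1]
}

#' Principal component analysis of shape power spectra
#'
#' Computes the mean spectrum, the (unbiased) covariance matrix of the
#' power-spectrum vectors, and its eigen-decomposition with eigenvalues in
#' descending order. Each eigenvector's sign is fixed so that its
#' largest-magnitude loading is positive. The fitted mean and basis are
#' intended to be frozen and applied to all subsequent data.
#'
#' @param spectra list of [elliptic_fourier()] objects, or a matrix with
#'   one spectrum per row
#' @return An object of class `spectrum_pca`: list with `mean`
#'   (`S_bar`), `values` (eigenvalues), `vectors` (columns = eigenvectors),
#'   `n_points`.
#' @export
fit_spectrum_pca <- function(spectra) {
  S <- if (is.matrix(spectra)) spectra
  else do.call(rbind, lapply(spectra, function(s) s$S))
  if (nrow(S) < 2) stop("need at least 2 spectra", call. = FALSE)
  if (nrow(S) <= ncol(S))
    warning("fewer spectra than spectrum dimensions: rank-deficient PCA")
  S_bar <- colMeans(S)
  eta <- cov(S)
  eg <- eigen(eta, symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = S_bar, values = pmax(eg$values, 0), vectors = V,
                 n_points = ncol(S)),
            class = "spectrum_pca")
}

#' Project spectra onto fitted principal components
#'
#' Scores are `PC_m = (S - S_bar) . e_m`.
#'
#' @param spectra a `shape_spectrum`, a list of them, or a spectrum matrix
#' @param pca a [fit_spectrum_pca()] result
#' @param n_components number of scores to return (default: all)
#' @return A matrix of scores (rows = shapes, columns = `PC1`, `PC2`, ...).
#' @export
project_spectra <- function(spectra, pca, n_components = NULL) {
  stopifnot(inherits(pca, "spectrum_pca"))
  S <- if (inherits(spectra, "shape_spectrum")) matrix(spectra$S, nrow = 1)
  else if (is.matrix(spectra)) spectra
  else do.call(rbind, lapply(spectra, function(s) s$S))
  if (is.null(n_components)) n_components <- ncol(pca$vectors)
  sc <- sweep(S, 2, pca$mean) %*% pca$vectors[, seq_len(n_components),
                                              drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(n_components))
  sc
}

#' Reconstruct a power spectrum and zero-phase contour from scores
#'
#' Rebuilds `S = S_bar + sum_m PC_m e_m` (negative entries clipped to zero
#' with a warning), then the zero-phase contour
#' `q_hat_j = (1/160) sum_k a_k e^{2 pi i k j / 160}` with real amplitudes
#' `a_k = S_k` (`amplitude = "power"`, the printed convention) or
#' `a_k = sqrt(S_k)` (`amplitude = "sqrt"`, which makes the contour's own
#' power spectrum equal `S`). Optionally rasterizes the rounded contour
#' pixels into a boundary image.
#'
#' @param scores numeric score vector (length <= number of eigenvectors)
#' @param pca a [fit_spectrum_pca()] result
#' @param amplitude `"power"` or `"sqrt"`
#' @param as_image if `TRUE`, also return a logical matrix marking the
#'   rounded contour pixels
#' @return List with `S`, `contour` (complex), and optionally `image`.
#' @export
reconstruct_shape <- function(scores, pca, amplitude = c("power", "sqrt"),
                              as_image = FALSE) {
  amplitude <- match.arg(amplitude)
  stopifnot(inherits(pca, "spectrum_pca"))
  m <- length(scores)
  S <- pca$mean + as.numeric(pca$vectors[, seq_len(m), drop = FALSE] %*%
                               scores)
  if (any(S < 0)) {
    warning("negative reconstructed spectrum entries clipped to 0")
    S <- pmax(S, 0)
  }
  a <- if (amplitude == "power") S else sqrt(S)
  contour <- fft(as.complex(a), inverse = TRUE) / length(a)
  out <- list(S = S, contour = contour)
  if (as_image) {
    px <- round(cbind(Re(contour), Im(contour)))
    px <- sweep(px, 2, apply(px, 2, min) - 1L)
    img <- matrix(FALSE, max(px[, 2]) + 1L, max(px[, 1]) + 1L)
    img[cbind(px[, 2], px[, 1])] <- TRUE
    out$image <- img
  }
  out
}

#' Autocorrelation of PC1/PC2 score time series
#'
#' The symmetric average
#' `AC(m dt) = 1/2 < PC1~(t_n) PC1~(t_{n+m}) + PC2~(t_n) PC2~(t_{n+m}) >`
#' over all cells and start times, where the tilde marks per-cell mean
#' centering.
#'
#' @param scores data frame with columns `cell_id`, `t_s`, `PC1`, `PC2`
#'   sampled uniformly
#' @param max_lag maximum lag in steps
#' @return Data frame: `lag` (s), `ac`.
#' @export
pc_autocorrelation <- function(scores, max_lag = 50) {
  cells <- split(scores, scores$cell_id)
  dt <- diff(cells[[1]]$t_s[1:2])
  n_min <- min(vapply(cells, nrow, integer(1)))
  max_lag <- min(max_lag, n_min - 1)
  s1 <- numeric(max_lag + 1); cnt <- numeric(max_lag + 1)
  for (d in cells) {
    p1 <- d$PC1 - mean(d$PC1)
    p2 <- d$PC2 - mean(d$PC2)
    n <- nrow(d)
    for (m in 0:min(max_lag, n - 1)) {
      i <- seq_len(n - m)
      s1[m + 1] <- s1[m + 1] +
        sum(p1[i] * p1[i + m] + p2[i] * p2[i + m]) / 2
      cnt[m + 1] <- cnt[m + 1] + (n - m)
    }
  }
  data.frame(lag = (0:max_lag) * dt, ac = s1 / cnt)
}

#' Autocorrelation and decay time of a complex mode series
#'
#' Normalized autocorrelation
#' `AC(tau) = Re < C(t) conj(C(t + tau)) > / < |C(t) - <C>|^2 >` after mean
#' removal, with an exponential-decay time fitted by log-linear least
#' squares over the positive initial segment. A non-decaying series
#' (rotating phasor) is flagged with an infinite decay time.
#'
#' @param z complex series, uniformly sampled
#' @param delta_t sampling interval, s
#' @param max_lag maximum lag in steps
#' @return List with `ac` (data frame `lag`, `ac`) and `decay_time` (s;
#'   `Inf` when the autocorrelation does not decay).
#' @export
mode_autocorrelation <- function(z, delta_t = 1, max_lag = 50) {
  z <- z - mean(z)
  n <- length(z)
  max_lag <- min(max_lag, n - 1)
  acz <- vapply(0:max_lag, function(m) {
    i <- seq_len(n - m)
    mean(z[i] * Conj(z[i + m]))
  }, complex(1))
  ac0 <- Re(acz[1])
  acn <- Re(acz) / ac0
  mod <- Mod(acz) / ac0
  # a rotating phasor keeps |AC| ~ 1: flagged as non-decaying
  if (all(mod > 0.9)) {
    decay <- Inf
  } else {
    # log-linear fit of |AC| over the initial decay (down to 0.1),
    # excluding lag 0 and the noise-dominated tail
    keep <- which(cumsum(mod < 0.1) == 0)
    keep <- keep[keep > 1]
    if (length(keep) < 2) {
      # correlation gone within one lag: decay from the first step alone
      decay <- -delta_t / log(max(mod[2], 1e-12))
    } else {
      lagv <- (keep - 1) * delta_t
      decay <- -1 / unname(coef(lm(log(mod[keep]) ~ lagv))[2])
    }
  }
  list(ac = data.frame(lag = (0:max_lag) * delta_t, ac = acn, mod = mod),
       decay_time = decay)
}

#' Deformation-velocity mode coupling
#'
#' Computes the coupling `C_nm(t) = Cdot_{-n} C_m - C_{-n} Cdot_m`
#' (forward differences at the sampling interval) for mode indices with
#' `-n + m = 1`, and relates it to the centroid velocity: the circular
#' correlation between `arg(C_nm)` and the velocity angle, and linear
#' proportionality fits of `Re(C_nm) -> v_x` and `Im(C_nm) -> v_y`
#' (no intercept).
#'
#' @param c_minus_n complex series of mode `C_{-n}`
#' @param c_m complex series of mode `C_m` (same time base)
#' @param vx,vy centroid velocity components aligned with the series
#'   (length >= length(c_m) - 1; extra entries are ignored)
#' @param delta_t sampling interval, s
#' @param floor_frac couplings with `|C_nm|` below this fraction of the
#'   maximum are excluded from the angle statistics
#' @return List with `coupling` (complex, length n-1), `circular_cor`,
#'   `slope_x`, `slope_y`, and `n_used`.
#' @export
deformation_velocity_coupling <- function(c_minus_n, c_m, vx, vy,
                                          delta_t = 1, floor_frac = 1e-8) {
  n <- length(c_m)
  stopifnot(length(c_minus_n) == n, n >= 2)
  d_mn <- diff(c_minus_n) / delta_t
  d_m <- diff(c_m) / delta_t
  i <- seq_len(n - 1)
  cpl <- d_mn * c_m[i] - c_minus_n[i] * d_m
  vx <- vx[i]; vy <- vy[i]
  amp <- Mod(cpl)
  if (all(amp < .Machine$double.eps)) {
    return(list(coupling = cpl, circular_cor = NA_real_,
                slope_x = NA_real_, slope_y = NA_real_, n_used = 0L,
                degenerate = TRUE))
  }
  ok <- amp >= floor_frac * max(amp) & is.finite(vx) & is.finite(vy)
  ang_c <- Arg(cpl[ok])
  ang_v <- atan2(vy[ok], vx[ok])
  # Fisher-Lee circular correlation
  circ_cor <- {
    a <- ang_c - mean_circular(ang_c)
    b <- ang_v - mean_circular(ang_v)
    sum(sin(a) * sin(b)) / sqrt(sum(sin(a)^2) * sum(sin(b)^2))
  }
  sx <- sum(Re(cpl[ok]) * vx[ok]) / sum(Re(cpl[ok])^2)
  sy <- sum(Im(cpl[ok]) * vy[ok]) / sum(Im(cpl[ok])^2)
  list(coupling = cpl, circular_cor = circ_cor, slope_x = sx,
       slope_y = sy, n_used = sum(ok), degenerate = FALSE)
}

mean_circular <- function(a) Arg(mean(complex(argument = a)))

#' Identify the elongation-dominated principal component
#'
#' Returns the index of the fitted eigenvector with the largest combined
#' absolute loading on the two fundamental traversal modes (wavenumbers
#' +1 and -1, i.e. spectrum entries `S_1` and `S_{n-1}`), whose power
#' ratio encodes the contour's aspect ratio. The returned component is
#' oriented so that its loading on the counter-rotating (elongation) mode
#' `S_{n-1}` is positive.
#'
#' @param pca a [fit_spectrum_pca()] result
#' @param n_candidates restrict the search to the first so-many components
#' @return List with `index` and `vector` (the oriented eigenvector).
#' @export
elongation_pc <- function(pca, n_candidates = 5) {
  stopifnot(inherits(pca, "spectrum_pca"))
  np <- pca$n_points
  cand <- seq_len(min(n_candidates, ncol(pca$vectors)))
  load <- abs(pca$vectors[2, cand]) + abs(pca$vectors[np, cand])
  j <- cand[which.max(load)]
  v <- pca$vectors[, j]
  if (v[np] < 0) v <- -v
  list(index = j, vector = v)
}
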