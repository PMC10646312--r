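#' Parameters of the generalized Langevin equation
#'
#' Container for the parameters of the velocity-memory Langevin model
#' \deqn{dv = (-\beta v + \alpha V)\,dt + \sigma\,dB, \qquad
#'       dV = (\alpha v - \gamma V)\,dt,}
#' where \eqn{v} is the 2D cell velocity and \eqn{V} an exponentially
#' weighted memory of past velocities. Sampled positions may additionally
#' carry i.i.d. Gaussian positional (measurement) noise of standard
#' deviation `sigma_x`.
#'
#' @param alpha memory-coupling rate, 1/s (> 0)
#' @param beta velocity decay rate, 1/s (> 0)
#' @param gamma memory decay rate, 1/s (> 0)
#' @param sigma noise strength, um s^-3/2 (> 0)
#' @param sigma_x positional-noise standard deviation, um (>= 0; 0 = absent)
#' @return An object of class `gle_params`.
#' @examples
#' p <- gle_params(0.0741, 0.116, 0.0641, 0.266)
#' gle_eigen(p)
#' @export
gle_params <- function(alpha, beta, gamma, sigma, sigma_x = 0) {
  for (nm in c("alpha", "beta", "gamma", "sigma", "sigma_x"))
    stopifnot_finite(get(nm), nm)
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta, gamma must be > 0", call. = FALSE)
  if (sigma < 0 || sigma_x < 0)
    stop("sigma and sigma_x must be >= 0", call. = FALSE)
  # stationarity: both drift eigenvalues positive, i.e. beta*gamma > alpha^2
  if (beta * gamma <= alpha^2)
    stop("non-stationary parameters: beta * gamma must exceed alpha^2",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 sigma = sigma, sigma_x = sigma_x),
            class = "gle_params")
}

#' @export
print.gle_params <- function(x, ...) {
  cat("GLE parameters:\n")
  cat(sprintf("  alpha = %.4g 1/s, beta = %.4g 1/s, gamma = %.4g 1/s\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  sigma = %.4g um s^-3/2, sigma_x = %.4g um\n",
              x$sigma, x$sigma_x))
  invisible(x)
}

#' Reference parameter sets for the GLE model
#'
#' The fitted parameter sets for *Naegleria gruberi* centroid motion, without
#' (`"gle"`) and with (`"gle_noise"`) the positional-uncertainty term.
#'
#' @param row `"gle"` or `"gle_noise"`
#' @return A [gle_params] object.
#' @export
gle_reference_params <- function(row = c("gle_noise", "gle")) {
  row <- match.arg(row)
  sx <- if (row == "gle_noise") 0.155 else 0
  gle_params(alpha = 0.0741, beta = 0.116, gamma = 0.0641,
             sigma = 0.266, sigma_x = sx)
}

#' Eigen-structure of the GLE drift matrix
#'
#' Decomposes the 2x2 drift matrix `C = [[beta, -alpha], [-alpha, gamma]]`
#' of the (v, V) system into its eigenvalues (the fast and slow VAC decay
#' rates) and computes the weights of the two exponential components of the
#' stationary velocity autocorrelation,
#' \deqn{\mathrm{vac}(\Delta t) = \phi_+ e^{-\lambda_+ \Delta t}
#'                              + \phi_- e^{-\lambda_- \Delta t}.}
#'
#' The closed forms are
#' \deqn{\lambda_\pm = \frac{\beta + \gamma \pm
#'   \sqrt{(\beta-\gamma)^2 + 4\alpha^2}}{2}, \qquad
#'   \phi_\pm = 2\sigma^2\left[\frac{e_{x,\pm}^4}{2\lambda_\pm} +
#'   \frac{e_{x,+}^2 e_{x,-}^2}{\lambda_+ + \lambda_-}\right],}
#' with \eqn{e_\pm = (\cos\theta_\pm, \sin\theta_\pm)} the unit eigenvectors,
#' \eqn{\tan\theta_\pm = (\beta-\gamma \mp \sqrt{(\beta-\gamma)^2+4\alpha^2})
#' / (2\alpha)}. Independent of `sigma_x`.
#'
#' @param params a [gle_params] object
#' @return A list of class `gle_eigen` with `lambda_plus`, `lambda_minus`,
#'   `phi_plus`, `phi_minus`, `theta_plus`, `theta_minus`, and unit
#'   eigenvectors `e_plus`, `e_minus`.
#' @export
gle_eigen <- function(params) {
  stopifnot(inherits(params, "gle_params"))
  a <- params$alpha; b <- params$beta; g <- params$gamma; s <- params$sigma
  disc <- sqrt((b - g)^2 + 4 * a^2)
  lp <- (b + g + disc) / 2
  lm <- (b + g - disc) / 2
  tp <- ((b - g) - disc) / (2 * a)
  tm <- ((b - g) + disc) / (2 * a)
  th_p <- atan(tp); th_m <- atan(tm)
  ep <- c(cos(th_p), sin(th_p))
  em <- c(cos(th_m), sin(th_m))
  exp2 <- ep[1]^2; exm2 <- em[1]^2
  cross <- exp2 * exm2 / (lp + lm)
  phi_p <- 2 * s^2 * (exp2^2 / (2 * lp) + cross)
  phi_m <- 2 * s^2 * (exm2^2 / (2 * lm) + cross)
  structure(list(lambda_plus = lp, lambda_minus = lm,
                 phi_plus = phi_p, phi_minus = phi_m,
                 theta_plus = th_p, theta_minus = th_m,
                 e_plus = ep, e_minus = em),
            class = "gle_eigen")
}

#' @export
print.gle_eigen <- function(x, ...) {
  cat(sprintf("GLE eigen-structure: 1/lambda+ = %.3g s, 1/lambda- = %.3g s\n",
              1 / x$lambda_plus, 1 / x$lambda_minus))
  cat(sprintf("  phi+ = %.4g, phi- = %.4g um^2/s^2\n", x$phi_plus, x$phi_minus))
  invisible(x)
}

# Sampling-window weight of one exponential mode of the continuous VAC.
# For velocities estimated as finite position differences over delta_t, the
# sampled-VAC contribution of a mode phi e^{-lambda |dt|} at integer lag m is
# phi * vac_window_factor(lambda, delta_t, m):
#   m >= 1: e^{-(m-1) lambda dt} (1 - e^{-lambda dt})^2 / (lambda dt)^2
#   m == 0: 2 (lambda dt - 1 + e^{-lambda dt}) / (lambda dt)^2
# (the m = 0 window straddles the kink of e^{-lambda |dt|}, hence the
# separate branch; both equal the exact double integral of the continuous
# VAC over the two sampling windows).
vac_window_factor <- function(lambda, delta_t, m) {
  ld <- lambda * delta_t
  ifelse(m == 0,
         2 * (ld - 1 + exp(-ld)) / ld^2,
         exp(-(m - 1) * ld) * (1 - exp(-ld))^2 / ld^2)
}

#' Analytic steady-state velocity autocorrelation of the GLE
#'
#' Exact sampled-velocity autocorrelation of the stationary GLE at integer
#' lags, i.e. the autocorrelation of velocities estimated as finite
#' differences of positions sampled every `delta_t`. When `params$sigma_x`
#' is positive, the positional-noise correction is applied: the value at lag
#' 0 gains `+2 sigma_x^2 / delta_t^2`, the value at lag 1 gains
#' `-sigma_x^2 / delta_t^2`, and lags >= 2 are unchanged.
#'
#' @param params a [gle_params] object
#' @param delta_t sampling interval, s
#' @param max_lag maximum integer lag (the curve is returned for lags
#'   `0:max_lag`)
#' @return A data frame with columns `lag` (s) and `vac` (um^2/s^2).
#' @export
analytic_vac <- function(params, delta_t = 1, max_lag = 100) {
  stopifnot(inherits(params, "gle_params"), delta_t > 0, max_lag >= 0)
  eig <- gle_eigen(params)
  m <- 0:max_lag
  v <- eig$phi_plus * vac_window_factor(eig$lambda_plus, delta_t, m) +
    eig$phi_minus * vac_window_factor(eig$lambda_minus, delta_t, m)
  if (params$sigma_x > 0) {
    corr <- params$sigma_x^2 / delta_t^2
    if (max_lag >= 0) v[1] <- v[1] + 2 * corr
    if (max_lag >= 1) v[2] <- v[2] - corr
  }
  data.frame(lag = m * delta_t, vac = v)
}

#' Simulate GLE trajectories
#'
#' Integrates the GLE with the Euler-Maruyama scheme at a fine internal time
#' step, accumulates the position as the time integral of the velocity,
#' samples positions at `sample_interval`, and adds i.i.d. Gaussian
#' positional noise of standard deviation `params$sigma_x` to every sampled
#' position. `(v, V)` start at rest and a burn-in of `10 / lambda_minus`
#' seconds (by default) is discarded so that recorded statistics are
#' stationary.
#'
#' @param params a [gle_params] object
#' @param n_traj number of independent trajectories
#' @param duration recorded duration per trajectory, s
#' @param dt_internal Euler-Maruyama step, s (default 0.002)
#' @param sample_interval sampling interval of recorded positions, s
#' @param seed optional integer seed (applied via [set.seed()]); identical
#'   seeds give bit-identical output
#' @param burn_in burn-in time discarded before recording, s; default
#'   `10 / lambda_minus`
#' @return A data frame with columns `cell_id`, `t_s`, `x_um`, `y_um` and
#'   attribute `delta_t = sample_interval`.
#' @examples
#' p <- gle_reference_params("gle")
#' tr <- simulate_gle(p, n_traj = 2, duration = 60, dt_internal = 0.01,
#'                    seed = 1)
#' head(tr)
#' @export
simulate_gle <- function(params, n_traj, duration, dt_internal = 0.002,
                         sample_interval = 1, seed = NULL, burn_in = NULL) {
  stopifnot(inherits(params, "gle_params"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt_internal) ||
      dt_internal <= 0)
    stop("duration and dt_internal must be positive", call. = FALSE)
  if (dt_internal > sample_interval)
    stop("dt_internal must not exceed sample_interval", call. = FALSE)
  if (duration < sample_interval)
    stop("duration must be at least one sample_interval", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- 10 / gle_eigen(params)$lambda_minus
  n_sub <- round(sample_interval / dt_internal)
  if (abs(n_sub * dt_internal - sample_interval) > 1e-9 * sample_interval)
    stop("sample_interval must be an integer multiple of dt_internal",
         call. = FALSE)
  n_samples <- floor(duration / sample_interval)
  burn_steps <- round(burn_in / dt_internal)

  out <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    pos <- gle_sim_positions(params$alpha, params$beta, params$gamma,
                             params$sigma, dt_internal, n_sub, n_samples,
                             burn_steps)
    if (params$sigma_x > 0)
      pos <- pos + params$sigma_x *
        matrix(rnorm(2 * nrow(pos)), ncol = 2)
    out[[i]] <- data.frame(cell_id = i,
                           t_s = seq(0, by = sample_interval,
                                     length.out = nrow(pos)),
                           x_um = pos[, 1], y_um = pos[, 2])
  }
  res <- do.call(rbind, out)
  attr(res, "delta_t") <- sample_interval
  res
}
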