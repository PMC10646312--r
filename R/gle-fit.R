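# Fitting the VAC: multi-exponential least squares and full GLE inversion.

#' Fit a sum of exponentials to a VAC curve
#'
#' Least-squares fit of \eqn{\sum_j \Phi_j e^{-\tau / T_j}} to a velocity
#' autocorrelation curve, with nonnegative weights. Decay times are profiled
#' out on a log-spaced multi-start grid (the weights are linear given the
#' times, solved by nonnegative least squares) and refined with Nelder-Mead.
#' The Bayesian information criterion is computed under a Gaussian error
#' model as `N log(RSS / N) + k log(N)` with `k = 2 * n_components`.
#'
#' @param lag lag values, s
#' @param vac VAC values, um^2/s^2
#' @param n_components number of exponential components (1, 2 or 3)
#' @param n_grid number of candidate decay times per component in the
#'   multi-start grid
#' @return A list with `components` (data frame of `Phi`, `T`, sorted by
#'   increasing decay time), `bic`, `rss`, `mse`, `fitted`, and `converged`.
#' @export
fit_exponentials <- function(lag, vac, n_components = 2, n_grid = 12) {
  stopifnot(length(lag) == length(vac), n_components %in% 1:3)
  if (length(lag) < 2 * n_components + 1)
    stop("need at least 2 * n_components + 1 lags", call. = FALSE)
  lag <- as.numeric(lag); vac <- as.numeric(vac)

  span <- range(lag[lag > 0])
  t_grid <- exp(seq(log(max(span[1] / 2, 1e-3)), log(span[2] * 4),
                    length.out = n_grid))
  combos <- utils::combn(seq_along(t_grid), n_components)

  profile_fit <- function(Ts) {
    X <- sapply(Ts, function(T) exp(-lag / T))
    if (n_components == 1) X <- matrix(X, ncol = 1)
    fit <- tryCatch(pracma::lsqnonneg(X, vac), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(Phi = fit$x, rss = sum((vac - X %*% fit$x)^2))
  }

  best <- NULL
  for (j in seq_len(ncol(combos))) {
    Ts <- t_grid[combos[, j]]
    f <- profile_fit(Ts)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss))
      best <- list(Ts = Ts, Phi = f$Phi, rss = f$rss)
  }
  if (is.null(best))
    return(list(components = NULL, bic = NA_real_, rss = NA_real_,
                mse = NA_real_, fitted = NULL, converged = FALSE))

  obj <- function(logT) {
    f <- profile_fit(exp(logT))
    if (is.null(f)) return(1e300)
    f$rss
  }
  if (n_components == 1) {
    opt <- stats::optimize(obj, log(best$Ts) + c(-2, 2), tol = 1e-12)
    opt <- list(par = opt$minimum, convergence = 0L)
  } else {
    opt <- optim(log(best$Ts), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
  }
  Ts <- exp(opt$par)
  f <- profile_fit(Ts)
  ord <- order(Ts)
  Ts <- Ts[ord]; Phi <- f$Phi[ord]
  X <- sapply(Ts, function(T) exp(-lag / T))
  if (n_components == 1) X <- matrix(X, ncol = 1)
  fitted <- as.numeric(X %*% Phi)
  rss <- sum((vac - fitted)^2)
  n <- length(vac)
  # residuals below numerical precision are treated as equal when ranking
  # model orders, so the BIC penalty decides among exact fits
  rss_eff <- max(rss, n * (1e-8 * max(abs(vac)))^2)
  bic <- n * log(rss_eff / n) + (2 * n_components) * log(n)
  list(components = data.frame(Phi = Phi, T = Ts),
       bic = bic, rss = rss, mse = rss / n, fitted = fitted,
       converged = opt$convergence == 0)
}

# Closed-form inverse of gle_eigen: map (lambda+, lambda-, phi+, phi-) back
# to (alpha, beta, gamma, sigma). x = e_{x,+}^2 solves a quadratic obtained
# from the phi+/phi- ratio; then beta = lambda+ x + lambda- (1-x),
# gamma = lambda+ + lambda- - beta, alpha = (lambda+ - lambda-) sqrt(x(1-x)).
# Returns NULL when no admissible root exists (curve outside the model class).
params_from_eigen <- function(lambda_p, lambda_m, phi_p, phi_m,
                              sigma_x = 0) {
  if (!(lambda_p > lambda_m && lambda_m > 0 && phi_p > 0 && phi_m > 0))
    return(NULL)
  r <- phi_p / phi_m
  S <- lambda_p + lambda_m
  A <- 1 / (2 * lambda_p) - 1 / S - r / (2 * lambda_m) + r / S
  B <- 1 / S + r / lambda_m - r / S
  C <- -r / (2 * lambda_m)
  roots <- if (abs(A) < 1e-14) -C / B else {
    d <- B^2 - 4 * A * C
    if (d < 0) return(NULL)
    c((-B + sqrt(d)) / (2 * A), (-B - sqrt(d)) / (2 * A))
  }
  roots <- roots[roots > 1e-9 & roots < 1 - 1e-9]
  if (!length(roots)) return(NULL)
  cand <- lapply(roots, function(x) {
    beta <- lambda_p * x + lambda_m * (1 - x)
    gamma <- S - beta
    alpha <- (lambda_p - lambda_m) * sqrt(x * (1 - x))
    denom <- 2 * (x^2 / (2 * lambda_p) + x * (1 - x) / S)
    sigma <- sqrt(phi_p / denom)
    tryCatch(gle_params(alpha, beta, gamma, sigma, sigma_x),
             error = function(e) NULL)
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) return(NULL)
  # keep the root whose forward phi's reproduce the inputs best
  err <- vapply(cand, function(p) {
    e <- gle_eigen(p)
    abs(log(e$phi_plus / phi_p)) + abs(log(e$phi_minus / phi_m))
  }, numeric(1))
  cand[[which.min(err)]]
}

#' Fit GLE parameters to an empirical VAC curve
#'
#' Finds the GLE parameters whose analytic sampled-velocity autocorrelation
#' (see [analytic_vac()]) minimizes the mean squared error against an
#' empirical curve. A log-spaced grid over the two decay rates is scanned
#' first; at each grid point the component weights (and, when
#' `positional_noise = TRUE`, the squared positional-noise amplitude) enter
#' the model linearly and are profiled out by nonnegative least squares.
#' The best grid candidates are mapped back to `(alpha, beta, gamma, sigma)`
#' in closed form and refined by Nelder-Mead in log-parameter space.
#' Deterministic for fixed inputs. Ties are broken by lowest MSE, then
#' lowest fast rate.
#'
#' @param lag lag values, s; must be integer multiples of `delta_t`
#' @param vac VAC values, um^2/s^2
#' @param delta_t sampling interval of the underlying velocities, s
#' @param tau_min smallest lag used in the fit, s; use 2 for the noise-free
#'   variant and 0 when fitting the positional-noise model
#' @param positional_noise if `TRUE`, fit `sigma_x` too using the lag-0/1
#'   corrections
#' @param n_grid grid resolution per decay rate
#' @return A [gle_params] object with attributes `mse` and `converged`, or a
#'   flagged failure (`converged = FALSE`) for degenerate input.
#' @export
fit_gle_to_vac <- function(lag, vac, delta_t = 1, tau_min = 2,
                           positional_noise = FALSE, n_grid = 15) {
  stopifnot(length(lag) == length(vac))
  keep <- lag >= tau_min - 1e-9
  lag <- as.numeric(lag[keep]); vac <- as.numeric(vac[keep])
  if (length(lag) < 5 || var(vac) == 0 || all(vac <= 0))
    return(structure(list(converged = FALSE,
                          reason = "degenerate VAC input"),
                     class = "gle_fit_failure"))
  m <- round(lag / delta_t)
  if (max(abs(m * delta_t - lag)) > 1e-6 * delta_t)
    stop("lags must be integer multiples of delta_t", call. = FALSE)

  design <- function(lp, lm) {
    X <- cbind(vac_window_factor(lp, delta_t, m),
               vac_window_factor(lm, delta_t, m))
    if (positional_noise) {
      cx <- ifelse(m == 0, 2, ifelse(m == 1, -1, 0)) / delta_t^2
      X <- cbind(X, cx)
    }
    X
  }

  t_span <- range(pmax(lag, delta_t))
  rate_grid <- 1 / exp(seq(log(max(t_span[1] / 2, delta_t / 4)),
                           log(t_span[2] * 4), length.out = n_grid))
  cands <- list()
  for (lp in rate_grid) for (lm in rate_grid) {
    if (lm >= lp * 0.98) next
    X <- design(lp, lm)
    fit <- tryCatch(pracma::lsqnonneg(X, vac), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum((vac - X %*% fit$x)^2)
    cands[[length(cands) + 1]] <-
      list(lp = lp, lm = lm, w = fit$x, rss = rss)
  }
  if (!length(cands))
    return(structure(list(converged = FALSE, reason = "no admissible fit"),
                     class = "gle_fit_failure"))
  ord <- order(vapply(cands, `[[`, numeric(1), "rss"))
  cands <- cands[ord[seq_len(min(6, length(ord)))]]

  mse_of <- function(p) {
    curve <- analytic_vac(p, delta_t, max(m))$vac[m + 1]
    mean((curve - vac)^2)
  }
  obj <- function(lpar) {
    p <- tryCatch(
      gle_params(exp(lpar[1]), exp(lpar[2]), exp(lpar[3]), exp(lpar[4]),
                 if (positional_noise) exp(lpar[5]) else 0),
      error = function(e) NULL)
    if (is.null(p)) return(1e300)
    mse_of(p)
  }

  best <- NULL
  for (cand in cands) {
    phi <- cand$w[1:2]
    sx <- if (positional_noise && length(cand$w) >= 3)
      sqrt(max(cand$w[3], 1e-12)) else 0
    start <- params_from_eigen(cand$lp, cand$lm,
                               max(phi[1], 1e-8), max(phi[2], 1e-8), sx)
    if (is.null(start)) {
      # near-degenerate weights (e.g. a single-exponential curve): start
      # from an almost memory-free parameterization at the dominant rate
      lam <- if (phi[1] >= phi[2]) cand$lp else cand$lm
      ph <- max(sum(phi), 1e-8)
      start <- gle_params(alpha = lam * 1e-3, beta = lam, gamma = lam / 2,
                          sigma = sqrt(ph * 2 * lam / 2) *
                            sqrt(2), sigma_x = sx)
    }
    lpar <- log(c(start$alpha, start$beta, start$gamma,
                  max(start$sigma, 1e-8)))
    if (positional_noise) lpar <- c(lpar, log(max(start$sigma_x, 1e-4)))
    opt <- optim(lpar, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-15))
    opt <- optim(opt$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-15))
    lam_fast <- {
      p <- exp(opt$par)
      (p[2] + p[3] + sqrt((p[2] - p[3])^2 + 4 * p[1]^2)) / 2
    }
    if (is.null(best) || opt$value < best$value - 1e-18 ||
        (abs(opt$value - best$value) <= 1e-18 && lam_fast < best$lam_fast))
      best <- list(par = opt$par, value = opt$value, lam_fast = lam_fast,
                   convergence = opt$convergence)
  }
  p <- exp(best$par)
  res <- gle_params(p[1], p[2], p[3], p[4],
                    if (positional_noise) p[5] else 0)
  attr(res, "mse") <- best$value
  attr(res, "converged") <- TRUE
  res
}
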