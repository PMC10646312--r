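# Descriptive random-walk statistics of centroid trajectories.
#
# All functions take a trajectory data frame with columns cell_id, t_s,
# x_um, y_um sampled at a uniform interval (as produced by simulate_gle()
# or read_trajectories()).

traj_delta_t <- function(traj) {
  dt <- attr(traj, "delta_t")
  if (!is.null(dt)) return(dt)
  ts <- traj$t_s[traj$cell_id == traj$cell_id[1]]
  d <- diff(ts)
  if (length(d) == 0) stop("trajectory too short", call. = FALSE)
  if (max(abs(d - d[1])) > 1e-6 * d[1])
    stop("non-uniform sampling interval", call. = FALSE)
  d[1]
}

split_cells <- function(traj) split(traj, traj$cell_id)

#' Velocities and accelerations from sampled positions
#'
#' Forward-difference velocities `v(t_n) = (r(t_{n+1}) - r(t_n)) / dt` and
#' accelerations `a(t_n) = (v(t_{n+1}) - v(t_n)) / dt`, with the
#' acceleration decomposed into components parallel
#' (`a_par = a . v / |v|`) and orthogonal (`a_perp = (a x v) / |v|`, 2D
#' scalar cross product) to the instantaneous velocity. Steps with zero
#' speed have an undefined decomposition and carry `NA` there.
#'
#' @param traj trajectory data frame (`cell_id`, `t_s`, `x_um`, `y_um`)
#' @return A data frame with one row per velocity sample: `cell_id`, `t_s`,
#'   `vx`, `vy`, `speed`, and (where defined) `ax`, `ay`, `a_par`, `a_perp`.
#'   The sampling interval is kept in attribute `delta_t`.
#' @export
velocities <- function(traj) {
  dt <- traj_delta_t(traj)
  out <- lapply(split_cells(traj), function(d) {
    n <- nrow(d)
    if (n < 3) stop("need at least 3 positions per cell", call. = FALSE)
    vx <- diff(d$x_um) / dt
    vy <- diff(d$y_um) / dt
    sp <- sqrt(vx^2 + vy^2)
    nv <- n - 1
    ax <- c(diff(vx) / dt, NA)
    ay <- c(diff(vy) / dt, NA)
    a_par <- (ax * vx + ay * vy) / sp
    a_perp <- (ax * vy - ay * vx) / sp
    a_par[sp == 0] <- NA
    a_perp[sp == 0] <- NA
    data.frame(cell_id = d$cell_id[1], t_s = d$t_s[seq_len(nv)],
               vx = vx, vy = vy, speed = sp,
               ax = ax, ay = ay, a_par = a_par, a_perp = a_perp)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "delta_t") <- dt
  res
}

#' Ensemble mean square displacement
#'
#' Ensemble-and-time averaged squared displacement
#' `msd(m dt) = < |r(t_{n+m}) - r(t_n)|^2 >` over all cells and all valid
#' start times.
#'
#' @param traj trajectory data frame
#' @param max_lag largest lag in steps (default: shortest track length - 1)
#' @return Data frame with columns `lag` (s), `msd` (um^2), `n` (number of
#'   averaged pairs); the row at lag 0 is identically 0.
#' @export
msd <- function(traj, max_lag = NULL) {
  dt <- traj_delta_t(traj)
  cells <- split_cells(traj)
  n_min <- min(vapply(cells, nrow, integer(1)))
  if (is.null(max_lag)) max_lag <- n_min - 1
  max_lag <- min(max_lag, n_min - 1)
  sums <- numeric(max_lag)
  cnts <- numeric(max_lag)
  for (d in cells) {
    x <- d$x_um; y <- d$y_um; n <- length(x)
    for (m in seq_len(min(max_lag, n - 1))) {
      i <- seq_len(n - m)
      sums[m] <- sums[m] + sum((x[i + m] - x[i])^2 + (y[i + m] - y[i])^2)
      cnts[m] <- cnts[m] + (n - m)
    }
  }
  data.frame(lag = (0:max_lag) * dt, msd = c(0, sums / cnts),
             n = c(sum(vapply(cells, nrow, integer(1))), cnts))
}

#' Log-log MSD exponent
#'
#' Ordinary least squares slope of `log(msd)` against `log(lag)` over a lag
#' window (default 10-100 s, the crossover-to-persistent regime).
#'
#' @param msd_curve data frame from [msd()]
#' @param fit_range numeric length-2 lag window in seconds
#' @return The fitted exponent (scalar).
#' @export
msd_exponent <- function(msd_curve, fit_range = c(10, 100)) {
  k <- msd_curve$lag >= fit_range[1] & msd_curve$lag <= fit_range[2] &
    msd_curve$msd > 0
  if (sum(k) < 2) stop("fewer than 2 lags in fit range", call. = FALSE)
  unname(coef(lm(log(msd_curve$msd[k]) ~ log(msd_curve$lag[k])))[2])
}

#' Per-trajectory MSD exponents
#'
#' Splits each cell's track into non-overlapping sub-trajectories of
#' `window` seconds (default: the whole track), computes each
#' sub-trajectory's MSD and its log-log slope over `fit_range`, and returns
#' all slopes. The mean and standard deviation of these slopes summarize
#' the ensemble.
#'
#' @inheritParams msd
#' @param fit_range lag window (s) for the log-log fit
#' @param window sub-trajectory length in seconds, or `NULL` for whole
#'   tracks
#' @return Numeric vector of slopes, one per sub-trajectory.
#' @export
msd_exponents <- function(traj, fit_range = c(10, 100), window = NULL) {
  dt <- traj_delta_t(traj)
  out <- numeric(0)
  for (d in split_cells(traj)) {
    if (is.null(window)) {
      pieces <- list(d)
    } else {
      w <- floor(window / dt)
      idx <- split(seq_len(nrow(d)), (seq_len(nrow(d)) - 1) %/% w)
      pieces <- lapply(idx[vapply(idx, length, integer(1)) >= w], function(i) d[i, ])
    }
    for (p in pieces) {
      p$cell_id <- 1
      attr(p, "delta_t") <- dt
      mx <- min(nrow(p) - 1, ceiling(fit_range[2] / dt))
      out <- c(out, msd_exponent(msd(p, max_lag = mx), fit_range))
    }
  }
  out
}

#' Speed distribution and Rayleigh scale
#'
#' Normalized histogram of instantaneous speed in left-closed bins of width
#' `dv`, together with the scale `sigma_g` of the isotropic zero-mean 2D
#' Gaussian fitted to the pooled velocity components. For such a velocity
#' field the speed density is Rayleigh,
#' \eqn{p(v) = (v/\sigma_G^2) \exp(-v^2 / 2\sigma_G^2)}, which peaks at
#' \eqn{v = \sigma_G} and has median \eqn{\sigma_G \sqrt{2 \ln 2}}.
#'
#' @param vel velocity data frame from [velocities()]
#' @param dv speed bin width, um/s (default 0.1)
#' @return A list with `density` (data frame: `v_lo`, `v_mid`, `p`, `n`),
#'   `sigma_g`, `median_speed`, and `implied_median`
#'   (`sigma_g * sqrt(2 log 2)`).
#' @export
speed_distribution <- function(vel, dv = 0.1) {
  sp <- vel$speed
  stopifnot(length(sp) >= 1)
  bin <- floor(sp / dv)
  tab <- table(bin)
  ord <- order(as.integer(names(tab)))
  tab <- tab[ord]
  lo <- as.integer(names(tab)) * dv
  p <- as.numeric(tab) / (length(sp) * dv)
  sigma_g <- sqrt(mean(c(vel$vx, vel$vy)^2))
  list(density = data.frame(v_lo = lo, v_mid = lo + dv / 2,
                            p = p, n = as.integer(tab)),
       sigma_g = sigma_g,
       median_speed = median(sp),
       implied_median = sigma_g * sqrt(2 * log(2)))
}

#' Rayleigh speed density
#'
#' @param v speeds, um/s
#' @param sigma_g Gaussian component scale, um/s
#' @return Density values `(v / sigma_g^2) exp(-v^2 / (2 sigma_g^2))`.
#' @export
rayleigh_density <- function(v, sigma_g) {
  (v / sigma_g^2) * exp(-v^2 / (2 * sigma_g^2))
}

#' Empirical velocity autocorrelation
#'
#' Ensemble-averaged inner product `vac(m dt) = < v(t_n) . v(t_{n+m}) >`
#' over all cells and start times; `vac(0)` is the mean squared speed.
#'
#' @param vel velocity data frame from [velocities()]
#' @param max_lag largest lag in steps
#' @return Data frame with columns `lag` (s), `vac` (um^2/s^2), `n`.
#' @export
empirical_vac <- function(vel, max_lag = 100) {
  dt <- attr(vel, "delta_t")
  if (is.null(dt)) dt <- traj_delta_t(vel)
  cells <- split(vel, vel$cell_id)
  n_min <- min(vapply(cells, nrow, integer(1)))
  max_lag <- min(max_lag, n_min - 1)
  sums <- numeric(max_lag + 1)
  cnts <- numeric(max_lag + 1)
  for (d in cells) {
    n <- nrow(d)
    for (m in 0:min(max_lag, n - 1)) {
      i <- seq_len(n - m)
      sums[m + 1] <- sums[m + 1] +
        sum(d$vx[i] * d$vx[i + m] + d$vy[i] * d$vy[i + m])
      cnts[m + 1] <- cnts[m + 1] + (n - m)
    }
  }
  data.frame(lag = (0:max_lag) * dt, vac = sums / cnts, n = cnts)
}

speed_bins <- function(speed, dv) floor(speed / dv)

#' Speed-conditioned acceleration statistics
#'
#' Mean and unbiased standard deviation of the parallel and orthogonal
#' acceleration components, binned by instantaneous speed in left-closed
#' bins of width `dv`. Empty bins are absent from the output (not zero);
#' standard deviations require at least 2 samples and are `NA` below that.
#'
#' @inheritParams speed_distribution
#' @return Data frame: `v_lo`, `v_mid`, `mean_par`, `mean_perp`, `sd_par`,
#'   `sd_perp`, `n`.
#' @export
conditional_acceleration <- function(vel, dv = 0.1) {
  ok <- !is.na(vel$a_par) & !is.na(vel$a_perp)
  d <- vel[ok, ]
  b <- speed_bins(d$speed, dv)
  agg <- function(x, f) tapply(x, b, f)
  n <- as.integer(tapply(d$a_par, b, length))
  res <- data.frame(
    v_lo = as.integer(names(agg(d$a_par, mean))) * dv,
    mean_par = as.numeric(agg(d$a_par, mean)),
    mean_perp = as.numeric(agg(d$a_perp, mean)),
    sd_par = as.numeric(tapply(d$a_par, b, function(x)
      if (length(x) >= 2) sd(x) else NA_real_)),
    sd_perp = as.numeric(tapply(d$a_perp, b, function(x)
      if (length(x) >= 2) sd(x) else NA_real_)),
    n = n)
  res$v_mid <- res$v_lo + dv / 2
  res <- res[order(res$v_lo), ]
  rownames(res) <- NULL
  res[, c("v_lo", "v_mid", "mean_par", "mean_perp", "sd_par", "sd_perp", "n")]
}

#' Speed-conditioned turning cosine
#'
#' Mean cosine of the one-step direction change between consecutive
#' velocities, binned by the current speed. Pairs where either velocity has
#' zero norm are excluded.
#'
#' @inheritParams speed_distribution
#' @return Data frame: `v_lo`, `v_mid`, `cos_theta`, `n`.
#' @export
turning_cosine <- function(vel, dv = 0.1) {
  out <- lapply(split(vel, vel$cell_id), function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    i <- seq_len(n - 1)
    data.frame(speed = d$speed[i],
               cth = (d$vx[i] * d$vx[i + 1] + d$vy[i] * d$vy[i + 1]) /
                 (d$speed[i] * d$speed[i + 1]))
  })
  d <- do.call(rbind, out)
  d <- d[is.finite(d$cth), ]
  b <- speed_bins(d$speed, dv)
  res <- data.frame(v_lo = as.integer(names(tapply(d$cth, b, mean))) * dv,
                    cos_theta = as.numeric(tapply(d$cth, b, mean)),
                    n = as.integer(tapply(d$cth, b, length)))
  res$v_mid <- res$v_lo + dv / 2
  res <- res[order(res$v_lo), ]
  rownames(res) <- NULL
  res[, c("v_lo", "v_mid", "cos_theta", "n")]
}

#' Magnitude and orientation autocorrelations of the velocity
#'
#' Separates the velocity time series into its magnitude and direction.
#' The magnitude autocorrelation is the raw centered product
#' `< (|v|(t_n) - <|v|>) (|v|(t_{n+m}) - <|v|>) >` (the pooled mean is
#' subtracted; the curve is *not* normalized to 1 at lag 0 unless
#' `normalize = TRUE`). The orientation autocorrelation is the mean inner
#' product of unit velocity vectors at lag `m`, which is exactly 1 at lag 0.
#'
#' @inheritParams empirical_vac
#' @param normalize if `TRUE`, divide the magnitude curve by its lag-0 value
#' @return Data frame: `lag`, `mag_ac`, `orient_ac`, `n`.
#' @export
split_autocorrelations <- function(vel, max_lag = 100, normalize = FALSE) {
  dt <- attr(vel, "delta_t")
  if (is.null(dt)) dt <- traj_delta_t(vel)
  mbar <- mean(vel$speed)
  cells <- split(vel, vel$cell_id)
  n_min <- min(vapply(cells, nrow, integer(1)))
  max_lag <- min(max_lag, n_min - 1)
  msum <- numeric(max_lag + 1); osum <- numeric(max_lag + 1)
  cnt <- numeric(max_lag + 1)
  for (d in cells) {
    n <- nrow(d)
    cm <- d$speed - mbar
    ux <- d$vx / d$speed; uy <- d$vy / d$speed
    for (m in 0:min(max_lag, n - 1)) {
      i <- seq_len(n - m)
      msum[m + 1] <- msum[m + 1] + sum(cm[i] * cm[i + m])
      osum[m + 1] <- osum[m + 1] +
        sum(ux[i] * ux[i + m] + uy[i] * uy[i + m], na.rm = TRUE)
      cnt[m + 1] <- cnt[m + 1] + (n - m)
    }
  }
  mag <- msum / cnt
  if (normalize) mag <- mag / mag[1]
  data.frame(lag = (0:max_lag) * dt, mag_ac = mag,
             orient_ac = osum / cnt, n = cnt)
}
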