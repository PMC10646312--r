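# Seeded generators for every input the analysis stages consume: GLE
# trajectory ensembles, 1D persistent-random-walk angle series, and
# rasterized mask movies of deforming cells with programmed curvature
# waves and shape families.

#' Generate a GLE trajectory dataset
#'
#' Thin wrapper around [simulate_gle()] using the reference study
#' conditions by default (35 trajectories of 3600 s, Euler-Maruyama step
#' 2 ms, 1 s sampling). Optionally writes the standard trajectory CSV.
#'
#' @param params a [gle_params] object (default:
#'   `gle_reference_params("gle_noise")`)
#' @param n_traj,duration,dt_internal,sample_interval see [simulate_gle()]
#' @param seed integer seed
#' @param path optional CSV output path (see [write_trajectories()])
#' @return The trajectory data frame, invisibly if `path` is given.
#' @export
make_gle_dataset <- function(params = gle_reference_params("gle_noise"),
                             n_traj = 35, duration = 3600,
                             dt_internal = 0.002, sample_interval = 1,
                             seed = 1, path = NULL) {
  traj <- simulate_gle(params, n_traj, duration, dt_internal,
                       sample_interval, seed = seed)
  if (!is.null(path)) {
    write_trajectories(traj, path)
    return(invisible(traj))
  }
  traj
}

#' 1D persistent-random-walk angle series
#'
#' Every `tau` seconds the angle takes a binary step of +/- one step size
#' with equal probability (`increments = "gaussian"` substitutes zero-mean
#' Gaussian steps of the same standard deviation, the diffusive limit).
#' The default step size is `omega * tau / sqrt(2)`, which makes the angle
#' difference distribution converge to the Gaussian with variance
#' `omega^2 tau t / 2` whose direction autocorrelation decays as
#' `exp(-omega^2 tau t / 4)`, i.e. with the closed-form persistence time
#' `4 / (omega^2 tau)` of [estimate_persistence_time()]. (A literal step
#' of `omega * tau` — `step_scale = 1` — doubles the angular diffusion and
#' halves the decay time; the default is calibrated to the closed form.)
#'
#' @param omega angular step rate, rad/s (> 0)
#' @param tau step time, s (> 0)
#' @param duration total duration, s
#' @param seed integer seed
#' @param n_walkers number of independent walkers
#' @param increments `"binary"` or `"gaussian"`
#' @param step_scale step size as a multiple of `omega * tau` (default
#'   `1/sqrt(2)`, see above)
#' @return Data frame with columns `walker`, `t_s` (step times `0, tau,
#'   2 tau, ...`) and `psi` (rad, unwrapped).
#' @export
make_prw1d <- function(omega, tau, duration, seed = 1, n_walkers = 1,
                       increments = c("binary", "gaussian"),
                       step_scale = 1 / sqrt(2)) {
  increments <- match.arg(increments)
  stopifnot(omega > 0, tau > 0, duration >= tau)
  set.seed(seed)
  n_steps <- floor(duration / tau)
  step <- omega * tau * step_scale
  out <- lapply(seq_len(n_walkers), function(w) {
    d <- if (increments == "binary")
      sample(c(-1, 1), n_steps, replace = TRUE) * step
    else rnorm(n_steps, sd = step)
    data.frame(walker = w, t_s = (0:n_steps) * tau, psi = c(0, cumsum(d)))
  })
  do.call(rbind, out)
}

#' Specification of a synthetic deforming-cell mask movie
#'
#' The cell contour is a star-shaped radius profile
#' `r(theta, t) = r0 (1 + sum_k a_k cos(k theta + phase_k))` plus traveling
#' Gaussian curvature bumps (the programmed waves), rasterized to a binary
#' mask each frame. Presets emulate the recurring morphologies of crawling
#' amoebae: a fan (one broad front), a split front (two bumps), a
#' dumbbell (strong bipolar elongation), a trident (three bumps), and a
#' plain disc.
#'
#' @param preset `"circle"`, `"fan"`, `"split"`, `"dumbbell"` or
#'   `"trident"`
#' @param n_frames number of frames
#' @param delta_t frame interval, s
#' @param px_size pixel size, um/px
#' @param img_size image side, px
#' @param r0 base radius, px (cell diameter >= 80 px keeps curvature
#'   estimation accurate)
#' @param modes data frame (`k`, `amp`, `phase`) of base radius harmonics;
#'   overrides the preset's
#' @param waves data frame (`birth`, `theta0`, `omega`, `amp`, `width`,
#'   `lifetime`): bump birth time (s), start angle (rad), angular speed
#'   (rad/s), amplitude (px), angular width (rad), lifetime (s)
#' @param velocity translation velocity of the cell centre, px/s (length 2)
#' @param aspect aspect ratio of the elliptical base contour (the base is
#'   the constant-area polar ellipse with semi-axes `r0 sqrt(aspect)` and
#'   `r0 / sqrt(aspect)`); 1 = circular base
#' @return A list of class `shape_movie_spec`.
#' @export
shape_movie_spec <- function(preset = c("circle", "fan", "split",
                                        "dumbbell", "trident"),
                             n_frames = 60, delta_t = 1, px_size = 0.2,
                             img_size = 256, r0 = 45, modes = NULL,
                             waves = NULL, velocity = c(0, 0),
                             aspect = NULL) {
  preset <- match.arg(preset)
  if (is.null(aspect))
    aspect <- switch(preset, dumbbell = 2.2, 1)
  if (is.null(modes))
    modes <- switch(preset,
      circle = data.frame(k = integer(0), amp = numeric(0),
                          phase = numeric(0)),
      fan = data.frame(k = c(1, 2), amp = c(0.18, 0.10), phase = c(0, 0)),
      split = data.frame(k = 1, amp = 0.10, phase = 0),
      dumbbell = data.frame(k = integer(0), amp = numeric(0),
                            phase = numeric(0)),
      trident = data.frame(k = 1, amp = 0.08, phase = 0))
  if (is.null(waves))
    waves <- switch(preset,
      circle = data.frame(birth = numeric(0), theta0 = numeric(0),
                          omega = numeric(0), amp = numeric(0),
                          width = numeric(0), lifetime = numeric(0)),
      fan = data.frame(birth = 0, theta0 = 0, omega = 0.02, amp = 8,
                       width = 0.5, lifetime = Inf),
      split = data.frame(birth = c(0, 0), theta0 = c(-0.95, 0.95),
                         omega = c(-0.03, 0.03), amp = c(10, 10),
                         width = c(0.25, 0.25), lifetime = c(Inf, Inf)),
      dumbbell = data.frame(birth = c(0, 0), theta0 = c(0, pi),
                            omega = c(0, 0), amp = c(5, 5),
                            width = c(0.45, 0.45), lifetime = c(Inf, Inf)),
      trident = data.frame(birth = c(0, 0, 0), theta0 = c(-0.9, 0, 0.9),
                           omega = c(0, 0, 0), amp = c(8, 8, 8),
                           width = c(0.25, 0.25, 0.25),
                           lifetime = c(Inf, Inf, Inf)))
  spec <- structure(list(preset = preset, n_frames = n_frames,
                         delta_t = delta_t, px_size = px_size,
                         img_size = img_size, r0 = r0, modes = modes,
                         waves = waves, velocity = velocity,
                         aspect = aspect),
                    class = "shape_movie_spec")
  validate_shape_movie_spec(spec)
  spec
}

radius_profile <- function(spec, theta, t_s) {
  asp <- if (is.null(spec$aspect)) 1 else spec$aspect
  r <- if (asp == 1) rep(spec$r0, length(theta)) else {
    a <- spec$r0 * sqrt(asp); b <- spec$r0 / sqrt(asp)
    a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  }
  md <- spec$modes
  for (j in seq_len(nrow(md)))
    r <- r + spec$r0 * md$amp[j] * cos(md$k[j] * theta + md$phase[j])
  wv <- spec$waves
  for (j in seq_len(nrow(wv))) {
    if (t_s < wv$birth[j] || t_s >= wv$birth[j] + wv$lifetime[j]) next
    thc <- wv$theta0[j] + wv$omega[j] * (t_s - wv$birth[j])
    r <- r + wv$amp[j] * exp(-wrap_angle(theta - thc)^2 /
                               (2 * wv$width[j]^2))
  }
  r
}

validate_shape_movie_spec <- function(spec) {
  th <- seq(-pi, pi, length.out = 720)
  for (t in seq_len(spec$n_frames)) {
    ts <- (t - 1) * spec$delta_t
    r <- radius_profile(spec, th, ts)
    if (any(r <= 2))
      stop("shape spec degenerate: radius reaches <= 2 px at frame ", t,
           call. = FALSE)
    cen <- spec$img_size / 2 + spec$velocity * ts
    if (max(r) + max(abs(cen - spec$img_size / 2)) > spec$img_size / 2 - 4)
      stop("shape spec leaves the image bounds at frame ", t,
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Rasterize a synthetic mask movie with ground truth
#'
#' Renders the contour program of a [shape_movie_spec()] to binary masks
#' (pixel centres inside the radius profile) and records the exact ground
#' truth needed by downstream recovery tests: per-frame wave centre angles
#' and angular speeds, wave lifetimes, the centroid path and the shape
#' class.
#'
#' @param spec a [shape_movie_spec()]
#' @param seed integer seed (reserved for stochastic programs; rendering
#'   itself is deterministic)
#' @return A list of class `shape_movie` with `masks` (list of logical
#'   matrices), `ground_truth` (list: `preset`, `delta_t`, `px_size`,
#'   `center` T x 2 px, `waves`, `wave_angles` T x n_wave matrix), and
#'   `spec`.
#' @export
make_shape_movie <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "shape_movie_spec"))
  set.seed(seed)
  n <- spec$img_size
  xs <- matrix(rep(seq_len(n), each = n), n)   # column index = x
  ys <- matrix(rep(seq_len(n), times = n), n)  # row index = y
  masks <- vector("list", spec$n_frames)
  centers <- matrix(NA_real_, spec$n_frames, 2)
  wv <- spec$waves
  wave_angles <- matrix(NA_real_, spec$n_frames, nrow(wv))
  for (t in seq_len(spec$n_frames)) {
    ts <- (t - 1) * spec$delta_t
    cen <- spec$img_size / 2 + spec$velocity * ts
    centers[t, ] <- cen
    dx <- xs - cen[1]; dy <- ys - cen[2]
    th <- atan2(dy, dx)
    r <- matrix(radius_profile(spec, as.numeric(th), ts), n)
    masks[[t]] <- (dx^2 + dy^2) <= r^2
    for (j in seq_len(nrow(wv))) {
      if (ts >= wv$birth[j] && ts < wv$birth[j] + wv$lifetime[j])
        wave_angles[t, j] <- wrap_angle(wv$theta0[j] +
                                          wv$omega[j] * (ts - wv$birth[j]))
    }
  }
  structure(list(masks = masks,
                 ground_truth = list(preset = spec$preset,
                                     delta_t = spec$delta_t,
                                     px_size = spec$px_size,
                                     center_px = centers,
                                     waves = wv,
                                     wave_angles = wave_angles),
                 spec = spec),
            class = "shape_movie")
}

#' Generate a jittered family of single-frame shape masks
#'
#' Draws `n` masks from one shape class, randomizing the class's shape
#' parameters (mode amplitudes, bump positions, widths and amplitudes, and
#' a global rotation) around the preset values while keeping the base
#' radius fixed, so that within-family variation is morphological rather
#' than size-driven.
#'
#' @param preset `"fan"`, `"split"`, `"dumbbell"` or `"trident"`
#' @param n number of masks
#' @param seed integer seed
#' @param r0 base radius, px
#' @param img_size image side, px
#' @return A list of `n` logical mask matrices.
#' @export
make_shape_family <- function(preset, n = 21, seed = 1, r0 = 45,
                              img_size = 256) {
  set.seed(seed)
  base <- shape_movie_spec(preset, n_frames = 1, r0 = r0,
                           img_size = img_size)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # global rotation only for circular-base classes (the elliptical base
    # axis is fixed; the power spectrum is rotation-invariant anyway)
    rot <- if (base$aspect == 1) runif(1, -pi, pi) else 0
    asp <- base$aspect * if (base$aspect > 1) runif(1, 0.92, 1.08) else 1
    md <- base$modes
    if (nrow(md)) {
      md$amp <- md$amp * runif(nrow(md), 0.85, 1.15)
      md$phase <- md$phase + md$k * rot
    }
    wv <- base$waves
    if (nrow(wv)) {
      wv$amp <- wv$amp * runif(nrow(wv), 0.85, 1.15)
      wv$width <- wv$width * runif(nrow(wv), 0.9, 1.1)
      wv$theta0 <- wv$theta0 + rot + rnorm(nrow(wv), sd = 0.06)
    }
    spec <- shape_movie_spec(preset, n_frames = 1, r0 = r0,
                             img_size = img_size, modes = md, waves = wv,
                             aspect = asp)
    out[[i]] <- make_shape_movie(spec, seed = seed + i)$masks[[1]]
  }
  out
}
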