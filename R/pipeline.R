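# End-to-end analysis pipeline over a trajectory ensemble and a mask
# movie, reproducing the full analysis sequence with one call.

#' Run the full analysis pipeline
#'
#' Executes, in order: trajectory statistics (MSD exponent, speed
#' distribution, VAC), GLE fitting to the empirical VAC, boundary dynamics
#' (kymographs, wave tracking, leading-edge lifetimes, persistence-time
#' estimate) and Fourier morphometry (spectra, PCA, PC time series) on the
#' given inputs, and writes a JSON report plus per-stage CSV tables to
#' `out_dir`. A failing stage is marked failed in the report; the other
#' stages still complete.
#'
#' @param traj trajectory data frame (or CSV path)
#' @param masks list of binary mask matrices (or multi-page TIFF path),
#'   optional
#' @param out_dir output directory (created if missing)
#' @param px_size pixel size for the masks, um/px
#' @param frame_interval mask frame interval, s
#' @param dv speed bin width, um/s
#' @param msd_fit_range lag window (s) for the MSD exponent
#' @param tau_min smallest VAC lag used in the GLE fit, s
#' @param positional_noise fit the positional-noise GLE variant
#' @param n_boundary_points,n_fourier_points boundary / Fourier contour
#'   sampling
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs)
#' @return The report list, invisibly; also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(traj, masks = NULL, out_dir = tempfile("amoebo"),
                         px_size = 0.2, frame_interval = 1, dv = 0.1,
                         msd_fit_range = c(10, 100), tau_min = 2,
                         positional_noise = FALSE,
                         n_boundary_points = 500, n_fourier_points = 160,
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(traj)) traj <- read_trajectories(traj)
  if (is.character(masks)) masks <- read_mask_movie(masks)
  report <- list(package_version = as.character(utils::packageVersion("amoebokinetics")),
                 seed = seed, stages = list())
  scalars <- list()

  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     message = conditionMessage(res))
      NULL
    } else {
      report$stages[[name]] <<- list(status = "ok")
      res
    }
  }

  vel <- stage("velocities", function() velocities(traj))

  if (!is.null(vel)) {
    stage("trajectory_stats", function() {
      mx <- ceiling(msd_fit_range[2] / traj_delta_t(traj))
      msd_curve <- msd(traj, max_lag = mx)
      slopes <- msd_exponents(traj, fit_range = msd_fit_range)
      spd <- speed_distribution(vel, dv)
      vac <- empirical_vac(vel, max_lag = 100)
      write.csv(msd_curve, file.path(out_dir, "msd.csv"), row.names = FALSE)
      write.csv(vac, file.path(out_dir, "vac.csv"), row.names = FALSE)
      write.csv(spd$density, file.path(out_dir, "speed_density.csv"),
                row.names = FALSE)
      scalars$msd_exponent <<- mean(slopes)
      scalars$msd_exponent_sd <<- sd(slopes)
      scalars$sigma_G <<- spd$sigma_g
      scalars$median_speed_um_s <<- spd$median_speed
      scalars$median_speed_um_min <<- spd$median_speed * 60
      vac
    })
    vac <- tryCatch(read.csv(file.path(out_dir, "vac.csv")),
                    error = function(e) NULL)
    if (!is.null(vac)) {
      stage("gle_fit", function() {
        fit2 <- fit_exponentials(vac$lag[vac$lag >= tau_min],
                                 vac$vac[vac$lag >= tau_min], 2)
        gfit <- fit_gle_to_vac(vac$lag, vac$vac,
                               delta_t = traj_delta_t(traj),
                               tau_min = if (positional_noise) 0 else tau_min,
                               positional_noise = positional_noise)
        if (inherits(gfit, "gle_fit_failure"))
          stop("GLE fit failed: ", gfit$reason)
        write_gle_params(gfit, file.path(out_dir, "gle_fit.json"))
        scalars$T1 <<- fit2$components$T[1]
        scalars$T2 <<- fit2$components$T[2]
        scalars$Phi1 <<- fit2$components$Phi[1]
        scalars$Phi2 <<- fit2$components$Phi[2]
        scalars$alpha <<- gfit$alpha; scalars$beta <<- gfit$beta
        scalars$gamma <<- gfit$gamma; scalars$sigma <<- gfit$sigma
        scalars$sigma_x <<- gfit$sigma_x
        gfit
      })
    }
  }

  if (!is.null(masks)) {
    kym <- stage("boundary_dynamics", function() {
      series <- contour_series(masks, px_size, frame_interval,
                               n_boundary_points)
      k <- kymographs(series)
      write_kymograph(k$curvature, file.path(out_dir, "curvature_kym.csv"))
      write_kymograph(k$velocity, file.path(out_dir, "velocity_kym.csv"))
      k
    })
    if (!is.null(kym)) {
      stage("wave_tracking", function() {
        track <- classify_and_track_waves(kym)
        lel <- leading_edge_lifetimes(track, kym$psi)
        scalars$c1 <<- track$c1; scalars$c2 <<- track$c2
        scalars$omega_c <<- track$omega_c
        scalars$tau_d <<- lel$tau_d
        if (is.finite(track$omega_c) && isTRUE(lel$tau_d > 0))
          scalars$T_est <<- estimate_persistence_time(track$omega_c,
                                                      lel$tau_d)
        if (!is.null(track$fragments))
          write.csv(track$fragments, file.path(out_dir, "wave_fragments.csv"),
                    row.names = FALSE)
        track
      })
    }
    stage("fourier_shape", function() {
      spectra <- lapply(masks, elliptic_fourier, n_points = n_fourier_points)
      # a single movie rarely has more frames than spectrum dimensions;
      # the rank-deficient decomposition is expected here
      pca <- suppressWarnings(fit_spectrum_pca(spectra))
      sc <- project_spectra(spectra, pca, n_components = 2)
      scores <- data.frame(cell_id = 1,
                           t_s = (seq_along(masks) - 1) * frame_interval,
                           PC1 = sc[, 1], PC2 = sc[, 2])
      write.csv(scores, file.path(out_dir, "pc_scores.csv"),
                row.names = FALSE)
      scalars$pc1_var_share <<- pca$values[1] / sum(pca$values)
      scores
    })
  }

  report$scalars <- scalars
  report$config <- list(px_size = px_size, frame_interval = frame_interval,
                        dv = dv, msd_fit_range = msd_fit_range,
                        tau_min = tau_min,
                        positional_noise = positional_noise,
                        n_boundary_points = n_boundary_points,
                        n_fourier_points = n_fourier_points)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
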