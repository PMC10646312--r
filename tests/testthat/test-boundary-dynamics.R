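# Boundary extraction, linking, kymographs, wave tracking, persistence.

test_that("contour extraction and resampling reproduce calibration geometry", {
  m <- disc_mask(50, n = 201, cx = 101, cy = 101)
  ct <- extract_and_resample(m, 500)
  per <- sum(sqrt(rowSums(diff(rbind(ct, ct[1, ]))^2)))
  expect_equal(per, 2 * pi * 50, tolerance = 0.02)
  sp <- sqrt(rowSums(diff(rbind(ct, ct[1, ]))^2))
  expect_lt((max(sp) - min(sp)) / mean(sp), 0.01)

  # square: four curvature peaks at the corners
  sq <- square_mask(30)
  g <- amoebokinetics:::contour_geometry(extract_and_resample(sq, 500))
  high <- g$curvature > 0.5 * max(g$curvature)
  expect_equal(length(amoebokinetics:::circular_runs(high)), 4)

  expect_error(extract_and_resample(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 40, 40); two[5:10, 5:10] <- TRUE; two[25:30, 25:30] <- TRUE
  expect_error(extract_and_resample(two), "multiple")
})

test_that("frame linking recovers constructed cyclic shifts and is inverse-consistent", {
  th <- seq(0, 2 * pi, length.out = 501)[-501]
  ring <- cbind(10 * cos(th), 10 * sin(th))
  for (k in c(0, 17, 250, 499)) {
    shifted <- ring[((seq_len(500) - 1 + k) %% 500) + 1, ]
    res <- link_frames(ring, shifted)
    expect_equal(res$shift %% 500, (500 - k) %% 500)
    expect_equal(res$linked, ring, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # brute-force optimality on a translated contour
  moved <- ring + matrix(rep(c(0.8, -0.4), each = 500), ncol = 2)
  res <- link_frames(ring, moved)
  costs <- vapply(0:499, function(s) {
    idx <- ((seq_len(500) - 1 + s) %% 500) + 1
    mean(rowSums((ring - moved[idx, ])^2))
  }, numeric(1))
  expect_equal(res$shift, which.min(costs) - 1L)
  # inverse consistency
  ab <- link_frames(ring, moved)
  ba <- link_frames(moved, ab$linked)
  expect_equal(ba$shift, 0L)
})

test_that("kymographs satisfy the closed-contour and rigid-motion oracles", {
  masks <- list(disc_mask(45), disc_mask(45, cx = 131), disc_mask(45, cx = 134))
  k <- kymographs(contour_series(masks, px_size = 1, delta_t = 1))
  # curvature ~ 1/R, constant within 5%
  expect_equal(mean(k$curvature[, 1]) * 45, 1, tolerance = 0.05)
  expect_lt(sd(k$curvature[, 1]) / mean(k$curvature[, 1]), 0.05)
  # total turning 2*pi within 2%
  for (t in 1:3)
    expect_equal(sum(k$curvature[, t] * k$ds[, t]), 2 * pi, tolerance = 0.02)
  # translation at 3 px/s: u = s cos(phi), max at the front, psi = 0
  expect_equal(k$velocity[, 1], 3 * cos(k$normal_angle[, 1]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(k$psi[1], 0, tolerance = 1e-9)

  # uniform expansion: u = rdot everywhere
  ke <- kymographs(contour_series(list(disc_mask(45), disc_mask(47)), 1, 1))
  expect_equal(mean(ke$velocity), 2, tolerance = 0.05)
  expect_lt(sd(ke$velocity), 0.2)

  # stationary disc: u = 0
  ks <- kymographs(contour_series(list(disc_mask(45), disc_mask(45)), 1, 1))
  expect_lt(max(abs(ks$velocity)), 1e-9)
  expect_true(is.na(ks$psi[1]))
})

test_that("mask area change balances the integrated normal flux", {
  sp <- shape_movie_spec("circle", n_frames = 3,
                         waves = data.frame(birth = 0, theta0 = 0.5,
                                            omega = 0.3, amp = 8,
                                            width = 0.4, lifetime = Inf))
  mv <- make_shape_movie(sp)
  k <- kymographs(contour_series(mv$masks, 1, 1))
  for (t in 1:2) {
    dA <- sum(mv$masks[[t + 1]]) - sum(mv$masks[[t]])
    flux <- sum(k$velocity[, t] * k$ds[, t])
    expect_equal(flux, dA, tolerance = 0.1 * max(abs(dA), 50))
  }
})

test_that("three-class Otsu thresholds are ordered and shift-equivariant", {
  set.seed(5)
  x <- c(rnorm(500, 0), rnorm(500, 4), rnorm(500, 9))
  th <- otsu_thresholds(x, 3)
  expect_lt(th[1], th[2])
  expect_gt(th[1], 0); expect_lt(th[1], 4)
  expect_gt(th[2], 4); expect_lt(th[2], 9)
  th2 <- otsu_thresholds(x + 100, 3)
  expect_equal(th2, th + 100, tolerance = 1e-9)
  expect_error(otsu_thresholds(rep(1, 10), 3), "constant")
})

test_that("front/rear joint-cosine fit recovers its own model exactly", {
  n <- 500
  idx <- seq_len(n)
  for (ends in list(c(120, 260), c(430, 60))) {
    i1 <- ends[1]; i2 <- ends[2]
    in_f <- if (i1 <= i2) idx >= i1 & idx <= i2 else idx >= i1 | idx <= i2
    L <- if (i1 <= i2) i2 - i1 else n - (i1 - i2)
    Cf <- amoebokinetics:::fragment_center(i1, i2, n)
    Cr <- amoebokinetics:::fragment_center(i2, i1, n)
    cd <- function(i, c) pmin(abs(i - c), n - abs(i - c))
    u <- numeric(n)
    u[in_f] <- 2.5 * cos(pi * cd(idx[in_f], Cf) / L)
    u[!in_f] <- -1.2 * cos(pi * cd(idx[!in_f], Cr) / (n - L))
    f <- fit_front_rear(u)
    expect_equal(c(f$i1, f$i2), c(i1, i2))
    expect_equal(f$A1, 2.5, tolerance = 1e-9)
    expect_equal(f$A2, 1.2, tolerance = 1e-9)
  }
  d <- fit_front_rear(rep(0, n))
  expect_true(d$degenerate)
})

test_that("front centre of a translating disc aligns with the motion direction", {
  masks <- list(disc_mask(45), disc_mask(45, cx = 131))
  k <- kymographs(contour_series(masks, 1, 1))
  f <- fit_front_rear(k$velocity[, 1])
  ang <- k$normal_angle[round(f$center_front), 1]
  expect_lt(abs(ang - k$psi[1]), 2 * pi * 5 / 500 + 0.05)
})

test_that("wave classification matches brute-force ring labeling and tracks omega", {
  # constructed kymograph: Gaussian curvature ridge advancing on a ring of
  # 500 points whose normal angle is the point angle
  n <- 500; T_ <- 80; dt <- 1
  ang <- 2 * pi * (seq_len(n) - 1) / n - pi
  omega_true <- 0.05
  curv <- sapply(seq_len(T_), function(t) {
    thc <- -2 + omega_true * (t - 1) * dt
    0.02 + 0.08 * exp(-amoebokinetics:::wrap_angle(ang - thc)^2 / (2 * 0.3^2))
  })
  kym <- list(curvature = curv, normal_angle = matrix(ang, n, T_),
              delta_t = dt, psi = rep(NA_real_, T_ - 1))
  tr <- classify_and_track_waves(kym)
  expect_lt(tr$c1, tr$c2)
  expect_equal(nrow(tr$fragments), T_)        # one fragment per frame
  expect_equal(nrow(tr$links), T_ - 1)
  expect_equal(mean(tr$links$omega), omega_true, tolerance = 0.05)
  expect_equal(tr$omega_c, omega_true, tolerance = 0.1)

  # fragments equal brute-force labeling of the thresholded ring
  for (t in c(1, 40)) {
    b <- curv[, t] > tr$c2
    runs <- amoebokinetics:::circular_runs(b)
    got <- tr$members[[t]]
    expect_equal(length(got), length(runs))
    expect_setequal(unlist(got), which(b))
  }

  # two disjoint bumps: two fragments, no cross-links between them
  curv2 <- sapply(seq_len(10), function(t) {
    0.02 + 0.08 * exp(-amoebokinetics:::wrap_angle(ang + 2)^2 / (2 * 0.2^2)) +
      0.08 * exp(-amoebokinetics:::wrap_angle(ang - 2)^2 / (2 * 0.2^2))
  })
  tr2 <- classify_and_track_waves(list(curvature = curv2,
                                       normal_angle = matrix(ang, n, 10),
                                       delta_t = 1))
  expect_equal(sum(tr2$fragments$frame == 1), 2)
  # links only connect a fragment to its own continuation
  ang_match <- abs(amoebokinetics:::wrap_angle(
    tr2$fragments$angle[match(paste(tr2$links$frame, tr2$links$id),
                              paste(tr2$fragments$frame, tr2$fragments$id))] -
      tr2$fragments$angle[match(paste(tr2$links$frame + 1, tr2$links$id_next),
                                paste(tr2$fragments$frame, tr2$fragments$id))]))
  expect_lt(max(ang_match), 0.5)
})

test_that("degenerate (constant) curvature produces a flagged no-waves result", {
  kym <- list(curvature = matrix(1, 100, 5),
              normal_angle = matrix(0, 100, 5), delta_t = 1)
  expect_warning(tr <- classify_and_track_waves(kym), "degenerate")
  expect_true(is.na(tr$omega_c))
})

test_that("leading-edge lifetimes follow the printed break-time rule", {
  # constructed track: two fragments per frame at angles 0 and pi, always
  # self-linked; the leading edge alternates every K frames with psi
  n_frames <- 60; K <- 10; dt <- 1
  frags <- do.call(rbind, lapply(seq_len(n_frames), function(t)
    data.frame(frame = t, id = 1:2, i_l = c(10, 260), i_r = c(50, 300),
               center = c(30, 280), angle = c(0, pi))))
  links <- do.call(rbind, lapply(seq_len(n_frames - 1), function(t)
    data.frame(frame = t, id = 1:2, id_next = 1:2, omega = 0)))
  track <- structure(list(c1 = 0, c2 = 1, fragments = frags, links = links,
                          omega_c = 0.1, delta_t = dt,
                          members = NULL), class = "wave_track")
  psi <- rep(c(0, pi), each = K, length.out = n_frames)
  res <- leading_edge_lifetimes(track, psi)
  expect_equal(unique(res$lifetimes), K * dt - dt)
  expect_equal(res$tau_d, K * dt - dt)

  # single persistent aligned wave: no breaks, no finite lifetimes
  res1 <- leading_edge_lifetimes(track, rep(0, n_frames))
  expect_length(res1$lifetimes, 0)
})

test_that("persistence-time estimator has the closed form and scaling law", {
  expect_equal(estimate_persistence_time(0.1, 2.8), 4 / (0.01 * 2.8))
  t1 <- estimate_persistence_time(0.05, 3)
  expect_equal(estimate_persistence_time(0.1, 3), t1 / 4)
  expect_error(estimate_persistence_time(0, 1), "positive")
})

test_that("Monte-Carlo direction decay of the angle walk matches 4/(omega^2 tau)", {
  om <- 0.12; ta <- 3
  pw <- make_prw1d(om, ta, duration = 600, seed = 13, n_walkers = 800)
  ac <- tapply(cos(pw$psi), pw$t_s, mean)
  tt <- as.numeric(names(ac))
  o <- order(tt); tt <- tt[o]; ac <- as.numeric(ac)[o]
  # contiguous initial decay, before averaging noise dominates
  k <- which(cumsum(ac < 0.15) == 0)[-1]
  decay <- -1 / unname(coef(lm(log(ac[k]) ~ tt[k]))[2])
  expect_equal(decay, 4 / (om^2 * ta), tolerance = 0.1)
})
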