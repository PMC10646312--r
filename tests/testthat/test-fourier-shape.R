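# Elliptic Fourier descriptors, spectrum PCA, mode dynamics and coupling.

test_that("a disc concentrates spectral power in the fundamental mode", {
  s <- elliptic_fourier(disc_mask(40))
  expect_equal(which.max(s$S), 2)  # k = 1
  expect_lt(max(s$S[-c(1, 2)]) / s$S[2], 0.01)
  # centering: k = 0 mode is (numerically) zero
  expect_lt(s$S[1] / s$S[2], 1e-20)
})

test_that("the spectrum is invariant to mask translation", {
  s1 <- elliptic_fourier(disc_mask(40))
  s2 <- elliptic_fourier(disc_mask(40, cx = 141, cy = 117))
  expect_equal(s1$S, s2$S, tolerance = 1e-10)
})

test_that("growing ellipse aspect ratio grows the counter-rotating mode share", {
  aspects <- c(1.2, 1.5, 1.9, 2.4)
  share <- sapply(aspects, function(a) {
    s <- elliptic_fourier(ellipse_mask(40 * sqrt(a), 40 / sqrt(a)))
    s$S[160] / s$S[2]
  })
  expect_true(all(diff(share) > 0))
  # closed-form ellipse Fourier series: z = alpha e^{i th} + beta e^{-i th}
  # with alpha = (a+b)/2, beta = (a-b)/2 (up to the common rescale), so the
  # power ratio is approximately ((a-b)/(a+b))^2
  a <- 40 * sqrt(2); b <- 40 / sqrt(2)
  s <- elliptic_fourier(ellipse_mask(a, b))
  expect_equal(s$S[160] / s$S[2], ((a - b) / (a + b))^2, tolerance = 0.15)
})

test_that("signed mode accessor follows the adopted index convention", {
  s <- elliptic_fourier(disc_mask(40))
  expect_identical(shape_mode(s, 1), s$q_tilde[2])
  expect_identical(shape_mode(s, -1), s$q_tilde[160])
  expect_identical(shape_mode(s, -4), s$q_tilde[157])
})

test_that("spectrum PCA reproduces brute-force projections and orthonormality", {
  set.seed(6)
  S <- matrix(rexp(30 * 160), 30, 160)
  pca <- suppressWarnings(fit_spectrum_pca(S))
  V <- pca$vectors
  expect_lt(max(abs(t(V) %*% V - diag(160))), 1e-10)
  expect_true(all(diff(pca$values) <= 1e-8))
  sc <- project_spectra(S, pca, 5)
  for (m in 1:5)
    expect_equal(sc[, m], as.numeric((S - matrix(pca$mean, 30, 160,
                                                 byrow = TRUE)) %*% V[, m]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  # identical spectra: all eigenvalues and scores zero
  same <- matrix(rep(S[1, ], 5), 5, byrow = TRUE)
  pca0 <- suppressWarnings(fit_spectrum_pca(same))
  expect_lt(max(pca0$values), 1e-12)
  expect_lt(max(abs(project_spectra(same, pca0, 3))), 1e-6)
})

test_that("project/reconstruct round-trips the power spectrum at full rank", {
  set.seed(7)
  S <- matrix(rexp(40 * 160), 40, 160)
  pca <- suppressWarnings(fit_spectrum_pca(S))
  x <- S[3, ]
  sc <- as.numeric(project_spectra(matrix(x, 1), pca))
  rec <- suppressWarnings(reconstruct_shape(sc, pca))
  expect_equal(rec$S, x, tolerance = 1e-8, ignore_attr = TRUE)
  # zero scores give the mean spectrum
  rec0 <- suppressWarnings(reconstruct_shape(numeric(0), pca))
  expect_equal(rec0$S, pca$mean, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PC1 sweep on the synthetic three-class PCA grows the aspect ratio", {
  fams <- c("fan", "split", "dumbbell")
  masks <- unlist(lapply(seq_along(fams), function(i)
    make_shape_family(fams[i], 7, seed = 100 + i)), recursive = FALSE)
  spectra <- lapply(masks, elliptic_fourier, rescale = "unit")
  pca <- suppressWarnings(fit_spectrum_pca(spectra))
  ep <- elongation_pc(pca)
  lam <- pca$values[ep$index]
  aspect_of <- function(contour) {
    x <- Re(contour); y <- Im(contour)
    ev <- eigen(cov(cbind(x, y)))$values
    sqrt(ev[1] / ev[2])
  }
  # orient the sweep along the elongation direction of that component
  flip <- sign(sum(ep$vector * pca$vectors[, ep$index]))
  sweep_scores <- seq(-1.2 * sqrt(lam), 1.2 * sqrt(lam), length.out = 5)
  asp <- sapply(sweep_scores, function(s) {
    sc <- numeric(ep$index); sc[ep$index] <- s * flip
    rec <- suppressWarnings(reconstruct_shape(sc, pca, amplitude = "sqrt"))
    aspect_of(rec$contour)
  })
  # increasing along the sweep (flat only where clipping saturates the
  # elongation mode at zero)
  expect_true(all(diff(asp) > -1e-9))
  expect_gt(asp[5] - asp[1], 0.3)
})

test_that("PC autocorrelation matches closed forms and brute force", {
  # sinusoidal PC1, zero PC2: half-amplitude cosine
  n <- 2000; w <- 2 * pi / 40
  sc <- data.frame(cell_id = 1, t_s = 0:(n - 1),
                   PC1 = 3 * cos(w * (0:(n - 1))), PC2 = 0)
  ac <- pc_autocorrelation(sc, max_lag = 40)
  expect_equal(ac$ac, (9 / 4) * cos(w * ac$lag), tolerance = 0.01)

  # constant scores: identically zero after centering
  cc <- data.frame(cell_id = rep(1:2, each = 10), t_s = rep(0:9, 2),
                   PC1 = rep(c(5, -2), each = 10), PC2 = rep(c(1, 3), each = 10))
  expect_lt(max(abs(pc_autocorrelation(cc, 5)$ac)), 1e-12)

  # random series: brute-force oracle
  set.seed(9)
  rs <- data.frame(cell_id = 1, t_s = 0:49, PC1 = rnorm(50), PC2 = rnorm(50))
  got <- pc_autocorrelation(rs, 5)
  p1 <- rs$PC1 - mean(rs$PC1); p2 <- rs$PC2 - mean(rs$PC2)
  for (m in 0:5) {
    i <- seq_len(50 - m)
    expect_equal(got$ac[m + 1],
                 mean((p1[i] * p1[i + m] + p2[i] * p2[i + m]) / 2),
                 tolerance = 1e-12)
  }
})

test_that("complex-mode autocorrelation recovers decay times and flags phasors", {
  set.seed(2)
  th <- 0.08; n <- 6000
  z <- complex(real = numeric(n))
  cur <- 0 + 0i
  for (i in seq_len(n)) {
    cur <- cur * (1 - th) +
      complex(real = rnorm(1, sd = 0.3), imaginary = rnorm(1, sd = 0.3))
    z[i] <- cur
  }
  res <- mode_autocorrelation(z, delta_t = 1, max_lag = 80)
  expect_equal(res$decay_time, -1 / log(1 - th), tolerance = 0.1)

  expect_identical(mode_autocorrelation(complex(argument = 0.3 * (1:300)))$decay_time,
                   Inf)

  set.seed(10)
  wn <- complex(real = rnorm(800), imaginary = rnorm(800))
  expect_lt(mode_autocorrelation(wn)$decay_time, 2)
})

test_that("deformation-velocity coupling matches constructions and brute force", {
  # quadrature oscillation: the coupling is constant with the product-rule value
  t <- 0:300; w <- 0.17
  cm <- complex(argument = -w * t)          # C_{-3}
  cp <- complex(argument = w * t + pi / 3)  # C_4
  res <- deformation_velocity_coupling(cm, cp, vx = rep(1, 301),
                                       vy = rep(0.5, 301), delta_t = 1)
  expect_lt(sd(Mod(res$coupling)) / mean(Mod(res$coupling)), 1e-10)

  # static shape: degenerate, flagged
  res0 <- deformation_velocity_coupling(rep(2 + 1i, 20), rep(1 - 1i, 20),
                                        vx = rep(1, 20), vy = rep(0, 20))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$circular_cor))

  # brute-force oracle with independent differencing
  set.seed(12)
  n <- 60
  a <- complex(real = rnorm(n), imaginary = rnorm(n))
  b <- complex(real = rnorm(n), imaginary = rnorm(n))
  res2 <- deformation_velocity_coupling(a, b, vx = rnorm(n), vy = rnorm(n))
  for (i in sample(n - 1, 5)) {
    da <- a[i + 1] - a[i]; db <- b[i + 1] - b[i]
    expect_equal(res2$coupling[i], da * b[i] - a[i] * db, tolerance = 1e-12)
  }
})

test_that("coupling aligned with motion yields high circular correlation", {
  # construct C_nm whose argument equals the velocity angle plus noise
  set.seed(14)
  n <- 400
  ang <- cumsum(rnorm(n, sd = 0.3))
  vx <- cos(ang) + rnorm(n, sd = 0.05)
  vy <- sin(ang) + rnorm(n, sd = 0.05)
  # build series whose coupling has argument ~ang: C_{-n} = 1, C_m = cumulative
  # integral of e^{i ang} (then d/dt C_m = e^{i ang})
  cmn <- rep(1 + 0i, n)
  cm <- -c(0, cumsum(complex(argument = ang)))[seq_len(n)]
  res <- deformation_velocity_coupling(cmn, cm, vx, vy, delta_t = 1)
  expect_gt(res$circular_cor, 0.8)
  expect_gt(res$slope_x, 0)
  expect_gt(res$slope_y, 0)
})
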