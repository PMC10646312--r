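# Contour extraction, equal-arc resampling, frame linking and kymographs
# for binary single-cell mask movies.
#
# Masks are logical (or 0/1) matrices indexed mask[row, col]; x = column,
# y = row (image convention, y increasing downward). All geometric output
# is in micrometres once px_size is applied.

#' Trace the boundary pixel chain of a binary mask
#'
#' Moore-neighbour tracing of the single foreground component, starting at
#' the upper-left-most boundary pixel (smallest row, then smallest column)
#' and proceeding clockwise in image coordinates. Returns pixel centres as
#' an (x, y) matrix forming a closed 8-connected chain.
#'
#' @param mask logical or 0/1 matrix with exactly one foreground component
#' @return A two-column matrix of boundary pixel coordinates (`x`, `y`).
#' @export
extract_contour <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c]
  # start: first foreground pixel in raster order
  idx <- which(t(m))[1]  # row-major scan
  r0 <- (idx - 1) %/% nc + 1
  c0 <- (idx - 1) %% nc + 1
  # clockwise neighbour order (screen coords, y down): N NE E SE S SW W NW
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  # backtrack starts at the W neighbour of the start pixel (background by
  # construction of the raster scan)
  back <- 7L
  pr <- r0; pc <- c0
  path_r <- integer(0); path_c <- integer(0)
  max_iter <- 8L * (nr * nc)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (iter in seq_len(max_iter)) {
    key <- paste(pr, pc, back)
    if (!is.null(seen[[key]])) {
      # cycle closed: keep the path from the first occurrence of this state
      first <- seen[[key]]
      path_r <- path_r[first:length(path_r)]
      path_c <- path_c[first:length(path_c)]
      # index 1 at the upper-left-most point of the cycle
      j <- which.min(path_r * (nc + 1) + path_c)
      ord <- c(j:length(path_r), seq_len(j - 1))
      return(cbind(x = path_c[ord], y = path_r[ord]))
    }
    seen[[key]] <- length(path_r) + 1L
    path_r <- c(path_r, pr); path_c <- c(path_c, pc)
    found <- FALSE
    k <- back
    for (step in 1:8) {
      k <- (k %% 8L) + 1L
      rr <- pr + dr[k]; cc <- pc + dc[k]
      if (fg(rr, cc)) {
        # new backtrack: the neighbour examined just before k, expressed as
        # a direction from the new pixel
        prev_k <- if (step == 1) back else ((k - 2L) %% 8L) + 1L
        br <- pr + dr[prev_k]; bc <- pc + dc[prev_k]
        ndr <- br - rr; ndc <- bc - cc
        back <- which(dr == ndr & dc == ndc)
        pr <- rr; pc <- cc
        found <- TRUE
        break
      }
    }
    if (!found) return(cbind(x = pc, y = pr))  # isolated pixel
  }
  stop("contour tracing did not terminate", call. = FALSE)
}

# verify the mask has exactly one 4-connected foreground component
# (vectorized frontier flood fill: one sweep per boundary-distance step)
check_single_component <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  # restrict to the foreground bounding box
  rr <- range(which(rowSums(m) > 0)); cr <- range(which(colSums(m) > 0))
  m <- m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  visited <- matrix(FALSE, nr, nc)
  seed <- which(m, arr.ind = TRUE)[1, ]
  visited[seed[1], seed[2]] <- TRUE
  frontier <- visited
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  while (any(frontier)) {
    grown <- shift(frontier, 1, 0) | shift(frontier, -1, 0) |
      shift(frontier, 0, 1) | shift(frontier, 0, -1)
    frontier <- grown & m & !visited
    visited <- visited | frontier
  }
  if (any(m & !visited))
    stop("mask has multiple foreground components", call. = FALSE)
  invisible(TRUE)
}

polygon_length <- function(xy, closed = TRUE) {
  p <- if (closed) rbind(xy, xy[1, , drop = FALSE]) else xy
  sum(sqrt(rowSums(diff(p)^2)))
}

# equal-arc-length resampling of a closed polygon to n points, point 1 at
# the polygon's first vertex
resample_closed <- function(xy, n) {
  p <- rbind(xy, xy[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  keep <- c(TRUE, seg > 0)
  p <- p[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- seq(0, L, length.out = n + 1)[seq_len(n)]
  xi <- approx(s, p[, 1], xout = target)$y
  yi <- approx(s, p[, 2], xout = target)$y
  cbind(x = xi, y = yi)
}

#' Extract and resample a cell contour to equally spaced points
#'
#' Traces the boundary pixel chain, densely resamples it, applies light
#' circular Gaussian smoothing of the coordinates to remove pixelation
#' jaggedness, and resamples to `n_points` equal arc-length points. Point 1
#' corresponds to the chain start (the upper-left-most boundary pixel)
#' before any frame-to-frame index reset.
#'
#' @param mask binary matrix, single foreground component
#' @param n_points number of boundary points (default 500)
#' @param smooth_sigma Gaussian smoothing scale in units of final contour
#'   points (default 2); 0 disables smoothing
#' @param px_size pixel size (um/px) applied to the output coordinates
#' @return An `n_points` x 2 matrix (`x`, `y`) of contour coordinates.
#' @export
extract_and_resample <- function(mask, n_points = 500, smooth_sigma = 2,
                                 px_size = 1) {
  check_single_component(mask)
  chain <- extract_contour(mask)
  dense_n <- max(4L * n_points, nrow(chain))
  dense <- resample_closed(chain, dense_n)
  if (smooth_sigma > 0) {
    sig <- smooth_sigma * dense_n / n_points
    dense <- cbind(x = circular_gaussian_smooth(dense[, 1], sig),
                   y = circular_gaussian_smooth(dense[, 2], sig))
  }
  resample_closed(dense, n_points) * px_size
}

#' Optimal cyclic linking of two contour frames
#'
#' Finds the orientation-preserving cyclic index shift of the current frame
#' that minimizes the mean squared distance to the previous frame's points,
#' then re-indexes the current frame so that the point linked to the
#' previous frame's index 1 becomes index 1.
#'
#' @param prev,curr n x 2 contour matrices with the same n
#' @return A list with `shift` (0-based optimal shift) and `linked`
#'   (re-indexed current frame).
#' @export
link_frames <- function(prev, curr) {
  n <- nrow(prev)
  stopifnot(nrow(curr) == n)
  zp <- complex(real = prev[, 1], imaginary = prev[, 2])
  zc <- complex(real = curr[, 1], imaginary = curr[, 2])
  # cost(s) = mean |zp_i - zc_{i+s}|^2; the cross term via circular
  # correlation (direct evaluation; n = 500 is small)
  costs <- vapply(0:(n - 1), function(s) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    mean(Mod(zp - zc[idx])^2)
  }, numeric(1))
  s <- which.min(costs) - 1L
  idx <- ((seq_len(n) - 1 + s) %% n) + 1
  list(shift = s, linked = curr[idx, , drop = FALSE], cost = min(costs))
}

contour_orientation <- function(xy) {
  p <- rbind(xy, xy[1, , drop = FALSE])
  a <- sum(p[-nrow(p), 1] * p[-1, 2] - p[-1, 1] * p[-nrow(p), 2]) / 2
  sign(a)
}

# circular convolution with an arbitrary kernel indexed -half..half
circular_filter <- function(x, kern, half) {
  n <- length(x)
  idx <- outer(seq_len(n), seq(-half, half), function(i, d) ((i - 1 + d) %% n) + 1)
  as.numeric(matrix(x[idx], nrow = n) %*% kern)
}

# Tangent angle, curvature (protrusions positive) and outward normal angle
# of one closed contour frame. Derivatives with respect to the point index
# come from derivative-of-Gaussian filters of scale `sigma` points;
# curvature is the standard (x'y'' - y'x'') / |r'|^3. Because the local
# arc element ds = |r'| is taken from the same filtered curve, the
# closed-contour total sum(curvature * ds) is the total turning of the
# filtered curve, i.e. 2*pi, up to discretization. The filter scale is the
# single resolution knob: large enough to suppress the staircase runs of
# rasterized boundaries (which extend ~sqrt(2R) px), small enough to
# resolve protrusion-scale features.
contour_geometry <- function(xy, sigma = 16) {
  n <- nrow(xy)
  half <- min(n %/% 2 - 1, ceiling(5 * sigma))
  t <- seq(-half, half)
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -t / sigma^2 * g
  g2 <- (t^2 / sigma^2 - 1) / sigma^2 * g
  x1 <- circular_filter(xy[, 1], g1, half)
  y1 <- circular_filter(xy[, 2], g1, half)
  x2 <- circular_filter(xy[, 1], g2, half)
  y2 <- circular_filter(xy[, 2], g2, half)
  sp <- sqrt(x1^2 + y1^2)            # local arc element per index step
  curv <- (x1 * y2 - y1 * x2) / sp^3
  theta <- atan2(y1, x1)
  # sign convention: outward-convex boundary (protrusion) positive, so the
  # closed-contour total is +2*pi regardless of traversal orientation
  sgn <- if (sum(curv * sp) < 0) -1 else 1
  curv <- sgn * curv
  # outward normal: rotate the tangent by -sgn * 90 degrees; verify against
  # the centroid and flip globally if needed
  phi <- theta - sgn * pi / 2
  cen <- colMeans(xy)
  outward <- mean(cos(phi) * (xy[, 1] - cen[1]) +
                    sin(phi) * (xy[, 2] - cen[2]))
  if (outward < 0) phi <- phi + pi
  phi <- wrap_angle(phi)
  list(theta = theta, curvature = curv, normal_angle = phi,
       ds = sp, length = polygon_length(xy))
}

#' Build a linked contour series from a mask movie
#'
#' Extracts, resamples and links the contours of consecutive frames of a
#' binary mask movie. After linking, index i refers to (approximately) the
#' same material boundary point across frames.
#'
#' @param masks list of binary matrices (one per frame)
#' @param px_size pixel size, um/px
#' @param delta_t frame interval, s
#' @param n_points boundary points per frame (default 500)
#' @param smooth_sigma contour smoothing scale, in contour points
#' @return An object of class `contour_series`: list with `points`
#'   (`n_points` x 2 x T array, um), `centroid` (T x 2, um, mask pixel
#'   centroids), `delta_t`, `px_size`.
#' @export
contour_series <- function(masks, px_size = 1, delta_t = 1, n_points = 500,
                           smooth_sigma = 2) {
  T_ <- length(masks)
  stopifnot(T_ >= 1)
  pts <- array(NA_real_, c(n_points, 2, T_))
  cen <- matrix(NA_real_, T_, 2)
  for (t in seq_len(T_)) {
    fr <- extract_and_resample(masks[[t]], n_points, smooth_sigma, px_size)
    if (t > 1) fr <- link_frames(pts[, , t - 1], fr)$linked
    pts[, , t] <- fr
    w <- which(masks[[t]] != 0, arr.ind = TRUE)
    cen[t, ] <- c(mean(w[, 2]), mean(w[, 1])) * px_size  # (x, y)
  }
  structure(list(points = pts, centroid = cen, delta_t = delta_t,
                 px_size = px_size),
            class = "contour_series")
}

#' Curvature and normal-velocity kymographs
#'
#' Computes, for a linked contour series, the per-point curvature
#' `c_i(t)` (1/um, protrusions positive), the outward normal angle
#' `phi_i(t)` (rad), and the normal velocity `u_i(t)` (um/s, outward
#' positive) as the displacement of same-index points between consecutive
#' frames projected on the outward normal. Also returns the centroid
#' velocity angle `psi(t)`.
#'
#' @param series a [contour_series()] object
#' @param sigma curvature estimator scale (derivative-of-Gaussian filter
#'   width, in contour points)
#' @return A list of class `kymographs`: `curvature` (n x T),
#'   `normal_angle` (n x T), `velocity` (n x (T-1)), `ds` (n x T local arc
#'   elements), `psi` (length T-1, `NA` where the centroid is stationary),
#'   `delta_t`, `perimeter` (length T).
#' @export
kymographs <- function(series, sigma = 16) {
  stopifnot(inherits(series, "contour_series"))
  pts <- series$points
  n <- dim(pts)[1]; T_ <- dim(pts)[3]
  curv <- matrix(NA_real_, n, T_)
  phi <- matrix(NA_real_, n, T_)
  dsm <- matrix(NA_real_, n, T_)
  perim <- numeric(T_)
  for (t in seq_len(T_)) {
    g <- contour_geometry(pts[, , t], sigma)
    curv[, t] <- g$curvature
    phi[, t] <- g$normal_angle
    dsm[, t] <- g$ds
    perim[t] <- g$length
  }
  if (T_ >= 2) {
    u <- matrix(NA_real_, n, T_ - 1)
    for (t in seq_len(T_ - 1)) {
      dx <- pts[, 1, t + 1] - pts[, 1, t]
      dy <- pts[, 2, t + 1] - pts[, 2, t]
      u[, t] <- (dx * cos(phi[, t]) + dy * sin(phi[, t])) / series$delta_t
    }
    dc <- diff(series$centroid)
    psi <- atan2(dc[, 2], dc[, 1])
    psi[rowSums(dc^2) == 0] <- NA_real_
  } else {
    u <- matrix(NA_real_, n, 0)
    psi <- numeric(0)
  }
  structure(list(curvature = curv, normal_angle = phi, velocity = u,
                 ds = dsm, psi = psi, delta_t = series$delta_t,
                 perimeter = perim),
            class = "kymographs")
}
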