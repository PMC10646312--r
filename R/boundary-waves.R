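# Curvature-wave classification, tracking, leading-edge lifetimes and the
# persistence-time estimator.

#' Multi-level Otsu thresholds
#'
#' Exhaustive maximization of the between-class variance of a histogram
#' over `n_classes - 1` thresholds (two thresholds for the three-class
#' protrusive / flat / caved split of a curvature kymograph).
#'
#' @param x numeric values
#' @param n_classes number of classes (2 or 3)
#' @param n_bins histogram resolution
#' @return Sorted numeric vector of thresholds (length `n_classes - 1`).
#' @export
otsu_thresholds <- function(x, n_classes = 3, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0)
    stop("constant input: Otsu thresholds undefined", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  class_stat <- function(i, j) {
    # weight and mean of bins (i+1):j ; i, j are cumulative indices, i < j
    ww <- cw[j] - if (i == 0) 0 else cw[i]
    if (ww <= 0) return(c(0, 0))
    mm <- (cm[j] - if (i == 0) 0 else cm[i]) / ww
    c(ww, mm)
  }
  mu <- cm[n_bins]
  best <- -Inf; best_t <- NULL
  if (n_classes == 2) {
    for (t1 in 1:(n_bins - 1)) {
      s1 <- class_stat(0, t1); s2 <- class_stat(t1, n_bins)
      v <- s1[1] * (s1[2] - mu)^2 + s2[1] * (s2[2] - mu)^2
      if (v > best) { best <- v; best_t <- mids[t1] }
    }
  } else if (n_classes == 3) {
    for (t1 in 1:(n_bins - 2)) {
      s1 <- class_stat(0, t1)
      for (t2 in (t1 + 1):(n_bins - 1)) {
        s2 <- class_stat(t1, t2); s3 <- class_stat(t2, n_bins)
        v <- s1[1] * (s1[2] - mu)^2 + s2[1] * (s2[2] - mu)^2 +
          s3[1] * (s3[2] - mu)^2
        if (v > best) { best <- v; best_t <- c(mids[t1], mids[t2]) }
      }
    }
  } else stop("n_classes must be 2 or 3", call. = FALSE)
  sort(best_t)
}

# circular runs of TRUE in a logical vector (ring topology); returns a list
# of integer index vectors, each a contiguous arc
circular_runs <- function(b) {
  n <- length(b)
  if (!any(b)) return(list())
  if (all(b)) return(list(seq_len(n)))
  # rotate so position 1 is FALSE, take linear runs, rotate back
  z <- which(!b)[1]
  rot <- c(z:n, seq_len(z - 1))
  br <- b[rot]
  r <- rle(br)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k])
      out[[length(out) + 1]] <- rot[starts[k]:ends[k]]
  }
  out
}

# fragment centre index per the periodic midpoint rule: mean of the two arc
# ends, shifted by n/2 when the arc wraps
fragment_center <- function(iL, iR, n) {
  if (iL <= iR) (iL + iR) / 2
  else if (iL + iR <= n) (iL + iR + n) / 2
  else (iL + iR - n) / 2
}

#' Classify curvature kymograph and track protrusive waves
#'
#' Splits the curvature kymograph into three classes (caved / flat /
#' protrusive) using two Otsu thresholds `c1 < c2` computed over the whole
#' kymograph, extracts contiguous protrusive fragments per frame (with
#' periodic wraparound), links fragments in consecutive frames whenever
#' their index supports overlap, and computes the per-link angular velocity
#' of the wave's outward normal at the fragment centre (angle differences
#' wrapped to (-pi, pi]). The representative angular velocity `omega_c` is
#' the maximum-likelihood scale of an exponential distribution fitted to
#' the absolute angular velocities (i.e. their sample mean); a histogram
#' least-squares fit is available via `omega_method = "histogram"`.
#'
#' @param kym a [kymographs()] object (or a list with `curvature`,
#'   `normal_angle`, `delta_t`)
#' @param omega_method `"mle"` (default) or `"histogram"`
#' @return An object of class `wave_track`: list with `c1`, `c2`,
#'   `fragments` (data frame: `frame`, `id`, `i_l`, `i_r`, `center`,
#'   `angle`), `links` (data frame: `frame`, `id`, `id_next`, `omega`),
#'   `omega_c`, `delta_t`, and `members` (list of per-frame lists of index
#'   vectors).
#' @export
classify_and_track_waves <- function(kym, omega_method = c("mle", "histogram")) {
  omega_method <- match.arg(omega_method)
  curv <- kym$curvature
  phi <- kym$normal_angle
  dt <- kym$delta_t
  n <- nrow(curv); T_ <- ncol(curv)
  th <- tryCatch(otsu_thresholds(as.numeric(curv), 3),
                 error = function(e) NULL)
  if (is.null(th)) {
    warning("degenerate curvature kymograph: no waves detected")
    return(structure(list(c1 = NA_real_, c2 = NA_real_,
                          fragments = NULL, links = NULL,
                          omega_c = NA_real_, delta_t = dt,
                          members = vector("list", T_)),
                     class = "wave_track"))
  }
  c1 <- th[1]; c2 <- th[2]

  members <- vector("list", T_)
  frag_rows <- list()
  for (t in seq_len(T_)) {
    runs <- circular_runs(curv[, t] > c2)
    members[[t]] <- runs
    for (j in seq_along(runs)) {
      arc <- runs[[j]]
      iL <- arc[1]; iR <- arc[length(arc)]
      ctr <- if (length(arc) == n) arc[which.max(curv[arc, t])]
      else fragment_center(iL, iR, n)
      ci <- ((round(ctr) - 1) %% n) + 1
      frag_rows[[length(frag_rows) + 1]] <-
        data.frame(frame = t, id = j, i_l = iL, i_r = iR,
                   center = ctr, angle = phi[ci, t])
    }
  }
  fragments <- if (length(frag_rows)) do.call(rbind, frag_rows) else NULL

  link_rows <- list()
  for (t in seq_len(max(T_ - 1, 0))) {
    a <- members[[t]]; b <- members[[t + 1]]
    if (!length(a) || !length(b)) next
    occ <- logical(n)
    for (j in seq_along(a)) {
      occ[] <- FALSE; occ[a[[j]]] <- TRUE
      for (j2 in seq_along(b)) {
        if (any(occ[b[[j2]]])) {
          ang_a <- fragments$angle[fragments$frame == t & fragments$id == j]
          ang_b <- fragments$angle[fragments$frame == t + 1 &
                                     fragments$id == j2]
          link_rows[[length(link_rows) + 1]] <-
            data.frame(frame = t, id = j, id_next = j2,
                       omega = wrap_angle(ang_b - ang_a) / dt)
        }
      }
    }
  }
  links <- if (length(link_rows)) do.call(rbind, link_rows) else NULL

  omega_c <- if (is.null(links) || !nrow(links)) NA_real_
  else if (omega_method == "mle") mean(abs(links$omega))
  else {
    ab <- abs(links$omega)
    h <- hist(ab, breaks = "FD", plot = FALSE)
    pos <- h$density > 0
    if (sum(pos) < 2) mean(ab)
    else -1 / unname(coef(lm(log(h$density[pos]) ~ h$mids[pos]))[2])
  }
  structure(list(c1 = c1, c2 = c2, fragments = fragments, links = links,
                 omega_c = omega_c, delta_t = dt, members = members),
            class = "wave_track")
}

#' Leading-edge selection and lifetimes
#'
#' Selects, in each frame, the protrusive fragment whose outward-normal
#' angle at the fragment centre is circularly closest to the centroid
#' velocity angle `psi(t)` (the leading edge), then measures its lifetimes:
#' break times are frames `t` at which the chosen fragments at `t` and
#' `t+1` are not linked, and each lifetime is the spacing of consecutive
#' break times minus one frame interval. Frames with no fragments or with
#' undefined `psi` are excised and lifetimes never bridge the gaps. The
#' representative lifetime `tau_d` is the exponential maximum-likelihood
#' scale (the sample mean) of the lifetimes.
#'
#' @param track a [classify_and_track_waves()] result
#' @param psi centroid velocity angles, one per velocity frame (rad; `NA`
#'   where undefined)
#' @return A list with `leading` (data frame: `frame`, `id`, `angle`),
#'   `lifetimes` (s), and `tau_d` (s).
#' @export
leading_edge_lifetimes <- function(track, psi) {
  stopifnot(inherits(track, "wave_track"))
  fr <- track$fragments
  dt <- track$delta_t
  if (is.null(fr))
    return(list(leading = NULL, lifetimes = numeric(0), tau_d = NA_real_))
  T_ <- min(length(psi), max(fr$frame))
  lead <- rep(NA_integer_, T_)
  lead_ang <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    if (is.na(psi[t])) next
    sub <- fr[fr$frame == t, ]
    if (!nrow(sub)) next
    d <- abs(wrap_angle(sub$angle - psi[t]))
    k <- which.min(d)
    lead[t] <- sub$id[k]
    lead_ang[t] <- sub$angle[k]
  }
  has_link <- function(t, j, j2) {
    !is.null(track$links) &&
      any(track$links$frame == t & track$links$id == j &
            track$links$id_next == j2)
  }
  lifetimes <- numeric(0)
  valid <- which(!is.na(lead))
  if (length(valid) >= 2) {
    # contiguous runs of valid frames; break times inside each run
    runs <- split(valid, cumsum(c(1, diff(valid) != 1)))
    for (rn in runs) {
      if (length(rn) < 2) next
      breaks <- rn[vapply(rn[-length(rn)], function(t)
        !has_link(t, lead[t], lead[t + 1]), logical(1))]
      if (length(breaks) >= 2)
        lifetimes <- c(lifetimes, diff(breaks) * dt - dt)
    }
  }
  tau_d <- if (length(lifetimes)) mean(lifetimes) else NA_real_
  list(leading = data.frame(frame = seq_len(T_), id = lead,
                            angle = lead_ang),
       lifetimes = lifetimes, tau_d = tau_d)
}

#' Closed-form persistence time of the centroid direction
#'
#' For a centroid velocity angle performing a 1D persistent random walk
#' with step time `tau_d` and step size `omega_c * tau_d`, the direction
#' autocorrelation decays as `exp(-omega_c^2 tau_d t / 4)`; the estimated
#' decay time is
#' \deqn{T_{est} = \frac{4}{\omega_c^2 \tau_d}.}
#'
#' @param omega_c representative wave angular velocity, rad/s (> 0)
#' @param tau_d representative leading-edge lifetime, s (> 0)
#' @return The persistence time, s.
#' @examples
#' estimate_persistence_time(0.1, 2.8)  # ~142.9 s
#' @export
estimate_persistence_time <- function(omega_c, tau_d) {
  if (!is.finite(omega_c) || !is.finite(tau_d) || omega_c <= 0 || tau_d <= 0)
    stop("omega_c and tau_d must be positive", call. = FALSE)
  4 / (omega_c^2 * tau_d)
}

#' Fit the front/rear joint cosine profile to a normal-velocity profile
#'
#' Smooths one frame's normal-velocity profile with the piecewise joint
#' function: `A1 cos(pi d(i, C(I)) / L(I))` on a contiguous front arc `I`
#' bounded by `(i1, i2)` and `-A2 cos(pi d(i, Cbar(I)) / (n - L(I)))` on
#' the complementary rear arc, where `d` is the circular index distance and
#' the centres/length follow the periodic midpoint rules. The arc ends are
#' found by exhaustive search on a coarse grid (stride `stride`) followed
#' by local refinement; given the arc, the nonnegative amplitudes are the
#' (independent) linear least-squares solutions on the two disjoint
#' supports.
#'
#' @param u numeric normal-velocity profile (length n = number of boundary
#'   points)
#' @param stride coarse-grid stride for the arc-end search (default 5)
#' @return A list with `i1`, `i2`, `A1`, `A2`, `center_front`,
#'   `center_rear`, `L`, `fitted`, `rss`, `degenerate`.
#' @export
fit_front_rear <- function(u, stride = 5) {
  n <- length(u)
  if (all(u == 0) || all(!is.finite(u)))
    return(list(i1 = NA, i2 = NA, A1 = 0, A2 = 0, center_front = NA,
                center_rear = NA, L = NA, fitted = rep(0, n), rss = 0,
                degenerate = TRUE))
  idx <- seq_len(n)
  circ_dist <- function(i, c) pmin(abs(i - c), n - abs(i - c))

  eval_pair <- function(i1, i2) {
    L <- if (i1 <= i2) i2 - i1 else n - (i1 - i2)
    if (L < 2 || L > n - 2) return(NULL)
    in_front <- if (i1 <= i2) idx >= i1 & idx <= i2 else idx >= i1 | idx <= i2
    Cf <- fragment_center(i1, i2, n)
    Cr <- fragment_center(i2, i1, n)  # rear midpoint: swapped ends
    f <- cos(pi * circ_dist(idx[in_front], Cf) / L)
    g <- cos(pi * circ_dist(idx[!in_front], Cr) / (n - L))
    uf <- u[in_front]; ug <- u[!in_front]
    A1 <- max(0, sum(uf * f) / sum(f^2))
    A2 <- max(0, -sum(ug * g) / sum(g^2))
    fitted <- numeric(n)
    fitted[in_front] <- A1 * f
    fitted[!in_front] <- -A2 * g
    list(i1 = i1, i2 = i2, A1 = A1, A2 = A2, center_front = Cf,
         center_rear = Cr, L = L, fitted = fitted,
         rss = sum((u - fitted)^2), degenerate = FALSE)
  }

  grid <- seq(1, n, by = stride)
  best <- NULL
  for (i1 in grid) for (i2 in grid) {
    r <- eval_pair(i1, i2)
    if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
  }
  if (is.null(best))
    return(list(i1 = NA, i2 = NA, A1 = 0, A2 = 0, center_front = NA,
                center_rear = NA, L = NA, fitted = rep(0, n), rss = NA,
                degenerate = TRUE))
  for (i1 in (best$i1 - stride):(best$i1 + stride)) {
    for (i2 in (best$i2 - stride):(best$i2 + stride)) {
      r <- eval_pair(((i1 - 1) %% n) + 1, ((i2 - 1) %% n) + 1)
      if (!is.null(r) && r$rss < best$rss) best <- r
    }
  }
  best
}
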