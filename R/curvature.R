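# Signed membrane curvature by least-squares sphere fitting.
#
# |H| is the reciprocal of the radius of the best-fit sphere through the
# selected lipid head beads; the sign is positive when the membrane curves
# away from the cytoplasmic leaflet (cytoplasmic leaflet convex) and
# negative when it curves toward it.

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud by Gauss-Newton minimization of the
#' geometric residuals `sum((|x - c| - r)^2)`, started from two
#' independent initializations: the algebraic linear least-squares solution
#' (minimizing `sum((|x - c|^2 - r^2)^2)` via the linearized normal
#' equations) and an osculating-paraboloid estimate built from the best-fit
#' plane. The candidate with the smaller geometric sum of squares wins; the
#' reported `rms_residual` is the geometric RMS distance of the points from
#' the fitted surface. The second start matters for double-layer inputs
#' (e.g. head beads of both leaflets fitted jointly): there the algebraic
#' solution can sit in a spurious local minimum that wraps a small sphere
#' through both layers instead of following the mid-surface.
#'
#' Planar (coplanar) input makes the algebraic system rank-deficient; such
#' point sets, point sets fitted at least as well by a plane as by any
#' sphere candidate, and fits whose radius exceeds `flat_radius_cutoff`,
#' are flagged flat (`flat_flag = TRUE`) and treated as zero curvature
#' downstream. The default cutoff of 100 nm declares curvature below
#' 0.01 1/nm indistinguishable from flat at bicelle scale.
#'
#' @param points numeric `n x 3` matrix (nm), `n >= 4`.
#' @param flat_radius_cutoff radius (nm) above which the patch is flat.
#' @return object of class `"sphere_fit"`: `center` (nm), `radius` (nm),
#'   `rms_residual` (nm), `n_points`, `flat_flag`.
#' @export
fit_sphere <- function(points, flat_radius_cutoff = 100) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be n x 3", call. = FALSE)
  n <- nrow(points)
  if (n < 4) stop("sphere fit requires at least 4 points", call. = FALSE)
  if (!all(is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  spread <- max(apply(points, 2, function(v) diff(range(v))))
  if (spread == 0) {
    stop("degenerate input: all points identical", call. = FALSE)
  }

  mu <- colMeans(points)
  P <- sweep(points, 2, mu)

  # Best-fit plane through the centroid (degeneracy checks and the
  # paraboloid/large-radius starting points below).
  sv_P <- svd(P)
  nvec <- sv_P$v[, 3]
  h <- as.vector(P %*% nvec)
  ss_plane <- sum(h^2)

  starts <- list()

  # Start 1: algebraic (Coope) solution on centered coordinates.
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  svA <- svd(A, nu = 0, nv = 0)$d
  if (svA[4] > max(svA[1], 1) * 1e-10) {       # rank 4: not coplanar
    beta <- qr.coef(qr(A), b)
    ctr <- beta[1:3]
    r2 <- beta[4] + sum(ctr^2)
    if (is.finite(r2) && r2 > 0) {
      starts$algebraic <- list(center = ctr, radius = sqrt(r2))
    }
  } else {
    return(flat_fit(mu, n, ss_plane))           # exactly coplanar input
  }

  # Start 2: osculating paraboloid about the best-fit plane,
  # h ~ h0 + rho^2 / (2 R) with rho the in-plane distance; R signed, so
  # the start lands on the correct side.
  rho2 <- rowSums(P^2) - h^2
  vr <- sum((rho2 - mean(rho2))^2)
  if (vr > 0) {
    bq <- sum((rho2 - mean(rho2)) * (h - mean(h))) / vr
    if (abs(bq) > 1e-12 && is.finite(1 / (2 * bq))) {
      R <- 1 / (2 * bq)
      starts$paraboloid <- list(center = (mean(h) - R) * nvec,
                                radius = abs(R))
    }
  }

  # Starts 3/4: near-planar spheres on either side of the best-fit plane.
  # With the backtracked Gauss-Newton these track the shallow valley of
  # the objective down to gently curved solutions that both other starts
  # miss on double-layer (two-leaflet) input.
  R0 <- max(100 * flat_radius_cutoff, 100 * max(abs(h), 1))
  starts$plane_pos <- list(center = R0 * nvec, radius = R0)
  starts$plane_neg <- list(center = -R0 * nvec, radius = R0)

  best <- NULL
  for (s in starts) {
    cand <- sphere_gn_cpp(P, s$center, s$radius)
    ss <- cand[5]
    if (is.finite(ss) && (is.null(best) || ss < best[5])) best <- cand
  }
  # Flat when no sphere candidate beats the best-fit plane (the flat
  # limit of the sphere family) or the winning radius exceeds the cutoff.
  if (is.null(best) || best[4] > flat_radius_cutoff || best[4] <= 0 ||
      ss_plane <= best[5] * (1 + 1e-12)) {
    return(flat_fit(mu, n, ss_plane))
  }
  structure(list(center = best[1:3] + mu, radius = best[4],
                 rms_residual = sqrt(best[5] / n), n_points = n,
                 flat_flag = FALSE),
            class = "sphere_fit")
}

flat_fit <- function(mu, n, ss_plane) {
  structure(list(center = rep(NA_real_, 3),
                 radius = Inf, rms_residual = sqrt(ss_plane / n),
                 n_points = n, flat_flag = TRUE),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  if (x$flat_flag) {
    cat(sprintf("<sphere_fit> flat (n=%d, rms=%.3g nm)\n",
                x$n_points, x$rms_residual))
  } else {
    cat(sprintf(
      "<sphere_fit> r=%.4g nm, center=(%.3g, %.3g, %.3g), rms=%.3g nm, n=%d\n",
      x$radius, x$center[1], x$center[2], x$center[3], x$rms_residual,
      x$n_points))
  }
  invisible(x)
}

# Default fit selection: head beads of long-chain lipids from both leaflets;
# rim (short-chain) lipids sit on the high-curvature bicelle edge and are
# excluded. Fitting both leaflets jointly approximates the mid-surface.
default_fit_selection <- function(topology) {
  topology$entity_kind == "lipid" & topology$role == "head" &
    topology$leaflet %in% c("cytoplasmic", "luminal")
}

#' Signed membrane curvature of one frame
#'
#' `|H| = 1/radius` of the sphere fitted to the selected beads (0 when the
#' fit is flat). The sign is `+1` when the mean distance of
#' cytoplasmic-leaflet beads from the fitted center exceeds that of
#' luminal-leaflet beads -- i.e. the cytoplasmic leaflet is the convex one
#' and the membrane curves away from the cytoplasm -- and `-1` otherwise.
#'
#' @param traj a [trajectory()].
#' @param frame frame number (1-based).
#' @param fit_selection bead selector for the sphere fit (see
#'   [select_beads()]); default: head beads of long-chain lipids, both
#'   leaflets, rim excluded.
#' @param flat_radius_cutoff see [fit_sphere()].
#' @return signed curvature H (1/nm).
#' @export
signed_curvature <- function(traj, frame = 1,
                             fit_selection = default_fit_selection,
                             flat_radius_cutoff = 100) {
  topo <- traj$topology
  keep <- resolve_selector(topo, fit_selection)
  if (!any(keep)) stop("curvature fit selection is empty", call. = FALSE)
  sel <- topo[keep, , drop = FALSE]
  has_cyt <- any(sel$leaflet == "cytoplasmic")
  has_lum <- any(sel$leaflet == "luminal")
  if (!has_cyt || !has_lum) {
    stop("signed curvature needs beads from both the cytoplasmic and the ",
         "luminal leaflet in the fit selection; run leaflet assignment or ",
         "supply leaflet labels", call. = FALSE)
  }
  pts <- frame_coords(traj, frame)[keep, , drop = FALSE]
  fit <- fit_sphere(pts, flat_radius_cutoff = flat_radius_cutoff)
  if (fit$flat_flag) return(0)
  d <- sqrt(rowSums(sweep(pts, 2, fit$center)^2))
  sign_h <- if (mean(d[sel$leaflet == "cytoplasmic"]) >
                mean(d[sel$leaflet == "luminal"])) 1 else -1
  sign_h / fit$radius
}

#' Construct a curvature time series
#'
#' @param times frame times (ns), increasing.
#' @param H signed curvature per frame (1/nm).
#' @param smoothed whether the series has been smoothed.
#' @param window smoothing window (ns), required iff `smoothed`.
#' @param source replicate identifier (free-form string).
#' @return object of class `"curvature_series"`.
#' @export
curvature_series_new <- function(times, H, smoothed = FALSE, window = NULL,
                                 source = "") {
  stopifnot(length(times) == length(H))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (smoothed && (is.null(window) || window <= 0)) {
    stop("a smoothed series must record a positive window", call. = FALSE)
  }
  structure(list(times = as.numeric(times), H = as.numeric(H),
                 smoothed = smoothed, window = window, source = source),
            class = "curvature_series")
}

#' @export
print.curvature_series <- function(x, ...) {
  cat(sprintf("<curvature_series> %d samples%s%s\n", length(x$times),
              if (x$smoothed) sprintf(", smoothed (%g ns window)", x$window)
              else ", raw",
              if (nzchar(x$source)) paste0(", source=", x$source) else ""))
  invisible(x)
}

#' @export
as.data.frame.curvature_series <- function(x, ...) {
  data.frame(time_ns = x$times, H = x$H)
}

#' Per-frame signed curvature of a trajectory
#'
#' @inheritParams signed_curvature
#' @param source replicate identifier recorded in the series.
#' @return an unsmoothed [curvature_series_new()] with one `H` per frame.
#' @export
curvature_series <- function(traj, fit_selection = default_fit_selection,
                             flat_radius_cutoff = 100, source = "") {
  nf <- n_frames(traj)
  H <- numeric(nf)
  for (k in seq_len(nf)) {
    H[k] <- tryCatch(
      signed_curvature(traj, k, fit_selection, flat_radius_cutoff),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  curvature_series_new(traj$times, H, smoothed = FALSE, source = source)
}

#' Smooth a curvature series with a centered running mean
#'
#' Each output sample is the mean of all input samples within
#' `window / 2` ns of its time (the window shrinks symmetrically at the
#' edges, so output length equals input length). The default 11-ns window
#' matches the convention used for reporting curvature traces. Smoothing an
#' already-smoothed series is an error: the recorded window would no longer
#' describe the effective filter.
#'
#' @param series an unsmoothed [curvature_series_new()].
#' @param window averaging window (ns).
#' @return smoothed series with `smoothed = TRUE` and the window recorded.
#' @export
smooth_series <- function(series, window = 11) {
  stopifnot(inherits(series, "curvature_series"))
  if (series$smoothed) {
    stop("series is already smoothed; double smoothing is not supported",
         call. = FALSE)
  }
  if (window <= 0) stop("window must be positive", call. = FALSE)
  t <- series$times
  H <- series$H
  n <- length(t)
  half <- window / 2
  out <- numeric(n)
  # two-pointer sweep over the (sorted) times
  lo <- 1L; hi <- 0L; acc <- 0
  for (i in seq_len(n)) {
    while (hi < n && t[hi + 1L] <= t[i] + half) {
      hi <- hi + 1L; acc <- acc + H[hi]
    }
    while (t[lo] < t[i] - half) {
      acc <- acc - H[lo]; lo <- lo + 1L
    }
    out[i] <- acc / (hi - lo + 1L)
  }
  curvature_series_new(t, out, smoothed = TRUE, window = window,
                       source = series$source)
}
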