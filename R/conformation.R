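# Conformational-ensemble shape statistics: radius of gyration, Kabsch
# superposition, RMSF, pairwise RMSD and gromos clustering.

#' Radius of gyration of one frame
#'
#' `Rg = sqrt(sum(w_i |x_i - xbar|^2) / sum(w_i))` with `xbar` the
#' (weighted) centroid. Beads are unweighted by default: coarse-grained
#' backbone beads have near-uniform masses, so equal weights are the
#' natural choice; a mass vector may be supplied.
#'
#' @param traj a [trajectory()].
#' @param frame frame number (1-based).
#' @param selection bead selector (see [select_beads()]); default all beads.
#' @param masses optional non-negative weight per selected bead.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(traj, frame = 1, selection = NULL,
                               masses = NULL) {
  keep <- resolve_selector(traj$topology, selection)
  if (!any(keep)) stop("selection matches no beads", call. = FALSE)
  X <- frame_coords(traj, frame)[keep, , drop = FALSE]
  w <- if (is.null(masses)) rep(1, nrow(X)) else as.numeric(masses)
  if (length(w) != nrow(X)) {
    stop("masses must match the number of selected beads", call. = FALSE)
  }
  if (any(w < 0)) stop("masses must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("total mass must be positive", call. = FALSE)
  ctr <- colSums(X * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(X, 2, ctr)^2)) / sum(w))
}

#' Per-frame radius of gyration
#' @inheritParams radius_of_gyration
#' @return numeric vector, one Rg (nm) per frame.
#' @export
rg_trace <- function(traj, selection = NULL, masses = NULL) {
  vapply(seq_len(n_frames(traj)), function(k) {
    radius_of_gyration(traj, k, selection, masses)
  }, 0)
}

#' Probability density of the radius of gyration
#'
#' Gaussian kernel density over the per-frame Rg values; the bandwidth
#' defaults to Silverman's rule of thumb and the grid spans the data plus
#' three bandwidths on either side. A zero-variance ensemble yields a
#' delta-like density and is flagged.
#'
#' @param traj a [trajectory()] with at least 10 frames.
#' @param selection bead selector; default all beads.
#' @param bandwidth `"auto"` (Silverman) or a bandwidth in nm.
#' @param n_grid number of grid points.
#' @return object of class `"rg_density"`: `grid` (nm), `density` (1/nm),
#'   `bandwidth` (nm), `n` (frames), `delta_like` flag.
#' @export
rg_density <- function(traj, selection = NULL, bandwidth = "auto",
                       n_grid = 512) {
  if (n_frames(traj) < 10) {
    stop("rg_density requires at least 10 frames", call. = FALSE)
  }
  rg <- rg_trace(traj, selection)
  delta_like <- sd(rg) == 0
  bw <- if (identical(bandwidth, "auto")) {
    if (delta_like) 1e-3 else bw.nrd0(rg)
  } else {
    as.numeric(bandwidth)
  }
  d <- density(rg, bw = bw, n = n_grid, from = min(rg) - 3 * bw,
               to = max(rg) + 3 * bw)
  structure(list(grid = d$x, density = d$y, bandwidth = bw, n = length(rg),
                 delta_like = delta_like),
            class = "rg_density")
}

#' @export
print.rg_density <- function(x, ...) {
  cat(sprintf("<rg_density> n=%d frames, bw=%.4g nm%s\n", x$n, x$bandwidth,
              if (x$delta_like) " (delta-like: zero variance)" else ""))
  invisible(x)
}

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation (determinant +1; reflections are rejected, so
#' a mirror image of a chiral structure retains a positive RMSD) and
#' translation minimizing the RMSD over the fit selection, and applies the
#' transform to all beads of `mobile`.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm).
#' @param fit_selection indices or logical vector of rows used for the fit
#'   (default: all). At least 3 non-collinear positions are required.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (nm, over the fit selection) and `coords` (all transformed mobile
#'   beads).
#' @export
kabsch_superpose <- function(mobile, reference, fit_selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  sel <- if (is.null(fit_selection)) seq_len(nrow(mobile)) else fit_selection
  if (is.logical(sel)) sel <- which(sel)
  A <- mobile[sel, , drop = FALSE]
  Bm <- reference[sel, , drop = FALSE]
  if (nrow(A) != nrow(Bm)) {
    stop("fit selections must have equal bead counts", call. = FALSE)
  }
  if (nrow(A) < 3) stop("superposition needs at least 3 fit beads",
                        call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(Bm)
  Ac <- sweep(A, 2, ca); Bc <- sweep(Bm, 2, cb)
  sv_check <- svd(Ac)$d
  if (sv_check[2] < 1e-10 * max(sv_check[1], 1)) {
    stop("degenerate (collinear) fit selection", call. = FALSE)
  }
  C <- crossprod(Ac, Bc)  # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- cb - as.vector(R %*% ca)
  moved_sel <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved_sel - Bc)^2)))
  coords <- sweep(mobile %*% t(R), 2, translation, `+`)
  list(rotation = R, translation = translation, rmsd = rmsd,
       coords = coords)
}

#' Root mean square fluctuation per bead
#'
#' Frames are superposed via the fit selection and the RMSF of each
#' reported bead about its ensemble-mean position is computed. The
#' reference is the post-superposition mean structure (two passes: frames
#' are first superposed onto the first frame, their mean is computed, and
#' all frames are re-superposed onto that mean before the final
#' fluctuations are taken).
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param fit_selection bead selector used for the superposition (default
#'   all beads).
#' @param report_selection bead selector for the reported RMSF values
#'   (default all beads).
#' @return numeric vector of RMSF values (nm), one per reported bead, with
#'   bead indices as names.
#' @export
rmsf <- function(traj, fit_selection = NULL, report_selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF requires at least 2 frames", call. = FALSE)
  fit_keep <- resolve_selector(traj$topology, fit_selection)
  rep_keep <- resolve_selector(traj$topology, report_selection)
  if (!any(fit_keep) || !any(rep_keep)) {
    stop("empty bead selection", call. = FALSE)
  }
  align_to <- function(ref) {
    arr <- array(NA_real_, dim = dim(traj$coords))
    for (k in seq_len(nf)) {
      arr[k, , ] <- kabsch_superpose(frame_coords(traj, k), ref,
                                     fit_selection = fit_keep)$coords
    }
    arr
  }
  pass1 <- align_to(frame_coords(traj, 1))
  mean1 <- apply(pass1, c(2, 3), mean)
  arr <- array(NA_real_, dim = dim(traj$coords))
  for (k in seq_len(nf)) {
    arr[k, , ] <- kabsch_superpose(matrix(pass1[k, , ], ncol = 3), mean1,
                                   fit_selection = fit_keep)$coords
  }
  mean2 <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), mean2)
  msf <- apply(dev2^2, 2, sum) / nf  # summed over x,y,z, averaged over frames
  out <- sqrt(msf)[rep_keep]
  names(out) <- traj$topology$index[rep_keep]
  out
}

#' Pairwise RMSD matrix after optimal superposition
#'
#' Entry `(i, j)` is the minimal (Kabsch, proper-rotation) RMSD between
#' frames `i` and `j` over the selected beads. Computed in compiled code;
#' the matrix is exactly symmetric with a zero diagonal.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection bead selector (default all beads).
#' @return symmetric `n_frames x n_frames` matrix (nm).
#' @export
pairwise_rmsd <- function(traj, selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("pairwise RMSD requires at least 2 frames",
                   call. = FALSE)
  keep <- resolve_selector(traj$topology, selection)
  if (sum(keep) < 3) {
    stop("pairwise RMSD requires at least 3 selected beads", call. = FALSE)
  }
  sub <- traj$coords[, keep, , drop = FALSE]
  nb <- dim(sub)[2]
  # center every frame once; pack as (beads x 3 x frames) cube
  cube <- array(NA_real_, dim = c(nb, 3, nf))
  for (k in seq_len(nf)) {
    X <- matrix(sub[k, , ], ncol = 3)
    cube[, , k] <- sweep(X, 2, colMeans(X))
  }
  m <- pairwise_rmsd_cpp(cube)
  m
}

#' gromos clustering of a distance matrix
#'
#' Greedy neighbor-counting clustering: among the unassigned frames, the
#' frame with the most neighbors within `cutoff` (distance `<= cutoff`,
#' self excluded; ties broken by lowest frame index) becomes a cluster
#' center; it and its neighbors form the cluster and are removed, and the
#' procedure repeats until every frame is assigned. Singletons are allowed.
#' Extraction order is non-increasing in cluster size, so populations are
#' reported in descending order.
#'
#' @param mat square symmetric distance matrix with zero diagonal (nm).
#' @param cutoff neighbor cutoff (nm); 0.8 nm is the conventional backbone
#'   RMSD cutoff for coarse-grained protein ensembles.
#' @return object of class `"gromos_clustering"`: `assignments` (cluster id
#'   per frame, 1-based in extraction order), `centers` (frame index of
#'   each cluster's representative, 1-based), `populations` (fraction per
#'   cluster, descending), `cutoff`, `n_frames`.
#' @export
gromos_cluster <- function(mat, cutoff = 0.8) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n != ncol(mat)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(mat - t(mat))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(mat)) > 1e-8)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  adj <- (mat <= cutoff)
  diag(adj) <- FALSE
  assignments <- integer(n)
  centers <- integer(0)
  sizes <- integer(0)
  remaining <- rep(TRUE, n)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    counts <- colSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]  # which.max: first max = lowest index
    members <- c(center, idx[adj[center, idx]])
    members <- unique(members)
    assignments[members] <- cl
    centers[cl] <- center
    sizes[cl] <- length(members)
    remaining[members] <- FALSE
  }
  structure(list(assignments = assignments, centers = centers,
                 populations = sizes / n, cutoff = cutoff, n_frames = n),
            class = "gromos_clustering")
}

#' @export
print.gromos_clustering <- function(x, ...) {
  k <- length(x$centers)
  top <- head(x$populations, 3)
  cat(sprintf(
    "<gromos_clustering> %d clusters over %d frames (cutoff %g nm); top: %s\n",
    k, x$n_frames, x$cutoff,
    paste(sprintf("%.1f%%", 100 * top), collapse = ", ")))
  invisible(x)
}

#' Evenly subsample the frames of a trajectory
#'
#' Frames at indices `round(k (N - 1) / (n - 1))` for `k = 0 .. n-1`
#' (0-based; R's round-half-to-even), deduplicated, so a request larger
#' than the trajectory returns every frame once. "Evenly sampled" is
#' implemented as a deterministic stride, not random subsampling.
#'
#' @param traj a [trajectory()].
#' @param n number of frames requested (default 10000, the conventional
#'   ensemble size for conformational clustering).
#' @return trajectory of at most `n` frames.
#' @export
subsample_evenly <- function(traj, n = 10000) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  N <- n_frames(traj)
  if (n == 1) {
    idx0 <- 0
  } else {
    idx0 <- unique(round((0:(n - 1)) * (N - 1) / (n - 1)))
  }
  subset_frames(traj, idx0 + 1L)
}
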