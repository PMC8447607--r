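# Ground-truth-labeled synthetic inputs for the analysis stages: bicelle
# deformation trajectories, shifted-exponential waiting-time ensembles, and
# multi-state conformational ensembles.

#' Parameters for the synthetic bicelle generator
#'
#' Defines the study conditions under which bicelle-to-vesicle transitions
#' are emulated. The mid-surface of the patch is a spherical cap of fixed
#' area `membrane_area` whose curvature follows a linear ramp: `H(t) = 0`
#' before a stochastic event time `event = tau + Exp(k_prime)`, then rises
#' linearly to `H_vesicle` over `closure_duration` and holds. Lipid head
#' beads are placed quasi-uniformly (Fibonacci lattice) on the two leaflet
#' surfaces offset `leaflet_offset / 2` along the local normal on either
#' side of the mid-surface, with the cytoplasmic leaflet on the convex side;
#' short-chain rim lipids sit on the cap boundary circle. Isotropic Gaussian
#' jitter of sd `noise_sigma` emulates thermal disorder.
#'
#' Default sizes (300 long-chain / 100 rim lipids, one head bead per lipid)
#' are synthetic fixture choices; `membrane_area` defaults to half the
#' long-lipid count times a typical 0.6 nm^2 area per lipid.
#'
#' @param n_long_lipids long-chain (DMPC-like) lipid count, split evenly
#'   over the two leaflets; at least 50.
#' @param n_rim_lipids short-chain (DHPC-like) rim lipid count.
#' @param membrane_area mid-surface area (nm^2), conserved during
#'   deformation.
#' @param leaflet_offset distance between the two leaflet surfaces (nm).
#' @param k_prime true transition rate (1/ns).
#' @param tau true lag time (ns).
#' @param closure_duration ramp time from flat to vesicle curvature (ns).
#' @param H_vesicle final curvature (1/nm).
#' @param noise_sigma positional jitter sd (nm).
#' @param timestep frame spacing (ns).
#' @param horizon observation horizon (ns).
#' @param seed integer RNG seed.
#' @return list of validated parameters (class `"bicelle_params"`).
#' @export
bicelle_params <- function(n_long_lipids = 300, n_rim_lipids = 100,
                           membrane_area = NULL, leaflet_offset = 2.0,
                           k_prime = 0.02, tau = 150,
                           closure_duration = 10, H_vesicle = 0.15,
                           noise_sigma = 0.1, timestep = 1,
                           horizon = 1000, seed = 1) {
  if (is.null(membrane_area)) membrane_area <- 0.6 * n_long_lipids / 2
  p <- list(n_long_lipids = as.integer(n_long_lipids),
            n_rim_lipids = as.integer(n_rim_lipids),
            membrane_area = membrane_area, leaflet_offset = leaflet_offset,
            k_prime = k_prime, tau = tau,
            closure_duration = closure_duration, H_vesicle = H_vesicle,
            noise_sigma = noise_sigma, timestep = timestep,
            horizon = horizon, seed = as.integer(seed))
  if (p$n_long_lipids < 50) stop("n_long_lipids must be >= 50", call. = FALSE)
  if (p$k_prime <= 0 || p$tau < 0 || p$closure_duration <= 0 ||
      p$H_vesicle <= 0 || p$timestep <= 0 || p$horizon <= 0) {
    stop("rates and durations must be positive (tau may be zero)",
         call. = FALSE)
  }
  spacing <- sqrt(p$membrane_area / ceiling(p$n_long_lipids / 2))
  if (spacing < 0.5) {
    stop(sprintf(paste0("membrane_area too small for bead count: ",
                        "per-leaflet spacing %.2f nm < 0.5 nm"), spacing),
         call. = FALSE)
  }
  structure(p, class = "bicelle_params")
}

# Quasi-uniform Fibonacci lattice on a spherical cap of half-angle theta
# (cos(polar) in [cos_theta, 1]) on the sphere |x - center| = r, apex at
# +z. The golden-angle azimuth gives low-discrepancy coverage.
fib_cap_points <- function(n, r, cos_theta, center_z) {
  k <- seq_len(n) - 0.5
  cz <- 1 - (k / n) * (1 - cos_theta)
  sz <- sqrt(pmax(0, 1 - cz^2))
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  cbind(r * sz * cos(phi), r * sz * sin(phi), center_z + r * cz)
}

# Fibonacci sunflower lattice on a flat disc of radius R at height z.
fib_disc_points <- function(n, R, z) {
  k <- seq_len(n) - 0.5
  rad <- R * sqrt(k / n)
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  cbind(rad * cos(phi), rad * sin(phi), rep(z, n))
}

# Mid-surface + leaflet geometry for curvature H and fixed mid-surface area
# A. Returns one frame of noiseless head-bead and rim-bead positions.
cap_frame <- function(H, A, off, n_cyt, n_lum, n_rim) {
  if (H < 1e-9) {
    Rd <- sqrt(A / pi)
    cyt <- fib_disc_points(n_cyt, Rd,  off / 2)
    lum <- fib_disc_points(n_lum, Rd, -off / 2)
    ang <- 2 * pi * (seq_len(n_rim) - 1) / max(n_rim, 1)
    rim <- cbind(Rd * cos(ang), Rd * sin(ang), rep(0, n_rim))
  } else {
    r <- 1 / H
    cos_theta <- 1 - A / (2 * pi * r^2)
    if (cos_theta < -1) {
      stop("membrane_area exceeds the full sphere at this curvature",
           call. = FALSE)
    }
    cz <- -r  # sphere center below the apex; convex (cytoplasmic) side up
    cyt <- fib_cap_points(n_cyt, r + off / 2, cos_theta, cz)
    lum <- fib_cap_points(n_lum, r - off / 2, cos_theta, cz)
    sin_theta <- sqrt(max(0, 1 - cos_theta^2))
    ang <- 2 * pi * (seq_len(n_rim) - 1) / max(n_rim, 1)
    rim <- cbind(r * sin_theta * cos(ang), r * sin_theta * sin(ang),
                 rep(cz + r * cos_theta, n_rim))
  }
  rbind(cyt, lum, rim)
}

# Piecewise-linear curvature ramp shared by generator and ground truth.
ramp_curvature <- function(t, event_time, closure_duration, H_vesicle) {
  pmin(pmax((t - event_time) / closure_duration, 0), 1) * H_vesicle
}

#' Generate a synthetic bicelle-to-vesicle trajectory with ground truth
#'
#' See [bicelle_params()] for the shape model. The returned ground truth
#' records the stochastic `event_time` (start of the curvature ramp,
#' `tau + Exp(k_prime)`), the `crossing_time` at which the true curvature
#' first reaches `threshold`, a `censored` flag (crossing after the
#' horizon), and the noiseless per-frame curvature `H_true`.
#'
#' @param params a [bicelle_params()] object.
#' @param threshold curvature level defining the crossing time (1/nm);
#'   defaults to `H_vesicle`.
#' @return list with elements `trajectory` (a [trajectory()]) and
#'   `ground_truth` (list: `event_time`, `crossing_time`, `censored`,
#'   `H_true`).
#' @export
generate_bicelle_trajectory <- function(params = bicelle_params(),
                                        threshold = NULL) {
  stopifnot(inherits(params, "bicelle_params"))
  if (is.null(threshold)) threshold <- params$H_vesicle
  set.seed(params$seed)
  event_time <- params$tau + rexp(1, rate = params$k_prime)
  crossing_time <- event_time +
    params$closure_duration * min(threshold / params$H_vesicle, 1)
  censored <- crossing_time > params$horizon || threshold > params$H_vesicle

  n_cyt <- as.integer(ceiling(params$n_long_lipids / 2))
  n_lum <- params$n_long_lipids - n_cyt
  n_rim <- params$n_rim_lipids
  nb <- n_cyt + n_lum + n_rim
  times <- seq(0, params$horizon, by = params$timestep)
  nf <- length(times)
  H_true <- ramp_curvature(times, event_time, params$closure_duration,
                           params$H_vesicle)

  coords <- array(NA_real_, dim = c(nf, nb, 3))
  for (k in seq_len(nf)) {
    coords[k, , ] <- cap_frame(H_true[k], params$membrane_area,
                               params$leaflet_offset, n_cyt, n_lum, n_rim)
  }
  if (params$noise_sigma > 0) {
    coords <- coords + rnorm(length(coords), sd = params$noise_sigma)
  }

  topo <- data.frame(
    index = seq_len(nb) - 1L,
    name = "PO4",
    entity_kind = "lipid",
    species = rep(c("DMPC", "DMPC", "DHPC"), c(n_cyt, n_lum, n_rim)),
    role = "head",
    leaflet = rep(c("cytoplasmic", "luminal", "rim"),
                  c(n_cyt, n_lum, n_rim)),
    stringsAsFactors = FALSE
  )
  list(
    trajectory = trajectory(topo, coords, times = times,
                            timestep = params$timestep),
    ground_truth = list(event_time = event_time,
                        crossing_time = crossing_time,
                        censored = censored, H_true = H_true)
  )
}

#' Sample waiting times from the lagged single-Poisson model
#'
#' Draws `n` waiting times `t_i = tau + Exp(k_prime)`; draws exceeding
#' `horizon` are flagged censored and recorded at the horizon.
#'
#' @param k_prime transition rate (1/ns), positive.
#' @param tau deterministic lag (ns), non-negative.
#' @param n number of replicates.
#' @param horizon observation horizon (ns).
#' @param seed optional integer seed for reproducibility.
#' @param system_label label stored in the result.
#' @return a [waiting_time_set()].
#' @export
sample_waiting_times <- function(k_prime, tau, n, horizon = 1000,
                                 seed = NULL, system_label = "") {
  if (k_prime <= 0) stop("k_prime must be positive", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_raw <- tau + rexp(n, rate = k_prime)
  censored <- t_raw > horizon
  waiting_time_set(times = ifelse(censored, horizon, t_raw),
                   censored = censored, horizon = horizon,
                   system_label = system_label)
}

# Uniform random rotation matrix from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a multi-state conformational ensemble
#'
#' Each frame is drawn by picking a state center with the given weights,
#' adding isotropic Gaussian noise to every bead, and (by default) applying
#' a random rigid rotation and translation, so that downstream statistics
#' must superpose frames before comparing them. The state label of every
#' frame is returned for recovery scoring.
#'
#' @param state_centers list of `n_beads x 3` matrices (nm), equal sizes.
#' @param weights state probabilities, summing to 1 within 1e-9.
#' @param noise_sigma isotropic positional noise sd (nm).
#' @param n number of frames.
#' @param seed optional integer seed.
#' @param rigid_motion apply a random rotation + translation per frame.
#' @return list with `trajectory` (protein backbone beads, species
#'   `"RHD"`) and `labels` (state index per frame).
#' @export
generate_conformational_ensemble <- function(state_centers, weights,
                                             noise_sigma = 0.1, n = 1000,
                                             seed = NULL,
                                             rigid_motion = TRUE) {
  if (!is.list(state_centers) || !length(state_centers)) {
    stop("state_centers must be a non-empty list of matrices", call. = FALSE)
  }
  state_centers <- lapply(state_centers, as.matrix)
  nb <- nrow(state_centers[[1]])
  if (!all(vapply(state_centers, nrow, 1L) == nb)) {
    stop("all state centers must share the same bead count", call. = FALSE)
  }
  if (length(weights) != length(state_centers)) {
    stop("one weight per state center required", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1 within 1e-9",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  coords <- array(NA_real_, dim = c(n, nb, 3))
  for (k in seq_len(n)) {
    X <- state_centers[[labels[k]]] +
      if (noise_sigma > 0) {
        matrix(rnorm(3 * nb, sd = noise_sigma), ncol = 3)
      } else 0
    if (rigid_motion) {
      X <- X %*% t(random_rotation())
      X <- sweep(X, 2, rnorm(3, sd = 5), `+`)
    }
    coords[k, , ] <- X
  }
  topo <- data.frame(index = seq_len(nb) - 1L, name = "BB",
                     entity_kind = "protein", species = "RHD",
                     role = "backbone", leaflet = "unassigned",
                     stringsAsFactors = FALSE)
  list(trajectory = trajectory(topo, coords,
                               times = seq_len(n) - 1),
       labels = labels)
}
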