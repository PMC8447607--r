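# Independent oracles and fixture builders shared across the test files.
# Every oracle reimplements the quantity it checks from first principles,
# without touching the code path under test.

# Points exactly on a sphere (uniform directions), optionally jittered.
make_sphere_points <- function(n, radius, center = c(0, 0, 0), sd = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * radius, 2, center, `+`)
  if (sd > 0) pts <- pts + matrix(rnorm(3 * n, sd = sd), ncol = 3)
  pts
}

# Uniform random proper rotation (QR of a Gaussian matrix, det fixed).
random_rotation_oracle <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Derivative-free multi-start nonlinear least-squares sphere fit
# (Nelder-Mead on the geometric objective).
sphere_fit_oracle <- function(pts, n_starts = 6, seed = 99) {
  set.seed(seed)
  obj <- function(par) {
    d <- sqrt(rowSums(sweep(pts, 2, par[1:3])^2))
    sum((d - abs(par[4]))^2)
  }
  ctr0 <- colMeans(pts)
  r0 <- mean(sqrt(rowSums(sweep(pts, 2, ctr0)^2)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- c(ctr0 + rnorm(3, sd = if (s == 1) 0 else r0 / 4),
               r0 * if (s == 1) 1 else runif(1, 0.5, 2))
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-15))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(center = best$par[1:3], radius = abs(best$par[4]),
       ss = best$value)
}

# Horn's quaternion method for the minimal proper-rotation RMSD.
quaternion_rmsd_oracle <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  S <- crossprod(A, B)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Exhaustive brute-force implementation of the gromos neighbor-counting
# rule (distance <= cutoff, self excluded, ties to the lowest index).
gromos_oracle <- function(mat, cutoff) {
  n <- nrow(mat)
  remaining <- seq_len(n)
  assignments <- integer(n)
  centers <- integer(0)
  cl <- 0L
  while (length(remaining)) {
    best_center <- NA_integer_
    best_count <- -1L
    for (i in remaining) {
      cnt <- 0L
      for (j in remaining) {
        if (j != i && mat[i, j] <= cutoff) cnt <- cnt + 1L
      }
      if (cnt > best_count) {
        best_count <- cnt
        best_center <- i
      }
    }
    members <- best_center
    for (j in remaining) {
      if (j != best_center && mat[best_center, j] <= cutoff) {
        members <- c(members, j)
      }
    }
    cl <- cl + 1L
    assignments[members] <- cl
    centers[cl] <- best_center
    remaining <- setdiff(remaining, members)
  }
  list(assignments = assignments, centers = centers)
}

# Two-stage grid search of the shifted-exponential log-likelihood
# (uncensored), profiling tau over a grid up to the sample minimum.
shifted_exp_grid_oracle <- function(times, n_grid = 20001) {
  tmin <- min(times)
  loglik <- function(k, tau) {
    length(times) * log(k) - k * sum(times - tau)
  }
  # profile: for any k > 0 the log-likelihood increases in tau, so the
  # optimum sits at tau = tmin; confirm over a tau grid anyway
  tau_grid <- seq(0, tmin, length.out = 101)
  k_of_tau <- 1 / (mean(times) - tau_grid + 1e-300)
  ll_tau <- mapply(loglik, k_of_tau, tau_grid)
  tau_hat <- tau_grid[which.max(ll_tau)]
  k_lo <- 1e-4 / (mean(times) - tmin + 1e-300)
  k_hi <- 1e4 / (mean(times) - tmin + 1e-300)
  for (stage in 1:4) {
    ks <- exp(seq(log(k_lo), log(k_hi), length.out = n_grid))
    ll <- length(times) * log(ks) - ks * sum(times - tau_hat)
    i <- which.max(ll)
    k_lo <- ks[max(i - 1, 1)]
    k_hi <- ks[min(i + 1, length(ks))]
  }
  list(k_prime = ks[i], tau = tau_hat)
}

# Direct double-loop radius of gyration via the pairwise-distance identity
# Rg^2 = (1 / 2 N^2) sum_ij |x_i - x_j|^2.
rg_pairwise_oracle <- function(X) {
  n <- nrow(X)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + sum((X[i, ] - X[j, ])^2)
    }
  }
  sqrt(acc / (2 * n^2))
}

# Direct vector-sum hydrophobic moment.
moment_oracle <- function(h, delta_deg, phase_deg = 0) {
  ang <- ((seq_along(h) - 1) * delta_deg + phase_deg) * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

# Small rigid protein-like bead scaffold (non-degenerate, chiral).
make_scaffold <- function(n = 20, seed = 5) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 1.5), ncol = 3)
}

# Trajectory wrapper around a frames x beads x 3 array of protein beads.
protein_traj <- function(coords, times = NULL) {
  nb <- dim(coords)[2]
  topo <- data.frame(index = seq_len(nb) - 1L, name = "BB",
                     entity_kind = "protein", species = "RHD",
                     role = "backbone", leaflet = "unassigned",
                     stringsAsFactors = FALSE)
  trajectory(topo, coords, times = times)
}
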