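# Kinematic simulator of bond-vector trajectories with analytically
# solvable rank-2 correlation functions. These trajectories are the test
# stand-ins for large all-atom lipid simulations: every model carries a
# closed-form C(t) so that empirical estimators can be validated against
# exact oracles. No force field, thermostat or solvent is involved.

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Motion models for the bond-vector simulator
#'
#' Constructors for the kinematic motion models understood by
#' [simulate_motion()] and [analytic_ct()]. Rates are in 1/s, times in
#' seconds, angles in radians.
#'
#' \describe{
#'   \item{\code{motion_static()}}{No motion; \eqn{C(t) \equiv 1}.}
#'   \item{\code{motion_isotropic_diffusion(D)}}{Free rotational diffusion
#'     with diffusion coefficient \code{D}; \eqn{C(t) = e^{-6Dt}}.}
#'   \item{\code{motion_axial_diffusion(D, beta)}}{Diffusion about the model
#'     z axis with the bond inclined by \code{beta};
#'     \eqn{C(t) = \sum_p |d^2_{p0}(\beta)|^2 e^{-p^2 D t}}.}
#'   \item{\code{motion_n_site_jump(rates, site_angles, bond_beta)}}{Markov
#'     jumps between discrete orientations. \code{rates} is the generator
#'     matrix (rows sum to zero, \code{rates[i, j]} the i to j rate);
#'     \code{site_angles} a list of \code{euler_angles} (or 3x3 rotation
#'     matrices) giving each site's orientation. The bond points along the
#'     site frame z axis tilted by \code{bond_beta}.}
#'   \item{\code{motion_wobble_cone(D, theta0)}}{Diffusion restricted to a
#'     cone of half angle \code{theta0}. The analytic correlation function is
#'     the standard single-exponential approximation (the cone order
#'     parameter is exact).}
#'   \item{\code{motion_power_law(d, zrange, n_copies)}}{A mixture of
#'     isotropic diffusers whose log correlation times are drawn from the
#'     power-law density \eqn{\theta(z) \propto 10^{-z(d/2 - 1)}} on
#'     \code{zrange}, the form consistent with a collective-motion spectral
#'     density \eqn{J(\omega) \propto \omega^{-(2 - d/2)}} (\code{d = 2}
#'     gives a flat distribution, \code{d = 3} weights fast times).}
#' }
#'
#' @param D Rotational diffusion coefficient (1/s).
#' @param beta,bond_beta Bond inclination from the symmetry axis (radians).
#' @param rates Generator (rate) matrix, 1/s.
#' @param site_angles List of site orientations.
#' @param theta0 Cone half angle (radians).
#' @param d Power-law dimensionality.
#' @param zrange Range of \eqn{z = \log_{10}(\tau_c / s)}.
#' @param n_copies Number of mixture members simulated.
#' @return An object of class \code{motion_model}.
#' @name motion_models
NULL

new_motion_model <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "motion_model")
}

#' @rdname motion_models
#' @export
motion_static <- function() new_motion_model("static", bond0 = c(0, 0, 1))

#' @rdname motion_models
#' @export
motion_isotropic_diffusion <- function(D) {
  stopifnot(D > 0)
  new_motion_model("isotropic_diffusion", D = D, bond0 = c(0, 0, 1))
}

#' @rdname motion_models
#' @export
motion_axial_diffusion <- function(D, beta) {
  stopifnot(D > 0)
  new_motion_model("axial_diffusion", D = D, beta = beta,
                   bond0 = c(sin(beta), 0, cos(beta)))
}

#' @rdname motion_models
#' @export
motion_n_site_jump <- function(rates, site_angles, bond_beta = 0) {
  rates <- as.matrix(rates)
  k <- nrow(rates)
  stopifnot(k >= 2, ncol(rates) == k, length(site_angles) == k)
  if (max(abs(rowSums(rates))) > 1e-8 * max(abs(rates))) {
    stop("jump rate matrix rows must sum to zero")
  }
  Rs <- lapply(site_angles, function(s) {
    if (is.matrix(s)) s else rot_zyz(s)
  })
  new_motion_model("n_site_jump", rates = rates, site_rot = Rs,
                   bond0 = c(sin(bond_beta), 0, cos(bond_beta)))
}

#' @rdname motion_models
#' @export
motion_wobble_cone <- function(D, theta0) {
  stopifnot(D > 0, theta0 > 0, theta0 < pi / 2)
  new_motion_model("wobble_cone", D = D, theta0 = theta0, bond0 = c(0, 0, 1))
}

#' @rdname motion_models
#' @export
motion_power_law <- function(d, zrange = c(-11, -7), n_copies = 64) {
  stopifnot(length(zrange) == 2, zrange[1] < zrange[2], d > 0)
  new_motion_model("power_law_distribution", d = d, zrange = zrange,
                   n_copies = as.integer(n_copies), bond0 = c(0, 0, 1))
}

#' @export
print.motion_model <- function(x, ...) {
  cat("motion model:", x$kind, "\n")
  if (!is.null(x$D)) cat("  D =", format(x$D), "1/s\n")
  if (!is.null(x$rates)) cat("  ", nrow(x$rates), "sites\n")
  invisible(x)
}

# fastest relaxation rate (1/s) of the model: used to police dt
fastest_rate <- function(model) {
  switch(model$kind,
    static = 0,
    isotropic_diffusion = 6 * model$D,
    axial_diffusion = 4 * model$D,
    n_site_jump = max(abs(Re(eigen(model$rates)$values))),
    wobble_cone = 6 * model$D,
    power_law_distribution = 1 / 10^model$zrange[1])
}

# equilibrium populations of a generator matrix (pi Q = 0, sum pi = 1);
# the generator is scale-normalized so the unit-sum row is not swamped
equilibrium_populations <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q) / max(abs(Q)), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- qr.solve(A, b)
  p / sum(p)
}

# Simulate the orientational process of a model as a series of rotation
# matrices R(t) in the model's local frame (3 x 3 x n_steps). The bond
# vector is R(t) %*% bond0. Uses the current RNG stream.
sim_rotations <- function(model, n_steps, dt) {
  n <- as.integer(n_steps)
  switch(model$kind,
    static = {
      array(diag(3), c(3, 3, n))
    },
    isotropic_diffusion = {
      sd <- sqrt(2 * model$D * dt)
      inc <- matrix(stats::rnorm(3L * n, sd = sd), 3L, n)
      accumulate_rotations(inc)
    },
    axial_diffusion = {
      phi <- cumsum(stats::rnorm(n, sd = sqrt(2 * model$D * dt)))
      phi <- c(0, phi[-n])
      rot_zyz_series(euler_angles(phi, rep(0, n), rep(0, n)))
    },
    n_site_jump = {
      states <- sim_ctmc_states(model$rates, n, dt)
      out <- array(NA_real_, c(3, 3, n))
      for (s in seq_along(model$site_rot)) {
        idx <- which(states == s)
        if (length(idx)) out[, , idx] <- model$site_rot[[s]]
      }
      out
    },
    wobble_cone = {
      # reflected isotropic diffusion of the z axis inside the cone,
      # with free azimuthal component
      sd <- sqrt(2 * model$D * dt)
      th <- numeric(n); ph <- numeric(n)
      th[1] <- model$theta0 * sqrt(stats::runif(1))  # ~area-uniform start
      ph[1] <- stats::runif(1, 0, 2 * pi)
      dth <- stats::rnorm(n, sd = sd)
      dph <- stats::rnorm(n, sd = sd)
      for (i in 2:n) {
        t_new <- th[i - 1] + dth[i]
        t_new <- abs(t_new)                           # reflect at 0
        if (t_new > model$theta0) t_new <- 2 * model$theta0 - t_new
        th[i] <- min(max(t_new, 0), model$theta0)
        ph[i] <- ph[i - 1] + dph[i] / max(sin(th[i]), 0.05)
      }
      rot_zyz_series(euler_angles(ph, th, rep(0, n)))
    },
    power_law_distribution = stop(
      "power_law_distribution is simulated as a mixture; use simulate_motion()"),
    stop("unknown model kind: ", model$kind))
}

# cumulative composition of small rotations given 3 x n rotation-vector
# increments; R_1 = I, R_k = dR_k %*% R_{k-1}. Prefix products are built by
# binary doubling (log2 n batched 3x3 passes), which is what makes
# million-step diffusion trajectories affordable in pure R.
accumulate_rotations <- function(inc) {
  n <- ncol(inc)
  X <- rodrigues_series(inc)
  X[, , 1] <- diag(3)
  s <- 1L
  while (s < n) {
    idx <- (s + 1L):n
    A <- X[, , idx, drop = FALSE]
    B <- X[, , idx - s, drop = FALSE]
    for (i in 1:3) for (m in 1:3) {
      X[i, m, idx] <- A[i, 1, ] * B[1, m, ] + A[i, 2, ] * B[2, m, ] +
        A[i, 3, ] * B[3, m, ]
    }
    s <- 2L * s
  }
  X
}

# vectorized Rodrigues: rotation matrices for 3 x n rotation vectors
rodrigues_series <- function(w) {
  n <- ncol(w)
  th <- sqrt(colSums(w^2))
  th <- pmax(th, 1e-300)
  kx <- w[1, ] / th; ky <- w[2, ] / th; kz <- w[3, ] / th
  s <- sin(th); cc <- 1 - cos(th)
  out <- array(NA_real_, c(3, 3, n))
  out[1, 1, ] <- 1 + cc * (kx * kx - 1)
  out[1, 2, ] <- -s * kz + cc * kx * ky
  out[1, 3, ] <- s * ky + cc * kx * kz
  out[2, 1, ] <- s * kz + cc * kx * ky
  out[2, 2, ] <- 1 + cc * (ky * ky - 1)
  out[2, 3, ] <- -s * kx + cc * ky * kz
  out[3, 1, ] <- -s * ky + cc * kx * kz
  out[3, 2, ] <- s * kx + cc * ky * kz
  out[3, 3, ] <- 1 + cc * (kz * kz - 1)
  out
}

# rotation matrix from a rotation vector (axis * angle), Rodrigues
rotvec_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# exact continuous-time Markov chain sampled on the storage grid: the loop
# runs over jumps (Gillespie), not grid steps
sim_ctmc_states <- function(Q, n, dt) {
  k <- nrow(Q)
  rates <- -diag(Q)
  pi0 <- equilibrium_populations(Q)
  Pj <- Q / rates
  diag(Pj) <- 0
  t_tot <- n * dt
  cap <- as.integer(ceiling(t_tot * max(rates) * 1.5) + 100)
  st <- integer(cap); tm <- numeric(cap)
  cur <- sample.int(k, 1, prob = pi0)
  t_cur <- 0
  m <- 0L
  while (t_cur < t_tot) {
    m <- m + 1L
    if (m > length(st)) {
      st <- c(st, integer(cap)); tm <- c(tm, numeric(cap))
    }
    st[m] <- cur; tm[m] <- t_cur
    t_cur <- t_cur + stats::rexp(1, rates[cur])
    cur <- sample.int(k, 1, prob = Pj[cur, ])
  }
  st[findInterval((0:(n - 1)) * dt, tm[1:m])]
}

#' Simulate a bond-vector trajectory
#'
#' Generates a reproducible vector trajectory for a [motion model]
#' [motion_models], attaching the model's analytic correlation function and
#' order parameter as oracles.
#'
#' @param model A \code{motion_model}.
#' @param n_steps Number of stored steps.
#' @param dt Step interval in seconds. Must resolve the fastest correlation
#'   time of the model by at least a factor 20.
#' @param seed Integer seed; the trajectory is reproducible under a fixed
#'   seed and leaves the global RNG state untouched.
#' @param n_copies Number of statistically independent molecule copies.
#' @return An object of class \code{synthetic_trajectory}: a list with
#'   \code{vectors} (\code{3 x n_steps x n_copies}), \code{dt},
#'   \code{frames} (ground-truth frame axes where applicable),
#'   \code{analytic_ct} (function of lag seconds), \code{S2}, and metadata.
#' @export
simulate_motion <- function(model, n_steps, dt, seed = 1L, n_copies = 1L) {
  stopifnot(inherits(model, "motion_model"), n_steps >= 2, dt > 0)
  fr <- fastest_rate(model)
  if (fr > 0 && dt > 1 / (20 * fr)) {
    stop(sprintf(
      "dt = %.3g s too coarse for model rates; require dt <= %.3g s",
      dt, 1 / (20 * fr)))
  }
  n <- as.integer(n_steps)
  if (model$kind == "power_law_distribution") {
    nc <- model$n_copies
    z <- local_seed(seed, sample_power_law_z(model, nc))
    vec <- array(NA_real_, c(3, n, nc))
    for (j in seq_len(nc)) {
      sub <- motion_isotropic_diffusion(1 / (6 * 10^z[j]))
      R <- local_seed(seed + j, sim_rotations(sub, n, dt))
      vec[, , j] <- apply_rotation_series(R, sub$bond0)
    }
    traj <- new_synthetic_trajectory(vec, dt, model, seed, frames = NULL)
    return(traj)
  }
  vec <- array(NA_real_, c(3, n, n_copies))
  frames <- NULL; triads <- NULL
  for (j in seq_len(n_copies)) {
    R <- local_seed(seed + (j - 1L) * 7919L, sim_rotations(model, n, dt))
    vec[, , j] <- apply_rotation_series(R, model$bond0)
    if (j == 1L) {
      frames <- R
      triads <- compose_triads(R, bond0_triad(model$bond0))
    }
  }
  out <- new_synthetic_trajectory(vec, dt, model, seed, frames = frames)
  out$triads <- triads
  out
}

# a fixed triad with third column along v0
bond0_triad <- function(v0) {
  z <- v0 / sqrt(sum(v0^2))
  seedv <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- seedv - sum(seedv * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z, deparse.level = 0)
}

# R_t %*% R0 for a 3 x 3 x N series and fixed 3 x 3 R0
compose_triads <- function(R, R0) {
  out <- array(NA_real_, dim(R))
  for (i in 1:3) for (k in 1:3) {
    out[i, k, ] <- R[i, 1, ] * R0[1, k] + R[i, 2, ] * R0[2, k] +
      R[i, 3, ] * R0[3, k]
  }
  out
}

sample_power_law_z <- function(model, nc) {
  a <- -(model$d / 2 - 1) * log(10)     # theta(z) ~ exp(a z)
  z1 <- model$zrange[1]; z2 <- model$zrange[2]
  u <- stats::runif(nc)
  if (abs(a) < 1e-12) {
    z1 + u * (z2 - z1)
  } else {
    log(exp(a * z1) + u * (exp(a * z2) - exp(a * z1))) / a
  }
}

apply_rotation_series <- function(R, v) {
  rbind(R[1, 1, ] * v[1] + R[1, 2, ] * v[2] + R[1, 3, ] * v[3],
        R[2, 1, ] * v[1] + R[2, 2, ] * v[2] + R[2, 3, ] * v[3],
        R[3, 1, ] * v[1] + R[3, 2, ] * v[2] + R[3, 3, ] * v[3])
}

new_synthetic_trajectory <- function(vectors, dt, model, seed, frames = NULL,
                                     analytic = NULL, S2 = NULL,
                                     notes = character()) {
  if (length(dim(vectors)) == 2) dim(vectors) <- c(dim(vectors), 1L)
  nrm <- sqrt(vectors[1, , , drop = FALSE]^2 + vectors[2, , , drop = FALSE]^2 +
              vectors[3, , , drop = FALSE]^2)
  vectors <- vectors / rep(nrm, each = 3L)[seq_along(vectors)]
  if (is.null(analytic)) analytic <- function(t) analytic_ct_values(model, t)
  if (is.null(S2)) S2 <- analytic_S2(model)
  structure(list(vectors = vectors, dt = dt, model = model, seed = seed,
                 frames = frames, analytic_ct = analytic, S2 = S2,
                 notes = notes),
            class = "synthetic_trajectory")
}

#' @export
print.synthetic_trajectory <- function(x, ...) {
  d <- dim(x$vectors)
  cat(sprintf("synthetic trajectory: %d steps x %d copies, dt = %.3g s\n",
              d[2], d[3], x$dt))
  cat("  model:", if (inherits(x$model, "motion_model")) x$model$kind
      else "composed hierarchy", "\n")
  cat(sprintf("  analytic S2 = %.4f\n", x$S2))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Compose a two-level motional hierarchy
#'
#' Builds bond vectors as the outer frame rotation applied to the inner
#' motion, with statistically independent random streams, recording the
#' ground-truth outer frame axes and the analytic product correlation
#' function \eqn{C(t) = C_{inner}(t) C_{outer}(t)}.
#'
#' @param inner,outer \code{motion_model}s; \code{outer} should be slower
#'   than \code{inner}. A timescale ratio below 10 is recorded as a warning
#'   note in the returned object (the separation assumption is marginal).
#' @param n_steps,dt,seed,n_copies As in [simulate_motion()].
#' @param dependent If \code{TRUE}, drive inner and outer from the same
#'   random stream, deliberately violating statistical independence (used to
#'   validate the product-deviation diagnostic).
#' @return A \code{synthetic_trajectory}; \code{$frames} holds the outer
#'   rotation (ground-truth frame axes), and \code{$inner}/\code{$outer}
#'   the component models.
#' @export
compose_hierarchy <- function(inner, outer, n_steps, dt, seed = 1L,
                              n_copies = 1L, dependent = FALSE) {
  stopifnot(inherits(inner, "motion_model"), inherits(outer, "motion_model"))
  n <- as.integer(n_steps)
  fi <- fastest_rate(inner); fo <- fastest_rate(outer)
  notes <- character()
  if (fo > 0 && fi / fo < 10) {
    notes <- c(notes, sprintf(
      "timescale ratio inner/outer = %.2g < 10: separation assumption marginal",
      fi / fo))
  }
  if (fi > 0 && dt > 1 / (20 * fi)) {
    stop(sprintf("dt = %.3g s too coarse; require dt <= %.3g s", dt,
                 1 / (20 * fi)))
  }
  vec <- array(NA_real_, c(3, n, n_copies))
  frames <- NULL; triads <- NULL
  for (j in seq_len(n_copies)) {
    s_in <- seed + (j - 1L) * 7919L
    s_out <- if (dependent) s_in else s_in + 104729L
    Ri <- local_seed(s_in, sim_rotations(inner, n, dt))
    Ro <- local_seed(s_out, sim_rotations(outer, n, dt))
    vi <- apply_rotation_series(Ri, inner$bond0)
    vec[1, , j] <- Ro[1, 1, ] * vi[1, ] + Ro[1, 2, ] * vi[2, ] + Ro[1, 3, ] * vi[3, ]
    vec[2, , j] <- Ro[2, 1, ] * vi[1, ] + Ro[2, 2, ] * vi[2, ] + Ro[2, 3, ] * vi[3, ]
    vec[3, , j] <- Ro[3, 1, ] * vi[1, ] + Ro[3, 2, ] * vi[2, ] + Ro[3, 3, ] * vi[3, ]
    if (j == 1L) {
      frames <- Ro
      Ai <- compose_triads(Ri, bond0_triad(inner$bond0))
      triads <- array(NA_real_, dim(Ro))
      for (a in 1:3) for (b in 1:3) {
        triads[a, b, ] <- Ro[a, 1, ] * Ai[1, b, ] + Ro[a, 2, ] * Ai[2, b, ] +
          Ro[a, 3, ] * Ai[3, b, ]
      }
    }
  }
  analytic <- function(t) analytic_ct_values(inner, t) * analytic_ct_values(outer, t)
  S2 <- analytic_S2(inner) * analytic_S2(outer)
  out <- new_synthetic_trajectory(vec, dt, model = NULL, seed = seed,
                                  frames = frames, analytic = analytic,
                                  S2 = S2, notes = notes)
  out$inner <- inner; out$outer <- outer; out$triads <- triads
  out
}

#' Closed-form correlation function of a motion model
#'
#' Evaluates the analytic rank-2 correlation function of a
#' [motion model][motion_models] on a lag grid: C(0) = 1, C decays
#' monotonically to the model's S2. Jump models use the
#' eigen-decomposition of the rate matrix; the wobble-in-cone form is the
#' standard single-exponential approximation (exact S2).
#'
#' @param model A \code{motion_model} with a closed form (all kinds).
#' @param lags Lag times in seconds, or a [lag_grid()].
#' @return A \code{correlation_set} with the analytic values.
#' @export
analytic_ct <- function(model, lags) {
  times <- if (inherits(lags, "lag_grid")) lags$times else as.numeric(lags)
  new_correlation_set(times, analytic_ct_values(model, times),
                      lags = if (inherits(lags, "lag_grid")) lags$lags else NULL,
                      kind = "analytic")
}

# closed-form C(t) values at lag times t (seconds)
analytic_ct_values <- function(model, t) {
  switch(model$kind,
    static = rep(1, length(t)),
    isotropic_diffusion = exp(-6 * model$D * t),
    axial_diffusion = {
      b <- model$beta
      a <- vapply(-2:2, function(p) d2_element(p, 0, b)^2, numeric(1))
      sapply(t, function(tt) sum(a * exp(-(-2:2)^2 * model$D * tt)))
    },
    n_site_jump = {
      Q <- model$rates
      pi0 <- equilibrium_populations(Q)
      v <- vapply(model$site_rot, function(R) drop(R %*% model$bond0),
                  numeric(3))
      P2 <- (3 * crossprod(v)^2 - 1) / 2          # P2(v_i . v_j)
      ev <- eigen(Q)
      Vi <- solve(ev$vectors)
      sapply(t, function(tt) {
        Pt <- Re(ev$vectors %*% diag(exp(ev$values * tt), nrow(Q)) %*% Vi)
        sum(pi0 * rowSums(Pt * P2))
      })
    },
    wobble_cone = {
      x <- cos(model$theta0)
      S2 <- (x * (1 + x) / 2)^2
      tau <- wobble_cone_tau_eff(x, model$D)
      S2 + (1 - S2) * exp(-t / tau)
    },
    power_law_distribution = {
      z <- seq(model$zrange[1], model$zrange[2], length.out = 400)
      th <- 10^(-z * (model$d / 2 - 1))
      th <- th / sum(th)
      sapply(t, function(tt) sum(th * exp(-tt / 10^z)))
    },
    stop("no closed form for model kind ", model$kind))
}

# effective correlation time of wobble-in-cone (standard approximation)
wobble_cone_tau_eff <- function(x, D) {
  S2 <- (x * (1 + x) / 2)^2
  num <- -x^2 * (1 + x)^2 * (log((1 + x) / 2) + (1 - x) / 2) / (2 * (1 - x)) +
    (1 - x) * (6 + 8 * x - x^2 - 12 * x^3 - 7 * x^4) / 24
  num / ((1 - S2) * D)
}

analytic_S2 <- function(model) {
  if (is.null(model)) return(NA_real_)
  switch(model$kind,
    static = 1,
    isotropic_diffusion = 0,
    axial_diffusion = d2_element(0, 0, model$beta)^2,
    n_site_jump = {
      M <- analytic_residual(model)$tensor
      sum(M * M) * 2 / 3
    },
    wobble_cone = (cos(model$theta0) * (1 + cos(model$theta0)) / 2)^2,
    power_law_distribution = 0)
}

# residual (motionally averaged) rank-2 tensor of the bond in the model
# frame: mean of (3 v v' - I)/2 over the equilibrium ensemble
analytic_residual <- function(model) {
  M <- switch(model$kind,
    static = {
      v <- model$bond0
      (3 * tcrossprod(v) - diag(3)) / 2
    },
    isotropic_diffusion = matrix(0, 3, 3),
    power_law_distribution = matrix(0, 3, 3),
    axial_diffusion = d2_element(0, 0, model$beta) *
      (3 * diag(c(0, 0, 1)) - diag(3)) / 2,
    n_site_jump = {
      pi0 <- equilibrium_populations(model$rates)
      M <- matrix(0, 3, 3)
      for (i in seq_along(pi0)) {
        v <- drop(model$site_rot[[i]] %*% model$bond0)
        M <- M + pi0[i] * (3 * tcrossprod(v) - diag(3)) / 2
      }
      M
    },
    wobble_cone = {
      x <- cos(model$theta0)
      (x * (1 + x) / 2) * (3 * diag(c(0, 0, 1)) - diag(3)) / 2
    })
  ev <- eigen(M, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)
  lam <- ev$values[ord]
  list(tensor = M, delta_ratio = lam[1],
       eta = if (abs(lam[1]) > 1e-12) (lam[3] - lam[2]) / lam[1] else 0)
}
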