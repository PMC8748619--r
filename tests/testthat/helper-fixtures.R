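# Shared fixtures and independent oracles for the test suite. Everything
# here is generated in code at test time; nothing is read from disk.

# internal functions exercised directly by the unit tests
rot_y <- dynland:::rot_y
rot_z <- dynland:::rot_z
d2_element <- dynland:::d2_element
d2_p0_from_vec <- dynland:::d2_p0_from_vec
d2_0p_from_row3 <- dynland:::d2_0p_from_row3
euler_from_axes_series <- dynland:::euler_from_axes_series
analytic_ct_values <- dynland:::analytic_ct_values
analytic_S2 <- dynland:::analytic_S2
analytic_residual <- dynland:::analytic_residual
residual_components_from_shape <- dynland:::residual_components_from_shape
combine_two <- dynland:::combine_two
rates_row <- dynland:::rate_sensitivity_row

rand_euler <- function() {
  euler_angles(stats::runif(1, -pi, pi), stats::runif(1, 0, pi),
               stats::runif(1, -pi, pi))
}

rand_rotation <- function() rot_zyz(rand_euler())

# symmetric n-site jump about z with the bond at angle beta to the axis
tetra_jump_model <- function(rate = 1e9, n_sites = 3, beta = acos(-1 / 3)) {
  Q <- matrix(rate / (n_sites - 1), n_sites, n_sites)
  diag(Q) <- -rate
  sites <- lapply(seq_len(n_sites) - 1, function(j) {
    rot_zyz(euler_angles(2 * pi * j / n_sites, 0, 0))
  })
  motion_n_site_jump(Q, sites, bond_beta = beta)
}

# independent quaternion-method superposition oracle (Horn 1987)
quaternion_align <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
}

# angle (deg) between two rotations
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# build a toy single-lipid "POPC" topology with CHARMM36 atom names and
# geometrically plausible (jittered) coordinates, n_steps frames of mild
# rigid+internal motion
toy_popc_trajectory <- function(n_steps = 5, seed = 1, shuffle = FALSE) {
  set.seed(seed)
  cfg <- popc_preset()
  names_all <- c("N", "C13", "H13A", "H13B", "H13C", "C14", "H14A", "H14B",
                 "H14C", "C15", "H15A", "H15B", "H15C", "C12", "H12A",
                 "H12B", "C11", "H11A", "H11B", "P", "O11", "O12", "O13",
                 "O14", "C1", "HA", "HB", "C2", "HS", "C3", "HX", "HY",
                 "O21", "O22", "O31", "O32")
  for (k in 2:18) {
    names_all <- c(names_all, sprintf("C2%d", k),
                   if (k %in% 9:10) sprintf("H%dR", k)
                   else if (k == 18) sprintf("H18%s", c("R", "S", "T"))
                   else sprintf("H%d%s", k, c("R", "S")))
  }
  names_all <- c(names_all, "C21")
  for (k in 2:16) {
    names_all <- c(names_all, sprintf("C3%d", k),
                   if (k == 16) sprintf("H16%s", c("X", "Y", "Z"))
                   else sprintf("H%d%s", k, c("X", "Y")))
  }
  names_all <- c(names_all, "C31")
  na <- length(names_all)
  # spread atoms along a rough molecular axis with jitter: never collinear
  base <- cbind(seq(0, 30, length.out = na) + stats::rnorm(na, 0, 0.8),
                stats::rnorm(na, 0, 1.2), stats::rnorm(na, 0, 1.2))
  xyz <- array(NA_real_, c(na, 3, n_steps))
  for (s in seq_len(n_steps)) {
    R <- rot_zyz(euler_angles(0.02 * s, 0.01 * s, 0))
    xyz[, , s] <- base %*% t(R) + matrix(stats::rnorm(na * 3, 0, 0.02),
                                         na, 3)
  }
  ord <- if (shuffle) sample.int(na) else seq_len(na)
  atoms <- data.frame(name = names_all[ord], resid = "POPC", resno = 1L,
                      chain = "", index = seq_len(na),
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = xyz[ord, , , drop = FALSE],
                 dt = 5e-12, n_steps = n_steps),
            class = "trajectory_handle")
}
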