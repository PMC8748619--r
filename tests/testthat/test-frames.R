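test_that("moment-of-inertia frames find the chain long axis", {
  # straight chain of collinear beads along x -> degenerate about the axis
  # is fine (two equal large eigenvalues), nu_Z = +-x and constant
  n <- 8
  xyz <- array(0, c(n, 3, 4))
  xyz[, 1, ] <- seq_len(n)
  xyz[, 2, ] <- 0.01 * stats::rnorm(n)   # break the exact degeneracy
  xyz[, 3, ] <- 0.01 * stats::rnorm(n)
  fa <- build_frame_axes(xyz, "moi", atoms = 1:n)
  z <- fa$triads[, 3, ]
  expect_gt(min(abs(z[1, ])), 0.999)
  expect_lt(max(abs(z[, 1] - z[, 4])), 1e-6)
  # prolate random cloud: nu_Z matches the smallest-eigenvalue eigenvector
  # of an independently computed inertia tensor
  set.seed(14)
  cloud <- cbind(rnorm(30, sd = 5), rnorm(30, sd = 1), rnorm(30, sd = 1))
  xyz2 <- array(rep(cloud, 3), c(30, 3, 3))
  fa2 <- build_frame_axes(xyz2, "moi", atoms = 1:30)
  r <- sweep(cloud, 2, colMeans(cloud))
  IT <- diag(sum(r^2), 3) - crossprod(r)
  vz <- eigen(IT, symmetric = TRUE)$vectors[, 3]
  expect_gt(abs(sum(fa2$triads[, 3, 1] * vz)), 1 - 1e-8)
  # spherical group is refused
  sph <- array(rep(diag(3) * 2, 2), c(3, 3, 1))
  xyz3 <- array(0, c(4, 3, 1))
  xyz3[2:4, , 1] <- diag(3); xyz3[1, , 1] <- c(1, 1, 1) / 3 # tetrahedron-ish
  expect_error(build_frame_axes(array(rbind(diag(3), -diag(3)),
                                      c(6, 3, 1)) , "moi", atoms = 1:6),
               "degenerate inertia")
})

test_that("alignment frames co-rotate rigidly with their atoms", {
  set.seed(15)
  base <- matrix(rnorm(18), 6, 3)
  n <- 5
  xyz <- array(NA_real_, c(6, 3, n))
  Rs <- replicate(n, rand_rotation(), simplify = FALSE)
  for (i in seq_len(n)) xyz[, , i] <- base %*% t(Rs[[i]])
  fa <- build_frame_axes(xyz, "rigid_align", atoms = 1:6,
                         reference = xyz[, , 1])
  for (i in 2:n) {
    expected <- Rs[[i]] %*% t(Rs[[1]]) %*% fa$triads[, , 1]
    expect_lt(max(abs(fa$triads[, , i] - expected)), 1e-8)
  }
  expect_error(build_frame_axes(xyz, "rigid_align", atoms = 1:2),
               "at least 3")
})

test_that("motion within a frame reduces to the expected limits", {
  h <- compose_hierarchy(tetra_jump_model(1e10),
                         motion_isotropic_diffusion(1 / (6 * 2e-8)),
                         4e4, 3e-12, seed = 21)
  g <- lag_grid(4e4, 3e-12)
  # frame rigidly attached to the bond: C^{v-f} identically 1
  rigid <- correlation_in_frame(frame_axes(h$triads), frame_axes(h$triads),
                                g, dt = h$dt)
  expect_lt(max(abs(rigid$value - 1)), 1e-9)
  # static lab frame: C^{v-f} equals the total C(t) exactly
  lab <- frame_axes(array(diag(3), c(3, 3, 4e4)))
  tot <- autocorrelation_fft(h$vectors[, , 1], g)
  inlab <- correlation_in_frame(frame_axes(h$triads), lab, g, dt = h$dt)
  expect_lt(max(abs(inlab$value - tot$value)), 1e-10)
  # ground-truth frame: inner jump model's closed form is recovered
  cin <- correlation_in_frame(frame_axes(h$triads), frame_axes(h$frames),
                              g, dt = h$dt)
  an <- analytic_ct_values(h$inner, g$times)
  expect_lt(max(abs(cin$value[, 1] - an)), 0.05)
})

test_that("residual tensors have the exact limiting values", {
  n <- 2000
  # static bond in the frame
  tri <- array(diag(3), c(3, 3, n))
  rt <- residual_tensor(frame_axes(tri), NULL)
  expect_equal(unname(Re(rt$components[3])), 1, tolerance = 1e-12)
  expect_lt(max(Mod(rt$components[-3])), 1e-12)
  expect_equal(rt$delta_ratio, 1, tolerance = 1e-12)
  expect_equal(rt$eta, 0, tolerance = 1e-12)
  # isotropically sampled bond: everything vanishes within sampling error
  tr <- simulate_motion(motion_isotropic_diffusion(2e9), 1e5, 2e-12,
                        seed = 31)
  rti <- residual_tensor(tr)
  expect_lt(max(Mod(rti$components)), 0.05)
  # fast symmetric 3-site rotation at the tetrahedral angle
  # pool several copies: the residual is a pure time/ensemble average
  trj <- simulate_motion(tetra_jump_model(3e9), 5e4, 1e-11, seed = 32,
                         n_copies = 8)
  rtj <- residual_tensor(matrix(trj$vectors, nrow = 3))
  expect_equal(unname(Re(rtj$components[3])), -1 / 3, tolerance = 0.02)
  expect_lt(abs(rtj$eta), 0.1)
  rtp <- residual_tensor(trj)  # single copy, with pair limits
  expect_equal(rtp$pair$S2, 1 / 9, tolerance = 0.03)
})

test_that("residual components, shape parameters and angles are consistent", {
  set.seed(33)
  v <- matrix(rnorm(3 * 500), 3)
  v[3, ] <- abs(v[3, ]) + 1           # anisotropic orientation pool
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  rt <- residual_tensor(v, NULL)
  back <- residual_components_from_shape(rt$delta_ratio, rt$eta, rt$angles)
  expect_lt(max(Mod(rt$components - back)), 1e-8)
})

test_that("frame-motion correlation functions hit their closed forms", {
  n <- 6e4
  # static frame: C^{v:f} identically 1
  tr <- simulate_motion(tetra_jump_model(1e10), 5000, 3e-12, seed = 41)
  statf <- frame_axes(array(diag(3), c(3, 3, 5000)))
  g0 <- lag_grid(5000, 3e-12)
  c0 <- correlation_of_frame(frame_axes(tr$triads), statf, grid = g0,
                             dt = tr$dt)
  expect_lt(max(abs(c0$value - 1)), 1e-9)
  expect_equal(c0$value[1, 1], 1, tolerance = 1e-8)
  # bond rigid in a diffusing frame: C^{v:f} = exp(-6 D t)
  D <- 1 / (6 * 2e-9)
  h <- compose_hierarchy(motion_static(), motion_isotropic_diffusion(D),
                         n, 3e-12, seed = 42)
  g <- lag_grid(n, 3e-12)
  cf <- correlation_of_frame(frame_axes(h$triads), frame_axes(h$frames),
                             grid = g, dt = h$dt)
  dev <- abs(cf$value[, 1] - exp(-6 * D * g$times))
  expect_lt(stats::median(dev), 0.02)
  expect_lt(max(dev), 0.15)
})

test_that("the product of separated functions reproduces the total C(t)", {
  h <- compose_hierarchy(tetra_jump_model(1e10),
                         motion_isotropic_diffusion(1 / (6 * 2e-8)),
                         8e4, 3e-12, seed = 43)
  g <- lag_grid(8e4, 3e-12, per_decade = 15)
  dec <- decompose_hierarchy(h, frame_axes(h$frames), g)
  expect_lt(dec$max_deviation, 0.02)
  # order parameters multiply: 1 - S2_total vs 1 - prod(S2_i)
  S2_prod <- prod(vapply(dec$motions,
                         function(m) m$residual$pair$S2, numeric(1)))
  S2_tot <- residual_tensor(frame_axes(h$triads), NULL)$pair$S2
  expect_equal(S2_tot, S2_prod, tolerance = 0.02)
})

test_that("two-level ground-truth hierarchies recover per-level closed forms", {
  h <- compose_hierarchy(tetra_jump_model(1e10),
                         motion_isotropic_diffusion(1 / (6 * 2e-8)),
                         8e4, 3e-12, seed = 44)
  g <- lag_grid(8e4, 3e-12, per_decade = 15)
  dec <- decompose_hierarchy(h, frame_axes(h$frames), g)
  expect_length(dec$motions, 2)
  an_in <- analytic_ct_values(h$inner, g$times)
  an_out <- analytic_ct_values(h$outer, g$times)
  expect_lt(max(abs(dec$motions[[1]]$correlation$value[, 1] - an_in)), 0.03)
  expect_lt(max(abs(dec$motions[[2]]$correlation$value[, 1] - an_out)), 0.06)
  # all-static frames: innermost motion carries the total, others are 1
  stat <- frame_axes(array(diag(3), c(3, 3, 8e4)))
  dec2 <- decompose_hierarchy(h, list(stat, stat), g)
  tot <- autocorrelation_fft(h$vectors[, , 1], g)
  expect_lt(max(abs(dec2$motions[[1]]$correlation$value - tot$value)), 1e-9)
  expect_lt(max(abs(dec2$motions[[2]]$correlation$value - 1)), 1e-9)
  expect_lt(max(abs(dec2$motions[[3]]$correlation$value - 1)), 1e-9)
})

test_that("a deliberately non-separated fixture trips the diagnostic", {
  h <- compose_hierarchy(motion_axial_diffusion(3e9, 0.9),
                         motion_axial_diffusion(3e8, 0.9),
                         4e4, 3e-12, seed = 45, dependent = TRUE)
  g <- lag_grid(4e4, 3e-12, per_decade = 15)
  dec <- suppressWarnings(suppressMessages(
    decompose_hierarchy(h, frame_axes(h$frames), g)))
  expect_gt(dec$max_deviation, 0.05)
})

test_that("tensor evolution components have the right limits", {
  n <- 5000
  tr <- simulate_motion(motion_static(), n, 1e-12, seed = 51)
  statf <- frame_axes(array(diag(3), c(3, 3, n)))
  g <- lag_grid(n, 1e-12)
  te <- tensor_evolution(frame_axes(tr$triads), statf, g, dt = tr$dt)
  # static bond: C_00 = 1, C_0p = 0, and lag 0 reproduces delta_p0
  expect_lt(max(abs(te$value - 1)), 1e-10)
  expect_lt(max(Mod(te$components[-3, ])), 1e-10)
  # axially symmetric fast rotation: C_0+-1, C_0+-2 decay to ~0 and C_00
  # decays to the independent symmetric-top pair average
  beta <- acos(-1 / 3)
  h <- compose_hierarchy(motion_static(),
                         tetra_jump_model(1e9, n_sites = 6, beta = 0),
                         6e4, 5e-11, seed = 52)
  # bond tilted by beta from the rotation axis: tilt the bond triads
  tilt <- rot_y(beta)
  A <- dynland:::compose_triads(h$frames, tilt)
  g2 <- lag_grid(6e4, 5e-11, per_decade = 15)
  te2 <- tensor_evolution(frame_axes(A), frame_axes(h$frames), g2,
                          dt = h$dt)
  late <- which(g2$times > 20 / 1e9)
  # oracle: average of D_0p over independent pairs of 6-fold azimuths --
  # the tilted axial residual tensor seen in the bond frame
  phis <- 2 * pi * (0:5) / 6
  orac <- rowMeans(sapply(phis, function(dphi) {
    M <- t(tilt) %*% rot_z(dphi) %*% tilt
    Re(d2_0p_from_row3(M[3, 1], M[3, 2], M[3, 3])[, 1])
  }))
  got <- Re(rowMeans(te2$components[, late]))
  expect_equal(unname(got), unname(orac), tolerance = 0.05)
  expect_equal(te2$components[, 1], c(0, 0, 1, 0, 0) + 0i,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("POPC preset frames yield 4 chain motions and 3 head-group motions", {
  traj <- toy_popc_trajectory(n_steps = 6)
  sel <- resolve_selection(traj, popc_preset())
  # a palmitoyl methylene bond: libration + MOIxy + MOI -> 4 motions
  brow <- which(sel$bonds$site == "pal_C8")[1]
  expect_false(is.na(brow))
  vz <- bond_vectors(traj, sel$bonds[brow, c("C", "H")])[, , 1]
  bond <- bond_axes(vz)
  lib <- build_frame_axes(traj$xyz, "libration",
                          atoms = sel$libration[[brow]])
  pal <- sel$groups[[which(vapply(sel$groups, `[[`, "", "name") ==
                             "palmitoyl")]]
  moixy <- build_frame_axes(traj$xyz, "moixy", atoms = pal$atoms)
  moi <- build_frame_axes(traj$xyz, "moi", atoms = pal$atoms)
  g <- lag_grid(traj$n_steps, traj$dt, scheme = "all")
  dec <- suppressWarnings(suppressMessages(
    decompose_hierarchy(bond, list(lib, moixy, moi), g)))
  expect_length(dec$motions, 4)
  expect_equal(vapply(dec$motions, `[[`, "", "name"),
               c("libration", "parallel", "perpendicular", "overall"))
  # a head-group bond: libration + glycerol alignment -> 3 motions
  hrow <- which(sel$bonds$site == "beta")[1]
  vzh <- bond_vectors(traj, sel$bonds[hrow, c("C", "H")])[, , 1]
  libh <- build_frame_axes(traj$xyz, "libration",
                           atoms = sel$libration[[hrow]])
  gly <- sel$groups[[which(vapply(sel$groups, `[[`, "", "name") ==
                             "glycerol")]]
  glyf <- build_frame_axes(traj$xyz, "rigid_align", atoms = gly$atoms)
  dech <- suppressWarnings(suppressMessages(
    decompose_hierarchy(bond_axes(vzh), list(libh, glyf), g)))
  expect_length(dech$motions, 3)
  expect_equal(vapply(dech$motions, `[[`, "", "name"),
               c("libration", "internal", "overall"))
})
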