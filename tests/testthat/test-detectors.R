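test_that("experiment specs validate physical preconditions", {
  expect_error(experiment("R1"), "Larmor")
  expect_error(experiment("R1rho", field = 150e6, v1 = 2e3, vr = 5e3),
               "spin-lock condition")
  expect_error(experiment("R1", field = 150e6, sigma = -1), "sigma")
  expect_s3_class(experiment("order_parameter"), "experiment_spec")
})

test_that("rate sensitivities have the expected limiting behavior", {
  g <- z_grid()
  S <- build_rate_sensitivities(popc_experiment_set(), g)
  # extreme narrowing: all relaxation rows vanish as tau -> 0
  fast <- g$z <= -13.5
  expect_lt(max(S[1:7, fast] / apply(S[1:7, ], 1, max)), 1e-3)
  # order-parameter row is 1 at every z
  expect_equal(unname(S[8, ]), rep(1, length(g$z)))
  # R1 row maximum: agrees with an independent dense numeric scan of the
  # analytic expression
  spec <- popc_experiment_set()[[2]]                 # R1 at 150 MHz
  zfine <- seq(-10.5, -7.5, by = 1e-4)
  wC <- 2 * pi * 150e6; wH <- wC * dynland:::GAMMA_H / dynland:::GAMMA_C
  J <- function(w, tau) 2 / 5 * tau / (1 + (w * tau)^2)
  r1 <- function(z) {
    tau <- 10^z
    J(wH - wC, tau) + 3 * J(wC, tau) + 6 * J(wH + wC, tau)
  }
  z_star <- zfine[which.max(r1(zfine))]
  row <- S[2, ]
  expect_equal(g$z[which.max(row)], z_star, tolerance = g$dz * 1.01)
  # cross-check via root finding on the derivative
  dr <- function(z) (r1(z + 1e-6) - r1(z - 1e-6))
  root <- stats::uniroot(dr, c(-10, -8))$root
  expect_equal(z_star, root, tolerance = 1e-3)
})

test_that("R1rho reduces to R1-type terms at infinite spin lock", {
  g <- z_grid()
  slow <- g$z > -6
  hi <- build_rate_sensitivities(list(
    experiment("R1rho", field = 150e6, v1 = 5e9, vr = 5e3)), g)
  # at enormous omega_1 the near-spin-lock terms vanish: almost no
  # slow-motion sensitivity remains
  expect_lt(max(hi[1, slow]) / max(hi[1, ]), 5e-3)
  lo <- build_rate_sensitivities(list(
    experiment("R1rho", field = 150e6, v1 = 7e3, vr = 5e3)), g)
  expect_gt(max(lo[1, slow]) / max(lo[1, ]), 0.5)
})

test_that("trajectory time-point sensitivities are exp(-t/tau)", {
  g <- z_grid()
  lags <- c(1e-10, 1e-9, 1e-8)
  S <- build_md_sensitivities(lags, g)
  # first row is the zero lag: sensitivity identically 1
  expect_equal(unname(S[1, ]), rep(1, length(g$z)))
  # t = 10^z gives exactly exp(-1); rows 2.. are the positive lags
  for (i in seq_along(lags)) {
    zi <- which.min(abs(g$z - log10(lags[i])))
    expect_equal(unname(S[i + 1, zi]), exp(-lags[i] / 10^g$z[zi]),
                 tolerance = 1e-12)
  }
  # a very short positive lag is ~1 over the slower grid
  S0 <- build_md_sensitivities(c(1e-15, 1e-9), g)
  expect_gt(min(S0[2, g$z > -11]), 0.99)
  # sifting: a delta distribution at z0 reproduces exp(-t/10^z0) + S2
  z0 <- -9.06
  i0 <- which.min(abs(g$z - z0))
  A <- numeric(length(g$z)); A[i0] <- 1
  dd <- discrete_distribution(g$z, g$dz, A, one_minus_S2 = 1)
  got <- rates_from_distribution(dd, S)
  expect_equal(unname(got), exp(-c(0, lags) / 10^g$z[i0]),
               tolerance = 1e-12)
})

test_that("a single experiment yields its own normalized sensitivity", {
  g <- z_grid()
  S1 <- build_rate_sensitivities(list(experiment("R1", field = 150e6)), g)
  d1 <- optimize_detectors(S1, 1)
  expect_equal(unname(d1$rho[1, ]), unname(S1[1, ] / max(S1[1, ])),
               tolerance = 1e-6)
  expect_error(optimize_detectors(S1, 3), "usable rank")
})

test_that("well-separated synthetic rows are reconstructed by detectors", {
  g <- z_grid()
  centers <- c(-11, -8.5, -6)
  S <- t(sapply(centers, function(c0) 1 / (1 + ((g$z - c0) / 0.6)^2)))
  attr(S, "grid") <- g; attr(S, "norm") <- rep(1, 3)
  class(S) <- c("sensitivity_matrix", "matrix")
  ds <- optimize_detectors(S, 3)
  expect_lt(ds$recon_rel_error, 1e-3)
  expect_equal(order(ds$centers), 1:3)
})

test_that("the POPC experiment set reproduces the published detector geometry", {
  ds <- optimize_detectors(
    build_rate_sensitivities(popc_experiment_set(), z_grid()), 6)
  expect_equal(ds$widths[2:6], c(1.1, 0.8, 1.0, 1.3, 1.3), tolerance = 0.2)
  expect_equal(ds$tau0[2:5], c(110e-12, 790e-12, 3.7e-9, 6e-6),
               tolerance = 0.2)
  # partition of unity over the covered range (order-parameter row present)
  mid <- ds$grid$z > -13 & ds$grid$z < -4
  expect_true(all(colSums(ds$rho)[mid] > 0.9 & colSums(ds$rho)[mid] < 1.4))
  # non-negativity within tolerance, max-normalization
  expect_gt(min(ds$rho), -0.01)
  expect_equal(unname(apply(ds$rho, 1, max)), rep(1, 6), tolerance = 1e-6)
})

test_that("trajectory detectors match representable targets and refuse others", {
  g <- z_grid()
  target <- optimize_detectors(
    build_rate_sensitivities(popc_experiment_set(), g), 6)
  lags <- 10^seq(log10(5e-12), log10(8.4e-7), length.out = 40)
  md <- build_md_sensitivities(lags, g)
  # a target equal to one MD row is matched essentially exactly
  fake <- target
  fake$rho[2, ] <- md[20, ]
  fake$tau0[2] <- attr(md, "lags")[20]
  m1 <- match_detectors(md, fake, which = 2, k = 30)
  expect_lt(m1$mismatch[1], 1e-3)
  # the slow detectors (~6 and ~70 us) are beyond an 0.84 us trajectory
  expect_error(match_detectors(md, target, which = 6), "exceed")
  auto <- match_detectors(md, target)
  expect_equal(auto$target_index, 1:4)
  # matched ps-ns detectors overlap their targets to within 10% area
  expect_lt(max(auto$mismatch[2:4]), 0.10)
})

test_that("response fitting is exact, linear in data, and scales CIs", {
  g <- z_grid()
  specs <- popc_experiment_set()
  S <- build_rate_sensitivities(specs, g)
  ds <- optimize_detectors(S, 6)
  # zero rates and S2 = 1 give zero responses
  y0 <- rep(0, 8)
  r0 <- fit_responses(y0, ds, sigma = rep(0.01, 8))
  expect_lt(max(abs(r0$response)), 1e-12)
  # doubling sigma doubles the CI and leaves responses unchanged
  dist <- evaluate_distribution(
    motion_distribution("gaussian", 0.4, z0 = -8.5, sigma_z = 0.4), g)
  y <- rates_from_distribution(dist, S)
  f1 <- fit_responses(y, ds, sigma = pmax(abs(y) * 0.05, 1e-4))
  f2 <- fit_responses(y, ds, sigma = 2 * pmax(abs(y) * 0.05, 1e-4))
  expect_equal(f1$response, f2$response, tolerance = 1e-10)
  expect_equal(2 * f1$ci68, f2$ci68, tolerance = 1e-10)
  # responses of exact forward-model rates equal the response integrals
  # within the detector-set reconstruction error
  direct <- responses_from_distribution(dist, ds)
  expect_lt(max(abs(f1$response - direct$response)), 0.02)
  expect_error(fit_responses(y, ds), "uncertainty")
  expect_error(fit_responses(y[1:3], ds, sigma = rep(0.01, 3)),
               "8 experiments")
})

test_that("round trip matches direct integrals for many random distributions", {
  set.seed(61)
  g <- z_grid()
  S <- build_rate_sensitivities(popc_experiment_set(), g)
  ds <- optimize_detectors(S, 6)
  worst <- 0
  for (i in 1:50) {
    md <- motion_distribution("gaussian", runif(1, 0.05, 1),
                              z0 = runif(1, -12, -5),
                              sigma_z = runif(1, 0.2, 1.5))
    dist <- evaluate_distribution(md, g)
    y <- rates_from_distribution(dist, S)
    # 2% uncertainties on the scale of each measurement type
    fitted <- fit_responses(y, ds, sigma = 0.02 * attr(S, "norm"))
    direct <- responses_from_distribution(dist, ds)
    worst <- max(worst, max(abs(fitted$response - direct$response)))
  }
  expect_lt(worst, 0.02)
})

test_that("responses track (1-S2) theta(z0) times the width for smooth theta", {
  g <- z_grid()
  ds <- optimize_detectors(
    build_rate_sensitivities(popc_experiment_set(), g), 6)
  dist <- evaluate_distribution(
    motion_distribution("gaussian", 0.8, z0 = -8.6, sigma_z = 1.8), g)
  resp <- responses_from_distribution(dist, ds)
  for (n in 2:4) {           # detectors with centers inside the broad theta
    approx_r <- 0.8 * stats::approx(dist$z, dist$theta, ds$centers[n])$y *
      ds$widths[n]
    expect_lt(abs(resp$response[n] - approx_r), 0.1 * approx_r + 0.005)
  }
  # a delta at a detector peak with amplitude A returns ~A
  n <- 3
  ipk <- which.max(ds$rho[n, ])
  A <- numeric(length(g$z)); A[ipk] <- 1
  dd <- discrete_distribution(g$z, g$dz, A, one_minus_S2 = 0.37)
  expect_equal(responses_from_distribution(dd, ds)$response[n], 0.37,
               tolerance = 1e-9)
})

test_that("power-law distributions follow the detector scaling relations", {
  g <- z_grid()
  ds <- optimize_detectors(
    build_rate_sensitivities(popc_experiment_set(), g), 6)
  # 2D collective motion: flat theta, responses proportional to the width
  sel <- 2:6
  d2 <- evaluate_distribution(
    motion_distribution("power_law", 1, d = 2, zrange = range(g$z)), g)
  r2 <- responses_from_distribution(d2, ds)$response[sel]
  ratio2 <- r2 / ds$widths[sel]
  expect_lt(max(abs(ratio2 / mean(ratio2) - 1)), 0.10)
  # 3D: responses ~ width * 10^(-z0/2), over a power law supported on the
  # ps-ns window that detectors 1-3 cover cleanly
  sel <- 2:4
  d3 <- evaluate_distribution(
    motion_distribution("power_law", 1, d = 3, zrange = c(-11.5, -7.5)), g)
  r3 <- responses_from_distribution(d3, ds)$response[sel]
  ratio3 <- r3 / (ds$widths[sel] * 10^(-ds$centers[sel] / 2))
  expect_lt(max(abs(ratio3 / mean(ratio3) - 1)), 0.15)
})

test_that("exponential series fits recover rates with honest uncertainties", {
  tt <- c(0, 10^seq(-2.2, 0.5, length.out = 11))
  R0 <- 2.4
  y <- exp(-tt * R0)
  f <- fit_exponential_series(tt, y)
  expect_equal(f$rate, R0, tolerance = 1e-8)
  fr <- fit_exponential_series(tt, 3 * (1 - exp(-tt * R0)),
                               model = "recovery")
  expect_equal(fr$rate, R0, tolerance = 1e-8)
  expect_equal(fit_exponential_series(tt, rep(2, 12))$rate, 0)
  # Monte-Carlo coverage of the 95% CI with 5% Gaussian noise
  set.seed(62)
  hits <- 0; nrep <- 400
  for (i in seq_len(nrep)) {
    yn <- y + rnorm(length(y), sd = 0.05)
    fi <- fit_exponential_series(tt, yn, sigma = rep(0.05, length(y)))
    if (abs(fi$rate - R0) < 1.96 * fi$sigma_rate) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.93)
})

test_that("order parameters from couplings behave and validate", {
  expect_equal(order_parameter_from_coupling(0, 2)$S_abs, 0)
  expect_equal(order_parameter_from_coupling(2, 2)$one_minus_S2, 0)
  expect_error(order_parameter_from_coupling(3, 2), "rigid limit")
  # tetrahedral 3-site jump: |S| = |<P2>| = 1/3
  res <- analytic_residual(tetra_jump_model())
  s <- order_parameter_from_coupling(res$delta_ratio, 1)
  expect_equal(s$S_abs, 1 / 3, tolerance = 1e-10)
})

test_that("experiment tables round-trip through the text format", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("type field v1 vr value sigma",
               "R1 150e6 0 0 1.2 0.05",
               "R1rho 150e6 12e3 5e3 8.1 0.4",
               "order_parameter NA 0 0 0.71 0.02"), path)
  specs <- read_experiments(path)
  expect_length(specs, 3)
  expect_equal(specs[[2]]$v1, 12e3)
  expect_equal(specs[[3]]$value, 0.71)
})
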