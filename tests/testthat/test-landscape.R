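test_that("evaluated distributions are normalized with the stated shape", {
  g <- z_grid()
  d <- evaluate_distribution(
    motion_distribution("gaussian", 0.5, z0 = -9, sigma_z = 0.5), g)
  expect_equal(sum(d$theta) * d$dz, 1, tolerance = 1e-9)
  expect_equal(sum(d$z * d$A), -9, tolerance = 1e-6)
  # skewed Gaussian leans towards slow times for positive alpha
  sk <- evaluate_distribution(
    motion_distribution("skewed_gaussian", 0.5, z0 = -9, sigma_z = 0.5,
                        alpha = 4), g)
  expect_gt(sum(sk$z * sk$A), -9)
  expect_equal(sum(sk$theta) * sk$dz, 1, tolerance = 1e-9)
  # power law with d = 2 is uniform on its support
  pl <- evaluate_distribution(
    motion_distribution("power_law", 1, d = 2, zrange = c(-10, -8)), g)
  on_support <- pl$theta[pl$z > -9.9 & pl$z < -8.1]
  expect_lt(diff(range(on_support)) / mean(on_support), 1e-9)
  # far-off-grid center is refused
  expect_error(evaluate_distribution(
    motion_distribution("gaussian", 0.5, z0 = -30, sigma_z = 0.5), g),
    "outside the grid")
})

test_that("combining motions multiplies correlation functions and S2", {
  g <- z_grid()
  d1 <- evaluate_distribution(
    motion_distribution("gaussian", 0.5, z0 = -9, sigma_z = 0.5), g)
  d2 <- evaluate_distribution(
    motion_distribution("gaussian", 0.3, z0 = -6.5, sigma_z = 0.4), g)
  d3 <- evaluate_distribution(
    motion_distribution("skewed_gaussian", 0.7, z0 = -11, sigma_z = 0.3), g)
  comb <- combine_motions(list(d1, d2, d3))
  tt <- 10^seq(-12.5, -4, length.out = 100)
  prod_ct <- ct_from_distribution(d1, tt) * ct_from_distribution(d2, tt) *
    ct_from_distribution(d3, tt)
  expect_lt(max(abs(ct_from_distribution(comb, tt) - prod_ct)), 1e-3)
  expect_equal(comb$S2, d1$S2 * d2$S2 * d3$S2, tolerance = 1e-12)
  # identity element: S2 = 1 leaves the partner unchanged
  id <- evaluate_distribution(
    motion_distribution("gaussian", 0, z0 = -9, sigma_z = 0.5), g)
  expect_equal(combine_motions(list(id, d2))$A, d2$A, tolerance = 1e-12)
  # commutative and associative within re-binning tolerance
  c12 <- combine_motions(list(combine_two(d1, d2), d3))
  c21 <- combine_motions(list(d3, combine_two(d2, d1)))
  expect_lt(max(abs(ct_from_distribution(c12, tt) -
                    ct_from_distribution(c21, tt))), 1e-3)
})

test_that("two single-exponential motions produce the three-term expansion", {
  g <- z_grid(-12, -5, 400)
  mk <- function(a, i0) {
    A <- numeric(length(g$z)); A[i0] <- 1
    discrete_distribution(g$z, g$dz, A, a)
  }
  s1 <- mk(0.4, 100); s2 <- mk(0.6, 130)
  cb <- combine_two(s1, s2)
  t1 <- 10^g$z[100]; t2 <- 10^g$z[130]
  # amplitudes: S1^2 a2 at tau2, S2^2 a1 at tau1, a1 a2 at the cross time
  expect_equal(cb$A[130] * cb$one_minus_S2, 0.6 * 0.6, tolerance = 1e-9)
  expect_equal(cb$A[100] * cb$one_minus_S2, 0.4 * 0.4, tolerance = 1e-9)
  cross_z <- log10(t1 * t2 / (t1 + t2))
  icross <- which(cb$A > 1e-12 & !(seq_along(cb$A) %in% c(100, 130)))
  expect_lte(length(icross), 2)   # split over the two bracketing bins
  expect_equal(sum(cb$A[icross] * g$z[icross]) / sum(cb$A[icross]), cross_z,
               tolerance = 1e-9)  # first moment conserved
  tt <- 10^seq(-11, -5.5, length.out = 100)
  cexp <- (0.6 + 0.4 * exp(-tt / t1)) * (0.4 + 0.6 * exp(-tt / t2))
  expect_lt(max(abs(ct_from_distribution(cb, tt) - cexp)), 1e-3)
})

test_that("grid search recovers known distribution parameters", {
  g <- z_grid()
  ds <- optimize_detectors(
    build_rate_sensitivities(popc_experiment_set(), g), 6)
  truth <- motion_distribution("gaussian", 0.5, z0 = -9, sigma_z = 0.5)
  resp <- responses_from_distribution(evaluate_distribution(truth, g), ds)
  fit <- fit_motion_distribution(resp, ds, model = "gaussian")
  expect_lt(abs(fit$z0 - truth$z0), 0.1 + 1e-9)     # one grid step
  expect_lt(abs(fit$sigma_z - truth$sigma_z), 0.05 + 1e-9)
  expect_lt(abs(fit$one_minus_S2 - 0.5), 0.025)     # within 5%
  # delta-like distribution: width pinned at the grid minimum
  A <- numeric(length(g$z)); A[90] <- 1
  dd <- discrete_distribution(g$z, g$dz, A, 0.4)
  respd <- responses_from_distribution(dd, ds)
  fitd <- fit_motion_distribution(respd, ds, model = "gaussian")
  expect_equal(fitd$sigma_z, 0.1)
  expect_lt(abs(fitd$one_minus_S2 - 0.4), 0.02)
  # all-zero responses: amplitude zero, flagged undetermined
  z0r <- respd; z0r$response[] <- 0
  f0 <- fit_motion_distribution(z0r, ds)
  expect_equal(f0$one_minus_S2, 0)
  expect_true(isTRUE(attr(f0, "undetermined")))
})

test_that("site landscapes combine motions and refine against NMR", {
  g <- z_grid()
  ds <- optimize_detectors(
    build_rate_sensitivities(popc_experiment_set(), g), 6)
  mk_site <- function(site, z0_int) {
    site_landscape(site, motions = list(
      internal = motion_distribution("skewed_gaussian", 0.6, z0 = z0_int,
                                     sigma_z = 0.4),
      overall = motion_distribution("gaussian", 0.3, z0 = -6.2,
                                    sigma_z = 0.6)),
      internal = "internal", resonance = "res1", grid = g)
  }
  truth <- list(mk_site("s1", -9.2), mk_site("s2", -8.8))
  # combined S2 is the product of per-motion S2
  expect_equal(truth[[1]]$combined$S2, (1 - 0.6) * (1 - 0.3),
               tolerance = 1e-9)
  nmr <- list(res1 = responses_from_distribution(truth[[1]]$combined, ds))
  nmr$res1$ci68 <- pmax(0.02 * nmr$res1$response, 0.002)
  # already-matching landscape: refinement shift stays at zero
  ref0 <- refine_internal_timescales(truth[1], nmr, ds)
  expect_equal(ref0[[1]]$scale_shift, 0, tolerance = 1e-9)
  # internal timescale misstated by x3: the common shift recovers log10(3)
  wrong <- list(mk_site("s1", -9.2 + log10(3)))
  ref <- refine_internal_timescales(wrong, nmr, ds)
  expect_lt(abs(ref[[1]]$scale_shift + log10(3)), 0.051)
  # overall motion untouched by refinement
  expect_equal(ref[[1]]$motions$overall$z0, -6.2)
  # two sites sharing a resonance with opposite misfits: the applied common
  # shift matches an independent dense scan of the joint objective
  pair <- list(mk_site("s1", -9.2 + 0.4), mk_site("s2", -8.8 - 0.3))
  refp <- refine_internal_timescales(pair, nmr, ds)
  shifts <- seq(-1.5, 1.5, by = 0.05)
  w <- 1 / nmr$res1$ci68^2
  chi <- vapply(shifts, function(s) {
    tot <- 0
    for (sl in pair) {
      m <- sl$motions
      m$internal$z0 <- m$internal$z0 + s
      cmb <- combine_motions(lapply(m, evaluate_distribution, grid = g))
      r <- responses_from_distribution(cmb, ds)$response
      tot <- tot + sum(w * (nmr$res1$response - r)^2)
    }
    tot
  }, numeric(1))
  expect_equal(refp[[1]]$scale_shift, shifts[which.min(chi)],
               tolerance = 1e-9)
  # a group with no NMR data is left unscaled with a message
  lone <- list(mk_site("s3", -9))
  lone[[1]]$resonance <- "res_unmatched"
  expect_message(refl <- refine_internal_timescales(lone, nmr, ds),
                 "left unscaled")
  expect_equal(refl[[1]]$scale_shift, 0)
})

test_that("landscape tables serialize one row per site and motion", {
  g <- z_grid()
  sl <- site_landscape("s1", motions = list(
    internal = motion_distribution("skewed_gaussian", 0.5, -9, 0.4),
    overall = motion_distribution("gaussian", 0.2, -6, 0.5)), grid = g)
  tab <- landscape_table(list(sl))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$motion, c("internal", "overall"))
  prefix <- tempfile()
  write_landscape(list(sl), prefix)
  expect_true(file.exists(paste0(prefix, "_params.tsv")))
  th <- utils::read.delim(paste0(prefix, "_theta.tsv"), check.names = FALSE)
  expect_equal(nrow(th), length(g$z))
})
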