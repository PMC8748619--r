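# Dynamic landscape: parameterized correlation-time distributions fitted to
# detector responses per separated motion, combined across motions by
# correlation-function products, and refined against experimental detector
# responses by per-resonance timescale scaling.

#' Parameterized correlation-time distribution of one motion
#'
#' Three-parameter model of the distribution of motion \eqn{(1-S^2)\theta(z)}
#' on \eqn{z = \log_{10}(\tau_c/s)}: amplitude \eqn{1-S^2}, center
#' \eqn{z_0}, width \eqn{\sigma_z} (decades). Internal motions use a skewed
#' Gaussian (fixed skew shape \code{alpha}, motivated by power-law behavior
#' of collective contributions), overall motions a plain Gaussian; a
#' bounded power-law form is available for collective motion of
#' dimensionality \code{d}.
#'
#' @param model \code{"gaussian"}, \code{"skewed_gaussian"} or
#'   \code{"power_law"}.
#' @param one_minus_S2 Amplitude in \eqn{[0, 1]}.
#' @param z0 Center (log10 seconds).
#' @param sigma_z Width in decades (> 0).
#' @param alpha Skew shape (skewed Gaussian only; sign included).
#' @param d Dimensionality (power law only).
#' @param zrange Support (power law only).
#' @return An object of class \code{motion_distribution}.
#' @export
motion_distribution <- function(model = c("gaussian", "skewed_gaussian",
                                          "power_law"),
                                one_minus_S2, z0 = NA_real_,
                                sigma_z = NA_real_, alpha = 4,
                                d = NULL, zrange = NULL) {
  model <- match.arg(model)
  if (one_minus_S2 < -1e-9 || one_minus_S2 > 1 + 1e-9) {
    stop("amplitude 1 - S^2 must lie in [0, 1]")
  }
  if (model != "power_law" && (!is.finite(z0) || !is.finite(sigma_z) ||
                               sigma_z <= 0)) {
    stop("gaussian models need finite z0 and positive sigma_z")
  }
  if (model == "power_law" && (is.null(d) || is.null(zrange))) {
    stop("power_law needs d and zrange")
  }
  structure(list(model = model,
                 one_minus_S2 = min(max(one_minus_S2, 0), 1),
                 z0 = z0, sigma_z = sigma_z, alpha = alpha, d = d,
                 zrange = zrange),
            class = "motion_distribution")
}

#' @export
print.motion_distribution <- function(x, ...) {
  cat(sprintf("motion distribution (%s): 1-S2 = %.3f", x$model,
              x$one_minus_S2))
  if (x$model != "power_law") {
    cat(sprintf(", z0 = %.2f (tau = %.3g s), sigma_z = %.2f", x$z0, 10^x$z0,
                x$sigma_z))
  } else {
    cat(sprintf(", d = %g on [%g, %g]", x$d, x$zrange[1], x$zrange[2]))
  }
  cat("\n")
  if (isTRUE(attr(x, "undetermined"))) {
    cat("  (zero amplitude: center/width undetermined)\n")
  }
  invisible(x)
}

# unnormalized density of the model on z values
distribution_density <- function(model, z) {
  switch(model$model,
    gaussian = stats::dnorm(z, model$z0, model$sigma_z),
    skewed_gaussian = {
      u <- (z - model$z0) / model$sigma_z
      stats::dnorm(u) * stats::pnorm(model$alpha * u)
    },
    power_law = {
      th <- 10^(-z * (model$d / 2 - 1))
      th[z < model$zrange[1] | z > model$zrange[2]] <- 0
      th
    })
}

#' Discretize a motion distribution on a z grid
#'
#' Evaluates \eqn{\theta(z)} on the grid and renormalizes so that the
#' quadrature integral is exactly 1; the amplitude \eqn{1-S^2} is carried
#' separately.
#'
#' @param model A [motion_distribution()].
#' @param grid A [z_grid()].
#' @return An object of class \code{discrete_distribution}: fields \code{z},
#'   \code{dz}, \code{theta} (density, \eqn{\sum\theta_i \Delta z = 1}),
#'   \code{A} (bin amplitudes \eqn{\theta_i \Delta z}),
#'   \code{one_minus_S2}.
#' @export
evaluate_distribution <- function(model, grid = z_grid()) {
  z <- grid$z
  if (model$model != "power_law") {
    if (model$z0 < min(z) - 2 * model$sigma_z ||
        model$z0 > max(z) + 2 * model$sigma_z) {
      stop(sprintf("distribution center z0 = %.2f lies far outside the grid [%.1f, %.1f]",
                   model$z0, min(z), max(z)))
    }
  }
  th <- distribution_density(model, z)
  s <- sum(th) * grid$dz
  if (s <= 0) stop("distribution evaluates to zero on the grid")
  th <- th / s
  discrete_distribution(z, grid$dz, th * grid$dz, model$one_minus_S2)
}

#' Discrete correlation-time distribution
#'
#' @param z Grid of log10 correlation times.
#' @param dz Grid spacing.
#' @param A Non-negative bin amplitudes (normalized to sum 1).
#' @param one_minus_S2 Amplitude of the motion.
#' @return A \code{discrete_distribution}.
#' @export
discrete_distribution <- function(z, dz, A, one_minus_S2) {
  stopifnot(length(A) == length(z), all(A > -1e-12))
  A <- pmax(A, 0)
  s <- sum(A)
  if (s > 0) A <- A / s
  structure(list(z = z, dz = dz, A = A, theta = A / dz,
                 one_minus_S2 = one_minus_S2, S2 = 1 - one_minus_S2),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  zm <- if (sum(x$A) > 0) sum(x$z * x$A) else NA_real_
  cat(sprintf(
    "discrete distribution: %d bins, 1-S2 = %.3f, mean z = %.2f (tau ~ %.3g s)\n",
    length(x$z), x$one_minus_S2, zm, 10^zm))
  invisible(x)
}

#' Correlation function of a discrete distribution
#'
#' \eqn{C(t) = S^2 + (1-S^2)\sum_i A_i \exp(-t/\tau_i)} with
#' \eqn{\tau_i = 10^{z_i}} s.
#'
#' @param dist A \code{discrete_distribution}.
#' @param t Lag times in seconds.
#' @return Numeric vector of C(t).
#' @export
ct_from_distribution <- function(dist, t) {
  tau <- 10^dist$z
  dist$S2 + dist$one_minus_S2 *
    vapply(t, function(tt) sum(dist$A * exp(-tt / tau)), numeric(1))
}

# split weights w at log-times zc linearly between bracketing grid bins,
# conserving total amplitude and the first moment of z
rebin_weights <- function(zc, w, z, dz) {
  nz <- length(z)
  zc <- pmin(pmax(zc, z[1]), z[nz])
  lo <- pmin(findInterval(zc, z), nz - 1L)
  frac <- (zc - z[lo]) / dz
  acc <- numeric(nz)
  add <- function(idx, ww) {
    t <- tapply(ww, factor(idx, levels = seq_len(nz)), sum, default = 0)
    acc + as.numeric(t)
  }
  acc <- add(lo, w * (1 - frac))
  acc <- add(lo + 1L, w * frac)
  acc
}

combine_two <- function(d1, d2) {
  if (max(abs(d1$z - d2$z)) > 1e-9) stop("distributions on different z grids")
  z <- d1$z; dz <- d1$dz; nz <- length(z)
  a1 <- d1$one_minus_S2; a2 <- d2$one_minus_S2
  S1 <- 1 - a1; S2 <- 1 - a2
  S12 <- S1 * S2
  A <- S1 * a2 * d2$A + S2 * a1 * d1$A
  if (a1 > 0 && a2 > 0) {
    nz1 <- which(d1$A > 0); nz2 <- which(d2$A > 0)
    if (length(nz1) && length(nz2)) {
      t1 <- 10^z[nz1]; t2 <- 10^z[nz2]
      W <- outer(d1$A[nz1], d2$A[nz2]) * a1 * a2
      ZC <- log10(outer(t1, t2, function(x, y) x * y / (x + y)))
      A <- A + rebin_weights(as.vector(ZC), as.vector(W), z, dz)
    }
  }
  discrete_distribution(z, dz, A, 1 - S12)
}

#' Combine motions by the correlation-function product
#'
#' Combines discrete correlation-time distributions of independent motions
#' so that the combined distribution's correlation function equals the
#' product of the members': the product of multi-exponential decays yields
#' \eqn{S^2}-weighted original components plus cross terms at
#' \eqn{\tau_i\tau_j/(\tau_i + \tau_j)}, which are re-binned onto the grid
#' conserving amplitude and the first moment of \eqn{z}. The combined
#' order parameter is \eqn{S^2 = \prod_k S_k^2}.
#'
#' @param dists List of \code{discrete_distribution} on one grid (a single
#'   distribution is returned unchanged).
#' @return A \code{discrete_distribution}.
#' @export
combine_motions <- function(dists) {
  if (inherits(dists, "discrete_distribution")) return(dists)
  stopifnot(length(dists) >= 1)
  Reduce(combine_two, dists)
}

#' Fit a motion distribution to detector responses
#'
#' Grid search over center and width; at every node the amplitude is the
#' bounded linear least-squares solution against the forward-evaluated
#' detector responses of the unit-amplitude distribution. The chi-squared
#' profile over the grid is returned alongside the best node.
#'
#' @param responses A \code{detector_responses} object (uncertainties are
#'   used as weights when finite).
#' @param dset The \code{detector_set} the responses belong to.
#' @param model \code{"gaussian"} or \code{"skewed_gaussian"}.
#' @param z0_step Center grid step (decades).
#' @param sigma_grid Width grid (decades).
#' @param alpha Skew shape for the skewed model.
#' @param use Indices of responses to fit (default all).
#' @return A [motion_distribution()] with attributes \code{chi2},
#'   \code{profile} (chi2 matrix over the grid), \code{z0_grid},
#'   \code{sigma_grid}; flagged \code{undetermined} when all responses
#'   vanish.
#' @export
fit_motion_distribution <- function(responses, dset,
                                    model = c("skewed_gaussian", "gaussian"),
                                    z0_step = 0.1,
                                    sigma_grid = seq(0.1, 2, by = 0.05),
                                    alpha = 4, use = NULL) {
  model <- match.arg(model)
  y <- responses$response
  w <- ifelse(is.finite(responses$ci68) & responses$ci68 > 0,
              1 / responses$ci68^2, 1)
  if (!is.null(use)) {
    sel <- rep(FALSE, length(y)); sel[use] <- TRUE
    w[!sel] <- 0
  }
  grid <- dset$grid
  z0s <- seq(min(grid$z), max(grid$z), by = z0_step)
  prof <- matrix(NA_real_, length(z0s), length(sigma_grid))
  best <- list(chi2 = Inf)
  if (all(abs(y) < 1e-12)) {
    out <- motion_distribution(model, 0, z0 = mean(grid$z),
                               sigma_z = sigma_grid[1], alpha = alpha)
    attr(out, "undetermined") <- TRUE
    attr(out, "chi2") <- 0
    return(out)
  }
  for (i in seq_along(z0s)) {
    for (j in seq_along(sigma_grid)) {
      md <- motion_distribution(model, 1, z0 = z0s[i],
                                sigma_z = sigma_grid[j], alpha = alpha)
      dd <- tryCatch(evaluate_distribution(md, grid), error = function(e) NULL)
      if (is.null(dd)) next
      r <- drop(dset$rho %*% dd$theta) * dd$dz
      denom <- sum(w * r^2)
      a <- if (denom > 0) sum(w * r * y) / denom else 0
      a <- min(max(a, 0), 1)
      chi2 <- sum(w * (y - a * r)^2)
      prof[i, j] <- chi2
      if (chi2 < best$chi2) {
        best <- list(chi2 = chi2, z0 = z0s[i], sigma = sigma_grid[j], a = a)
      }
    }
  }
  out <- motion_distribution(model, best$a, z0 = best$z0,
                             sigma_z = best$sigma, alpha = alpha)
  attr(out, "chi2") <- best$chi2
  attr(out, "profile") <- prof
  attr(out, "z0_grid") <- z0s
  attr(out, "sigma_grid") <- sigma_grid
  out
}

#' Per-site landscape container
#'
#' @param site Site label.
#' @param motions Named list of [motion_distribution()] per separated
#'   motion.
#' @param internal Character vector naming which motions are internal
#'   (their timescales are subject to experimental refinement; overall
#'   motions are not).
#' @param resonance Resonance-group label shared by NMR-unresolved sites.
#' @param grid A [z_grid()] for the combined distribution.
#' @return An object of class \code{site_landscape}, with the combined
#'   \code{discrete_distribution} under \code{$combined}.
#' @export
site_landscape <- function(site, motions, internal = names(motions),
                           resonance = site, grid = z_grid()) {
  stopifnot(length(motions) >= 1, !is.null(names(motions)))
  combined <- combine_motions(lapply(motions, evaluate_distribution,
                                     grid = grid))
  structure(list(site = site, motions = motions, internal = internal,
                 resonance = resonance, grid = grid, combined = combined,
                 scale_shift = 0),
            class = "site_landscape")
}

#' @export
print.site_landscape <- function(x, ...) {
  cat(sprintf("site %s (resonance %s): %d motions, combined 1-S2 = %.3f\n",
              x$site, x$resonance, length(x$motions),
              x$combined$one_minus_S2))
  for (nm in names(x$motions)) {
    m <- x$motions[[nm]]
    cat(sprintf("  %-14s %-16s 1-S2 = %.3f  z0 = %.2f  sigma = %.2f%s\n",
                nm, m$model, m$one_minus_S2, m$z0, m$sigma_z,
                if (nm %in% x$internal) " (internal)" else ""))
  }
  invisible(x)
}

shift_site <- function(sl, shift) {
  sl$motions <- lapply(stats::setNames(names(sl$motions), names(sl$motions)),
                       function(nm) {
    m <- sl$motions[[nm]]
    if (nm %in% sl$internal && m$model != "power_law") m$z0 <- m$z0 + shift
    m
  })
  sl$combined <- combine_motions(lapply(sl$motions, evaluate_distribution,
                                        grid = sl$grid))
  sl$scale_shift <- sl$scale_shift + shift
  sl
}

#' Refine internal timescales against NMR detector responses
#'
#' For each resonance group, one common shift of the internal-motion
#' centers (all internal motions of all sites in the group shifted
#' identically; overall motions untouched) is chosen by a dense scan to
#' minimize the weighted squared deviation between the NMR detector
#' responses and the responses of the combined distribution. Groups
#' without NMR data are left unscaled and reported.
#'
#' @param landscape List of [site_landscape()] objects.
#' @param nmr Named list: for each resonance-group label, a
#'   \code{detector_responses} object (68% CIs used as weights).
#' @param dset The experimental \code{detector_set}.
#' @param shifts Candidate shifts in decades.
#' @return The refined list of \code{site_landscape}; each carries its
#'   applied shift in \code{$scale_shift} (the correlation-time scale
#'   factor is \code{10^shift}).
#' @export
refine_internal_timescales <- function(landscape, nmr, dset,
                                       shifts = seq(-1.5, 1.5, by = 0.05)) {
  groups <- split(seq_along(landscape),
                  vapply(landscape, `[[`, "", "resonance"))
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (is.null(nmr[[g]])) {
      message("resonance group ", g, " has no NMR data; left unscaled")
      next
    }
    resp <- nmr[[g]]
    w <- ifelse(is.finite(resp$ci68) & resp$ci68 > 0, 1 / resp$ci68^2, 1)
    chi <- vapply(shifts, function(s) {
      tot <- 0
      for (i in idx) {
        sl <- shift_site(landscape[[i]], s)
        r <- responses_from_distribution(sl$combined, dset)$response
        tot <- tot + sum(w * (resp$response - r)^2)
      }
      tot
    }, numeric(1))
    s_best <- shifts[which.min(chi)]
    for (i in idx) landscape[[i]] <- shift_site(landscape[[i]], s_best)
  }
  landscape
}

#' Landscape long-format table
#'
#' @param landscape List of \code{site_landscape}.
#' @return Data frame with one row per site and motion (site, motion,
#'   model, amplitude, center, width, shift).
#' @export
landscape_table <- function(landscape) {
  do.call(rbind, lapply(landscape, function(sl) {
    do.call(rbind, lapply(names(sl$motions), function(nm) {
      m <- sl$motions[[nm]]
      data.frame(site = sl$site, motion = nm, model = m$model,
                 one_minus_S2 = m$one_minus_S2, z0 = m$z0,
                 sigma_z = m$sigma_z, shift = sl$scale_shift,
                 resonance = sl$resonance)
    }))
  }))
}

#' Write a landscape as delimited tables
#'
#' Writes the long-format parameter table and the gridded
#' \eqn{(1-S^2)\theta(z)} matrix of the combined distributions.
#'
#' @param landscape List of \code{site_landscape}.
#' @param prefix Output path prefix (creates \code{<prefix>_params.tsv} and
#'   \code{<prefix>_theta.tsv}).
#' @export
write_landscape <- function(landscape, prefix) {
  tab <- landscape_table(landscape)
  utils::write.table(tab, paste0(prefix, "_params.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  th <- sapply(landscape, function(sl) sl$combined$theta *
                 sl$combined$one_minus_S2)
  colnames(th) <- vapply(landscape, `[[`, "", "site")
  df <- data.frame(z = landscape[[1]]$grid$z, th, check.names = FALSE)
  utils::write.table(df, paste0(prefix, "_theta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
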