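# Timescale sensitivities of NMR relaxation experiments and of trajectory
# correlation-function time points, on a grid of log10 correlation times.
#
# All relaxation sensitivities are dipolar (1H-13C), evaluated for a
# unit-amplitude motion at a single correlation time tau_c = 10^z s with
# the normalized Lorentzian spectral density J(w) = (2/5) tau/(1+(w tau)^2).
# CSA contributions are omitted by default (dipolar coupling dominates for
# protonated carbons); a hook is left via the `delta` override.

GAMMA_H <- 2.6752218744e8   # rad/s/T
GAMMA_C <- 6.728284e7       # rad/s/T
HBAR <- 1.054571817e-34     # J s
MU0_4PI <- 1e-7

#' Log-correlation-time grid
#'
#' Uniform grid in \eqn{z = \log_{10}(\tau_c / s)}. The default spans
#' \code{[-14, -3]} (fs to ms) with 200 points, bracketing the sensitive
#' ranges of all supported experiments.
#'
#' @param zmin,zmax Grid limits.
#' @param n Number of points.
#' @return An object of class \code{z_grid} with fields \code{z} and
#'   \code{dz}.
#' @export
z_grid <- function(zmin = -14, zmax = -3, n = 200L) {
  stopifnot(zmax > zmin, n >= 10)
  z <- seq(zmin, zmax, length.out = n)
  structure(list(z = z, dz = z[2] - z[1]), class = "z_grid")
}

#' @export
print.z_grid <- function(x, ...) {
  cat(sprintf("z grid: %d points on [%.1f, %.1f] (tau_c %.3g..%.3g s)\n",
              length(x$z), min(x$z), max(x$z), 10^min(x$z), 10^max(x$z)))
  invisible(x)
}

#' NMR experiment descriptor
#'
#' Describes one measurement used for detector analysis. \code{type}
#' \code{"R1"} is the longitudinal relaxation rate, \code{"NOE_sigma"} the
#' heteronuclear cross-relaxation rate constant, \code{"R1rho"} the
#' rotating-frame rate under an on-resonance spin lock with magic-angle
#' spinning, and \code{"order_parameter"} a residual-coupling measurement
#' whose data value is \eqn{1 - S^2} (its sensitivity is 1 at every
#' correlation time).
#'
#' @param type Experiment type (see above).
#' @param field \eqn{^{13}}C Larmor frequency \eqn{\omega_0/2\pi} in Hz.
#' @param v1 Spin-lock strength \eqn{\omega_1/2\pi} in Hz (R1rho only).
#' @param vr MAS rate \eqn{\omega_r/2\pi} in Hz (R1rho only).
#' @param value,sigma Measured value and its uncertainty (1/s for rates;
#'   dimensionless \eqn{1-S^2} for \code{order_parameter}).
#' @param dHC Effective H-C distance in meters (default 1.115 Angstrom,
#'   vibrationally corrected).
#' @return An object of class \code{experiment_spec}.
#' @export
experiment <- function(type = c("R1", "NOE_sigma", "R1rho", "order_parameter"),
                       field = NA_real_, v1 = 0, vr = 0,
                       value = NA_real_, sigma = NA_real_,
                       dHC = 1.115e-10) {
  type <- match.arg(type)
  if (type != "order_parameter" && (!is.finite(field) || field <= 0)) {
    stop("relaxation experiments require a positive 13C Larmor frequency")
  }
  if (type == "R1rho") {
    if (v1 <= 0) stop("R1rho requires a positive spin-lock strength")
    if (v1 <= vr / 2) {
      stop(sprintf(
        "spin-lock condition violated: omega_1/2pi = %g Hz <= omega_r/4pi = %g Hz",
        v1, vr / 2))
    }
  }
  if (is.finite(sigma) && sigma <= 0) stop("sigma must be positive")
  structure(list(type = type, field = field, v1 = v1, vr = vr,
                 value = value, sigma = sigma, dHC = dHC),
            class = "experiment_spec")
}

# dipolar coupling anisotropy delta = (mu0/4pi) gammaH gammaC hbar / r^3 (rad/s)
dipolar_delta <- function(dHC) {
  MU0_4PI * GAMMA_H * GAMMA_C * HBAR / dHC^3
}

# normalized spectral density for tau_c = 10^z
Jw <- function(w, tau) (2 / 5) * tau / (1 + (w * tau)^2)

# one sensitivity row R_zeta(z) over the grid
rate_sensitivity_row <- function(spec, grid) {
  tau <- 10^grid$z
  if (spec$type == "order_parameter") return(rep(1, length(tau)))
  wC <- 2 * pi * spec$field
  wH <- wC * GAMMA_H / GAMMA_C
  d2 <- dipolar_delta(spec$dHC)^2
  switch(spec$type,
    R1 = d2 / 4 * (Jw(wH - wC, tau) + 3 * Jw(wC, tau) + 6 * Jw(wH + wC, tau)),
    NOE_sigma = d2 / 4 * (6 * Jw(wH + wC, tau) - Jw(wH - wC, tau)),
    R1rho = {
      w1 <- 2 * pi * spec$v1
      wr <- 2 * pi * spec$vr
      # standard Redfield dipolar treatment under on-resonance spin lock
      # with MAS: the solution-state 4 J(w1) spin-lock term splits over the
      # rotary-resonance sidebands w1 +- wr and w1 +- 2 wr; w1 -> Inf
      # leaves only the R1-type (high-frequency) terms, wr -> 0 restores
      # the total weight 4 J(w1).
      sl <- (2 / 3) * Jw(abs(w1 - 2 * wr), tau) +
        (4 / 3) * Jw(abs(w1 - wr), tau) +
        (4 / 3) * Jw(w1 + wr, tau) +
        (2 / 3) * Jw(w1 + 2 * wr, tau)
      d2 / 8 * (Jw(wH - wC, tau) + 3 * Jw(wC, tau) + 6 * Jw(wH + wC, tau) +
                6 * Jw(wH, tau) + sl)
    })
}

#' Sensitivity matrix of a set of experiments
#'
#' One row per experiment, evaluated on the z grid; the
#' \code{order_parameter} row is identically 1 (a residual coupling weighs
#' all correlation times equally).
#'
#' @param specs List of [experiment()] objects.
#' @param grid A [z_grid()].
#' @return A \code{sensitivity_matrix}: numeric matrix with attributes
#'   \code{grid}, \code{specs}, \code{norm} (the per-row normalization used
#'   downstream: the measurement uncertainty where available, otherwise the
#'   row maximum).
#' @export
build_rate_sensitivities <- function(specs, grid = z_grid()) {
  if (inherits(specs, "experiment_spec")) specs <- list(specs)
  S <- t(vapply(specs, rate_sensitivity_row, numeric(length(grid$z)),
                grid = grid))
  rownames(S) <- vapply(specs, function(s) {
    switch(s$type,
      order_parameter = "1-S2",
      R1 = sprintf("R1_%gMHz", s$field / 1e6),
      NOE_sigma = sprintf("NOE_%gMHz", s$field / 1e6),
      R1rho = sprintf("R1rho_%gkHz", s$v1 / 1e3))
  }, character(1))
  nrm <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (is.finite(s$sigma) && s$sigma > 0) s$sigma else max(abs(S[i, ]))
  }, numeric(1))
  structure(S, grid = grid, specs = specs, norm = nrm,
            class = c("sensitivity_matrix", "matrix"))
}

#' Sensitivity matrix of trajectory time points
#'
#' The sensitivity of a correlation-function value at lag \eqn{t} to motion
#' at \eqn{z} is \eqn{\exp(-t/10^z)}; the \eqn{S^2} offset is deliberately
#' absorbed into correlation times beyond the trajectory length, so no
#' constant row is added.
#'
#' @param lags Lag times in seconds (typically a log-spaced subset of a
#'   [lag_grid()]). The zero lag, whose sensitivity is identically 1
#'   (C(0) = 1 regardless of timescale), anchors the fastest window and is
#'   always included.
#' @param grid A [z_grid()].
#' @return A \code{sensitivity_matrix} with one row per lag; attribute
#'   \code{lags} holds the lag times.
#' @export
build_md_sensitivities <- function(lags, grid = z_grid()) {
  if (inherits(lags, "lag_grid")) lags <- lags$times
  lags <- c(0, lags[lags > 0])
  stopifnot(length(lags) >= 3)
  tau <- 10^grid$z
  S <- t(vapply(lags, function(t) exp(-t / tau), numeric(length(tau))))
  rownames(S) <- sprintf("C(%.3gs)", lags)
  structure(S, grid = grid, lags = lags,
            norm = rep(1, length(lags)),
            class = c("sensitivity_matrix", "matrix"))
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("sensitivity matrix: %d rows x %d z points\n", nrow(x),
              length(g$z)))
  cat(" ", paste(utils::head(rownames(x), 10), collapse = ", "),
      if (nrow(x) > 10) "..." else "", "\n")
  invisible(x)
}

#' Exponential fit of a relaxation series
#'
#' Fits \eqn{A e^{-tR}} (decay) or \eqn{A(1 - e^{-tR})} (recovery) to a
#' measured intensity series by nonlinear least squares and returns the
#' rate with its covariance-based uncertainty.
#'
#' @param delays Delay times (s), >= 3 points; the first may be 0.
#' @param intensities Measured intensities.
#' @param sigma Optional intensity uncertainties (weights
#'   \eqn{1/\sigma^2}).
#' @param model \code{"decay"} or \code{"recovery"}.
#' @return List with \code{rate}, \code{sigma_rate}, \code{amplitude},
#'   \code{fit} (the \code{nls} object).
#' @export
fit_exponential_series <- function(delays, intensities, sigma = NULL,
                                   model = c("decay", "recovery")) {
  model <- match.arg(model)
  stopifnot(length(delays) >= 3, length(delays) == length(intensities))
  df <- data.frame(t = delays, y = intensities)
  w <- if (is.null(sigma)) rep(1, nrow(df)) else 1 / sigma^2
  span <- diff(range(delays[delays > 0 | model == "decay"]))
  r0 <- 1 / max(span, .Machine$double.eps)
  a0 <- max(abs(intensities))
  if (stats::sd(intensities) < 1e-12 * max(abs(a0), 1)) {
    # constant data: zero rate, exactly
    return(list(rate = 0, sigma_rate = 0, amplitude = mean(intensities),
                fit = NULL))
  }
  form <- if (model == "decay") y ~ A * exp(-t * R) else y ~ A * (1 - exp(-t * R))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = list(A = a0, R = r0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- summary(fit)$coefficients
  list(rate = co["R", "Estimate"], sigma_rate = co["R", "Std. Error"],
       amplitude = co["A", "Estimate"], fit = fit)
}

#' Order parameter from residual couplings
#'
#' \eqn{|S| = |\delta_{resid}/\delta_{rigid}|}; also returns the
#' \eqn{1 - S^2} value used as the data entry of an
#' \code{order_parameter} experiment row.
#'
#' @param delta_resid Residual (motionally averaged) coupling anisotropy.
#' @param delta_rigid Rigid-limit anisotropy (nonzero).
#' @return List with \code{S_abs} and \code{one_minus_S2}.
#' @export
order_parameter_from_coupling <- function(delta_resid, delta_rigid) {
  if (abs(delta_rigid) <= 0) stop("rigid-limit coupling must be nonzero")
  S <- abs(delta_resid / delta_rigid)
  if (any(S > 1 + 1e-9)) {
    stop("|S| > 1: residual coupling exceeds the rigid limit")
  }
  list(S_abs = pmin(S, 1), one_minus_S2 = 1 - pmin(S, 1)^2)
}

#' Read an experiment table
#'
#' Reads a delimited text table with columns \code{type, field, v1, vr,
#' value, sigma} (frequencies in Hz) into a list of [experiment()] specs.
#'
#' @param path File path.
#' @return List of \code{experiment_spec}.
#' @export
read_experiments <- function(path) {
  df <- utils::read.delim(path, sep = "", header = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    experiment(type = df$type[i],
               field = if ("field" %in% names(df)) df$field[i] else NA,
               v1 = if ("v1" %in% names(df)) df$v1[i] else 0,
               vr = if ("vr" %in% names(df)) df$vr[i] else 0,
               value = if ("value" %in% names(df)) df$value[i] else NA,
               sigma = if ("sigma" %in% names(df)) df$sigma[i] else NA)
  })
}

#' The published POPC experiment set
#'
#' The eight-measurement set used for six-detector analysis of POPC
#' membranes: \eqn{^{13}}C R1 at 100, 150 and 175 MHz, the heteronuclear
#' NOE cross-relaxation rate at 150 MHz, R1rho at spin-lock strengths 7.0,
#' 12.0 and 22.1 kHz under 5 kHz MAS, plus one residual-coupling order
#' parameter row.
#'
#' @param dHC Effective H-C distance (m).
#' @return List of [experiment()] specs.
#' @export
popc_experiment_set <- function(dHC = 1.115e-10) {
  list(
    experiment("R1", field = 100e6, dHC = dHC),
    experiment("R1", field = 150e6, dHC = dHC),
    experiment("R1", field = 175e6, dHC = dHC),
    experiment("NOE_sigma", field = 150e6, dHC = dHC),
    experiment("R1rho", field = 150e6, v1 = 7.0e3, vr = 5e3, dHC = dHC),
    experiment("R1rho", field = 150e6, v1 = 12.0e3, vr = 5e3, dHC = dHC),
    experiment("R1rho", field = 150e6, v1 = 22.1e3, vr = 5e3, dHC = dHC),
    experiment("order_parameter", dHC = dHC)
  )
}
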