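# Rank-2 reorientational correlation functions on a lag grid.
#
# C(t_n) = 1/(N-n) sum_m P2( v(tau_m) . v(tau_m+n) ), i.e. the exact
# all-pairs average at each sampled lag. A fast path evaluates the same
# quantity through the five rank-2 spherical components and the FFT.

#' Lag grid for correlation functions
#'
#' Defines which lags of a trajectory of \code{n_steps} stored steps are
#' evaluated. The default keeps every lag up to \code{all_max} steps and
#' then log-spaced lags (\code{per_decade} points per decade) up to
#' \code{max_frac} of the trajectory length; longer lags average too few
#' pairs to be useful.
#'
#' @param n_steps Number of stored trajectory steps.
#' @param dt Step interval in seconds.
#' @param scheme \code{"log_spaced"} (default) or \code{"all"}.
#' @param all_max Number of initial consecutive lags always kept.
#' @param per_decade Log-spaced density beyond \code{all_max}.
#' @param max_frac Longest lag as a fraction of the trajectory length.
#' @return An object of class \code{lag_grid} with integer \code{lags}
#'   (0-based) and \code{times} (seconds, \code{times[1] = 0}).
#' @export
lag_grid <- function(n_steps, dt, scheme = c("log_spaced", "all"),
                     all_max = 10L, per_decade = 50L, max_frac = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(n_steps >= 2, dt > 0)
  nmax <- max(1L, floor((n_steps - 1) * max_frac))
  if (scheme == "all") {
    lags <- 0:nmax
  } else {
    head <- 0:min(all_max, nmax)
    if (nmax > all_max) {
      lg <- 10^seq(log10(all_max + 1), log10(nmax), by = 1 / per_decade)
      lags <- sort(unique(c(head, unique(round(lg)))))
    } else {
      lags <- head
    }
  }
  structure(list(lags = as.integer(lags), times = lags * dt, dt = dt,
                 scheme = scheme, n_steps = as.integer(n_steps)),
            class = "lag_grid")
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("lag grid: %d lags (%s), t in [0, %.4g s], dt = %.4g s\n",
              length(x$lags), x$scheme, max(x$times), x$dt))
  invisible(x)
}

new_correlation_set <- function(times, value, lags = NULL, err = NULL,
                                dt = NULL, kind = "total", labels = NULL,
                                components = NULL, n_averaged = 1L,
                                diagnostics = list()) {
  value <- as.matrix(value)
  if (!is.null(labels)) colnames(value) <- labels
  structure(list(times = times, lags = lags, value = value, err = err,
                 dt = dt, kind = kind, components = components,
                 n_averaged = n_averaged, diagnostics = diagnostics),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("correlation set (%s): %d lags x %d series\n",
              x$kind, nrow(x$value), ncol(x$value)))
  cat(sprintf("  C(0) = %s; C(t_max = %.4g s) = %s\n",
              paste(round(x$value[1, ], 4), collapse = ", "), max(x$times),
              paste(round(x$value[nrow(x$value), ], 4), collapse = ", ")))
  if (!is.null(x$err)) cat("  jackknife errors attached\n")
  if (x$n_averaged > 1L) cat("  averaged over", x$n_averaged, "copies\n")
  invisible(x)
}

#' @export
plot.correlation_set <- function(x, ..., log_time = TRUE) {
  tt <- x$times
  pos <- tt > 0
  graphics::matplot(if (log_time) tt[pos] else tt,
                    if (log_time) x$value[pos, , drop = FALSE] else x$value,
                    type = "l", lty = 1, log = if (log_time) "x" else "",
                    xlab = "lag time (s)", ylab = "C(t)", ...)
  invisible(x)
}

as_vector_array <- function(vectors) {
  if (inherits(vectors, "synthetic_trajectory")) vectors <- vectors$vectors
  if (length(dim(vectors)) == 2) dim(vectors) <- c(dim(vectors), 1L)
  stopifnot(dim(vectors)[1] == 3)
  vectors
}

check_unit_vectors <- function(v, tol = 1e-6) {
  nrm2 <- v[1, , ]^2 + v[2, , ]^2 + v[3, , ]^2
  dev <- max(abs(nrm2 - 1))
  if (dev > 2 * tol) {
    stop(sprintf("bond vectors must be unit length (max |norm^2 - 1| = %.3g)",
                 dev))
  }
}

#' Rank-2 autocorrelation function (direct all-pairs sum)
#'
#' Evaluates \eqn{C(t_n) = \langle P_2(v(\tau) \cdot v(\tau + t_n))
#' \rangle_\tau} with exact pair averaging at every lag of \code{grid}.
#'
#' @param vectors Unit bond vectors: a \code{3 x N} matrix, a
#'   \code{3 x N x C} array of molecule copies, or a
#'   \code{synthetic_trajectory}.
#' @param grid A [lag_grid()]; defaults to the standard grid for \code{N}
#'   steps (requires \code{dt}).
#' @param dt Step interval in seconds (taken from the trajectory if given).
#' @param error Attach block-jackknife errors (10 contiguous blocks; lags
#'   longer than half a block get \code{NA}).
#' @return A \code{correlation_set} with one column per copy.
#' @export
autocorrelation_p2 <- function(vectors, grid = NULL, dt = NULL, error = FALSE) {
  if (inherits(vectors, "synthetic_trajectory") && is.null(dt)) {
    dt <- vectors$dt
  }
  v <- as_vector_array(vectors)
  check_unit_vectors(v)
  n <- dim(v)[2]; nc <- dim(v)[3]
  if (is.null(grid)) grid <- lag_grid(n, dt %||% 1)
  lags <- grid$lags
  out <- matrix(NA_real_, length(lags), nc)
  for (j in seq_len(nc)) {
    x <- v[1, , j]; y <- v[2, , j]; z <- v[3, , j]
    for (i in seq_along(lags)) {
      k <- lags[i]
      idx <- seq_len(n - k)
      d <- x[idx] * x[idx + k] + y[idx] * y[idx + k] + z[idx] * z[idx + k]
      out[i, j] <- mean((3 * d^2 - 1) / 2)
    }
  }
  cs <- new_correlation_set(grid$times, out, lags = lags, dt = grid$dt,
                            kind = "total")
  if (error) cs$err <- jackknife_blocks(v, grid, fft = FALSE)
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# five rank-2 component series for one copy: 5 x N complex
p2_components <- function(x, y, z) {
  d2_p0_from_vec(x, y, z)
}

fft_pair_sums <- function(a, lags) {
  # sum_tau conj(a_p(tau)) a_p(tau+n) for each component, summed over p
  n <- ncol(a)
  m <- stats::nextn(2 * n, 2)
  tot <- numeric(n)
  for (p in 1:5) {
    A <- stats::fft(c(a[p, ], rep(0 + 0i, m - n)))
    s <- stats::fft(Conj(A) * A, inverse = TRUE) / m
    tot <- tot + Re(s[1:n])
  }
  tot[lags + 1L]
}

#' Rank-2 autocorrelation via spherical components and the FFT
#'
#' Identical to [autocorrelation_p2()] (to ~1e-9) but computed through the
#' five rank-2 spherical-component autocorrelations with FFTs, which makes
#' long trajectories affordable.
#'
#' @inheritParams autocorrelation_p2
#' @return A \code{correlation_set}.
#' @export
autocorrelation_fft <- function(vectors, grid = NULL, dt = NULL,
                                error = FALSE) {
  if (inherits(vectors, "synthetic_trajectory") && is.null(dt)) {
    dt <- vectors$dt
  }
  v <- as_vector_array(vectors)
  check_unit_vectors(v)
  n <- dim(v)[2]; nc <- dim(v)[3]
  if (is.null(grid)) grid <- lag_grid(n, dt %||% 1)
  lags <- grid$lags
  out <- matrix(NA_real_, length(lags), nc)
  for (j in seq_len(nc)) {
    a <- p2_components(v[1, , j], v[2, , j], v[3, , j])
    out[, j] <- fft_pair_sums(a, lags) / (n - lags)
  }
  cs <- new_correlation_set(grid$times, out, lags = lags, dt = grid$dt,
                            kind = "total")
  if (error) cs$err <- jackknife_blocks(v, grid, fft = TRUE)
  cs
}

# block jackknife over n_blocks contiguous blocks; returns matrix of SE
# (lags x copies), NA where the lag exceeds half a block
jackknife_blocks <- function(v, grid, n_blocks = 10L, fft = TRUE) {
  n <- dim(v)[2]; nc <- dim(v)[3]
  bl <- floor(n / n_blocks)
  lags <- grid$lags
  ok <- lags <= bl / 2
  err <- matrix(NA_real_, length(lags), nc)
  if (!any(ok) || bl < 4) return(err)
  lag_ok <- lags[ok]
  for (j in seq_len(nc)) {
    cb <- matrix(NA_real_, sum(ok), n_blocks)
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1) * bl + 1):(b * bl)
      x <- v[1, idx, j]; y <- v[2, idx, j]; z <- v[3, idx, j]
      if (fft) {
        a <- p2_components(x, y, z)
        cb[, b] <- fft_pair_sums(a, lag_ok) / (bl - lag_ok)
      } else {
        for (i in seq_along(lag_ok)) {
          k <- lag_ok[i]
          ii <- seq_len(bl - k)
          d <- x[ii] * x[ii + k] + y[ii] * y[ii + k] + z[ii] * z[ii + k]
          cb[i, b] <- mean((3 * d^2 - 1) / 2)
        }
      }
    }
    err[ok, j] <- apply(cb, 1, stats::sd) / sqrt(n_blocks)
  }
  err
}

#' Average correlation functions over equivalent bonds
#'
#' Uniform-weight mean per lag over molecule copies or symmetry-equivalent
#' bonds (e.g. NMR-unresolved chain carbons), with a delete-one jackknife
#' error across members.
#'
#' @param sets A \code{correlation_set} with several columns, or a list of
#'   sets on identical lag grids.
#' @param groups Optional named list mapping group labels to column indices
#'   or column names; by default all columns form one group.
#' @return A \code{correlation_set} with one column per group and jackknife
#'   errors across members.
#' @export
average_equivalent <- function(sets, groups = NULL) {
  if (inherits(sets, "correlation_set")) sets <- list(sets)
  t0 <- sets[[1]]$times
  for (s in sets) {
    if (length(s$times) != length(t0) || max(abs(s$times - t0)) > 1e-12 * max(t0, 1e-300)) {
      stop("correlation sets must share an identical lag grid")
    }
  }
  val <- do.call(cbind, lapply(sets, function(s) s$value))
  if (is.null(groups)) groups <- list(mean = seq_len(ncol(val)))
  out <- matrix(NA_real_, nrow(val), length(groups))
  err <- matrix(NA_real_, nrow(val), length(groups))
  colnames(out) <- names(groups)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (is.character(idx)) idx <- match(idx, colnames(val))
    m <- length(idx)
    sub <- val[, idx, drop = FALSE]
    out[, g] <- rowMeans(sub)
    if (m > 1) err[, g] <- apply(sub, 1, stats::sd) / sqrt(m)
  }
  new_correlation_set(t0, out, lags = sets[[1]]$lags, err = err,
                      dt = sets[[1]]$dt, kind = sets[[1]]$kind,
                      n_averaged = sum(lengths(groups)))
}

#' Write / read a correlation set as a delimited table
#'
#' Long-format tab-separated serialization (site label, lag index, lag time,
#' value, error); [read_correlation()] restores the object.
#'
#' @param set A \code{correlation_set}.
#' @param path Output file.
#' @export
write_correlation <- function(set, path) {
  labs <- colnames(set$value) %||% paste0("series", seq_len(ncol(set$value)))
  if (is.null(colnames(set$value))) colnames(set$value) <- labs
  df <- do.call(rbind, lapply(seq_along(labs), function(j) {
    data.frame(site = labs[j],
               lag = set$lags %||% seq_len(nrow(set$value)) - 1L,
               time = set$times,
               value = set$value[, j],
               err = if (!is.null(set$err)) set$err[, j] else NA_real_)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- utils::read.delim(path)
  labs <- unique(df$site)
  times <- sort(unique(df$time))
  val <- sapply(labs, function(l) df$value[df$site == l][order(df$time[df$site == l])])
  err <- sapply(labs, function(l) df$err[df$site == l][order(df$time[df$site == l])])
  if (all(is.na(err))) err <- NULL
  lags <- sort(unique(df$lag))
  new_correlation_set(times, val, lags = lags, err = err,
                      dt = if (length(times) > 1) diff(times)[1] else NULL,
                      kind = "total", labels = labs)
}
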