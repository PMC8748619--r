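# Frame analysis: separation of the total reorientational correlation
# function into correlation functions of motion *within* and *of* a
# hierarchy of physically defined frames, with residual-tensor bookkeeping.
#
# Conventions. A triad series is a 3 x 3 x N array whose columns at each
# time are the frame axes expressed in the lab. For a bond triad A and a
# frame triad F, B = t(F) A is the bond expressed in the frame; motion
# within the frame is the evolution of B, motion of the frame enters via
# F_{tau+t} t(F_tau) applied to the frame-stripped bond and re-expressed in
# the bond frame at the initial time.

# ---- batched 3x3xN algebra ------------------------------------------------

bt_tmul <- function(A, B) {
  # t(A_t) %*% B_t per slice
  n <- dim(A)[3]
  out <- array(NA_real_, c(3, 3, n))
  for (i in 1:3) for (k in 1:3) {
    out[i, k, ] <- A[1, i, ] * B[1, k, ] + A[2, i, ] * B[2, k, ] +
      A[3, i, ] * B[3, k, ]
  }
  out
}

bt_tvec <- function(A, v) {
  # t(A_t) %*% v_t per slice, v is 3 x N
  rbind(A[1, 1, ] * v[1, ] + A[2, 1, ] * v[2, ] + A[3, 1, ] * v[3, ],
        A[1, 2, ] * v[1, ] + A[2, 2, ] * v[2, ] + A[3, 2, ] * v[3, ],
        A[1, 3, ] * v[1, ] + A[2, 3, ] * v[2, ] + A[3, 3, ] * v[3, ])
}

bt_vec <- function(A, v) {
  rbind(A[1, 1, ] * v[1, ] + A[1, 2, ] * v[2, ] + A[1, 3, ] * v[3, ],
        A[2, 1, ] * v[1, ] + A[2, 2, ] * v[2, ] + A[2, 3, ] * v[3, ],
        A[3, 1, ] * v[1, ] + A[3, 2, ] * v[2, ] + A[3, 3, ] * v[3, ])
}

# ---- frame axes -----------------------------------------------------------

#' Frame axes from a triad array
#'
#' Wraps a \code{3 x 3 x N} array of orthonormal triads as a
#' \code{frame_axes} object (kind \code{"ground_truth"}), e.g. the recorded
#' outer rotation of a composed synthetic hierarchy.
#'
#' @param triads \code{3 x 3 x N} array, columns = axes.
#' @param kind Frame kind label.
#' @return A \code{frame_axes} object.
#' @export
frame_axes <- function(triads, kind = "ground_truth") {
  stopifnot(length(dim(triads)) == 3, all(dim(triads)[1:2] == c(3, 3)))
  structure(list(triads = triads, kind = kind,
                 n_steps = dim(triads)[3]),
            class = "frame_axes")
}

#' @export
print.frame_axes <- function(x, ...) {
  cat(sprintf("frame axes (%s): %d steps\n", x$kind, x$n_steps))
  invisible(x)
}

# enforce nu_Z sign continuity, re-completing x/y by parallel transport
sign_continuous_z <- function(zmat, sign_ref = NULL) {
  n <- ncol(zmat)
  if (!is.null(sign_ref) && sum(zmat[, 1] * sign_ref) < 0) {
    zmat[, 1] <- -zmat[, 1]
  }
  for (i in 2:n) {
    if (sum(zmat[, i] * zmat[, i - 1]) < 0) zmat[, i] <- -zmat[, i]
  }
  zmat
}

# complete a z-axis series to smooth triads by parallel transport of x
complete_triads <- function(zmat, x0 = NULL) {
  n <- ncol(zmat)
  out <- array(NA_real_, c(3, 3, n))
  if (is.null(x0)) {
    seedv <- if (abs(zmat[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  } else {
    seedv <- x0
  }
  x <- seedv - sum(seedv * zmat[, 1]) * zmat[, 1]
  x <- x / sqrt(sum(x^2))
  for (i in seq_len(n)) {
    z <- zmat[, i]
    x <- x - sum(x * z) * z
    nx <- sqrt(sum(x^2))
    if (nx < 1e-8) stop("degenerate frame: parallel transport lost the x axis at time index ", i)
    x <- x / nx
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])   # y = z x x: right-handed triad
    out[, 1, i] <- x; out[, 2, i] <- y; out[, 3, i] <- z
  }
  out
}

#' Build frame axes from trajectory coordinates
#'
#' Constructs the motional frames used to separate bond motion:
#' \describe{
#'   \item{\code{libration}}{Rigid-body (Kabsch) superposition of the bond
#'     carbon and its directly bonded atoms onto a reference structure;
#'     captures the local covalent cage, so bond motion within this frame is
#'     the one-bond libration.}
#'   \item{\code{rigid_align}}{Kabsch superposition of an arbitrary atom
#'     group (e.g. the glycerol C/O atoms) onto the reference; its motion is
#'     the overall motion of that moiety.}
#'   \item{\code{moi}}{z axis along the principal axis of the group's
#'     inertia tensor with the smallest eigenvalue (the chain's long axis);
#'     x/y completed by parallel transport, so rotation about the long axis
#'     is not tracked.}
#'   \item{\code{moixy}}{As \code{moi}, but the x axis follows a chain-fixed
#'     in-plane reference bond (projected perpendicular to z), so rotation
#'     about the long axis is tracked and can be separated.}
#' }
#'
#' @param xyz Coordinates, \code{n_atoms x 3 x n_steps} (any length unit).
#' @param kind One of \code{"libration"}, \code{"rigid_align"},
#'   \code{"moi"}, \code{"moixy"}.
#' @param atoms Integer indices of the atom group (>= 3 atoms).
#' @param reference Reference coordinates for the Kabsch kinds
#'   (\code{n_atoms x 3}); defaults to the first step.
#' @param xy_ref For \code{moixy}: integer pair of atoms whose bond,
#'   projected perpendicular to the long axis, defines x; defaults to the
#'   mid-chain pair of \code{atoms}.
#' @param sign_ref Reference direction fixing the sign of the long axis at
#'   the first step (default: vector from the first to the last atom of the
#'   group).
#' @param masses Optional atomic masses for the inertia tensor (default
#'   unit masses).
#' @return A \code{frame_axes} object.
#' @export
build_frame_axes <- function(xyz, kind = c("libration", "rigid_align",
                                           "moi", "moixy"),
                             atoms, reference = NULL, xy_ref = NULL,
                             sign_ref = NULL, masses = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  n <- dim(xyz)[3]
  atoms <- as.integer(atoms)
  if (length(atoms) < 3) stop("frame atom group must contain at least 3 atoms")
  if (kind %in% c("libration", "rigid_align")) {
    if (is.null(reference)) reference <- xyz[, , 1]
    ref <- reference[atoms, , drop = FALSE]
    out <- array(NA_real_, c(3, 3, n))
    for (i in seq_len(n)) {
      out[, , i] <- tryCatch(
        kabsch_align(ref, xyz[atoms, , i], as_matrix = TRUE),
        error = function(e) stop(sprintf(
          "degenerate frame (%s) at time index %d: %s", kind, i,
          conditionMessage(e)), call. = FALSE))
    }
    return(frame_axes(out, kind))
  }
  m <- masses %||% rep(1, length(atoms))
  zs <- matrix(NA_real_, 3, n)
  for (i in seq_len(n)) {
    r <- xyz[atoms, , i, drop = TRUE]
    r <- sweep(r, 2, colSums(r * m) / sum(m))
    IT <- diag(sum(m * rowSums(r^2)), 3) - crossprod(r * m, r)
    ev <- eigen(IT, symmetric = TRUE)
    lam <- ev$values  # decreasing
    if ((lam[2] - lam[3]) < 1e-6 * lam[1]) {
      stop(sprintf("degenerate inertia tensor (spherical atom group) at time index %d", i))
    }
    zs[, i] <- ev$vectors[, 3]  # smallest eigenvalue: long axis
  }
  if (is.null(sign_ref)) {
    sign_ref <- xyz[atoms[length(atoms)], , 1] - xyz[atoms[1], , 1]
  }
  zs <- sign_continuous_z(zs, sign_ref)
  if (kind == "moi") {
    return(frame_axes(complete_triads(zs), kind))
  }
  # moixy: x from a chain-fixed reference bond projected perpendicular to z
  if (is.null(xy_ref)) {
    h <- length(atoms) %/% 2
    xy_ref <- c(atoms[max(1, h)], atoms[min(length(atoms), h + 1)])
  }
  u <- xyz[xy_ref[2], , ] - xyz[xy_ref[1], , ]  # 3 x n
  if (is.null(dim(u))) u <- matrix(u, 3, n)
  out <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    z <- zs[, i]
    x <- u[, i] - sum(u[, i] * z) * z
    nx <- sqrt(sum(x^2))
    if (nx < 1e-8) {
      stop(sprintf("degenerate frame (moixy): in-plane reference parallel to the long axis at time index %d", i))
    }
    x <- x / nx
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    out[, 1, i] <- x; out[, 2, i] <- y; out[, 3, i] <- z
  }
  frame_axes(out, kind)
}

#' Bond frame axes
#'
#' Builds the time-dependent frame of a bond: \code{v_Z} along the
#' (normalized) bond vector and a designated reference direction (for an
#' H-C bond, a C-C bond sharing the carbon) constrained to the XZ plane.
#'
#' @param vz \code{3 x N} bond vectors (normalized internally).
#' @param xz_ref \code{3 x N} (or length-3) reference direction kept in the
#'   XZ plane; if \code{NULL}, a smooth parallel-transport completion is
#'   used (any consistent completion is admissible).
#' @return A \code{bond_axes} object (a \code{frame_axes} of kind
#'   \code{"bond"}).
#' @export
bond_axes <- function(vz, xz_ref = NULL) {
  if (length(dim(vz)) == 3) vz <- vz[, , 1]
  nrm <- sqrt(colSums(vz^2))
  vz <- sweep(vz, 2, nrm, "/")
  n <- ncol(vz)
  if (is.null(xz_ref)) {
    out <- complete_triads(vz)
  } else {
    if (is.null(dim(xz_ref))) xz_ref <- matrix(xz_ref, 3, n)
    out <- array(NA_real_, c(3, 3, n))
    for (i in seq_len(n)) {
      z <- vz[, i]
      x <- xz_ref[, i] - sum(xz_ref[, i] * z) * z
      nx <- sqrt(sum(x^2))
      if (nx < 1e-8) {
        stop(sprintf("degenerate bond frame: XZ-plane reference parallel to the bond at time index %d", i))
      }
      x <- x / nx
      y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
             z[1] * x[2] - z[2] * x[1])
      out[, 1, i] <- x; out[, 2, i] <- y; out[, 3, i] <- z
    }
  }
  f <- frame_axes(out, "bond")
  class(f) <- c("bond_axes", class(f))
  f
}

as_triads <- function(x, what = "bond") {
  if (inherits(x, "frame_axes")) return(x$triads)
  if (inherits(x, "synthetic_trajectory")) {
    if (!is.null(x$triads)) return(x$triads)
    return(bond_axes(x$vectors[, , 1])$triads)
  }
  if (is.array(x) && length(dim(x)) == 3 && all(dim(x)[1:2] == c(3, 3))) {
    return(x)
  }
  stop("cannot interpret ", what, " input as a triad series")
}

# ---- correlation functions in / of a frame --------------------------------

#' Correlation function of motion within a frame
#'
#' Evaluates the rank-2 autocorrelation of the bond after removing the
#' motion of \code{frame}: the bond vector is expressed in the frame
#' (\code{t(F_tau) v_Z(tau)}) and the all-pairs P2 average is taken on the
#' transformed vectors.
#'
#' @param bond Bond axes (\code{bond_axes}), a \code{3 x N} vector matrix,
#'   or a \code{synthetic_trajectory}.
#' @param frame A \code{frame_axes} object (or triad array).
#' @param grid A [lag_grid()].
#' @param dt Step interval (seconds) if not implied by the inputs.
#' @return A \code{correlation_set} of kind \code{"in_frame"}.
#' @export
correlation_in_frame <- function(bond, frame, grid = NULL, dt = NULL) {
  vz <- bond_z_vectors(bond)
  Ft <- as_triads(frame, "frame")
  if (ncol(vz) != dim(Ft)[3]) stop("bond and frame series lengths differ")
  if (inherits(bond, "synthetic_trajectory") && is.null(dt)) dt <- bond$dt
  w <- bt_tvec(Ft, vz)
  if (is.null(grid)) grid <- lag_grid(ncol(w), dt %||% 1)
  cs <- autocorrelation_fft(w, grid, dt = grid$dt)
  cs$kind <- "in_frame"
  cs
}

bond_z_vectors <- function(bond) {
  if (inherits(bond, "synthetic_trajectory")) return(bond$vectors[, , 1])
  if (inherits(bond, "frame_axes")) return(bond$triads[, 3, ])
  if (is.array(bond) && length(dim(bond)) == 3 && dim(bond)[2] == 3 &&
      dim(bond)[1] == 3) {
    return(bond[, 3, ])
  }
  if (is.matrix(bond) && nrow(bond) == 3) return(bond)
  stop("cannot interpret bond input")
}

# mean 5x5 Wigner matrix over triads, chunked to bound memory
mean_wigner_chunked <- function(triads, chunk = 20000L) {
  n <- dim(triads)[3]
  acc <- matrix(0 + 0i, 5, 5)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    om <- euler_from_axes_series(triads[, , s:e, drop = FALSE])
    D <- wigner_d2_series(om)
    acc <- acc + apply(D, c(1, 2), sum)
  }
  acc / n
}

#' Residual tensor of motion within a frame
#'
#' The motionally averaged rank-2 (dipolar) tensor of a bond within a
#' frame. \code{components} are the time-averaged spherical components
#' \eqn{\langle D^2_{p0}(\Omega_\tau)\rangle} of the bond orientation in the
#' frame (p = -2..2; the p = 0 component is the familiar residual
#' \eqn{\langle P_2(\cos\beta)\rangle}). The anisotropy ratio
#' \eqn{\delta_{eff}/\delta_{rigid}}, asymmetry \eqn{\eta} and principal
#' Euler angles come from the eigen-decomposition of the Cartesian mean
#' tensor. When full bond triads are supplied, the equal-weight all-pairs
#' limits required by the frame-motion correlation function (and the ratio
#' terms \eqn{\epsilon_p}) are evaluated through Wigner closure, which
#' reduces the double loop over pairs to products of single-time averages.
#'
#' @param bond Bond axes or \code{3 x N} bond vectors.
#' @param frame \code{frame_axes} (or \code{NULL} for the lab frame).
#' @return An object of class \code{residual_tensor}.
#' @export
residual_tensor <- function(bond, frame = NULL) {
  vz <- bond_z_vectors(bond)
  have_triads <- inherits(bond, "frame_axes") ||
    inherits(bond, "synthetic_trajectory") ||
    (is.array(bond) && length(dim(bond)) == 3)
  Ft <- if (is.null(frame)) NULL else as_triads(frame, "frame")
  u <- if (is.null(Ft)) vz else bt_tvec(Ft, vz)
  nrm <- sqrt(colSums(u^2)); u <- sweep(u, 2, nrm, "/")
  comp <- rowMeans(d2_p0_from_vec(u[1, ], u[2, ], u[3, ]))
  M <- matrix(0, 3, 3)
  M[1, 1] <- mean(3 * u[1, ]^2 - 1) / 2
  M[2, 2] <- mean(3 * u[2, ]^2 - 1) / 2
  M[3, 3] <- mean(3 * u[3, ]^2 - 1) / 2
  M[1, 2] <- M[2, 1] <- mean(3 * u[1, ] * u[2, ]) / 2
  M[1, 3] <- M[3, 1] <- mean(3 * u[1, ] * u[3, ]) / 2
  M[2, 3] <- M[3, 2] <- mean(3 * u[2, ] * u[3, ]) / 2
  shape <- tensor_shape(M)
  pair <- NULL
  if (have_triads) {
    A <- as_triads(bond)
    B <- if (is.null(Ft)) A else bt_tmul(Ft, A)
    mD <- mean_wigner_chunked(B)
    res <- vapply(1:5, function(p) sum(Conj(mD[, 3]) * mD[, p]),
                  complex(1))
    pair <- list(meanD = mD, limits = res, S2 = Re(res[3]),
                 eps = if (Mod(res[3]) > 1e-8) res / res[3] else NULL)
  }
  structure(list(components = comp, cartesian = M,
                 delta_ratio = shape$delta, eta = shape$eta,
                 angles = shape$angles, pair = pair),
            class = "residual_tensor")
}

# Haeberlen shape parameters of a symmetric traceless 3x3 tensor
tensor_shape <- function(M) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)
  lam <- ev$values[ord]          # |zz| >= |xx| >= |yy| (Haeberlen)
  V <- ev$vectors[, ord[c(2, 3, 1)], drop = FALSE]  # columns x, y, z
  if (det(V) < 0) V[, 2] <- -V[, 2]
  ang <- euler_from_axes(V)
  list(delta = lam[1],
       eta = if (abs(lam[1]) > 1e-12) (lam[3] - lam[2]) / lam[1] else 0,
       angles = ang)
}

# forward map: residual spherical components of a tensor with shape
# (delta_ratio, eta) and principal-axis Euler angles
residual_components_from_shape <- function(delta, eta, angles) {
  V <- rot_zyz(angles)
  lam <- c(-delta * (1 + eta) / 2, -delta * (1 - eta) / 2, delta)
  M <- V %*% diag(lam) %*% t(V)
  spherical_from_cartesian(M)
}

# linear map M -> <D_p0> components, built once from a fixed set of unit
# vectors (Fibonacci sphere; no RNG involved). A symmetric traceless M has
# 5 dof, parameterized by features (M11, M22, M12, M13, M23).
sph_features <- function(M) c(M[1, 1], M[2, 2], M[1, 2], M[1, 3], M[2, 3])

spherical_from_cartesian <- function(M) {
  drop(get_sph_map() %*% sph_features(M))
}

.dynland_env <- new.env(parent = emptyenv())

get_sph_map <- function() {
  if (!is.null(.dynland_env$sph_map)) return(.dynland_env$sph_map)
  k <- 40
  i <- seq_len(k)
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  cz <- 1 - (2 * i - 1) / k
  sz <- sqrt(pmax(0, 1 - cz^2))
  v <- rbind(sz * cos(phi), sz * sin(phi), cz)
  X <- t(vapply(seq_len(k), function(j) {
    sph_features((3 * tcrossprod(v[, j]) - diag(3)) / 2)
  }, numeric(5)))
  Y <- t(d2_p0_from_vec(v[1, ], v[2, ], v[3, ]))  # k x 5
  map <- t(qr.solve(X, Re(Y)) + 1i * qr.solve(X, Im(Y)))  # 5 x 5
  rownames(map) <- c("-2", "-1", "0", "1", "2")
  .dynland_env$sph_map <- map
  map
}

#' @export
print.residual_tensor <- function(x, ...) {
  cat("residual tensor\n")
  cat(sprintf("  <D2_00> = %.4f; delta_eff/delta_rigid = %.4f; eta = %.4f\n",
              Re(x$components[3]), x$delta_ratio, x$eta))
  if (!is.null(x$pair)) {
    cat(sprintf("  all-pairs limit S2 = %.4f\n", x$pair$S2))
  }
  invisible(x)
}

#' Correlation function of the motion of a frame
#'
#' Evaluates the frame-motion correlation function: the frame rotation
#' between times \eqn{\tau} and \eqn{t+\tau} is applied to the
#' frame-stripped bond axes, re-expressed in the bond frame at the initial
#' time, and the resulting rank-2 components are combined with the residual
#' tensor ratio terms of the motion within the frame, so that the product
#' with the within-frame function reproduces the total correlation
#' function under statistical independence and timescale separation.
#'
#' @param bond Bond axes (full triads required).
#' @param frame \code{frame_axes}.
#' @param inner_residual Optional precomputed [residual_tensor()] of the
#'   bond within \code{frame}; computed if missing.
#' @param grid A [lag_grid()].
#' @param dt Step interval (seconds).
#' @return A \code{correlation_set} of kind \code{"of_frame"}; if the
#'   residual tensor of the inner motion vanishes the function is returned
#'   unscaled with \code{diagnostics$vanishing_residual = TRUE}.
#' @export
correlation_of_frame <- function(bond, frame, inner_residual = NULL,
                                 grid = NULL, dt = NULL) {
  A <- as_triads(bond)
  Ft <- as_triads(frame, "frame")
  n <- dim(A)[3]
  if (dim(Ft)[3] != n) stop("bond and frame series lengths differ")
  if (inherits(bond, "synthetic_trajectory") && is.null(dt)) dt <- bond$dt
  if (is.null(grid)) grid <- lag_grid(n, dt %||% 1)
  if (is.null(inner_residual)) {
    inner_residual <- residual_tensor(frame_axes(A), frame)
  }
  pr <- inner_residual$pair
  vanishing <- is.null(pr$eps)
  eps <- if (vanishing) c(0, 0, 1, 0, 0) + 0i else pr$eps
  vz <- A[, 3, ]
  w <- bt_tvec(Ft, vz)                # frame-stripped bond direction
  lags <- grid$lags
  cval <- numeric(length(lags))
  mcomp <- matrix(0 + 0i, 5, length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    idx <- seq_len(n - k)
    Fk <- Ft[, , idx + k, drop = FALSE]
    y <- bt_vec(Fk, w[, idx, drop = FALSE])
    u <- bt_tvec(A[, , idx, drop = FALSE], y)
    mp <- rowMeans(d2_p0_from_vec(u[1, ], u[2, ], u[3, ]))
    mcomp[, i] <- mp
    cval[i] <- Re(sum(mp * eps))
  }
  new_correlation_set(grid$times, cval, lags = lags, dt = grid$dt,
                      kind = "of_frame", components = mcomp,
                      diagnostics = list(vanishing_residual = vanishing,
                                         eps = eps))
}

#' Residual-tensor evolution under frame motion
#'
#' Component correlation functions \eqn{C_{0p}(t) =
#' \langle D^2_{0p}(\Omega^{v:f}_{\tau,t+\tau})\rangle_\tau} tracking how
#' the residual tensor carried by the bond is reoriented by the motion of
#' \code{frame}; their long-lag limits are the all-pairs residual-tensor
#' components.
#'
#' @inheritParams correlation_of_frame
#' @return A \code{correlation_set} whose \code{components} matrix (5 x
#'   n_lags, rows p = -2..2) holds the complex \eqn{C_{0p}(t)}; the
#'   \code{value} column is \eqn{Re(C_{00})}.
#' @export
tensor_evolution <- function(bond, frame, grid = NULL, dt = NULL) {
  A <- as_triads(bond)
  Ft <- as_triads(frame, "frame")
  n <- dim(A)[3]
  if (inherits(bond, "synthetic_trajectory") && is.null(dt)) dt <- bond$dt
  if (is.null(grid)) grid <- lag_grid(n, dt %||% 1)
  B <- bt_tmul(Ft, A)
  vz <- A[, 3, ]
  lags <- grid$lags
  comp <- matrix(0 + 0i, 5, length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    idx <- seq_len(n - k)
    q <- bt_tvec(Ft[, , idx + k, drop = FALSE], vz[, idx, drop = FALSE])
    Bi <- B[, , idx, drop = FALSE]
    r31 <- q[1, ] * Bi[1, 1, ] + q[2, ] * Bi[2, 1, ] + q[3, ] * Bi[3, 1, ]
    r32 <- q[1, ] * Bi[1, 2, ] + q[2, ] * Bi[2, 2, ] + q[3, ] * Bi[3, 2, ]
    r33 <- q[1, ] * Bi[1, 3, ] + q[2, ] * Bi[2, 3, ] + q[3, ] * Bi[3, 3, ]
    comp[, i] <- rowMeans(d2_0p_from_row3(r31, r32, r33))
  }
  new_correlation_set(grid$times, Re(comp[3, ]), lags = lags, dt = grid$dt,
                      kind = "tensor_evolution", components = comp)
}

# ---- hierarchy decomposition ----------------------------------------------

#' Separate a bond's motion over a hierarchy of frames
#'
#' The central decomposition: given frames ordered inner to outer, returns
#' per-motion correlation functions — motion within the innermost frame,
#' motion of each frame within the next (outer motion stripped from both
#' bond and frame axes), and motion of the outermost frame in the lab —
#' together with per-motion residual tensors, the total correlation
#' function, and the product-deviation diagnostic
#' \eqn{|\prod_i C^i(t) - C(t)|}, which is never silently discarded.
#'
#' @param bond Bond axes (full triads) or a \code{synthetic_trajectory}
#'   with recorded triads.
#' @param frames List of \code{frame_axes}, ordered inner to outer.
#' @param grid A [lag_grid()].
#' @param dt Step interval (seconds).
#' @param names Optional motion names (length \code{length(frames) + 1}).
#' @param warn_tol,fail_tol Product-deviation thresholds: deviations above
#'   \code{warn_tol} raise a warning, above \code{fail_tol} an error.
#' @return An object of class \code{decomposition}: list with
#'   \code{motions} (each: name, correlation \code{correlation_set},
#'   residual \code{residual_tensor}), \code{total}, \code{product},
#'   \code{deviation} (per-lag), \code{max_deviation}.
#' @export
decompose_hierarchy <- function(bond, frames, grid = NULL, dt = NULL,
                                names = NULL, warn_tol = 0.02,
                                fail_tol = 0.1) {
  A <- as_triads(bond)
  if (inherits(bond, "synthetic_trajectory") && is.null(dt)) dt <- bond$dt
  n <- dim(A)[3]
  if (is.null(grid)) grid <- lag_grid(n, dt %||% 1)
  if (inherits(frames, "frame_axes")) frames <- list(frames)
  k <- length(frames)
  stopifnot(k >= 1)
  Fts <- lapply(seq_along(frames), function(j) {
    tr <- as_triads(frames[[j]], sprintf("frame %d", j))
    if (dim(tr)[3] != n) stop("frame ", j, " length differs from bond series")
    tr
  })
  if (is.null(names)) {
    names <- if (k == 1) c("internal", "overall")
    else if (k == 2) c("libration", "internal", "overall")
    else if (k == 3) c("libration", "parallel", "perpendicular", "overall")
    else c("innermost", paste0("level", seq_len(k - 1)), "overall")
  }
  stopifnot(length(names) == k + 1)
  motions <- vector("list", k + 1)
  # innermost: bond within frame 1
  c_in <- correlation_in_frame(frame_axes(A), frames[[1]], grid, dt = grid$dt)
  r_in <- residual_tensor(frame_axes(A), frames[[1]])
  motions[[1]] <- list(name = names[1], correlation = c_in, residual = r_in)
  # middle motions: frame j within frame j+1 (outer motion stripped)
  for (j in seq_len(max(0, k - 1))) {
    G <- Fts[[j + 1]]
    A_s <- bt_tmul(G, A)
    F_s <- bt_tmul(G, Fts[[j]])
    r_j <- residual_tensor(frame_axes(A_s), frame_axes(F_s))
    c_j <- correlation_of_frame(frame_axes(A_s), frame_axes(F_s),
                                inner_residual = r_j, grid = grid,
                                dt = grid$dt)
    motions[[j + 1]] <- list(name = names[j + 1], correlation = c_j,
                             residual = r_j)
  }
  # outermost: frame k in the lab
  r_k <- residual_tensor(frame_axes(A), frames[[k]])
  c_k <- correlation_of_frame(frame_axes(A), frames[[k]],
                              inner_residual = r_k, grid = grid,
                              dt = grid$dt)
  motions[[k + 1]] <- list(name = names[k + 1], correlation = c_k,
                           residual = r_k)
  total <- autocorrelation_fft(A[, 3, ], grid, dt = grid$dt)
  prod_c <- Reduce(`*`, lapply(motions, function(m) m$correlation$value[, 1]))
  dev <- abs(prod_c - total$value[, 1])
  mdev <- max(dev)
  if (mdev > fail_tol) {
    warning(sprintf(
      "product of separated correlation functions deviates from the total by %.3f (> %.2f): frame separation assumptions violated",
      mdev, fail_tol))
  } else if (mdev > warn_tol) {
    message(sprintf(
      "note: product deviation %.3f exceeds %.2f; separation assumptions marginal",
      mdev, warn_tol))
  }
  structure(list(motions = motions, total = total,
                 product = new_correlation_set(grid$times, prod_c,
                                               lags = grid$lags,
                                               dt = grid$dt,
                                               kind = "product"),
                 deviation = dev, max_deviation = mdev, grid = grid),
            class = "decomposition")
}

#' Ensemble-average frame decompositions
#'
#' Averages the per-motion, total and product correlation functions of
#' several decompositions of statistically equivalent trajectories
#' (molecule copies) with uniform weights, recomputing the product and its
#' deviation from the averaged total. This mirrors how correlation
#' functions of a membrane simulation are averaged over lipid copies before
#' any interpretation.
#'
#' @param decs List of \code{decomposition} objects on identical lag grids.
#' @return A \code{decomposition} with averaged correlation functions
#'   (residual tensors are taken from the first member).
#' @export
average_decompositions <- function(decs) {
  stopifnot(length(decs) >= 1)
  d0 <- decs[[1]]
  nm <- length(d0$motions)
  motions <- d0$motions
  for (j in seq_len(nm)) {
    vals <- sapply(decs, function(d) d$motions[[j]]$correlation$value[, 1])
    motions[[j]]$correlation$value <- cbind(rowMeans(vals))
  }
  tot <- rowMeans(sapply(decs, function(d) d$total$value[, 1]))
  prod_c <- Reduce(`*`, lapply(motions, function(m) m$correlation$value[, 1]))
  dev <- abs(prod_c - tot)
  out <- d0
  out$motions <- motions
  out$total$value <- cbind(tot)
  out$product$value <- cbind(prod_c)
  out$deviation <- dev
  out$max_deviation <- max(dev)
  out
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("frame decomposition: %d motions, %d lags\n",
              length(x$motions), length(x$deviation)))
  for (m in x$motions) {
    cf <- m$correlation$value[, 1]
    cat(sprintf("  %-14s C(0)=%.3f  C(t_max)=%.3f  <D2_00>=%.3f\n",
                m$name, cf[1], cf[length(cf)], Re(m$residual$components[3])))
  }
  cat(sprintf("  max |product - total| = %.4f\n", x$max_deviation))
  invisible(x)
}

#' @export
plot.decomposition <- function(x, ...) {
  tt <- x$grid$times
  pos <- tt > 0
  vals <- cbind(total = x$total$value[, 1], product = x$product$value[, 1],
                sapply(x$motions, function(m) m$correlation$value[, 1]))
  colnames(vals)[-(1:2)] <- vapply(x$motions, `[[`, "", "name")
  graphics::matplot(tt[pos], vals[pos, ], type = "l", log = "x",
                    xlab = "lag time (s)", ylab = "C(t)", lty = 1, ...)
  graphics::legend("bottomleft", colnames(vals), col = seq_len(ncol(vals)),
                   lty = 1, cex = 0.7)
  invisible(x)
}
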