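# Rotation algebra: ZYZ Euler angles (active convention), rank-2 Wigner
# rotation matrix elements, and rigid-body superposition. All rotations in
# this package are proper (det = +1) and the gauge freedom at beta = 0 or pi
# is resolved by setting gamma = 0.

#' Euler angles (ZYZ, active)
#'
#' Construct an Euler-angle object in the ZYZ active convention used
#' throughout the package: the rotation matrix is
#' \code{Rz(alpha) \%*\% Ry(beta) \%*\% Rz(gamma)} and acts on column vectors.
#'
#' @param alpha,beta,gamma Angles in radians. \code{beta} is folded into
#'   \code{[0, pi]}.
#' @return An object of class \code{euler_angles} (a named list with numeric
#'   fields \code{alpha}, \code{beta}, \code{gamma}).
#' @export
euler_angles <- function(alpha, beta, gamma) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma))
  if (any(beta < -1e-9 | beta > pi + 1e-9)) {
    # fold via the equivalence (a, -b, g) == (a + pi, b, g + pi)
    neg <- beta < 0
    alpha[neg] <- alpha[neg] + pi
    gamma[neg] <- gamma[neg] + pi
    beta[neg] <- -beta[neg]
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma)),
            class = "euler_angles")
}

#' @export
print.euler_angles <- function(x, ...) {
  n <- length(x$alpha)
  cat(sprintf("ZYZ Euler angles (%d rotation%s)\n", n, if (n == 1) "" else "s"))
  m <- min(n, 6L)
  print(round(cbind(alpha = x$alpha[seq_len(m)], beta = x$beta[seq_len(m)],
                    gamma = x$gamma[seq_len(m)]), 6))
  if (n > m) cat("...\n")
  invisible(x)
}

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(b) {
  matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
}

#' Rotation matrix from ZYZ Euler angles
#'
#' @param omega An \code{euler_angles} object (or a list with fields
#'   \code{alpha}, \code{beta}, \code{gamma}); only the first element of each
#'   field is used.
#' @return A 3x3 proper rotation matrix.
#' @export
rot_zyz <- function(omega) {
  rot_z(omega$alpha[1]) %*% rot_y(omega$beta[1]) %*% rot_z(omega$gamma[1])
}

#' Series of rotation matrices from Euler-angle vectors
#'
#' Vectorized companion of [rot_zyz()]: returns a \code{3 x 3 x N} array of
#' rotation matrices for Euler-angle vectors of length \code{N}.
#'
#' @param omega An \code{euler_angles} object with vector fields.
#' @return A \code{3 x 3 x N} array.
#' @export
rot_zyz_series <- function(omega) {
  ca <- cos(omega$alpha); sa <- sin(omega$alpha)
  cb <- cos(omega$beta);  sb <- sin(omega$beta)
  cg <- cos(omega$gamma); sg <- sin(omega$gamma)
  n <- length(ca)
  out <- array(NA_real_, c(3, 3, n))
  out[1, 1, ] <- ca * cb * cg - sa * sg
  out[2, 1, ] <- sa * cb * cg + ca * sg
  out[3, 1, ] <- -sb * cg
  out[1, 2, ] <- -ca * cb * sg - sa * cg
  out[2, 2, ] <- -sa * cb * sg + ca * cg
  out[3, 2, ] <- sb * sg
  out[1, 3, ] <- ca * sb
  out[2, 3, ] <- sa * sb
  out[3, 3, ] <- cb
  out
}

check_orthonormal <- function(R, tol = 1e-6, what = "triad", index = NULL) {
  dev <- max(abs(crossprod(R) - diag(3)))
  if (!is.finite(dev) || dev > tol || det(R) < 0) {
    where <- if (is.null(index)) "" else sprintf(" at time index %d", index)
    stop(sprintf(
      "degenerate frame: %s%s is not a proper orthonormal triad (max deviation %.3g)",
      what, where, dev), call. = FALSE)
  }
  invisible(TRUE)
}

#' Euler angles mapping the lab axes onto an orthonormal triad
#'
#' Finds the ZYZ Euler angles \eqn{\Omega} such that
#' \code{rot_zyz(omega)} maps the lab X, Y, Z unit vectors onto the columns
#' of \code{axes}, i.e. the triad *is* the rotation matrix.
#'
#' @param axes A 3x3 matrix whose columns are the frame axes
#'   \eqn{\nu_X, \nu_Y, \nu_Z}, orthonormal to within \code{tol}.
#' @param tol Orthonormality tolerance (default \code{1e-6}).
#' @param index Optional time index used in the error message when the triad
#'   is degenerate.
#' @return An \code{euler_angles} object.
#' @export
euler_from_axes <- function(axes, tol = 1e-6, index = NULL) {
  axes <- as.matrix(axes)
  stopifnot(all(dim(axes) == c(3, 3)))
  check_orthonormal(axes, tol, "frame axes", index)
  euler_from_matrix_components(
    axes[1, 1], axes[2, 1], axes[3, 1],
    axes[1, 2], axes[2, 2], axes[3, 2],
    axes[1, 3], axes[2, 3], axes[3, 3])
}

# Vectorized ZYZ extraction from rotation-matrix components. Gauge at
# beta ~ 0 or pi: gamma = 0.
euler_from_matrix_components <- function(r11, r21, r31, r12, r22, r32,
                                         r13, r23, r33) {
  beta <- acos(pmin(1, pmax(-1, r33)))
  sb <- sin(beta)
  reg <- sb > 1e-8
  alpha <- numeric(length(beta))
  gamma <- numeric(length(beta))
  alpha[reg] <- atan2(r23[reg], r13[reg])
  gamma[reg] <- atan2(r32[reg], -r31[reg])
  deg <- !reg
  if (any(deg)) {
    up <- deg & r33 > 0       # beta ~ 0: R = Rz(alpha + gamma)
    dn <- deg & r33 <= 0      # beta ~ pi: R = Rz(alpha - gamma) Ry(pi)
    alpha[up] <- atan2(r21[up], r11[up])
    alpha[dn] <- atan2(-r21[dn], -r11[dn])
    gamma[deg] <- 0
  }
  euler_angles(alpha, beta, gamma)
}

#' Euler angles of a series of orthonormal triads
#'
#' @param axes A \code{3 x 3 x N} array of orthonormal triads (columns are
#'   the frame axes).
#' @param tol Orthonormality tolerance.
#' @return An \code{euler_angles} object with vector fields of length N.
#' @export
euler_from_axes_series <- function(axes, tol = 1e-6) {
  stopifnot(length(dim(axes)) == 3, all(dim(axes)[1:2] == c(3, 3)))
  # cheap orthonormality screen: |col| = 1 and col3 = col1 x col2
  n1 <- axes[1, 1, ]^2 + axes[2, 1, ]^2 + axes[3, 1, ]^2
  n3 <- axes[1, 3, ]^2 + axes[2, 3, ]^2 + axes[3, 3, ]^2
  cx <- axes[2, 1, ] * axes[3, 2, ] - axes[3, 1, ] * axes[2, 2, ]
  cy <- axes[3, 1, ] * axes[1, 2, ] - axes[1, 1, ] * axes[3, 2, ]
  cz <- axes[1, 1, ] * axes[2, 2, ] - axes[2, 1, ] * axes[1, 2, ]
  dev <- pmax(abs(n1 - 1), abs(n3 - 1),
              abs(cx - axes[1, 3, ]), abs(cy - axes[2, 3, ]),
              abs(cz - axes[3, 3, ]))
  bad <- which(dev > 10 * tol)
  if (length(bad)) {
    stop(sprintf("degenerate frame: triad at time index %d is not proper orthonormal (deviation %.3g)",
                 bad[1], dev[bad[1]]), call. = FALSE)
  }
  euler_from_matrix_components(
    axes[1, 1, ], axes[2, 1, ], axes[3, 1, ],
    axes[1, 2, ], axes[2, 2, ], axes[3, 2, ],
    axes[1, 3, ], axes[2, 3, ], axes[3, 3, ])
}

#' Rigid-body superposition (Kabsch)
#'
#' Returns the proper rotation that, applied to the centered \code{mobile}
#' point set, minimizes the RMSD to the centered \code{reference} set.
#' Reflections are forbidden (determinant correction), so the result is
#' always a proper rotation and can feed the Wigner algebra.
#'
#' @param mobile,reference Numeric \code{n x 3} matrices of matching row
#'   count, \code{n >= 3}, not collinear. Both sets are centered internally.
#' @param as_matrix If \code{TRUE} return the 3x3 rotation matrix instead of
#'   Euler angles.
#' @return An \code{euler_angles} object (or a rotation matrix) such that
#'   \code{rot_zyz(result) \%*\% t(centered mobile)} superposes onto the
#'   centered reference.
#' @export
kabsch_align <- function(mobile, reference, as_matrix = FALSE) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3 ||
      nrow(mobile) < 3) {
    stop("point sets must be matching n x 3 matrices with n >= 3")
  }
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  H <- crossprod(P, Q)            # 3x3 covariance
  sv <- svd(H)
  # degenerate (collinear/coincident) sets: rank of the cross-covariance < 2
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300)) {
    stop("degenerate frame: point set is collinear or coincident; rotation undetermined",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (as_matrix) R else euler_from_axes(R)
}
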