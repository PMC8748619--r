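# Rank-2 Wigner rotation matrix elements.
#
# Convention: D^2_{p q}(alpha, beta, gamma) = exp(-i p alpha) d^2_{p q}(beta)
# exp(-i q gamma) with ZYZ active Euler angles, so that the 5x5 matrices obey
# the same homomorphism as the rotation matrices: D(R1 %*% R2) = D(R1) D(R2).
# Indices p, q run over -2..2 (stored rows/columns 1..5 = p,q + 3).

# little-d element by Wigner's sum formula (j = 2); vectorized over beta
d2_element <- function(mp, m, beta) {
  j <- 2
  pref <- sqrt(factorial(j + mp) * factorial(j - mp) *
               factorial(j + m) * factorial(j - m))
  c2 <- cos(beta / 2); s2 <- sin(beta / 2)
  out <- 0
  for (s in max(0, m - mp):min(j + m, j - mp)) {
    out <- out + (-1)^(mp - m + s) /
      (factorial(j + m - s) * factorial(s) *
       factorial(mp - m + s) * factorial(j - mp - s)) *
      c2^(2 * j + m - mp - 2 * s) * s2^(mp - m + 2 * s)
  }
  pref * out
}

#' Rank-2 Wigner rotation matrix
#'
#' Evaluates the full 5x5 complex matrix \eqn{D^2_{pq}(\Omega)} for ZYZ
#' active Euler angles, with \eqn{p, q \in \{-2, ..., 2\}} indexing rows and
#' columns. \eqn{D^2_{00}(0, \beta, 0) = (3\cos^2\beta - 1)/2} and the
#' matrices compose like the rotation matrices themselves.
#'
#' @param omega An \code{euler_angles} object (first element of each field
#'   used).
#' @return A 5x5 complex matrix of class \code{wigner_d2} with dimnames
#'   \code{p = -2..2}, \code{q = -2..2}.
#' @export
wigner_d2 <- function(omega) {
  a <- omega$alpha[1]; b <- omega$beta[1]; g <- omega$gamma[1]
  p <- -2:2
  d <- outer(p, p, function(mp, m) mapply(d2_element, mp, m, MoreArgs = list(beta = b)))
  D <- exp(-1i * (p %o% rep(1, 5)) * a) * d * exp(-1i * (rep(1, 5) %o% p) * g)
  dimnames(D) <- list(p = as.character(p), q = as.character(p))
  structure(D, class = c("wigner_d2", class(D)))
}

#' @export
print.wigner_d2 <- function(x, ...) {
  cat("rank-2 Wigner rotation matrix D^2_pq (p, q = -2..2)\n")
  print(round(unclass(x), 6))
  invisible(x)
}

# D^2_{p0} components from unit vectors u = R(Omega) %*% c(0,0,1).
# Only (alpha, beta) enter for q = 0:
#   D_{00} = (3 u_z^2 - 1)/2
#   D_{+-1,0} = -+ sqrt(3/2) u_z (u_x -+ i u_y)
#   D_{+-2,0} = sqrt(3/8) (u_x -+ i u_y)^2
# Returns a 5 x N complex matrix (rows p = -2..2).
d2_p0_from_vec <- function(ux, uy, uz) {
  em <- complex(real = ux, imaginary = -uy)  # sin(beta) e^{-i alpha}
  ep <- Conj(em)
  rbind(`-2` = sqrt(3 / 8) * ep^2,
        `-1` = sqrt(3 / 2) * uz * ep,
        `0`  = (3 * uz^2 - 1) / 2 + 0i,
        `1`  = -sqrt(3 / 2) * uz * em,
        `2`  = sqrt(3 / 8) * em^2)
}

# D^2_{0p} row from the transpose relation D_{0p}(Omega) = conj(D_{p0}(Omega^-1));
# directly: D_{0p}(alpha,beta,gamma) = d_{0p}(beta) exp(-i p gamma).
# For a rotation matrix R, the row depends on the *third row* of R, i.e. the
# preimage of z: w = t(R) %*% z has components (sin b cos g', ...). Using
# R[3,1] = -sin b cos g, R[3,2] = sin b sin g, R[3,3] = cos b:
#   D_{00} = (3 R33^2 - 1)/2
#   D_{0,+1} = -sqrt(3/2) R33 (R31... ) -- derived below from d_{0p}:
#   d_{0,+-1}(b) = +- sqrt(3/2) sin b cos b ; d_{0,+-2}(b) = sqrt(3/8) sin^2 b
#   D_{0p} = d_{0p}(b) e^{-i p g}
# With e^{-ig} sin b = (-R31 - i R32):
d2_0p_from_row3 <- function(r31, r32, r33) {
  em <- complex(real = -r31, imaginary = -r32)  # sin(beta) e^{-i gamma}
  ep <- Conj(em)
  rbind(`-2` = sqrt(3 / 8) * ep^2,
        `-1` = -sqrt(3 / 2) * r33 * ep,
        `0`  = (3 * r33^2 - 1) / 2 + 0i,
        `1`  = sqrt(3 / 2) * r33 * em,
        `2`  = sqrt(3 / 8) * em^2)
}

# Full 5x5 D^2 for a series of Euler angles: returns 5 x 5 x N complex array.
wigner_d2_series <- function(omega) {
  p <- -2:2
  n <- length(omega$beta)
  d <- array(NA_real_, c(5, 5, n))
  for (i in 1:5) for (k in 1:5) {
    d[i, k, ] <- d2_element(p[i], p[k], omega$beta)
  }
  ea <- exp(-1i * outer(p, omega$alpha))      # 5 x N
  eg <- exp(-1i * outer(p, omega$gamma))
  D <- array(complex(real = 0), c(5, 5, n))
  for (i in 1:5) for (k in 1:5) {
    D[i, k, ] <- ea[i, ] * d[i, k, ] * eg[k, ]
  }
  D
}

# time-averaged 5x5 D^2 matrix over a triad series (3 x 3 x N)
mean_wigner_of_triads <- function(axes) {
  om <- euler_from_axes_series(axes)
  D <- wigner_d2_series(om)
  apply(D, c(1, 2), mean)
}
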