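## Wigner rotation matrices for the action of SO(3) on spherical-harmonic
## coefficients.  The small-d matrix is computed as exp(-i beta J_y) from a
## precomputed eigendecomposition of the angular-momentum generator J_y per
## degree l, which is fast and numerically stable for the moderate l used
## here.  Euler angles are z-y-z: R = Rz(alpha) Ry(beta) Rz(gamma).

#' Precompute Wigner rotation tables up to degree L
#' @param L maximal degree.
#' @return list indexed `[[l+1]]` with the eigenvectors `U` and eigenvalues
#'   `mu` of `J_y` in the `|l m>` basis (m = -l..l).
#' @export
wigner_tables <- function(L) {
  out <- vector("list", L + 1L)
  for (l in 0:L) {
    m <- -l:l
    n <- 2L * l + 1L
    Jp <- matrix(0, n, n); Jm <- matrix(0, n, n)
    if (l > 0) {
      for (k in 1:(n - 1)) {
        mm <- m[k]
        Jp[k + 1, k] <- sqrt(l * (l + 1) - mm * (mm + 1))  # raises m -> m+1
        Jm[k, k + 1] <- sqrt(l * (l + 1) - m[k + 1] * (m[k + 1] - 1))
      }
    }
    Jy <- (Jp - Jm) / (2i)
    e <- eigen(Jy, symmetric = TRUE)
    out[[l + 1L]] <- list(U = e$vectors, mu = Re(e$values))
  }
  out
}

#' Wigner small-d matrix d^l(beta)
#' @param l degree; @param beta second Euler angle; @param tab [wigner_tables()].
#' @return real `(2l+1) x (2l+1)` matrix, rows/cols ordered m = -l..l.
#' @export
wigner_d <- function(l, beta, tab) {
  w <- tab[[l + 1L]]
  d <- w$U %*% (exp(-1i * beta * w$mu) * Conj(t(w$U)))
  Re(d)
}

#' Full Wigner D matrix D^l(alpha, beta, gamma)
#' @param l degree; @param abc Euler angles (z-y-z); @param tab [wigner_tables()].
#' @return complex `(2l+1) x (2l+1)` matrix; a function f with coefficients
#'   `c_m` rotated by `R(abc)` (i.e. `f'(x) = f(R^{-1} x)`) has coefficients
#'   `c'_{m'} = sum_m D_{m'm} c_m`.
#' @export
wigner_D <- function(l, abc, tab) {
  m <- -l:l
  d <- wigner_d(l, abc[2], tab)
  exp(-1i * m * abc[1]) * d * rep(exp(-1i * m * abc[3]), each = 2L * l + 1L)
}

#' Rotate stacked spherical-harmonic coefficients
#' @param cf array `(N_shell, L+1, 2L+1)` of coefficients.
#' @param abc Euler angles (z-y-z).
#' @param tab [wigner_tables()] of sufficient degree.
#' @return rotated coefficient array of the same shape.
#' @export
rotate_sph_coeffs <- function(cf, abc, tab) {
  L <- dim(cf)[2] - 1L
  Ns <- dim(cf)[1]
  out <- array(0 + 0i, dim = dim(cf))
  for (l in 0:L) {
    cols <- (L + 1L - l):(L + 1L + l)
    D <- wigner_D(l, abc, tab)
    cm <- matrix(cf[, l + 1L, cols], nrow = Ns)
    out[, l + 1L, cols] <- cm %*% t(D)
  }
  out
}

#' z-y-z Euler rotation matrix
#' @param abc Euler angles `(alpha, beta, gamma)`.
#' @return 3x3 rotation matrix `Rz(alpha) Ry(beta) Rz(gamma)`.
#' @export
rot_zyz <- function(abc) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz(abc[1]) %*% ry(abc[2]) %*% rz(abc[3])
}

#' Draw Haar-uniform rotations as z-y-z Euler angles
#'
#' `alpha` and `gamma` are uniform on `[0, 2pi)` and `cos(beta)` is uniform on
#' `[-1, 1]`, which is exactly the Haar measure on SO(3) in z-y-z angles.
#' @param n number of rotations.
#' @return `n x 3` matrix of Euler angle triples.
#' @export
sample_so3 <- function(n) {
  cbind(stats::runif(n, 0, 2 * pi),
        acos(stats::runif(n, -1, 1)),
        stats::runif(n, 0, 2 * pi))
}
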