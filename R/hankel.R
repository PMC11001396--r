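## Midpoint-rule Hankel transforms connecting real- and reciprocal-space
## harmonic coefficients.
##
## 2D (polar):     A_m(q)   = 2 pi (-i)^m  int J_m(q r)  rho_m(r)  r   dr
##                 rho_m(r) = (i)^m/(2 pi) int J_m(q r)  A_m(q)    q   dq
## 3D (spherical): A_lm(q)  = 4 pi (-i)^l  int j_l(q r)  rho_lm(r) r^2 dr
##                 rho_lm(r)= (i)^l/(2 pi^2) int j_l(q r) A_lm(q)  q^2 dq
##
## Integrals are approximated by midpoint Riemann sums on the conjugate
## radial grids (r_k, q_p midpoints, R_max = pi N / Q_max), giving one dense
## N x N weight matrix per harmonic order; the inverse weights are the
## forward weights with the roles of p and k transposed.

## spherical Bessel function of the first kind
sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) out[pos] <- sqrt(pi / (2 * x[pos])) * besselJ(x[pos], l + 0.5)
  if (any(!pos)) out[!pos] <- if (l == 0) 1 else 0
  out
}

#' Precompute midpoint-rule Hankel quadrature matrices
#'
#' @param grids conjugate grids from [make_grids()].
#' @param L_max maximal harmonic order.
#' @param case `"2D"` (integer-order Bessel `J_m`) or `"3D"` (spherical
#'   Bessel `j_l`).
#' @return `fxs_hankel` with per-order complex weight matrices
#'   `forward[[m+1]]` (maps the N real-space samples of order m to N
#'   reciprocal samples) and `inverse[[m+1]]`.
#' @export
hankel_weights <- function(grids, L_max, case = c("3D", "2D")) {
  case <- match.arg(case)
  r <- grids$real$points; q <- grids$reciprocal$points
  dr <- grids$real$step; dq <- grids$reciprocal$step
  N <- grids$real$N
  fw <- vector("list", L_max + 1L); iv <- vector("list", L_max + 1L)
  X <- outer(q, r)                       # q_p r_k
  for (m in 0:L_max) {
    if (case == "2D") {
      B <- besselJ(X, m)                 # rows p, cols k
      fw[[m + 1L]] <- (2 * pi) * (-1i)^m * B * rep(r * dr, each = N)
      iv[[m + 1L]] <- (1i)^m / (2 * pi) * t(B) * rep(q * dq, each = N)
    } else {
      B <- matrix(sph_bessel_j(m, X), N, N)
      fw[[m + 1L]] <- (4 * pi) * (-1i)^m * B * rep(r^2 * dr, each = N)
      iv[[m + 1L]] <- (1i)^m / (2 * pi^2) * t(B) * rep(q^2 * dq, each = N)
    }
  }
  structure(list(case = case, L_max = L_max, forward = fw, inverse = iv,
                 N = N), class = "fxs_hankel")
}

#' Hankel-transform stacked harmonic coefficients
#'
#' Orders act block-diagonally: each harmonic order is transformed by its own
#' quadrature matrix, orders do not mix.
#'
#' @param coef coefficients: 2D case a complex matrix `N x (2*L_max+1)`
#'   (columns = signed orders `-L..L`); 3D case a complex array
#'   `(N, L_max+1, 2*L_max+1)`.
#' @param hw [hankel_weights()].
#' @param direction `"forward"` (real to reciprocal) or `"inverse"`.
#' @return transformed coefficients, same shape.
#' @export
hankel <- function(coef, hw, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  W <- if (direction == "forward") hw$forward else hw$inverse
  if (hw$case == "2D") {
    if (nrow(coef) != hw$N) stop("grid mismatch")
    L <- (ncol(coef) - 1L) %/% 2L
    if (L > hw$L_max) stop("order exceeds precomputed weights")
    out <- coef
    for (n in -L:L) out[, n + L + 1L] <- W[[abs(n) + 1L]] %*% coef[, n + L + 1L]
    out
  } else {
    if (dim(coef)[1] != hw$N) stop("grid mismatch")
    L <- dim(coef)[2] - 1L
    if (L > hw$L_max) stop("order exceeds precomputed weights")
    out <- array(0 + 0i, dim = dim(coef))
    for (l in 0:L) {
      cols <- (L + 1L - l):(L + 1L + l)
      out[, l + 1L, cols] <- W[[l + 1L]] %*% matrix(coef[, l + 1L, cols], nrow = hw$N)
    }
    out
  }
}
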