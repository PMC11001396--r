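## Circular and spherical harmonic transforms.
##
## Conventions (pinned by tests):
##  * circular synthesis  f(phi) = sum_n c_n exp(i n phi), orders
##    n in [-N_phi/2, N_phi/2); forward is the plain DFT / N_phi.
##  * spherical harmonics are orthonormal with the Condon-Shortley phase,
##    Y_lm(theta,phi) = Ptilde_l^m(cos theta) exp(i m phi) where Ptilde
##    carries the full normalization sqrt((2l+1)/(4pi) (l-m)!/(l+m)!).
##    A constant field c therefore has the single coefficient c*sqrt(4pi).

#' Signed harmonic orders resolved by an azimuthal grid
#' @param N_phi number of azimuthal samples.
#' @return integer vector of orders `-floor(N_phi/2) .. ceiling(N_phi/2)-1`
#'   in the storage order used by [circular_transform()].
#' @export
circ_orders <- function(N_phi) {
  n <- seq.int(0L, N_phi - 1L)
  ifelse(n < ceiling(N_phi / 2), n, n - N_phi)
}

## map signed order m to 1-based FFT bin
order_bin <- function(m, N_phi) (m %% N_phi) + 1L

#' Circular harmonic (Fourier series) transform of detector rings
#'
#' @param x numeric/complex vector of length `N_phi`, or a matrix whose rows
#'   are rings (columns = azimuthal samples).
#' @param direction `"forward"` (ring values to coefficients) or `"inverse"`.
#' @return same shape as `x`; coefficient columns are in FFT bin order, i.e.
#'   column `j` holds order `circ_orders(N_phi)[j]` after reordering -- use
#'   [circ_coef_signed()] to obtain signed-order layout.
#' @export
circular_transform <- function(x, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else x
  if (direction == "forward") {
    out <- t(stats::mvfft(t(xm))) / ncol(xm)
  } else {
    out <- t(stats::mvfft(t(xm), inverse = TRUE))
  }
  if (vec) drop(out) else out
}

#' Reorder FFT-bin circular coefficients to signed orders -L..L
#' @param cf coefficient matrix in FFT bin order (rows = rings).
#' @param L_max maximal retained order.
#' @return matrix with `2*L_max+1` columns for orders `-L_max..L_max`.
#' @export
circ_coef_signed <- function(cf, L_max) {
  vec <- is.null(dim(cf))
  cfm <- if (vec) matrix(cf, nrow = 1L) else cf
  N_phi <- ncol(cfm)
  if (2L * L_max + 1L > N_phi) stop("L_max exceeds grid capacity")
  out <- cfm[, order_bin(-L_max:L_max, N_phi), drop = FALSE]
  colnames(out) <- as.character(-L_max:L_max)
  if (vec) drop(out) else out
}

## inverse of circ_coef_signed: scatter signed-order coefficients into FFT bins
circ_coef_bins <- function(cs, N_phi) {
  vec <- is.null(dim(cs))
  csm <- if (vec) matrix(cs, nrow = 1L) else cs
  L_max <- (ncol(csm) - 1L) %/% 2L
  out <- matrix(0 + 0i, nrow(csm), N_phi)
  out[, order_bin(-L_max:L_max, N_phi)] <- csm
  if (vec) drop(out) else out
}

#' Orthonormal associated Legendre functions
#'
#' Returns `Ptilde_l^m(x)` for `0 <= m <= l <= L` with the spherical-harmonic
#' normalization and Condon-Shortley phase, computed by the standard stable
#' three-term recurrences.
#'
#' @param L maximal degree.
#' @param x evaluation points in `[-1, 1]`.
#' @return array `dim = c(L+1, L+1, length(x))`, index `[l+1, m+1, ]`; entries
#'   with `m > l` are zero.  Negative orders follow from
#'   `Ptilde_l^{-m} = (-1)^m Ptilde_l^m`.
#' @export
alp_normalized <- function(L, x) {
  nx <- length(x)
  P <- array(0, dim = c(L + 1L, L + 1L, nx))
  s <- sqrt(pmax(0, 1 - x^2))
  P[1, 1, ] <- sqrt(1 / (4 * pi))
  if (L >= 1) {
    for (m in 1:L) {   # diagonal Ptilde_m^m
      P[m + 1, m + 1, ] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[m, m, ]
    }
  }
  for (m in 0:L) {
    if (m + 1 <= L)    # first off-diagonal
      P[m + 2, m + 1, ] <- x * sqrt(2 * m + 3) * P[m + 1, m + 1, ]
    if (m + 2 <= L) {
      for (l in (m + 2):L) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[l + 1, m + 1, ] <- a * (x * P[l, m + 1, ] - b * P[l - 1, m + 1, ])
      }
    }
  }
  P
}

## Ptilde for signed m: matrix (l rows for l=|m|..L) at nodes x
alp_signed <- function(Ptab, m, L) {
  am <- abs(m)
  v <- Ptab[(am + 1):(L + 1), am + 1, , drop = FALSE]
  v <- array(v, dim = dim(v)[c(1, 3)])       # (L-|m|+1) x nx
  if (m < 0 && am %% 2 == 1) v <- -v
  v
}

#' Spherical harmonic transform on a Gauss--Legendre x uniform-phi grid
#'
#' @param x for `"forward"`: field values, matrix `N_theta x N_phi` or array
#'   `(N_shell, N_theta, N_phi)`; for `"inverse"`: coefficients, matrix
#'   `(L_max+1) x (2*L_max+1)` (columns = orders `-L_max..L_max`) or array
#'   `(N_shell, L_max+1, 2*L_max+1)`.
#' @param ang a 3D [angular_grid()].
#' @param L_max maximal degree; must not exceed the grid capacity.
#' @param direction `"forward"` or `"inverse"`.
#' @return coefficients (forward) or complex field values (inverse) in the
#'   shapes described above.
#' @export
spherical_transform <- function(x, ang, L_max = ang$L_max,
                                direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (ang$case != "3D") stop("spherical_transform needs a 3D angular grid")
  if (L_max > ang$L_max) stop("L_max exceeds grid capacity")
  plan <- sph_plan(ang, L_max)
  if (direction == "forward") {
    single <- length(dim(x)) == 2L
    f <- if (single) array(x, dim = c(1L, dim(x))) else x
    sph_analysis_stack(f, ang, L_max, plan, drop_single = single)
  } else {
    single <- length(dim(x)) == 2L
    cf <- if (single) array(x, dim = c(1L, dim(x))) else x
    sph_synthesis_stack(cf, ang, L_max, plan, drop_single = single)
  }
}

## per-m Legendre matrices for analysis (theta-weighted) and synthesis
sph_plan <- function(ang, L_max) {
  Ptab <- alp_normalized(L_max, ang$ct)
  w <- ang$theta_weights
  Pw <- vector("list", 2L * L_max + 1L)   # analysis: (Nt, nl)
  Ps <- vector("list", 2L * L_max + 1L)   # synthesis: (nl, Nt)
  for (m in -L_max:L_max) {
    Pm <- alp_signed(Ptab, m, L_max)
    Pw[[m + L_max + 1L]] <- t(Pm * rep(w, each = nrow(Pm)))
    Ps[[m + L_max + 1L]] <- Pm
  }
  list(Pw = Pw, Ps = Ps, L_max = L_max)
}

## forward analysis of a stack of shells: f (Ns, N_theta, N_phi)
sph_analysis_stack <- function(f, ang, L_max, plan = NULL, drop_single = FALSE) {
  if (is.null(plan)) plan <- sph_plan(ang, L_max)
  Ns <- dim(f)[1]; Nt <- ang$N_theta; Np <- ang$N_phi
  ## phi integral: (2*pi/N_phi) * DFT over the phi dimension
  fm <- aperm(f, c(3, 1, 2))                   # (N_phi, Ns, Nt)
  dim(fm) <- c(Np, Ns * Nt)
  Fm <- stats::mvfft(fm) * (2 * pi / Np)
  dim(Fm) <- c(Np, Ns, Nt)
  cf <- array(0 + 0i, dim = c(Ns, L_max + 1L, 2L * L_max + 1L))
  for (m in -L_max:L_max) {
    A <- matrix(Fm[order_bin(m, Np), , ], nrow = Ns, ncol = Nt)
    cf[, (abs(m) + 1):(L_max + 1), m + L_max + 1L] <-
      A %*% plan$Pw[[m + L_max + 1L]]
  }
  if (drop_single) array(cf, dim = dim(cf)[2:3]) else cf
}

## inverse synthesis of a stack: cf (Ns, L+1, 2L+1) -> (Ns, N_theta, N_phi)
sph_synthesis_stack <- function(cf, ang, L_max, plan = NULL, drop_single = FALSE) {
  if (is.null(plan)) plan <- sph_plan(ang, L_max)
  Ns <- dim(cf)[1]; Nt <- ang$N_theta; Np <- ang$N_phi
  G <- array(0 + 0i, dim = c(Np, Ns, Nt))
  for (m in -L_max:L_max) {
    cm <- matrix(cf[, (abs(m) + 1):(L_max + 1), m + L_max + 1L],
                 nrow = Ns, ncol = L_max - abs(m) + 1L)
    G[order_bin(m, Np), , ] <- cm %*% plan$Ps[[m + L_max + 1L]]  # (Ns, Nt)
  }
  dim(G) <- c(Np, Ns * Nt)
  f <- stats::mvfft(G, inverse = TRUE)         # unnormalized: sum over bins
  dim(f) <- c(Np, Ns, Nt)
  out <- aperm(f, c(2, 3, 1))
  if (drop_single) array(out, dim = dim(out)[2:3]) else out
}

## Synthesis of shell-wise spherical coefficients on arbitrary per-shell
## polar angles (Ewald slice): returns rings (Ns x N_phi_det).
## ct: cos(theta) per shell (length Ns).
sph_synthesis_slice <- function(cf, ct, L_max, N_phi_det) {
  if (N_phi_det < 2L * L_max + 1L) stop("N_phi_det cannot resolve L_max")
  Ns <- dim(cf)[1]
  Ptab <- alp_normalized(L_max, ct)
  G <- matrix(0 + 0i, Ns, N_phi_det)
  for (m in -L_max:L_max) {
    Pm <- alp_signed(Ptab, m, L_max)           # (nl, Ns)
    cm <- matrix(cf[, (abs(m) + 1):(L_max + 1), m + L_max + 1L],
                 nrow = Ns, ncol = L_max - abs(m) + 1L)
    G[, order_bin(m, N_phi_det)] <- rowSums(cm * t(Pm))
  }
  t(stats::mvfft(t(G), inverse = TRUE))        # rings
}
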