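## Extraction of rotational invariants from the averaged CCF.
##
## 2D: the CCF is the circular Fourier series of the invariants,
##       C(q,q',D) = sum_n B_n(q,q') exp(-i n D),  B_n = I_n(q) I_n(q')*.
## 3D: C(q,q',D) = sum_l B_l(q,q') F_l(q,q',D) with the Legendre kernel
##       F_l(q,q',D) = P_l(cos th cos th' + sin th sin th' cos D) / (4 pi),
##     th = theta(q) on the Ewald sphere.  B_l = sum_m I_lm(q) I_lm(q')*.
## The circular spectrum of F_l is a trigonometric polynomial of degree l,
## so the coefficient system linking the CCF spectrum C_n to B_l is upper
## triangular and solved by back-substitution; a pseudo-inverse path over
## the angular-lag samples is kept as the reference method.

## circular coefficient of an array over its 3rd index, convention
## f(D) = sum_n c_n exp(-i n D):  c_n = (1/N) sum_t f(D_t) exp(+i n D_t)
lag_to_spec <- function(vals) {
  d <- dim(vals)
  dim(vals) <- c(d[1] * d[2], d[3])
  out <- t(stats::mvfft(t(vals), inverse = TRUE)) / d[3]
  dim(out) <- d
  out
}

## minimum-norm least squares for complex systems (R's qr is real-only)
lstsq_complex <- function(A, y, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((Conj(t(sv$u[, keep, drop = FALSE])) %*% y) / sv$d[keep])
}

#' Legendre extraction kernel for the 3D invariants
#'
#' Tabulates `F_l(q,q',Delta_t)` and its circular spectrum
#' `M[n+1, l+1](q,q')` (the upper-triangular matrix linking the CCF spectrum
#' to the invariants).  The spectrum is computed by FFT over the lag grid,
#' which is exact because `F_l` is a trigonometric polynomial of degree
#' `l <= L_max < N_delta/2`.
#'
#' @param grids conjugate grids ([make_grids()]).
#' @param geom [ewald_geometry()].
#' @param L_max maximal invariant order.
#' @param N_delta number of angular-lag samples (default `2*L_max + 2`).
#' @return `fxs_kernel` with `F` (array `(L+1, N, N, N_delta)`), `Mtri`
#'   (array `(L+1, L+1, N, N)`, entry `[n+1, l+1, , ]` zero for `l < n`),
#'   `theta`, `delta`.
#' @export
build_kernel <- function(grids, geom, L_max, N_delta = 2L * L_max + 2L) {
  if (L_max >= N_delta / 2) stop("L_max must be < N_delta/2")
  q <- grids$reciprocal$points
  if (any(q > 2 * geom$kappa)) stop("grid extends beyond backscattering (q > 2 kappa)")
  N <- grids$reciprocal$N
  th <- ewald_theta(q, geom)
  ct <- cos(th); st <- sin(th)
  delta <- (seq_len(N_delta) - 1L) * 2 * pi / N_delta
  Fk <- array(0, dim = c(L_max + 1L, N, N, N_delta))
  cc <- outer(ct, ct); ss <- outer(st, st)
  ## Legendre recursion in the composite argument, vectorized over (q,q',D)
  for (t in seq_len(N_delta)) {
    x <- cc + ss * cos(delta[t])
    Pm1 <- matrix(1, N, N); P0 <- x
    Fk[1, , , t] <- 1 / (4 * pi)
    if (L_max >= 1) Fk[2, , , t] <- x / (4 * pi)
    if (L_max >= 2) for (l in 2:L_max) {
      P1 <- ((2 * l - 1) * x * P0 - (l - 1) * Pm1) / l
      Fk[l + 1, , , t] <- P1 / (4 * pi)
      Pm1 <- P0; P0 <- P1
    }
  }
  ## circular spectrum of each F_l: real, even in n; keep n = 0..L
  Mtri <- array(0, dim = c(L_max + 1L, L_max + 1L, N, N))
  for (l in 0:L_max) {
    sp <- lag_to_spec(array(Fk[l + 1, , , ], dim = c(N, N, N_delta)))
    for (n in 0:l) Mtri[n + 1, l + 1, , ] <- Re(sp[, , n + 1])
  }
  structure(list(L_max = L_max, N_delta = N_delta, delta = delta,
                 theta = th, F = Fk, Mtri = Mtri),
            class = "fxs_kernel")
}

## CCF synthesis from known invariants via the kernel (Eq. 9 direction);
## B given as list over l of N x N matrices
synthesize_ccf_3d <- function(B, kernel) {
  d <- dim(kernel$F)
  out <- array(0, dim = d[2:4])
  for (l in seq_along(B) - 1L) {
    if (is.null(B[[l + 1]])) next
    for (t in seq_len(d[4]))
      out[, , t] <- out[, , t] + Re(B[[l + 1]]) * kernel$F[l + 1, , , t]
  }
  out
}

new_invariant_set <- function(case, L_max, B, method, N_p = 1L) {
  structure(list(case = case, L_max = L_max, B = B, eigen = NULL,
                 method = method, N_p = N_p), class = "fxs_invariants")
}

#' @export
print.fxs_invariants <- function(x, ...) {
  cat(sprintf("<rotational invariants: %s, orders 0..%d, N=%d, method=%s%s>\n",
              x$case, x$L_max, nrow(x$B[[1]]), x$method,
              if (is.null(x$eigen)) "" else ", decomposed"))
  invisible(x)
}

#' Extract 2D invariants B_n from an averaged CCF
#'
#' The invariants are the circular harmonic coefficients of the CCF in the
#' angular lag; each extracted matrix is Hermitianized.  For `(q,q')` pairs
#' with missing lag samples (masked-out cells) the coefficients are obtained
#' by least squares over the valid samples only.
#'
#' @param ccf `fxs_ccf` from a flat-geometry 2D pattern set.
#' @param L_max maximal order (`< N_delta/2`).
#' @return `fxs_invariants` with `B[[n+1]]` for `n = 0..L_max`
#'   (`B_{-n} = Conj(B_n)`).
#' @export
extract_bn_2d <- function(ccf, L_max) {
  Nd <- ccf$N_phi
  if (L_max >= Nd / 2) stop("L_max must be < N_delta/2")
  vals <- ccf$values
  N <- dim(vals)[1]
  incomplete <- !apply(ccf$valid, c(1, 2), all)
  if (any(incomplete)) {
    vals[is.na(vals)] <- 0       # spectra of complete rows are unaffected
  }
  sp <- lag_to_spec(vals)
  B <- lapply(0:L_max, function(n) matrix(sp[, , n + 1], N, N))
  if (any(incomplete)) {
    E <- exp(-1i * outer(ccf$delta, -L_max:L_max))
    for (ii in which(incomplete)) {
      k <- (ii - 1) %% N + 1; p <- (ii - 1) %/% N + 1
      ok <- ccf$valid[k, p, ]
      if (sum(ok) < 2 * L_max + 1) { for (n in 0:L_max) B[[n + 1]][k, p] <- NA; next }
      cf <- lstsq_complex(E[ok, , drop = FALSE], ccf$values[k, p, ok])
      for (n in 0:L_max) B[[n + 1]][k, p] <- cf[n + L_max + 1]
    }
  }
  B <- lapply(B, function(m) (m + Conj(t(m))) / 2)
  new_invariant_set("2D", L_max, B, "circular")
}

#' Extract 3D invariants B_l by pseudo-inversion over the lag samples
#'
#' For each `(q,q')` pair the CCF over the angular lag is fit to the Legendre
#' kernel by least squares (minimum-norm solution via the pivoted QR when the
#' design is rank deficient), using only valid lag samples.
#'
#' @param ccf `fxs_ccf` (3D case).
#' @param kernel matching [build_kernel()].
#' @return `fxs_invariants` with `B[[l+1]]`, `l = 0..L_max`, Hermitianized.
#' @export
extract_bl_lstsq <- function(ccf, kernel) {
  L <- kernel$L_max; N <- dim(ccf$values)[1]
  if (ccf$N_phi != kernel$N_delta) stop("lag grids differ")
  B <- lapply(0:L, function(l) matrix(0, N, N))
  warned <- FALSE
  for (k in seq_len(N)) for (p in seq_len(N)) {
    ok <- ccf$valid[k, p, ]
    if (!any(ok)) { for (l in 0:L) B[[l + 1]][k, p] <- NA; next }
    Fm <- t(matrix(kernel$F[, k, p, ], nrow = L + 1L))[ok, , drop = FALSE]
    y <- ccf$values[k, p, ok]
    ## SVD-based pseudo-inverse; minimum-norm when the design is deficient
    sv <- svd(Fm)
    keep <- sv$d > 1e-10 * sv$d[1]
    if (!all(keep) && !warned) {
      warning("rank-deficient kernel; minimum-norm solution")
      warned <- TRUE
    }
    fit <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
    for (l in 0:L) B[[l + 1]][k, p] <- fit[l + 1]
  }
  B <- lapply(B, function(m) (m + Conj(t(m))) / 2)
  new_invariant_set("3D", L, B, "lstsq")
}

#' Extract 3D invariants B_l by triangular back-substitution
#'
#' Computes the circular spectrum of the CCF in the angular lag and solves
#' the upper-triangular system linking it to the invariants from the highest
#' order downward.  `(q,q')` cells with missing lag samples fall back to the
#' least-squares path.  Cost per pair is linear in `L_max` once the spectra
#' are cached, versus cubic for the SVD-based pseudo-inverse.
#'
#' @inheritParams extract_bl_lstsq
#' @return `fxs_invariants`, method `"backsub"`.
#' @export
extract_bl_backsub <- function(ccf, kernel) {
  L <- kernel$L_max; N <- dim(ccf$values)[1]
  if (ccf$N_phi != kernel$N_delta) stop("lag grids differ")
  vals <- ccf$values
  incomplete <- !apply(ccf$valid, c(1, 2), all)
  vals[is.na(vals)] <- 0
  Cn <- lag_to_spec(vals)                 # spectra, orders in FFT bins
  ## vectorized substitution: per (q,q') cell the system is upper triangular
  ## in the orders; sweep l = L..0 with one fused update per order
  Bmat <- matrix(0 + 0i, N * N, L + 1L)   # columns: solved B_l, flattened
  Mflat <- matrix(kernel$Mtri, (L + 1L)^2, N * N)  # [(n,l) pair, cell]
  dropped <- integer(0)
  for (l in L:0) {
    resid <- as.vector(Cn[, , l + 1])     # C_l bin
    if (l < L) {
      idx <- (l + 1L) + ((l + 1L):L) * (L + 1L)  # rows (n=l, lp>l) of Mtri
      resid <- resid - rowSums(Bmat[, (l + 2L):(L + 1L), drop = FALSE] *
                                 t(Mflat[idx, , drop = FALSE]))
    }
    diagm <- Mflat[(l + 1L) + l * (L + 1L), ]
    if (any(abs(diagm) < 1e-14)) {
      dropped <- c(dropped, l)
    } else {
      Bmat[, l + 1L] <- resid / diagm
    }
  }
  if (length(dropped))
    warning(sprintf("singular diagonal at order(s) %s; order dropped",
                    paste(sort(dropped), collapse = ", ")))
  B <- lapply(0:L, function(l) matrix(Bmat[, l + 1L], N, N))
  if (any(incomplete)) {
    ls <- extract_bl_lstsq(ccf, kernel)
    for (l in 0:L) B[[l + 1]][incomplete] <- ls$B[[l + 1]][incomplete]
  }
  B <- lapply(B, function(m) (m + Conj(t(m))) / 2)
  new_invariant_set("3D", L, B, "backsub")
}

#' Zero-order invariant from the SAXS profile
#'
#' `B_0(q,q') = 4 pi I_SAXS(q) I_SAXS(q')` in the 3D case (the `4 pi` stems
#' from the orthonormal spherical-harmonic normalization); in 2D the circular
#' mean enters without the factor.
#'
#' @param saxs numeric SAXS profile, or an `fxs_saxs`/`fxs_ccf` carrying one.
#' @param case `"3D"` or `"2D"`.
#' @return `N x N` matrix.
#' @export
b0_from_saxs <- function(saxs, case = c("3D", "2D")) {
  case <- match.arg(case)
  I <- if (is.numeric(saxs)) saxs else if (inherits(saxs, "fxs_saxs")) saxs$I
       else saxs$saxs
  (if (case == "3D") 4 * pi else 1) * outer(I, I)
}

#' Rescale invariants extracted from multi-particle data
#'
#' In the dilute limit the order-zero invariant scales with `N_p^2` (the
#' SAXS profile is proportional to `N_p`) and all higher orders with `N_p`.
#'
#' @param inv `fxs_invariants`.
#' @param N_p particles per snapshot used in the acquisition (>= 1).
#' @return rescaled `fxs_invariants` (eigendecomposition dropped).
#' @export
normalize_multiparticle <- function(inv, N_p) {
  if (N_p < 1) stop("N_p must be >= 1")
  inv$B[[1]] <- inv$B[[1]] / N_p^2
  if (inv$L_max >= 1)
    for (l in 1:inv$L_max) inv$B[[l + 1]] <- inv$B[[l + 1]] / N_p
  inv$eigen <- NULL
  inv$N_p <- 1L
  inv
}

#' Eigendecompose invariants for the phasing constraint
#'
#' Per order, keeps the top `N_l = min(2l+1, N)` eigenpairs (`N_1 = 1` per
#' order in 2D), clips negative eigenvalues to zero and stores the factor
#' `R_l = V_l Lambda_l^(1/2)` so that `B_l ~ R_l R_l^+`.
#'
#' @param inv `fxs_invariants` (missing entries treated as zero).
#' @return `inv` with an `eigen` list: per order `values` (kept eigenvalues),
#'   `factor` (`N x N_l`), `clipped_mass` (fraction of squared mass removed).
#' @export
decompose <- function(inv) {
  N <- nrow(inv$B[[1]])
  inv$eigen <- lapply(0:inv$L_max, function(l) {
    Bm <- inv$B[[l + 1]]
    if (is.null(Bm)) return(NULL)     # unconstrained order
    Bm[is.na(Bm)] <- 0
    Nl <- if (inv$case == "3D") min(2L * l + 1L, N) else 1L
    e <- eigen(Bm, symmetric = TRUE)
    vals <- pmax(Re(e$values), 0)
    keep <- seq_len(Nl)
    clipped <- 1 - sum(vals[keep]^2) / max(sum(Re(e$values)^2), .Machine$double.xmin)
    list(values = vals[keep],
         factor = e$vectors[, keep, drop = FALSE] *
           rep(sqrt(vals[keep]), each = N),
         clipped_mass = max(clipped, 0))
  })
  inv
}
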