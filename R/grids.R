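#' Conjugate real- and reciprocal-space radial grids
#'
#' Builds the midpoint-rule radial sampling used throughout the workflow:
#' the reciprocal grid has `N` shells `q_k = (k + 1/2) * Q_max / N` and the
#' real-space grid has `N` shells `r_k = (k + 1/2) * R_max / N` with the
#' Fourier-conjugate band-limit pairing `R_max = pi * N / Q_max`.  All Hankel
#' quadratures and L2 norms in the package use these midpoints with constant
#' step weights.
#'
#' @param N number of radial shells (>= 2).
#' @param Q_max reciprocal-space cutoff (inverse Angstroem).
#' @return A list with elements `real` and `reciprocal`, each a `fxs_radial_grid`
#'   with fields `N`, `step`, `points`, `max_value`, `space`.
#' @export
make_grids <- function(N, Q_max) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop("N must be an integer >= 2")
  if (length(Q_max) != 1L || !is.finite(Q_max) || Q_max <= 0)
    stop("Q_max must be positive")
  N <- as.integer(N)
  R_max <- pi * N / Q_max
  list(
    real       = radial_grid(N, R_max / N, R_max, "real"),
    reciprocal = radial_grid(N, Q_max / N, Q_max, "reciprocal")
  )
}

radial_grid <- function(N, step, max_value, space) {
  structure(list(
    N = as.integer(N), step = step,
    points = (seq_len(N) - 0.5) * step,
    max_value = max_value, space = space
  ), class = "fxs_radial_grid")
}

#' @export
print.fxs_radial_grid <- function(x, ...) {
  cat(sprintf("<radial grid: %s space, N=%d, step=%.6g, max=%.6g>\n",
              x$space, x$N, x$step, x$max_value))
  invisible(x)
}

#' Angular grid for circular (2D) or spherical (3D) harmonic analysis
#'
#' Azimuthal points are uniform, `phi_t = t * 2*pi / N_phi`.  For the 3D case
#' the polar nodes are Gauss--Legendre in `cos(theta)`, which gives exact
#' analysis quadrature for band-limited fields.  `N_phi` is chosen at least
#' `2*L_max + 2` so the maximal harmonic order is resolvable; the default
#' oversampling factor 1.5 keeps the analysis of intensity fields (which are
#' squares of band-limited amplitudes) accurate.
#'
#' @param L_max maximal harmonic order to be resolved.
#' @param case `"2D"` or `"3D"`.
#' @param oversample oversampling factor (>= 1) applied to the minimal sampling.
#' @return `fxs_angular_grid` with `N_phi`, `phi_points` and, in 3D, `N_theta`,
#'   `theta_points`, `ct` (cos theta nodes) and `theta_weights`
#'   (Gauss--Legendre weights in cos theta).
#' @export
angular_grid <- function(L_max, case = c("3D", "2D"), oversample = 1.5) {
  case <- match.arg(case)
  L_max <- as.integer(L_max)
  if (L_max < 0) stop("L_max must be >= 0")
  if (oversample < 1) stop("oversample must be >= 1")
  N_phi <- max(2L * L_max + 2L, 2L * as.integer(ceiling(oversample * L_max)) + 2L)
  g <- list(case = case, L_max = L_max, N_phi = N_phi,
            phi_points = (seq_len(N_phi) - 1L) * 2 * pi / N_phi)
  if (case == "3D") {
    N_theta <- as.integer(ceiling(oversample * L_max)) + 1L
    N_theta <- max(N_theta, L_max + 1L)
    gl <- pracma::gaussLegendre(N_theta, -1, 1)
    ## order nodes so theta increases (cos theta decreases)
    ord <- order(gl$x, decreasing = TRUE)
    g$N_theta <- N_theta
    g$ct <- gl$x[ord]
    g$theta_weights <- gl$w[ord]
    g$theta_points <- acos(g$ct)
  }
  structure(g, class = "fxs_angular_grid")
}

#' @export
print.fxs_angular_grid <- function(x, ...) {
  cat(sprintf("<angular grid: %s, L_max=%d, N_phi=%d%s>\n", x$case, x$L_max,
              x$N_phi,
              if (x$case == "3D") sprintf(", N_theta=%d (Gauss-Legendre)", x$N_theta) else ""))
  invisible(x)
}

#' Ewald-sphere geometry
#'
#' @param wavelength X-ray wavelength in Angstroem.
#' @param flat if `TRUE`, the small-angle (flat Ewald sphere) approximation
#'   `theta(q) = pi/2` is used for all `q`.
#' @return `fxs_ewald` with fields `wavelength`, `kappa` (`2*pi/wavelength`),
#'   `flat`.
#' @export
ewald_geometry <- function(wavelength = 1.23984, flat = FALSE) {
  if (wavelength <= 0) stop("wavelength must be positive")
  structure(list(wavelength = wavelength, kappa = 2 * pi / wavelength,
                 flat = isTRUE(flat)), class = "fxs_ewald")
}

#' Polar angle of the Ewald sphere at momentum transfer q
#'
#' The detector samples reciprocal space on the Ewald sphere, which in
#' spherical coordinates is a q-dependent polar angle.  The convention is the
#' lower hemisphere, `theta(q) = pi/2 + asin(q / (2*kappa))`; only products
#' over pairs `(q, q')` enter the extraction kernels, so the global sign of
#' the half-angle is immaterial (verified by test).
#'
#' @param q momentum transfer (vector allowed), `0 <= q <= 2*kappa`.
#' @param geom an [ewald_geometry()].
#' @return polar angles in radians.
#' @export
ewald_theta <- function(q, geom) {
  if (any(q < 0) || any(q > 2 * geom$kappa + 1e-12))
    stop("q must satisfy 0 <= q <= 2*kappa")
  if (geom$flat) return(rep(pi / 2, length(q)))
  pi / 2 + asin(pmin(1, q / (2 * geom$kappa)))
}

#' @export
print.fxs_ewald <- function(x, ...) {
  cat(sprintf("<Ewald geometry: lambda=%.5g A, kappa=%.5g 1/A%s>\n",
              x$wavelength, x$kappa, if (x$flat) ", flat" else ""))
  invisible(x)
}

## geometry metadata attached to every persisted product
geometry_meta <- function(grids, ang, geom, L_max) {
  list(N = grids$reciprocal$N,
       Q_max = grids$reciprocal$max_value,
       R_max = grids$real$max_value,
       N_phi = ang$N_phi,
       case = ang$case,
       L_max = L_max,
       wavelength = geom$wavelength,
       flat = geom$flat,
       radial_rule = "midpoint",
       harmonic_convention = "orthonormal, Condon-Shortley")
}
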