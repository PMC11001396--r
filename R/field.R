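#' Harmonic-coefficient representation of a real- or reciprocal-space field
#'
#' @param coef 2D case: complex matrix `N x (2*L_max+1)` (columns = signed
#'   circular orders); 3D case: complex array `(N, L_max+1, 2*L_max+1)`.
#' @param grid the radial grid the shells live on.
#' @param space `"real"` or `"reciprocal"`.
#' @param case `"2D"` or `"3D"`.
#' @param L_max maximal harmonic order.
#' @return `fxs_field` object.
#' @export
harmonic_field <- function(coef, grid, space = c("real", "reciprocal"),
                           case = c("3D", "2D"), L_max) {
  space <- match.arg(space); case <- match.arg(case)
  if (case == "3D") {
    stopifnot(length(dim(coef)) == 3L, dim(coef)[2] == L_max + 1L,
              dim(coef)[3] == 2L * L_max + 1L)
  } else {
    stopifnot(length(dim(coef)) == 2L, ncol(coef) == 2L * L_max + 1L)
  }
  stopifnot(dim(coef)[1] == grid$N)
  structure(list(coef = coef, grid = grid, space = space, case = case,
                 L_max = L_max), class = "fxs_field")
}

#' @export
print.fxs_field <- function(x, ...) {
  cat(sprintf("<harmonic field: %s %s space, N=%d shells, L_max=%d>\n",
              x$case, x$space, x$grid$N, x$L_max))
  invisible(x)
}

## synthesize field values on the angular grid: (N, N_theta, N_phi) or (N, N_phi)
field_values <- function(field, ang) {
  if (field$case == "3D") {
    sph_synthesis_stack(field$coef, ang, field$L_max)
  } else {
    t(stats::mvfft(t(circ_coef_bins(field$coef, ang$N_phi)), inverse = TRUE))
  }
}

## analyze grid values back into a coefficient stack
field_analyze <- function(values, ang, L_max, case = c("3D", "2D")) {
  case <- match.arg(case)
  if (case == "3D") {
    sph_analysis_stack(values, ang, L_max)
  } else {
    circ_coef_signed(circular_transform(values, "forward"), L_max)
  }
}

## quadrature weights of the polar/spherical L2 norm on the angular x radial grid
l2_weights <- function(grid, ang) {
  if (ang$case == "3D") {
    w <- outer(grid$points^2 * grid$step, ang$theta_weights)
    array(rep(w, times = ang$N_phi) * (2 * pi / ang$N_phi),
          dim = c(grid$N, ang$N_theta, ang$N_phi))
  } else {
    matrix(grid$points * grid$step * (2 * pi / ang$N_phi),
           nrow = grid$N, ncol = ang$N_phi)
  }
}

## weighted L2 norm of grid values
wnorm <- function(x, w) sqrt(sum(w * (Re(x)^2 + Im(x)^2)))
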