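## Analytic sphere-cluster phantoms.  All lengths are in nanometres; the
## reciprocal grids are in inverse nanometres.

#' Sphere-cluster phantom
#'
#' @param centers numeric matrix `n x 3` of sphere centers (nm).
#' @param radii sphere radii (nm).
#' @param densities electron densities (arbitrary units, > 0).
#' @return `fxs_model` with fields `centers`, `radii`, `densities`,
#'   `bounding_diameter`.
#' @export
sphere_cluster <- function(centers, radii, densities) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  radii <- rep_len(radii, n); densities <- rep_len(densities, n)
  if (any(radii <= 0) || any(densities <= 0))
    stop("radii and densities must be positive")
  bd <- 2 * max(sqrt(rowSums(centers^2)) + radii)
  structure(list(centers = centers, radii = radii, densities = densities,
                 bounding_diameter = bd), class = "fxs_model")
}

#' Pentagonal sphere-cluster phantom (model A)
#'
#' Five spheres of uniform density at the vertices of a regular pentagon in
#' the xy plane (through the origin), with a selectable subset carrying
#' doubled density.  Defaults inscribe the cluster in a bounding diameter of
#' 140 nm: `circumradius + sphere_radius = 70` with
#' `sphere_radius = 0.45 * circumradius`, and one doubled-density sphere.
#'
#' @param circumradius pentagon circumradius (nm).
#' @param sphere_radius radius of each sphere (nm).
#' @param doubled_indices 1-based indices of spheres with density 2 (others 1).
#' @return `fxs_model`.
#' @export
make_pentagonal_cluster <- function(circumradius = 70 / 1.45,
                                    sphere_radius = 0.45 * circumradius,
                                    doubled_indices = 1L) {
  if (circumradius < 0 || sphere_radius <= 0) stop("radii must be positive")
  if (length(doubled_indices) && (min(doubled_indices) < 1 || max(doubled_indices) > 5))
    stop("doubled_indices must be in 1..5")
  a <- 2 * pi * (0:4) / 5
  centers <- cbind(circumradius * cos(a), circumradius * sin(a), 0)
  dens <- rep(1, 5); dens[doubled_indices] <- 2
  side <- 2 * circumradius * sin(pi / 5)
  if (side < 2 * sphere_radius)
    warning("adjacent spheres overlap for this geometry")
  sphere_cluster(centers, sphere_radius, dens)
}

#' @export
print.fxs_model <- function(x, ...) {
  cat(sprintf("<sphere cluster: %d spheres, bounding diameter %.4g nm>\n",
              nrow(x$centers), x$bounding_diameter))
  invisible(x)
}

## 3D density at Cartesian points (n x 3), nm
model_density_xyz <- function(model, pts) {
  out <- numeric(nrow(pts))
  for (s in seq_along(model$radii)) {
    d2 <- (pts[, 1] - model$centers[s, 1])^2 +
          (pts[, 2] - model$centers[s, 2])^2 +
          (pts[, 3] - model$centers[s, 3])^2
    out <- out + model$densities[s] * (d2 < model$radii[s]^2)
  }
  out
}

## 2D projected density (along z) at points (n x 2): chord-length profile
model_density_proj <- function(model, pts) {
  out <- numeric(nrow(pts))
  for (s in seq_along(model$radii)) {
    d2 <- (pts[, 1] - model$centers[s, 1])^2 +
          (pts[, 2] - model$centers[s, 2])^2
    out <- out + 2 * model$densities[s] * sqrt(pmax(0, model$radii[s]^2 - d2))
  }
  out
}

#' Real-space harmonic analysis of a phantom density
#'
#' Evaluates the model density (3D) or its projection along the beam axis
#' (2D) on the polar/spherical sampling grid and analyzes each radial shell
#' into harmonic coefficients.
#'
#' @param model an `fxs_model`, or a function `f(pts)` returning density at
#'   Cartesian points (`n x 3` in the 3D case, `n x 2` in 2D).
#' @param grids conjugate grids from [make_grids()] (real part used; nm).
#' @param ang [angular_grid()] matching `case`.
#' @param L_max maximal harmonic order.
#' @param case `"2D"` or `"3D"`.
#' @return real-space `fxs_field`.
#' @export
density_harmonics <- function(model, grids, ang, L_max = ang$L_max,
                              case = ang$case) {
  g <- grids$real
  if (inherits(model, "fxs_model") && model$bounding_diameter / 2 > g$max_value)
    stop("model support exceeds R_max")
  f <- if (inherits(model, "fxs_model")) {
    if (case == "3D") function(p) model_density_xyz(model, p)
    else function(p) model_density_proj(model, p)
  } else model
  if (case == "3D") {
    st <- sqrt(1 - ang$ct^2)
    dims <- c(g$N, ang$N_theta, ang$N_phi)
    ux <- outer(st, cos(ang$phi_points)); uy <- outer(st, sin(ang$phi_points))
    X <- outer(g$points, ux); Y <- outer(g$points, uy)
    Z <- outer(g$points, outer(ang$ct, rep(1, ang$N_phi)))
    vals <- array(f(cbind(as.vector(X), as.vector(Y), as.vector(Z))), dim = dims)
    harmonic_field(sph_analysis_stack(vals, ang, L_max), g, "real", "3D", L_max)
  } else {
    x <- outer(g$points, cos(ang$phi_points))
    y <- outer(g$points, sin(ang$phi_points))
    vals <- matrix(f(cbind(as.vector(x), as.vector(y))), g$N, ang$N_phi)
    harmonic_field(field_analyze(vals, ang, L_max, "2D"), g, "real", "2D", L_max)
  }
}

#' Single-particle intensity harmonics from a real-space density field
#'
#' Fourier-transforms the density via the midpoint-rule Hankel transform,
#' synthesizes the scattering amplitude on the angular grid, takes the
#' squared modulus and re-analyzes into intensity harmonics up to `L_max`.
#'
#' @param density real-space `fxs_field`.
#' @param grids conjugate grids ([make_grids()]).
#' @param ang angular grid used for the squared-modulus evaluation.
#' @param hw optional precomputed [hankel_weights()].
#' @return reciprocal-space intensity `fxs_field`.
#' @export
intensity_harmonics <- function(density, grids, ang, hw = NULL) {
  if (density$space != "real") stop("density must be a real-space field")
  L <- density$L_max
  if (is.null(hw)) hw <- hankel_weights(grids, L, density$case)
  A <- hankel(density$coef, hw, "forward")
  vals <- field_values(harmonic_field(A, grids$reciprocal, "reciprocal",
                                      density$case, L), ang)
  I <- abs(vals)^2
  harmonic_field(field_analyze(I, ang, L, density$case),
                 grids$reciprocal, "reciprocal", density$case, L)
}

#' Orientation-averaged (SAXS) intensity profile of an intensity field
#'
#' @param intensity reciprocal-space intensity `fxs_field`.
#' @return numeric vector `I_SAXS(q_k)`: the spherical mean
#'   `I_00(q)/sqrt(4*pi)` in 3D, the circular mean `I_0(q)` in 2D.
#' @export
saxs_from_harmonics <- function(intensity) {
  L <- intensity$L_max
  if (intensity$case == "3D") Re(intensity$coef[, 1, L + 1]) / sqrt(4 * pi)
  else Re(intensity$coef[, L + 1])
}
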