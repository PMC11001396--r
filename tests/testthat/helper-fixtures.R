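## Shared fixtures: small grids, phantoms and reference evaluators used
## across the suite.  Everything is generated in code at test time.

fix_grids_small <- function(N = 16, Q = 0.4) make_grids(N, Q)

## direct pointwise spherical-harmonic evaluation (independent of the
## package's synthesis path): coefficient matrix (L+1) x (2L+1)
eval_sph <- function(cf, theta, phi, L) {
  P <- alp_normalized(L, cos(theta))
  s <- 0 + 0i
  for (l in 0:L) for (m in -l:l) {
    pv <- P[l + 1, abs(m) + 1, 1]
    if (m < 0 && abs(m) %% 2 == 1) pv <- -pv
    s <- s + cf[l + 1, m + L + 1] * pv * exp(1i * m * phi)
  }
  s
}

## brute-force voxel rasterization of a sphere-cluster model (oracle)
voxel_mass <- function(model, h = 2) {
  ext <- model$bounding_diameter / 2 + h
  g <- seq(-ext, ext, by = h)
  tot <- 0
  for (z in g) {
    pts <- cbind(rep(g, each = length(g)), rep(g, times = length(g)), z)
    tot <- tot + sum(model_density_xyz(model, pts)) * h^3
  }
  tot
}

## small 3D intensity model shared by several tests (pentagon, N=16, L=6)
pent_intensity_small <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    grids <- make_grids(16, 0.4)
    ang <- angular_grid(6, "3D")
    mod <- make_pentagonal_cluster()
    rho <- density_harmonics(mod, grids, ang, 6)
    I <- intensity_harmonics(rho, grids, ang)
    memo <<- list(grids = grids, ang = ang, model = mod, density = rho,
                  intensity = I)
    memo
  }
})
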