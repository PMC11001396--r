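## direct pointwise intensity evaluation used by the quadrature oracle:
## independent of the package's synthesis and rotation code paths
eval_intensity_at <- function(cf, L, th, ph) Re(eval_sph(cf, th, ph, L))

test_that("2D extraction recovers the Eq.6 form of the invariants", {
  grids <- make_grids(32, 0.8)
  ang <- angular_grid(6, "2D")
  geom <- ewald_geometry(0.124, flat = TRUE)
  mod <- make_pentagonal_cluster()
  I <- intensity_harmonics(density_harmonics(mod, grids, ang, 6, case = "2D"),
                           grids, ang)
  cc <- accumulate_ccf(sample_patterns(I, 100, geom, seed = 4))
  inv <- extract_bn_2d(cc, 6)
  L <- 6
  for (n in seq(0, 6, 2)) {
    v <- I$coef[, n + L + 1]
    expect_lt(max(abs(inv$B[[n + 1]] - outer(v, Conj(v)))),
              1e-8 * max(abs(v))^2)
    expect_true(all(abs(inv$B[[n + 1]] - Conj(t(inv$B[[n + 1]]))) < 1e-12))
  }
  ## isotropic CCF: only B_0 nonzero
  s0 <- intensity_harmonics(
    density_harmonics(sphere_cluster(matrix(0, 1, 3), 30, 1), grids, ang, 6,
                      case = "2D"), grids, ang)
  cc0 <- accumulate_ccf(sample_patterns(s0, 5, geom, seed = 4))
  inv0 <- extract_bn_2d(cc0, 6)
  hi <- max(vapply(1:6, function(n) max(abs(inv0$B[[n + 1]])), numeric(1)))
  expect_lt(hi, 1e-8 * max(abs(inv0$B[[1]])))
  ## noiseless B_n has numerical rank 1
  sv <- svd(inv$B[[3]])$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 1)
})

test_that("masked 2D rows fall back to least squares over valid lags", {
  grids <- make_grids(16, 0.4)
  ang <- angular_grid(4, "2D")
  geom <- ewald_geometry(0.124, flat = TRUE)
  mod <- make_pentagonal_cluster()
  I <- intensity_harmonics(density_harmonics(mod, grids, ang, 4, case = "2D"),
                           grids, ang)
  cc <- accumulate_ccf(sample_patterns(I, 60, geom, N_phi_det = 16, seed = 5))
  ref <- extract_bn_2d(cc, 4)
  ## knock out a few lag samples of one (q,q') row; enough remain to solve
  cc2 <- cc
  cc2$valid[3, 5, 1:2] <- FALSE
  cc2$values[3, 5, 1:2] <- NA
  out <- extract_bn_2d(cc2, 4)
  sc <- max(vapply(ref$B, function(m) max(abs(m)), numeric(1)))
  for (n in 0:4)
    expect_lt(abs(out$B[[n + 1]][3, 5] - ref$B[[n + 1]][3, 5]), 1e-10 * sc)
})

test_that("the Legendre kernel matches an exact SO(3) quadrature oracle", {
  ## oracle: C(q,q',D) = <I(R a) I(R b)>_SO(3) computed by product quadrature
  ## (Gauss-Legendre in beta, trapezoid in alpha and gamma), exact for
  ## band-limited intensity; evaluation is direct pointwise synthesis.
  L <- 4; N <- 6
  grids <- make_grids(N, 0.8)
  geom <- ewald_geometry(1)    # strong curvature regime
  set.seed(6)
  ang <- angular_grid(L, "3D")
  f <- array(rnorm(ang$N_theta * ang$N_phi), dim = c(ang$N_theta, ang$N_phi))
  base <- spherical_transform(f, ang, L)        # one random band-limited shell
  cf <- lapply(seq_len(N), function(k) base * k)  # radial scaling per shell
  Btrue <- lapply(0:L, function(l) {
    Il0 <- base[l + 1, (L + 1 - l):(L + 1 + l)]
    outer(seq_len(N), seq_len(N)) * sum(Il0 * Conj(Il0))
  })
  kern <- build_kernel(grids, geom, L)
  synth <- synthesize_ccf_3d(Btrue, kern)
  ## quadrature over SO(3): n_b Gauss nodes in beta, n_a in alpha/gamma
  th <- ewald_theta(grids$reciprocal$points, geom)
  n_a <- 2 * (2 * L) + 2
  gl <- pracma::gaussLegendre(2 * L + 2, -1, 1)
  alphas <- 2 * pi * (0:(n_a - 1)) / n_a
  pair <- list(c(1, 3), c(2, 2), c(4, 1))
  for (kp in pair) {
    k <- kp[1]; p <- kp[2]
    for (ti in c(1, 3, 6)) {
      D <- kern$delta[ti]
      acc <- 0
      for (ib in seq_along(gl$x)) for (ia in seq_along(alphas)) for (ig in seq_along(alphas)) {
        R <- rot_zyz(c(alphas[ia], acos(gl$x[ib]), alphas[ig]))
        xa <- t(R) %*% c(sin(th[k]), 0, cos(th[k]))
        xb <- t(R) %*% c(sin(th[p]) * cos(D), sin(th[p]) * sin(D), cos(th[p]))
        Ia <- eval_intensity_at(base * k, L, acos(xa[3]), atan2(xa[2], xa[1]))
        Ib <- eval_intensity_at(base * p, L, acos(xb[3]), atan2(xb[2], xb[1]))
        acc <- acc + gl$w[ib] * Ia * Ib
      }
      oracle <- acc / (2 * n_a^2)   # weights: (1/8pi^2) da dcosb dg
      expect_equal(synth[k, p, ti], oracle, tolerance = 1e-6 * abs(oracle))
    }
  }
  ## flat geometry: kernel reduces to Legendre polynomials of cos(Delta)
  kf <- build_kernel(grids, ewald_geometry(1, flat = TRUE), L)
  for (l in 0:L) {
    pl <- vapply(cos(kf$delta), function(x) {
      if (l == 0) return(1); if (l == 1) return(x)
      pm <- 1; pc <- x
      for (j in 2:l) { pn <- ((2 * j - 1) * x * pc - (j - 1) * pm) / j; pm <- pc; pc <- pn }
      pc
    }, numeric(1))
    expect_equal(kf$F[l + 1, 2, 4, ], pl / (4 * pi), tolerance = 1e-12)
  }
  ## triangular structure: coefficients vanish for l < |n|
  for (n in 1:L) for (l in 0:(n - 1))
    expect_lt(max(abs(kern$Mtri[n + 1, l + 1, , ])), 1e-12)
  expect_error(build_kernel(grids, geom, L, N_delta = 2 * L), "N_delta")
})

test_that("back-substitution and pseudo-inverse extraction agree and recover", {
  L <- 8; N <- 16
  grids <- make_grids(N, 0.8)
  geom <- ewald_geometry(3)
  kern <- build_kernel(grids, geom, L)
  set.seed(7)
  B <- lapply(0:L, function(l) { m <- matrix(rnorm(N * N), N); (m + t(m)) / 2 })
  vals <- synthesize_ccf_3d(B, kern)
  cc <- structure(list(values = vals, valid = array(TRUE, dim = dim(vals)),
                       N_phi = kern$N_delta, delta = kern$delta, M = 1,
                       saxs = NULL, grid = grids$reciprocal, case = "3D",
                       geom = geom), class = "fxs_ccf")
  i1 <- extract_bl_lstsq(cc, kern)
  i2 <- extract_bl_backsub(cc, kern)
  for (l in 0:L) {
    expect_lt(max(abs(i1$B[[l + 1]] - B[[l + 1]])), 1e-8)
    expect_lt(max(abs(i2$B[[l + 1]] - i1$B[[l + 1]])), 1e-6)
  }
  ## zero CCF -> zero invariants
  cc0 <- cc; cc0$values[] <- 0
  expect_lt(max(abs(unlist(extract_bl_backsub(cc0, kern)$B))), 1e-14)
  ## masked cells: backsub falls back to least squares over valid lags
  cc3 <- cc
  cc3$valid[2, 3, 1:3] <- cc3$valid[3, 2, c(1, kern$N_delta - 1, kern$N_delta)] <- FALSE
  cc3$values[2, 3, 1:3] <- NA
  i3 <- extract_bl_backsub(cc3, kern)
  for (l in 0:L)
    expect_lt(abs(i3$B[[l + 1]][2, 3] - B[[l + 1]][2, 3]), 1e-6)
})

test_that("back-substitution cost grows more slowly with order than the SVD path", {
  N <- 16
  tb <- tl <- numeric(0)
  for (L in c(8, 16, 32)) {
    grids <- make_grids(N, 0.8)
    kern <- build_kernel(grids, ewald_geometry(0.124), L)
    B <- lapply(0:L, function(l) matrix(1, N, N))
    vals <- synthesize_ccf_3d(B, kern)
    cc <- structure(list(values = vals, valid = array(TRUE, dim = dim(vals)),
                         N_phi = kern$N_delta, delta = kern$delta, M = 1,
                         grid = grids$reciprocal, case = "3D"), class = "fxs_ccf")
    invisible(extract_bl_backsub(cc, kern))   # warm up
    invisible(extract_bl_lstsq(cc, kern))
    tb <- c(tb, system.time(for (i in 1:30) extract_bl_backsub(cc, kern))[3] / 30)
    tl <- c(tl, system.time(for (i in 1:5) extract_bl_lstsq(cc, kern))[3] / 5)
  }
  ## the spectral path is consistently several times faster, and its absolute
  ## advantage widens monotonically as the order grows
  expect_true(all(tl > 2 * tb))
  expect_true(all(diff(tl - tb) > 0))
})

test_that("B_0 from the SAXS profile carries the 4 pi normalization", {
  expect_equal(b0_from_saxs(rep(1, 5), "3D"), matrix(4 * pi, 5, 5),
               tolerance = 1e-12)
  expect_equal(b0_from_saxs(rep(0, 4), "3D"), matrix(0, 4, 4))
  ## agreement with the CCF-extracted order 0 for an isotropic simulation
  grids <- fix_grids_small()
  ang <- angular_grid(4, "3D")
  geom <- ewald_geometry(0.124)
  I0 <- intensity_harmonics(
    density_harmonics(sphere_cluster(matrix(0, 1, 3), 30, 1), grids, ang, 4),
    grids, ang)
  cc <- accumulate_ccf(sample_patterns(I0, 50, geom, seed = 13))
  kern <- build_kernel(grids, geom, 4, cc$N_phi)
  ex <- extract_bl_backsub(cc, kern)
  expect_equal(Re(ex$B[[1]]), b0_from_saxs(cc$saxs, "3D"), tolerance = 1e-6)
})

test_that("multi-particle invariants rescale to the single-particle ones", {
  fix <- pent_intensity_small()
  geom <- ewald_geometry(0.124)
  grids <- fix$grids
  M <- 3000
  kern <- build_kernel(grids, geom, 6, 2 * 6 + 2)
  cc1 <- accumulate_ccf(sample_patterns(fix$intensity, M, geom, seed = 51))
  cc10 <- accumulate_ccf(sample_patterns(fix$intensity, M, geom, N_p = 10, seed = 52))
  i1 <- extract_bl_backsub(cc1, kern)
  i10 <- normalize_multiparticle(extract_bl_backsub(cc10, kern), 10)
  expect_error(normalize_multiparticle(i1, 0), "N_p")
  ## N_p = 1 normalization is the identity
  idn <- normalize_multiparticle(i1, 1)
  expect_equal(idn$B, i1$B, tolerance = 1e-12)
  ## raw l=2 invariant scales ~ N_p at well-sampled cells
  raw10 <- extract_bl_backsub(cc10, kern)
  big <- abs(i1$B[[3]]) > 0.3 * max(abs(i1$B[[3]]))
  ratio <- Re(raw10$B[[3]][big]) / Re(i1$B[[3]][big])
  expect_lt(abs(stats::median(ratio) - 10) / 10, 0.1)
  ## normalized multi-particle invariants match the single-particle truth
  Bgt <- lapply(c(0, 2), function(l) {
    Il <- matrix(fix$intensity$coef[, l + 1, (7 - l):(7 + l)], nrow = grids$reciprocal$N)
    Re(Il %*% Conj(t(Il)))
  })
  for (j in 1:2) {
    l <- c(0, 2)[j]
    sc <- max(abs(Bgt[[j]]))
    expect_lt(stats::median(abs(Re(i10$B[[l + 1]]) - Bgt[[j]])) / sc, 0.05)
  }
})

test_that("eigendecomposition has the contracted rank structure", {
  set.seed(8)
  N <- 24
  ## rank-1 Hermitian: single positive eigenvalue, factor recovers the vector
  v <- complex(real = rnorm(N), imaginary = rnorm(N))
  inv2 <- new_invariant_set("2D", 1, list(outer(v, Conj(v)), outer(v, Conj(v))), "t")
  d2 <- decompose(inv2)
  expect_equal(length(d2$eigen[[1]]$values), 1)
  w <- d2$eigen[[1]]$factor[, 1]
  ph <- sum(Conj(w) * v); ph <- ph / abs(ph)
  expect_lt(max(abs(w * ph - v)), 1e-8 * max(abs(v)))
  ## 3D rank cap N_l = min(2l+1, N)
  Il <- matrix(complex(real = rnorm(N * 5), imaginary = rnorm(N * 5)), N)
  B2 <- Il %*% Conj(t(Il))
  inv3 <- new_invariant_set("3D", 2, list(diag(N), diag(N), B2), "t")
  d3 <- decompose(inv3)
  expect_equal(length(d3$eigen[[3]]$values), 5)
  R <- d3$eigen[[3]]$factor
  expect_lt(max(abs(R %*% Conj(t(R)) - B2)), 1e-10 * max(abs(B2)))
  expect_lt(d3$eigen[[3]]$clipped_mass, 1e-10)
})
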