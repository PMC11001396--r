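test_that("Hankel quadrature reproduces closed forms and round-trips", {
  g <- make_grids(256, 1)
  s <- 40
  r <- g$real$points; q <- g$reciprocal$points
  inner <- q <= 0.5
  ## 3D l=0: Gaussian pair within 1% over the inner half band
  hw3 <- hankel_weights(g, 4, "3D")
  cf <- array(0 + 0i, dim = c(256, 5, 9)); cf[, 1, 5] <- exp(-r^2 / (2 * s^2))
  A <- hankel(cf, hw3, "forward")
  exact <- (2 * pi * s^2)^1.5 * exp(-q^2 * s^2 / 2)
  expect_lt(max(abs(A[inner, 1, 5] - exact[inner])) / max(exact), 0.01)
  ## 2D m=0 Gaussian pair
  hw2 <- hankel_weights(g, 4, "2D")
  cf2 <- matrix(0 + 0i, 256, 9); cf2[, 5] <- exp(-r^2 / (2 * s^2))
  A2 <- hankel(cf2, hw2, "forward")
  ex2 <- 2 * pi * s^2 * exp(-q^2 * s^2 / 2)
  expect_lt(max(abs(A2[inner, 5] - ex2[inner])) / max(ex2), 0.01)
  ## round trips on band-limited profiles occupying the band interior
  ring <- exp(-(r - 200)^2 / (2 * 25^2))
  cf[, 1, 5] <- 0; cf[, 3, 7] <- ring
  back3 <- hankel(hankel(cf, hw3, "forward"), hw3, "inverse")
  expect_lt(max(abs(back3[, 3, 7] - ring)) / max(ring), 1e-3)
  cf2[, 5] <- 0; cf2[, 7] <- ring
  back2 <- hankel(hankel(cf2, hw2, "forward"), hw2, "inverse")
  expect_lt(max(abs(back2[, 7] - ring)) / max(ring), 1e-3)
  ## linearity and order-wise block diagonality
  cfa <- array(0 + 0i, dim = c(256, 5, 9)); cfa[, 2, 5] <- ring
  out <- hankel(cfa, hw3, "forward")
  out[, 2, ] <- 0
  expect_equal(max(abs(out)), 0)
  expect_equal(hankel(2 * cfa, hw3, "forward"),
               2 * hankel(cfa, hw3, "forward"), tolerance = 1e-12)
  expect_error(hankel(matrix(0 + 0i, 8, 9), hw2, "forward"), "mismatch")
})

test_that("value-support projection clamps, zeroes and is idempotent", {
  set.seed(9)
  v <- array(complex(real = rnorm(60), imaginary = rnorm(60)), dim = c(5, 12))
  S <- array(rep(c(TRUE, FALSE), 30), dim = c(5, 12))
  b <- c(0, 1.5, -0.1, 0.1)
  p1 <- project_value_support(v, S, b)
  expect_equal(project_value_support(p1, S, b), p1, tolerance = 1e-15)
  expect_true(all(p1[!S] == 0))
  expect_true(all(Re(p1[S]) >= 0 & Re(p1[S]) <= 1.5))
  expect_true(all(abs(Im(p1[S])) <= 0.1))
  ## real non-negative bounds -> real non-negative supported output
  p2 <- project_value_support(v, S, c(0, Inf, 0, 0))
  expect_true(all(Im(p2) == 0) && all(Re(p2) >= 0))
  ## identity for full support and infinite bounds
  full <- array(TRUE, dim = dim(v))
  expect_equal(project_value_support(v, full, c(-Inf, Inf, -Inf, Inf)), v)
})

test_that("ER and HIO updates follow their defining arithmetic", {
  set.seed(10)
  S <- array(TRUE, dim = c(4, 6))
  b <- c(0, Inf, -Inf, Inf)
  good <- array(complex(real = abs(rnorm(24)), imaginary = 0), dim = c(4, 6))
  ## ER on an admissible density: unchanged; HIO then coincides with ER
  expect_equal(update_er(good, S, b), good, tolerance = 1e-15)
  expect_equal(update_hio(good, good * 0 + 1, S, b, 0.5),
               update_er(good * 0 + 1, S, b), tolerance = 1e-15)
  ## beta = 1, constraint violated everywhere: next = prev_in - out
  bad <- -good                       # negative everywhere
  prev <- array(complex(real = rnorm(24)), dim = c(4, 6))
  expect_equal(update_hio(prev, bad, S, b, 1), prev - bad, tolerance = 1e-15)
})

test_that("shrinkwrap brackets a hard ball and is monotone in the threshold", {
  grids <- make_grids(48, 0.8)
  ctx <- mtip_context(grids, 6, "3D")
  a <- 40
  ball <- array(rep(ctx$r < a, ctx$ang$N_theta * ctx$ang$N_phi),
                dim = c(48, ctx$ang$N_theta, ctx$ang$N_phi)) + 0i
  sig <- 4
  S <- shrinkwrap(ball, sig, 0.11, ctx)
  inside <- array(rep(ctx$r < a - sig, ctx$ang$N_theta * ctx$ang$N_phi), dim = dim(S))
  outside <- array(rep(ctx$r > a + 3 * sig, ctx$ang$N_theta * ctx$ang$N_phi), dim = dim(S))
  expect_true(all(S[inside]))
  expect_true(all(!S[outside]))
  ## superlevel sets shrink as gamma grows
  S2 <- shrinkwrap(ball, sig, 0.5, ctx)
  expect_true(all(S[S2]))
  ## translation equivariance within grid resolution: the support of a
  ## shifted ball is centered at the shifted center of mass
  sh <- density_harmonics(sphere_cluster(matrix(c(30, 0, 0), 1, 3), 35, 1),
                          grids, ctx$ang, 6)
  vals <- ctx$synth(sh$coef)
  Ssh <- shrinkwrap(vals, sig, 0.3, ctx)
  xyz <- grid_xyz(ctx, "real")
  wS <- ctx$w_real * Ssh           # volume-weighted support occupancy
  com_x <- sum(xyz$x * wS) / sum(wS)
  expect_lt(abs(com_x - 30), 2 * grids$real$step)
  expect_lt(abs(sum(xyz$y * wS) / sum(wS)), 2 * grids$real$step)
})

test_that("the 2D correlation projection picks the optimal phase", {
  set.seed(11)
  N <- 20; L <- 3
  q <- (seq_len(N) - 0.5)
  v <- complex(real = rnorm(N), imaginary = rnorm(N))
  B <- lapply(0:L, function(n) outer(v, Conj(v)))
  eig <- decompose(new_invariant_set("2D", L, B, "t"))$eigen
  Icf <- matrix(complex(real = rnorm(N * (2 * L + 1)),
                        imaginary = rnorm(N * (2 * L + 1))), N)
  out <- project_correlation_2d(Icf, eig, q)
  ## fixed point: an admissible input is returned unchanged
  w <- eig[[2]]$factor[, 1]
  adm <- Icf; adm[, 2 + L + 1] <- exp(1i * 0.77) * w; adm[, -2 + L + 1] <- Conj(adm[, 2 + L + 1])
  out_adm <- project_correlation_2d(adm, eig, q)
  expect_lt(max(abs(out_adm[, 2 + L + 1] - adm[, 2 + L + 1])), 1e-10 * max(abs(w)))
  ## invariants of the output equal the targets exactly
  for (n in 0:L) {
    vo <- out[, n + L + 1]
    expect_lt(max(abs(outer(vo, Conj(vo)) - B[[n + 1]])), 1e-10 * max(abs(B[[n + 1]])))
  }
  ## minimality against a dense phase sweep
  dist <- function(u, n) sum(q * abs(u * eig[[n + 1]]$factor[, 1] - Icf[, n + L + 1])^2)
  for (n in 0:L) {
    i0 <- which.max(abs(eig[[n + 1]]$factor[, 1]))
    u_star <- out[i0, n + L + 1] / eig[[n + 1]]$factor[i0, 1]
    sweep_d <- vapply(seq(0, 2 * pi, length.out = 10000),
                      function(a) dist(exp(1i * a), n), numeric(1))
    expect_lte(dist(u_star, n), min(sweep_d) + 1e-9 * abs(min(sweep_d)))
  }
})

test_that("the 3D correlation projection solves the weighted Procrustes problem", {
  set.seed(12)
  N <- 18; l <- 2; L <- 2
  q <- seq_len(N) - 0.5
  Il <- matrix(complex(real = rnorm(N * 5), imaginary = rnorm(N * 5)), N)
  B <- list(diag(N) * 0, diag(N) * 0, Il %*% Conj(t(Il)))
  eig <- decompose(new_invariant_set("3D", L, B, "t"))$eigen
  R <- eig[[3]]$factor
  rand_semiunitary <- function() {
    Z <- matrix(complex(real = rnorm(5 * 5), imaginary = rnorm(5 * 5)), 5)
    qr.Q(qr(Z))[, 1:5]
  }
  Icf <- array(complex(real = rnorm(N * 3 * 5), imaginary = rnorm(N * 3 * 5)),
               dim = c(N, L + 1, 2 * L + 1))
  out <- project_correlation_3d(Icf, eig, q)
  Ol <- matrix(out[, 3, 1:5], N)
  ## semi-unitarity of the implied U: B is reproduced exactly
  expect_lt(max(abs(Ol %*% Conj(t(Ol)) - B[[3]])), 1e-8 * max(abs(B[[3]])))
  ## fixed point for an admissible input
  U0 <- rand_semiunitary()
  adm <- Icf; adm[, 3, 1:5] <- R %*% U0
  out2 <- project_correlation_3d(adm, eig, q)
  expect_lt(max(abs(out2[, 3, 1:5] - adm[, 3, 1:5])), 1e-10 * max(abs(R)))
  ## minimality against random semi-unitary samples
  wdist <- function(X) sum(q^2 * abs(X - matrix(Icf[, 3, 1:5], N))^2)
  dstar <- wdist(Ol)
  for (i in 1:1000) expect_gte(wdist(R %*% rand_semiunitary()), dstar - 1e-8 * dstar)
})

test_that("the intensity projection swaps the modulus and keeps the phase", {
  set.seed(13)
  A <- array(complex(real = rnorm(40), imaginary = rnorm(40)), dim = c(8, 5))
  I <- array(abs(rnorm(40)), dim = c(8, 5))
  out <- project_intensity(A, I)
  expect_equal(abs(out), sqrt(I), tolerance = 1e-12)
  expect_equal(Arg(out)[abs(A) > 0], Arg(A)[abs(A) > 0], tolerance = 1e-12)
  expect_equal(project_intensity(out, I), out, tolerance = 1e-12)
  expect_equal(project_intensity(array(2 + 0i, dim = c(3, 3)),
                                 array(4, dim = c(3, 3))),
               array(2 + 0i, dim = c(3, 3)))
  ## matching modulus: unchanged
  expect_equal(project_intensity(A, abs(A)^2), A, tolerance = 1e-12)
})

test_that("stabilization is an exact fixed point at reciprocal convergence", {
  grids <- make_grids(24, 0.8)
  ctx <- mtip_context(grids, 4, "3D")
  set.seed(14)
  rho <- array(complex(real = rnorm(24 * ctx$ang$N_theta * ctx$ang$N_phi)),
               dim = c(24, ctx$ang$N_theta, ctx$ang$N_phi))
  A <- ctx$synth(hankel(ctx$analyze(rho), ctx$hw, "forward"))
  expect_identical(stabilize(rho, A, A, ctx), rho + 0)
  ## rho = 0, A = 0: output is the inverse transform of A'
  z <- rho * 0
  Ap <- A
  expect_equal(stabilize(z, z, Ap, ctx),
               ctx$synth(hankel(ctx$analyze(Ap), ctx$hw, "inverse")),
               tolerance = 1e-12)
  ## linear in the residual
  d1 <- stabilize(rho, A, A + Ap, ctx) - rho
  d2 <- stabilize(rho, A, A + 2 * Ap, ctx) - rho
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("error metrics vanish on constraint-satisfying states and scale right", {
  grids <- make_grids(16, 0.8)
  ctx <- mtip_context(grids, 2, "3D")
  S <- array(TRUE, dim = c(16, ctx$ang$N_theta, ctx$ang$N_phi))
  good <- array(complex(real = abs(rnorm(prod(dim(S))))), dim = dim(S))
  b <- c(0, Inf, -1, 1)
  expect_equal(error_real(good, S, b, ctx$w_real), 0)
  expect_equal(error_real(3 * good, S, b, ctx$w_real),
               error_real(good, S, b, ctx$w_real))
  Icf <- array(complex(real = rnorm(16 * 3 * 5)), dim = c(16, 3, 5))
  expect_equal(error_reciprocal(Icf, Icf, ctx$qw), 0)
  B <- lapply(0:2, function(l) {
    Il <- matrix(Icf[, l + 1, (3 - l):(3 + l)], 16); Il %*% Conj(t(Il)) })
  expect_lt(error_invariants(Icf, B, ctx$q), 1e-12)
  ## B' = 2B gives exactly 1 (here via I -> sqrt(2) I)
  expect_equal(error_invariants(sqrt(2) * Icf, B, ctx$q), 1, tolerance = 1e-10)
})

test_that("seeded MTIP runs are bitwise reproducible and error-decreasing", {
  fix <- pent_intensity_small()
  N <- 16; L <- 6
  B <- lapply(0:L, function(l) {
    Il <- matrix(fix$intensity$coef[, l + 1, (L + 1 - l):(L + 1 + l)], N)
    Il %*% Conj(t(Il))
  })
  inv <- new_invariant_set("3D", L, B, "exact")
  cfg <- mtip_config("3D", blocks = 1, hio = 10, er = 8, refine_er = 6,
                     sigma_start = 12, sigma_end = 10, support_radius = 80)
  r1 <- run_mtip(inv, fix$grids, cfg, seed = 3)
  r2 <- run_mtip(inv, fix$grids, cfg, seed = 3)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$density, r2$density)
  r3 <- run_mtip(inv, fix$grids, cfg, seed = 4)
  expect_false(identical(r1$traces$E_real, r3$traces$E_real))
  expect_length(r1$traces$E_real, 24)
  expect_true(all(is.finite(r1$traces$E_real)))
  expect_lt(min(r1$traces$E_real), r1$traces$E_real[1])
})
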