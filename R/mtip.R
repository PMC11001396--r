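## Multitiered iterative phase retrieval (MTIP).
##
## The loop alternates real-space constraints (support + value bounds,
## enforced through ER/HIO updates with shrinkwrap support refinement) and
## reciprocal-space constraints (the correlation projection onto the
## eigendecomposed invariants, followed by the intensity projection), with
## all Fourier transforms realized as midpoint-rule Hankel transforms on
## harmonic coefficients and a residual-feedback stabilization that makes a
## fully converged iteration a fixed point.

#' Phasing configuration
#'
#' Defaults follow the reference reconstruction protocol: shrinkwrap
#' threshold `gamma = 0.11`, HIO feedback decreasing exponentially
#' (0.5 to 0.14 in 3D, 0.1 to 0.01 in 2D), non-negative real part and a small
#' symmetric bound on the imaginary part of the density.
#'
#' @param case `"3D"` or `"2D"`.
#' @param blocks number of main-stage blocks.
#' @param hio,er HIO / ER iterations per main block.
#' @param refine_er ER iterations in the refinement stage (preceded by one
#'   shrinkwrap update).
#' @param beta_start,beta_end endpoints of the exponential HIO feedback
#'   schedule `beta(i) = a*exp(b*i) + c` (with `c = beta_end`,
#'   `a = beta_start - beta_end` and `b` set so the term decays to 1% over
#'   the main stage).
#' @param sigma_start,sigma_end shrinkwrap Gaussian width schedule (nm),
#'   linear over the shrinkwrap steps.
#' @param gamma shrinkwrap relative threshold in (0,1).
#' @param support_radius initial spherical support radius (nm); default
#'   `R_max/3`.
#' @param re_bounds bounds on the real part of the density.
#' @param im_rel half-width of the imaginary-part bound, relative to the
#'   maximum absolute real part of the current iterate.
#' @param zero_odd use only even invariant orders as constraints (odd-order
#'   targets set to zero).
#' @param L_rep harmonic order of the loop's density/intensity representation
#'   (`NULL`: same as the invariants).  Orders above the invariant cutoff are
#'   not constrained by the correlation projection; letting the
#'   representation exceed the constraint order gives the real-space
#'   constraints sharper fields to act on.
#' @param gauge_order optional 2D gauge fix: the correlation-projection phase
#'   at this order is rotated to be real-positive each iteration (`NULL`
#'   disables).
#' @param converge_threshold final `E_real` below which a run is classified
#'   as converged.
#' @return `fxs_config` list.
#' @export
mtip_config <- function(case = c("3D", "2D"),
                        blocks = if (case == "3D") 5L else 10L,
                        hio = if (case == "3D") 60L else 500L,
                        er = if (case == "3D") 40L else 200L,
                        refine_er = 200L,
                        beta_start = if (case == "3D") 0.5 else 0.1,
                        beta_end = if (case == "3D") 0.14 else 0.01,
                        sigma_start = 2, sigma_end = 1.5, gamma = 0.11,
                        support_radius = NULL,
                        re_bounds = c(0, Inf), im_rel = 1e-3,
                        zero_odd = TRUE, gauge_order = NULL,
                        L_rep = NULL,
                        converge_threshold = 1e-2) {
  case <- match.arg(case)
  stopifnot(gamma > 0, gamma < 1, sigma_start > 0, sigma_end > 0,
            beta_start > 0, beta_start <= 1, beta_end > 0)
  structure(as.list(environment()), class = "fxs_config")
}

## squared modulus without the sqrt of abs()
mod2 <- function(x) Re(x)^2 + Im(x)^2

## ---- elementary projections -----------------------------------------------

#' Value-and-support projection P_SV
#'
#' Inside the support the real and imaginary parts are clamped to their
#' bounds; outside the support the density is set to zero.  Idempotent.
#'
#' @param vals complex density values on the real-space grid (any shape).
#' @param support logical array of the same shape.
#' @param bounds numeric `c(re_min, re_max, im_min, im_max)`.
#' @return projected values.
#' @export
project_value_support <- function(vals, support, bounds) {
  stopifnot(bounds[1] <= bounds[2], bounds[3] <= bounds[4])
  re <- Re(vals); im <- Im(vals)
  if (bounds[1] > -Inf) re <- pmax(re, bounds[1])
  if (bounds[2] < Inf)  re <- pmin(re, bounds[2])
  if (bounds[3] > -Inf) im <- pmax(im, bounds[3])
  if (bounds[4] < Inf)  im <- pmin(im, bounds[4])
  array(complex(real = re, imaginary = im) * support, dim = dim(vals))
}

#' Error-reduction update
#' @param out_prev output density of the completed iteration.
#' @inheritParams project_value_support
#' @return input density for the next iteration, `P_SV(out_prev)`.
#' @export
update_er <- function(out_prev, support, bounds)
  project_value_support(out_prev, support, bounds)

#' Hybrid input-output update
#'
#' Where the output satisfies the support/value constraint the next input is
#' `P_SV(out)`; elsewhere it is `in - beta * out` (negative feedback).
#'
#' @param in_prev input density of the completed iteration.
#' @param out_prev its output density.
#' @param beta feedback strength in (0, 1].
#' @inheritParams project_value_support
#' @return input density for the next iteration.
#' @details The constraint set is judged on the support and the real-part
#'   bounds; the imaginary-part clamp (a soft regularization) does not by
#'   itself mark a point as violating.
#' @export
update_hio <- function(in_prev, out_prev, support, bounds, beta) {
  psv <- project_value_support(out_prev, support, bounds)
  tol <- 1e-9 * max(abs(out_prev), 1e-300)
  re <- Re(out_prev)
  ok <- support & (re >= bounds[1] - tol) & (re <= bounds[2] + tol)
  out <- in_prev - beta * out_prev
  out[ok] <- psv[ok]
  array(out, dim = dim(out_prev))
}

#' Shrinkwrap support update
#'
#' Threshold of the Gaussian-smoothed density modulus: the support keeps the
#' points where `|rho| convolved with G_sigma` exceeds `gamma` times its
#' maximum.  The convolution is carried out in reciprocal space (Gaussian
#' multiplier on the Hankel-transformed harmonics).
#'
#' @param vals complex density values on the real-space grid.
#' @param sigma Gaussian standard deviation (nm).
#' @param gamma relative threshold in (0,1).
#' @param ctx transform context from [mtip_context()].
#' @param prev previous support (returned, with a warning, if the update
#'   would empty the support).
#' @return logical support array.
#' @export
shrinkwrap <- function(vals, sigma, gamma, ctx, prev = NULL) {
  stopifnot(sigma > 0, gamma > 0, gamma < 1)
  g <- abs(vals)
  cf <- ctx$analyze(g)
  Af <- hankel(cf, ctx$hw, "forward")
  mult <- exp(-ctx$q^2 * sigma^2 / 2)
  Af <- if (ctx$case == "3D") Af * as.vector(mult) else Af * mult
  sm <- Re(ctx$synth(hankel(Af, ctx$hw, "inverse")))
  S <- sm >= gamma * max(sm)
  if (!any(S)) {
    warning("shrinkwrap produced an empty support; keeping previous")
    return(if (is.null(prev)) array(TRUE, dim = dim(vals)) else prev)
  }
  S
}

#' Correlation projection (2D): closest coefficients with the target B_n
#'
#' Per order the projected coefficient vector is `u_n * v_n * sqrt(lambda_n)`
#' with `u_n` the unit phase of the q-weighted inner product between the
#' eigenvector factor and the current coefficients (tie broken to `u_n = 1`).
#'
#' @param Icf current intensity coefficients, `N x (2L+1)` signed orders.
#' @param eig eigen list from [decompose()] (entries may be `NULL` for a
#'   zero target).
#' @param q radial points (weighting).
#' @param gauge_order optional order whose phase factor is rotated to be
#'   real-positive (global rotation applied to all orders).
#' @return projected coefficient matrix.
#' @export
project_correlation_2d <- function(Icf, eig, q, gauge_order = NULL) {
  L <- (ncol(Icf) - 1L) %/% 2L
  out <- matrix(0 + 0i, nrow(Icf), ncol(Icf))
  u <- rep(1 + 0i, L + 1L)
  for (n in 0:L) {
    e <- if (n + 1L <= length(eig)) eig[[n + 1]] else NULL
    if (is.null(e)) {   # unconstrained order: passes through unchanged
      out[, n + L + 1L] <- Icf[, n + L + 1L]
      if (n > 0) out[, -n + L + 1L] <- Icf[, -n + L + 1L]
      next
    }
    w <- e$factor[, 1]
    if (!any(w != 0)) next
    ip <- sum(q * Conj(w) * Icf[, n + L + 1L])
    u[n + 1L] <- if (abs(ip) == 0) 1 + 0i else ip / abs(ip)
    out[, n + L + 1L] <- u[n + 1L] * w
    if (n > 0) out[, -n + L + 1L] <- Conj(out[, n + L + 1L])
  }
  if (!is.null(gauge_order) && gauge_order > 0 && gauge_order <= L) {
    al <- Arg(u[gauge_order + 1L]) / gauge_order
    out <- out * rep(exp(-1i * (-L:L) * al), each = nrow(Icf))
  }
  out
}

#' Correlation projection (3D): semi-unitary Procrustes fit to the target B_l
#'
#' Per order solves the q^2-weighted semi-unitary Procrustes problem via the
#' SVD of `(V_l Lambda_l^(1/2))^+ D^2 I_l` and returns
#' `V_l Lambda_l^(1/2) W1 W2^+`.
#'
#' @param Icf current intensity coefficients, array `(N, L+1, 2L+1)`.
#' @param eig eigen list from [decompose()].
#' @param q radial points.
#' @return projected coefficient array.
#' @export
project_correlation_3d <- function(Icf, eig, q) {
  L <- dim(Icf)[2] - 1L; N <- dim(Icf)[1]
  out <- array(0 + 0i, dim = dim(Icf))
  q2 <- q^2
  for (l in 0:L) {
    cols <- (L + 1L - l):(L + 1L + l)
    e <- if (l + 1L <= length(eig)) eig[[l + 1]] else NULL
    if (is.null(e)) {   # unconstrained order: passes through unchanged
      out[, l + 1L, cols] <- Icf[, l + 1L, cols]
      next
    }
    R <- e$factor
    if (!any(R != 0)) next
    Il <- matrix(Icf[, l + 1L, cols], nrow = N)
    M <- Conj(t(R)) %*% (q2 * Il)
    sv <- svd(M)
    U <- sv$u %*% Conj(t(sv$v))
    out[, l + 1L, cols] <- R %*% U
  }
  out
}

#' Intensity projection P_I
#'
#' Sets the amplitude modulus to the square root of the projected intensity
#' while preserving the phase (zero-amplitude points get phase 0).
#'
#' @param A complex amplitudes on the reciprocal grid.
#' @param I projected intensity values (negative values clamped to zero).
#' @return amplitudes with `|A'| = sqrt(max(I,0))`.
#' @export
project_intensity <- function(A, I) {
  m <- sqrt(pmax(Re(I), 0))
  am <- abs(A)
  zero <- am == 0
  am[zero] <- 1
  ph <- A / am
  ph[zero] <- 1 + 0i
  array(m * ph, dim = dim(A))
}

#' Fourier-transform stabilization
#'
#' `rho' = rho + FT^-1[A' - A]`: feeds back only the reciprocal-space
#' residual, so a converged iteration (`A' = A`) leaves the density exactly
#' unchanged despite the approximate discrete transforms.
#'
#' @param rho input density values (real-space grid).
#' @param A pre-projection amplitudes (reciprocal grid values).
#' @param A_proj post-projection amplitudes.
#' @param ctx transform context from [mtip_context()].
#' @return stabilized output density values.
#' @export
stabilize <- function(rho, A, A_proj, ctx) {
  dcf <- ctx$analyze(A_proj - A)
  rho + ctx$synth(hankel(dcf, ctx$hw, "inverse"))
}

## ---- error metrics ---------------------------------------------------------

#' Real-space error metric
#' @param rho_out output density values; @param support,bounds constraint;
#' @param w quadrature weights of the real-space L2 norm.
#' @return `||P_SV(rho) - rho|| / ||rho||` (0 when both vanish).
#' @export
error_real <- function(rho_out, support, bounds, w) {
  num <- wnorm(project_value_support(rho_out, support, bounds) - rho_out, w)
  den <- wnorm(rho_out, w)
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

#' Reciprocal-space error metric from harmonic coefficients
#'
#' Uses the Parseval identity of the orthonormal angular bases: the L2 norm
#' over a shell is the coefficient norm, radially weighted by `q dq` (2D) or
#' `q^2 dq` (3D).
#'
#' @param Icf,Icf_proj intensity coefficients before/after the correlation
#'   projection.
#' @param qw radial quadrature weights per shell.
#' @param case `"3D"` or `"2D"`.
#' @return `||P_C(I) - I|| / ||I||`.
#' @export
error_reciprocal <- function(Icf, Icf_proj, qw, case = "3D") {
  f <- if (case == "3D") function(x) sqrt(sum(qw * apply(abs(x)^2, 1, sum)))
       else function(x) sqrt(sum(qw * rowSums(abs(x)^2)))
  num <- f(Icf_proj - Icf); den <- f(Icf)
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

#' Invariant-space error metric
#'
#' Relative L2 difference between the invariants of the current intensity
#' coefficients and the target invariants, aggregated over the constrained
#' orders with `q^2 q'^2` (3D) or `q q'` (2D) weights.
#'
#' @param Icf current intensity coefficients.
#' @param targets list of target matrices per order (`NULL` = unconstrained).
#' @param q radial points; @param case `"3D"` or `"2D"`.
#' @return scalar `||B' - B|| / ||B||`.
#' @export
error_invariants <- function(Icf, targets, q, case = "3D") {
  wq <- if (case == "3D") q^2 else q
  W2 <- outer(wq, wq)
  num <- 0; den <- 0
  L <- length(targets) - 1L
  for (l in 0:L) {
    Bt <- targets[[l + 1]]
    if (is.null(Bt)) next
    Bc <- invariant_from_coef(Icf, l, case)
    num <- num + sum(W2 * abs(Bc - Bt)^2)
    den <- den + sum(W2 * abs(Bt)^2)
  }
  if (den == 0) { if (num == 0) 0 else Inf } else sqrt(num / den)
}

## precomputed weighted targets for the fast in-loop invariant error:
## per order, Bw = diag(sqrt(wq)) B diag(sqrt(wq)) and its squared norm
invariant_error_cache <- function(targets, q, case = "3D") {
  wq <- if (case == "3D") q^2 else q
  sw <- sqrt(wq)
  cache <- lapply(targets, function(Bt) {
    if (is.null(Bt)) return(NULL)
    Bw <- Bt * outer(sw, sw)
    list(Bw = Bw, n2 = sum(mod2(Bw)))
  })
  list(cache = cache, sw = sw, den = sum(vapply(cache, function(e)
    if (is.null(e)) 0 else e$n2, numeric(1))))
}

## || I_l I_l^+ - B ||_W^2 summed over orders via the expansion
## ||G||_F^2 - 2 Re tr(Iw^+ Bw Iw) + ||Bw||_F^2 with Iw = diag(sw) I_l
invariant_error_fast <- function(Icf, ic, case = "3D") {
  num <- 0
  L <- length(ic$cache) - 1L
  for (l in 0:L) {
    e <- ic$cache[[l + 1]]
    if (is.null(e)) next
    if (case == "3D") {
      Lr <- dim(Icf)[2] - 1L
      Iw <- matrix(Icf[, l + 1L, (Lr + 1L - l):(Lr + 1L + l)],
                   nrow = dim(Icf)[1]) * ic$sw
    } else {
      Lr <- (ncol(Icf) - 1L) %/% 2L
      Iw <- matrix(Icf[, l + Lr + 1L], ncol = 1) * ic$sw
    }
    G <- Conj(t(Iw)) %*% Iw
    num <- num + sum(mod2(G)) - 2 * Re(sum(Conj(Iw) * (e$Bw %*% Iw))) + e$n2
  }
  if (ic$den == 0) { if (num <= 0) 0 else Inf } else sqrt(max(num, 0) / ic$den)
}

## B matrix of one order from intensity coefficients
invariant_from_coef <- function(Icf, l, case = "3D") {
  if (case == "3D") {
    L <- dim(Icf)[2] - 1L
    Il <- matrix(Icf[, l + 1L, (L + 1L - l):(L + 1L + l)], nrow = dim(Icf)[1])
    Il %*% Conj(t(Il))
  } else {
    L <- (ncol(Icf) - 1L) %/% 2L
    v <- Icf[, l + L + 1L]
    outer(v, Conj(v))
  }
}

## ---- context and main loop -------------------------------------------------

#' Transform context shared by the MTIP operations
#'
#' Bundles grids, angular quadrature, Hankel weights and analysis/synthesis
#' closures for one case, so the elementary operations stay cheap.
#'
#' @param grids conjugate grids ([make_grids()]).
#' @param L_max maximal harmonic order.
#' @param case `"3D"` or `"2D"`.
#' @return `fxs_mtip_ctx` list.
#' @export
mtip_context <- function(grids, L_max, case = c("3D", "2D")) {
  case <- match.arg(case)
  ang <- angular_grid(L_max, case)
  hw <- hankel_weights(grids, L_max, case)
  r <- grids$real$points; q <- grids$reciprocal$points
  ctx <- list(case = case, L_max = L_max, grids = grids, ang = ang, hw = hw,
              r = r, q = q,
              w_real = l2_weights(grids$real, ang),
              w_recip = l2_weights(grids$reciprocal, ang),
              qw = if (case == "3D") q^2 * grids$reciprocal$step
                   else q * grids$reciprocal$step)
  if (case == "3D") {
    plan <- sph_plan(ang, L_max)
    ctx$analyze <- function(vals) sph_analysis_stack(vals, ang, L_max, plan)
    ctx$synth <- function(cf) sph_synthesis_stack(cf, ang, L_max, plan)
  } else {
    ctx$analyze <- function(vals)
      circ_coef_signed(circular_transform(vals, "forward"), L_max)
    ctx$synth <- function(cf)
      t(stats::mvfft(t(circ_coef_bins(cf, ang$N_phi)), inverse = TRUE))
  }
  structure(ctx, class = "fxs_mtip_ctx")
}

## spherical support of radius r0 on the context grid
initial_support <- function(ctx, r0) {
  inside <- ctx$r <= r0
  if (ctx$case == "3D")
    array(inside, dim = c(length(ctx$r), ctx$ang$N_theta, ctx$ang$N_phi))
  else
    matrix(inside, length(ctx$r), ctx$ang$N_phi)
}

#' Run one seeded MTIP reconstruction
#'
#' Starting from uniform random noise inside a spherical support, iterates
#' ER/HIO blocks with shrinkwrap support updates (main stage), keeps the
#' density with the lowest real-space error, and polishes it in a refinement
#' stage.  Deterministic for a fixed seed.
#'
#' @param inv `fxs_invariants` (decomposed automatically if needed).
#' @param grids conjugate grids the invariants live on.
#' @param config [mtip_config()].
#' @param seed integer seed for the starting density.
#' @param ctx optional precomputed [mtip_context()] (reused across runs).
#' @return `fxs_recon`: final density (grid values + harmonic coefficients),
#'   intensity coefficients, support, error traces, configuration echo, seed
#'   and convergence flag.
#' @export
run_mtip <- function(inv, grids, config = mtip_config(inv$case), seed = 1L,
                     ctx = NULL) {
  case <- inv$case
  L_inv <- inv$L_max
  L <- if (is.null(config$L_rep)) L_inv else max(config$L_rep, L_inv)
  if (is.null(ctx)) ctx <- mtip_context(grids, L, case)
  if (ctx$L_max != L) stop("ctx does not match config L_rep")
  ## constraint targets: eigen factors, odd orders zeroed on request,
  ## orders above the invariant cutoff unconstrained (NULL)
  N0 <- nrow(inv$B[[1]])
  targets <- vector("list", L + 1L)
  for (l in 0:L_inv) targets[[l + 1]] <- inv$B[[l + 1]]
  if (config$zero_odd && L_inv >= 1)
    for (l in seq(1, L_inv, by = 2)) targets[[l + 1]] <- matrix(0, N0, N0)
  tinv <- new_invariant_set(case, L, targets, inv$method)
  tinv <- decompose(tinv)
  eig <- tinv$eigen
  r0 <- if (is.null(config$support_radius)) grids$real$max_value / 3
        else config$support_radius
  support <- initial_support(ctx, r0)
  set.seed(seed)
  rho_in <- array(complex(real = stats::runif(length(support)), imaginary = 0),
                  dim = dim(support))
  rho_in[!support] <- 0 + 0i
  ## schedules
  n_hio_total <- config$blocks * config$hio
  bsched <- if (n_hio_total > 0) {
    i <- seq_len(n_hio_total) - 1
    (config$beta_start - config$beta_end) *
      exp(log(0.01) * i / max(n_hio_total - 1, 1)) + config$beta_end
  } else numeric(0)
  n_sw <- config$blocks + 1L
  ssched <- seq(config$sigma_start, config$sigma_end, length.out = max(n_sw, 2L))
  steps <- c(rep(c(rep("HIO", config$hio), "SW", rep("ER", config$er)),
                 config$blocks),
             "SW", rep("ER", config$refine_er))
  refine_start <- config$blocks * (config$hio + config$er) + 1L
  E_real <- E_recip <- E_B <- numeric(0)
  best <- list(err = Inf, rho = NULL, support = NULL, stage = NA)
  final <- list(err = Inf, rho = NULL, Icf = NULL, support = NULL)
  hio_i <- 0L; sw_i <- 0L; iter <- 0L
  bounds_for <- function(rho) {
    imb <- config$im_rel * max(abs(Re(rho)), 1e-300)
    c(config$re_bounds[1], config$re_bounds[2], -imb, imb)
  }
  ic <- invariant_error_cache(targets, ctx$q, case)
  for (s in steps) {
    if (s == "SW") {
      sw_i <- sw_i + 1L
      sig <- ssched[min(sw_i, length(ssched))]
      if (iter == refine_start - 1L && !is.null(best$rho)) {
        ## refinement begins: restart from the best main-stage density
        rho_in <- best$rho
        support <- shrinkwrap(rho_in, sig, config$gamma, ctx, prev = best$support)
        rho_in <- project_value_support(rho_in, support, bounds_for(rho_in))
      } else {
        support <- shrinkwrap(rho_in, sig, config$gamma, ctx, prev = support)
      }
      next
    }
    iter <- iter + 1L
    rcf <- ctx$analyze(rho_in)
    Acf <- hankel(rcf, ctx$hw, "forward")
    Agrid <- ctx$synth(Acf)
    Igrid <- mod2(Agrid)
    Icf <- ctx$analyze(Igrid)
    Icf_p <- if (case == "3D") project_correlation_3d(Icf, eig, ctx$q)
             else project_correlation_2d(Icf, eig, ctx$q, config$gauge_order)
    e_rec <- error_reciprocal(Icf, Icf_p, ctx$qw, case)
    e_B <- invariant_error_fast(Icf, ic, case)
    Igrid_p <- Re(ctx$synth(Icf_p))
    A2 <- project_intensity(Agrid, Igrid_p)
    rho_out <- stabilize(rho_in, Agrid, A2, ctx)
    bnd <- bounds_for(rho_out)
    psv <- project_value_support(rho_out, support, bnd)
    den <- sqrt(sum(ctx$w_real * mod2(rho_out)))
    num <- sqrt(sum(ctx$w_real * mod2(psv - rho_out)))
    e_real <- if (den == 0) { if (num == 0) 0 else Inf } else num / den
    if (!is.finite(e_real) || is.nan(e_real))
      stop("MTIP diverged (non-finite error metric); trace length ", iter)
    E_real <- c(E_real, e_real); E_recip <- c(E_recip, e_rec); E_B <- c(E_B, e_B)
    in_refine <- iter >= refine_start
    if (!in_refine && e_real < best$err)
      best <- list(err = e_real, rho = rho_out, support = support)
    if (in_refine && e_real <= final$err)
      final <- list(err = e_real, rho = rho_out, Icf = Icf_p, support = support)
    rho_in <- if (s == "ER") psv
              else { hio_i <- hio_i + 1L
                     re <- Re(rho_out)
                     tol <- 1e-9 * max(abs(re), 1e-300)
                     ok <- support & (re >= bnd[1] - tol) & (re <= bnd[2] + tol)
                     nx <- rho_in - bsched[min(hio_i, length(bsched))] * rho_out
                     nx[ok] <- psv[ok]
                     array(nx, dim = dim(rho_out)) }
  }
  if (is.null(final$rho)) final <- list(err = best$err, rho = best$rho,
                                        Icf = NULL, support = best$support)
  dens <- final$rho
  structure(list(
    density = dens,
    density_coef = ctx$analyze(dens),
    intensity_coef = final$Icf,
    support = final$support,
    traces = list(E_real = E_real, E_reciprocal = E_recip, E_B = E_B),
    final_error = final$err,
    converged = is.finite(final$err) && final$err < config$converge_threshold,
    config = config, seed = seed, case = case, L_max = L, L_inv = L_inv,
    grids = grids), class = "fxs_recon")
}

#' @export
print.fxs_recon <- function(x, ...) {
  cat(sprintf("<MTIP reconstruction: %s, seed %d, %d iterations, final E_real=%.3g (%s)>\n",
              x$case, x$seed, length(x$traces$E_real), x$final_error,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
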