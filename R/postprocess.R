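## Selection, centering, rotational alignment, inversion resolution,
## averaging and PRTF resolution estimation of MTIP reconstructions.

## FT of a real-space grid field: reciprocal grid values (via context)
field_ft <- function(vals, ctx) {
  ctx$synth(hankel(ctx$analyze(vals), ctx$hw, "forward"))
}
field_ift <- function(Avals, ctx) {
  ctx$synth(hankel(ctx$analyze(Avals), ctx$hw, "inverse"))
}

## Cartesian coordinates of the real/reciprocal grid points
grid_xyz <- function(ctx, space = c("real", "reciprocal")) {
  space <- match.arg(space)
  r <- if (space == "real") ctx$r else ctx$q
  if (ctx$case == "3D") {
    st <- sqrt(1 - ctx$ang$ct^2)
    ux <- outer(st, cos(ctx$ang$phi_points))
    uy <- outer(st, sin(ctx$ang$phi_points))
    uz <- outer(ctx$ang$ct, rep(1, ctx$ang$N_phi))
    list(x = outer(r, ux), y = outer(r, uy), z = outer(r, uz))
  } else {
    list(x = outer(r, cos(ctx$ang$phi_points)),
         y = outer(r, sin(ctx$ang$phi_points)))
  }
}

#' Center a density at its center of mass
#'
#' Translates the density so the center of mass of its modulus sits at the
#' origin, by applying a linear phase ramp to the scattering amplitudes.
#' Iterates until the residual shift is below a quarter radial step.
#'
#' @param vals complex density values on the real-space grid.
#' @param ctx [mtip_context()].
#' @param max_iter maximal number of phase-ramp applications.
#' @return list `values` (centered density), `shift` (total applied shift).
#' @export
center_density <- function(vals, ctx, max_iter = 5L) {
  w <- ctx$w_real
  xyz <- grid_xyz(ctx, "real")
  qxyz <- grid_xyz(ctx, "reciprocal")
  tot <- numeric(length(xyz))
  for (it in seq_len(max_iter)) {
    g <- abs(vals) * w
    m <- sum(g)
    if (m == 0) stop("zero density cannot be centered")
    com <- vapply(xyz, function(cc) sum(cc * g) / m, numeric(1))
    if (sqrt(sum(com^2)) < 0.25 * ctx$grids$real$step) break
    A <- field_ft(vals, ctx)
    ramp <- qxyz$x * com[1] + qxyz$y * com[2]
    if (ctx$case == "3D") ramp <- ramp + qxyz$z * com[3]
    vals <- field_ift(A * exp(1i * ramp), ctx)
    tot <- tot + com
  }
  list(values = vals, shift = tot)
}

## radial-restriction weights for alignment (r_range in absolute units)
range_shells <- function(ctx, r_range) {
  ctx$r >= r_range[1] & ctx$r <= r_range[2]
}

#' Rotational alignment of a 3D density to a reference
#'
#' Evaluates the SO(3) rotational cross-correlation of the two densities via
#' the Wigner-D coupling of their shell-wise spherical-harmonic coefficients
#' (radially restricted to `r_range`), scans a dense Euler grid, refines the
#' peak locally and applies the optimal rotation.
#'
#' @param vals density to align (real-space grid values).
#' @param ref reference density (same grids), assumed centered.
#' @param ctx [mtip_context()].
#' @param r_range radial window (defaults to `c(0.2, 0.9) * R_max`) used to
#'   exclude the symmetric core and the rim.
#' @return list `values` (rotated density), `report` (class
#'   `fxs_alignment`: rotation, correlation peak, relative distance).
#' @export
align_3d <- function(vals, ref, ctx, r_range = NULL) {
  L <- ctx$L_max
  if (is.null(r_range)) r_range <- c(0.2, 0.9) * ctx$grids$real$max_value
  keep <- range_shells(ctx, r_range)
  cf <- ctx$analyze(vals); cfr <- ctx$analyze(ref)
  wk <- ctx$r^2 * ctx$grids$real$step * keep
  ## T^l_{m m'} = sum_k w_k conj(ref_lm) rho_lm'
  Tl <- lapply(0:L, function(l) {
    cols <- (L + 1 - l):(L + 1 + l)
    A <- matrix(cfr[, l + 1, cols], ncol = 2 * l + 1)  # ref
    B <- matrix(cf[, l + 1, cols], ncol = 2 * l + 1)
    Conj(t(A * wk)) %*% B                               # (m, m')
  })
  aniso <- sum(vapply(seq_len(L), function(l) sum(abs(Tl[[l + 1]])), numeric(1)))
  iso <- sum(abs(Tl[[1]]))
  if (aniso < 1e-9 * max(iso, 1e-300)) {
    warning("reference is spherically symmetric in r_range; identity alignment")
    rep <- alignment_report(c(0, 0, 0), FALSE, Re(Tl[[1]][1, 1]),
                            rel_distance(vals, ref, ctx))
    return(list(values = vals, report = rep))
  }
  tab <- wigner_tables(L)
  nb <- 2L * L + 2L
  beta_g <- pi * (seq_len(nb) - 0.5) / nb
  alg <- 2 * pi * (seq_len(nb) - 1L) / nb
  m <- -L:L
  Ea <- exp(-1i * outer(alg, m))                         # (na, m)
  best <- c(-Inf, 0, 0, 0)
  for (b in seq_along(beta_g)) {
    S <- matrix(0 + 0i, 2 * L + 1, 2 * L + 1)
    for (l in 0:L) {
      d <- wigner_d(l, beta_g[b], tab)
      idx <- (L + 1 - l):(L + 1 + l)
      S[idx, idx] <- S[idx, idx] + d * Tl[[l + 1]]
    }
    Cg <- Re(Ea %*% S %*% t(Ea))                         # (alpha, gamma)
    pk <- arrayInd(which.max(Cg), dim(Cg))
    if (Cg[pk] > best[1]) best <- c(Cg[pk], alg[pk[1]], beta_g[b], alg[pk[2]])
  }
  corr_at <- function(abc) {
    s <- 0
    for (l in 0:L) s <- s + Re(sum(wigner_D(l, abc, tab) * Tl[[l + 1]]))
    s
  }
  opt <- stats::optim(best[2:4], function(p) -corr_at(p), method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10))
  abc <- opt$par
  rot <- ctx$synth(rotate_sph_coeffs(cf, abc, tab))
  rep <- alignment_report(abc, FALSE, corr_at(abc), rel_distance(rot, ref, ctx))
  list(values = rot, report = rep)
}

#' Planar rotational alignment of a 2D density to a reference
#'
#' The rotation angle maximizes the circular cross-correlation of the radial
#' harmonic coefficients (computed densely over the azimuthal grid and
#' refined by golden-section search).
#'
#' @inheritParams align_3d
#' @return list `values`, `report`.
#' @export
align_2d <- function(vals, ref, ctx, r_range = NULL) {
  L <- ctx$L_max
  if (is.null(r_range)) r_range <- c(0, 1) * ctx$grids$real$max_value
  keep <- range_shells(ctx, r_range)
  cf <- ctx$analyze(vals); cfr <- ctx$analyze(ref)
  wk <- ctx$r * ctx$grids$real$step * keep
  Tn <- colSums(Conj(cfr) * cf * wk)                     # per signed order
  if (sum(abs(Tn[-(L + 1)])) < 1e-9 * max(abs(Tn[L + 1]), 1e-300)) {
    warning("reference is rotationally symmetric; identity alignment")
    rep <- alignment_report(0, FALSE, Re(Tn[L + 1]), rel_distance(vals, ref, ctx))
    return(list(values = vals, report = rep))
  }
  corr_at <- function(a) Re(sum(Tn * exp(-1i * (-L:L) * a)))
  agrid <- 2 * pi * (0:(8 * L - 1)) / (8 * L)
  a0 <- agrid[which.max(vapply(agrid, corr_at, numeric(1)))]
  opt <- stats::optimize(function(a) -corr_at(a), c(a0 - pi / (4 * L), a0 + pi / (4 * L)),
                         tol = 1e-10)
  a <- opt$minimum
  rot_cf <- cf * rep(exp(-1i * (-L:L) * a), each = nrow(cf))
  rot <- ctx$synth(rot_cf)
  rep <- alignment_report(a, FALSE, corr_at(a), rel_distance(rot, ref, ctx))
  list(values = rot, report = rep)
}

alignment_report <- function(rotation, inverted, peak, distance) {
  structure(list(rotation = rotation, inverted = inverted,
                 peak = peak, distance = distance), class = "fxs_alignment")
}

#' @export
print.fxs_alignment <- function(x, ...) {
  cat(sprintf("<alignment: rotation (%s)%s, distance %.4g>\n",
              paste(sprintf("%.3f", x$rotation), collapse = ", "),
              if (x$inverted) ", inverted" else "", x$distance))
  invisible(x)
}

## relative L2 distance of two grid fields
rel_distance <- function(a, ref, ctx) {
  wnorm(a - ref, ctx$w_real) / max(wnorm(ref, ctx$w_real), 1e-300)
}

## point inverse of a density (3D: r -> -r; 2D: conjugate reflection phi -> -phi)
invert_density <- function(vals, ctx) {
  cf <- ctx$analyze(vals)
  L <- ctx$L_max
  if (ctx$case == "3D") {
    for (l in 0:L) if (l %% 2 == 1) cf[, l + 1, ] <- -cf[, l + 1, ]
  } else {
    cf <- cf[, rev(seq_len(ncol(cf))), drop = FALSE]  # c_n -> c_{-n}: phi -> -phi
  }
  ctx$synth(cf)
}

#' Resolve the point-inversion ambiguity against a reference
#'
#' Aligns both the density and its point inverse to the reference and keeps
#' the candidate with the smaller relative L2 distance (ties go to the
#' non-inverted candidate).
#'
#' @inheritParams align_3d
#' @return list `values` (chosen aligned candidate), `report`.
#' @export
resolve_inversion <- function(vals, ref, ctx, r_range = NULL) {
  alignfun <- if (ctx$case == "3D") align_3d else align_2d
  a1 <- alignfun(vals, ref, ctx, r_range)
  a2 <- alignfun(invert_density(vals, ctx), ref, ctx, r_range)
  ## ties (within alignment tolerance) resolve to the non-inverted candidate
  if (a2$report$distance < a1$report$distance - 1e-5 * (1 + a1$report$distance)) {
    a2$report$inverted <- TRUE
    a2
  } else a1
}

#' Select, align and average reconstructions
#'
#' Keeps the runs whose final real-space error is below `error_threshold`,
#' centers them, aligns them (rotation + point inversion) to the
#' lowest-error member, optionally drops members farther than
#' `distance_threshold` from the reference, and averages pointwise.
#'
#' @param results list of `fxs_recon` objects on common grids.
#' @param error_threshold inclusion threshold on the final `E_real`.
#' @param distance_threshold optional cut on the aligned relative distance.
#' @param ctx optional [mtip_context()] (rebuilt from the first result
#'   otherwise).
#' @param r_range radial window for the rotational alignment.
#' @return `fxs_average`: mean density, member bookkeeping with alignment
#'   reports, PRTF and resolution estimate (see [compute_prtf()]).
#' @export
select_and_average <- function(results, error_threshold = 1e-2,
                               distance_threshold = NULL, ctx = NULL,
                               r_range = NULL) {
  errs <- vapply(results, function(r) r$final_error, numeric(1))
  keep <- which(errs < error_threshold)
  if (!length(keep)) stop("no reconstruction passes the error threshold")
  if (is.null(ctx))
    ctx <- mtip_context(results[[keep[1]]]$grids, results[[keep[1]]]$L_max,
                        results[[keep[1]]]$case)
  ref_i <- keep[which.min(errs[keep])]
  ref <- center_density(results[[ref_i]]$density, ctx)$values
  members <- list(); reports <- list()
  for (i in keep) {
    cen <- center_density(results[[i]]$density, ctx)$values
    al <- resolve_inversion(cen, ref, ctx, r_range)
    if (!is.null(distance_threshold) && al$report$distance > distance_threshold)
      next
    members[[length(members) + 1L]] <- al$values
    reports[[length(reports) + 1L]] <- al$report
    names(members)[length(members)] <- names(reports)[length(reports)] <-
      sprintf("seed_%d", results[[i]]$seed)
  }
  if (!length(members)) stop("no member passes the distance threshold")
  avg <- Reduce(`+`, members) / length(members)
  prtf <- if (length(members) >= 2) compute_prtf(members, ctx) else NULL
  structure(list(density = avg, members = reports, n_members = length(members),
                 member_densities = members,
                 reference_index = ref_i, prtf = prtf, ctx_case = ctx$case),
            class = "fxs_average")
}

#' @export
print.fxs_average <- function(x, ...) {
  cat(sprintf("<averaged reconstruction: %d members%s>\n", x$n_members,
              if (!is.null(x$prtf))
                sprintf(", PRTF resolution %.4g nm^-1", x$prtf$resolution)
              else ""))
  invisible(x)
}

#' Phase retrieval transfer function of aligned reconstructions
#'
#' `PRTF(q)`: shell average (quadrature-weighted) of the pointwise ratio
#' `|<FT rho_i>| / <|FT rho_i|>` over the aligned members, clipped to
#' `[0, 1]`.  Shells where the mean modulus vanishes are `NA`.
#'
#' @param members list of aligned density grids (>= 2).
#' @param ctx [mtip_context()].
#' @return list `q`, `prtf`, `resolution` (the first crossing of `1/e`,
#'   `Q_max` if none: Fourier-limited resolution).
#' @export
compute_prtf <- function(members, ctx) {
  if (length(members) < 2) stop("need at least two aligned members")
  As <- lapply(members, field_ft, ctx = ctx)
  num <- abs(Reduce(`+`, As) / length(As))
  den <- Reduce(`+`, lapply(As, abs)) / length(As)
  ratio <- ifelse(den > 0, pmin(num / den, 1), NA_real_)
  ## quadrature-weighted shell average
  if (ctx$case == "3D") {
    wang <- rep(ctx$ang$theta_weights, times = ctx$ang$N_phi)
    prtf <- apply(ratio, 1, function(s) {
      v <- as.vector(s); ok <- !is.na(v)
      if (!any(ok)) NA_real_ else sum(v[ok] * wang[ok]) / sum(wang[ok])
    })
  } else {
    prtf <- rowMeans(ratio, na.rm = TRUE)
  }
  below <- which(prtf < exp(-1))
  resolution <- if (length(below)) ctx$q[below[1]] else ctx$grids$reciprocal$max_value
  list(q = ctx$q, prtf = prtf, resolution = resolution)
}
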