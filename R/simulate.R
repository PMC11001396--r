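## Simulation of dilute-ensemble diffraction snapshots.
##
## Each snapshot is the single-particle intensity evaluated on the Ewald
## slice (theta(q_k), phi_j) after a Haar-uniform rotation of its harmonic
## coefficients (Wigner-D action in 3D, a phase factor in 2D), summed over
## N_p independent orientations in the dilute limit (interference omitted).
## Evaluation is by direct harmonic synthesis: exact for band-limited
## intensity, no voxel interpolation.

#' Stream of randomly oriented diffraction snapshots
#'
#' Returns a closure producing batches of snapshots; [sample_patterns()]
#' materializes a full set.  Patterns are reproducible for a fixed seed.
#'
#' @param intensity reciprocal-space intensity `fxs_field` (2D or 3D).
#' @param M total number of snapshots (> 0).
#' @param geom [ewald_geometry()]; the 2D case requires flat geometry.
#' @param N_phi_det number of detector azimuthal samples (defaults to
#'   `2*L_max + 2`, the minimum that resolves the harmonic content).
#' @param N_p particles per shot (dilute sum of independent orientations).
#' @param mask_fn optional `function(n)` returning a binary array
#'   `(n, N, N_phi_det)` of per-snapshot masks (1 = keep).
#' @param poisson_scale if not `NULL`, intensities are replaced by Poisson
#'   counts of mean `intensity * poisson_scale` (off for all noiseless runs).
#' @param clip_negative clip the small negative undershoot that harmonic
#'   truncation of a sharp-edged phantom can produce.  Off by default so the
#'   ensemble statistics of the snapshots match the band-limited harmonic
#'   model exactly.
#' @param seed integer seed for the orientation (and noise) stream.
#' @return `function(n)` yielding `list(intensity, mask, orientations)` with
#'   `intensity` an `(n, N, N_phi_det)` array, or `NULL` when exhausted.
#' @export
pattern_stream <- function(intensity, M, geom, N_phi_det = NULL, N_p = 1L,
                           mask_fn = NULL, poisson_scale = NULL,
                           clip_negative = FALSE, seed = 1L) {
  if (M <= 0) stop("M must be positive")
  if (N_p < 1) stop("N_p must be >= 1")
  L <- intensity$L_max
  if (is.null(N_phi_det)) N_phi_det <- 2L * L + 2L
  if (N_phi_det < 2L * L + 2L) stop("N_phi_det cannot resolve L_max")
  case <- intensity$case
  if (case == "2D" && !geom$flat)
    stop("the 2D case requires flat Ewald geometry")
  q <- intensity$grid$points
  N <- intensity$grid$N
  ct <- cos(ewald_theta(q, geom))
  rngstate <- NULL     # private RNG substream, isolated from the caller's
  left <- as.integer(M)
  if (case == "3D") {
    tab <- wigner_tables(L)
    Ptab <- alp_normalized(L, ct)
    Pm <- lapply(-L:L, function(m) t(alp_signed(Ptab, m, L)))  # N x nl
  }
  function(n) {
    if (left <= 0L) return(NULL)
    n <- min(as.integer(n), left)
    left <<- left - n
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    if (is.null(rngstate)) set.seed(seed)
    else assign(".Random.seed", rngstate, envir = .GlobalEnv)
    on.exit({
      rngstate <<- get(".Random.seed", envir = .GlobalEnv)
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
    out <- array(0, dim = c(n, N, N_phi_det))
    orient <- if (case == "3D") array(NA_real_, dim = c(n, N_p, 3))
              else matrix(NA_real_, n, N_p)
    for (i in seq_len(n)) {
      G <- matrix(0 + 0i, N, N_phi_det)
      if (case == "3D") {
        abc <- sample_so3(N_p)
        orient[i, , ] <- abc
        for (p in seq_len(N_p)) {
          cfr <- rotate_sph_coeffs(intensity$coef, abc[p, ], tab)
          for (m in -L:L) {
            cm <- matrix(cfr[, (abs(m) + 1):(L + 1), m + L + 1L], nrow = N)
            G[, order_bin(m, N_phi_det)] <- G[, order_bin(m, N_phi_det)] +
              rowSums(cm * Pm[[m + L + 1L]])
          }
        }
      } else {
        al <- stats::runif(N_p, 0, 2 * pi)
        orient[i, ] <- al
        for (p in seq_len(N_p)) {
          ph <- exp(-1i * (-L:L) * al[p])
          cs <- intensity$coef * rep(ph, each = N)
          G[, order_bin(-L:L, N_phi_det)] <- G[, order_bin(-L:L, N_phi_det)] + cs
        }
      }
      ring <- Re(t(stats::mvfft(t(G), inverse = TRUE)))
      out[i, , ] <- ring
    }
    if (clip_negative) out[out < 0] <- 0
    if (!is.null(poisson_scale)) {
      cnt <- stats::rpois(length(out), out * poisson_scale)
      out <- array(cnt / poisson_scale, dim = dim(out))
    }
    mask <- if (is.null(mask_fn)) NULL else mask_fn(n)
    list(intensity = out, mask = mask, orientations = orient)
  }
}

#' Materialized set of diffraction snapshots
#'
#' @inheritParams pattern_stream
#' @return `fxs_patterns`: list with `intensity` `(M, N, N_phi)`, optional
#'   `mask`, `orientations`, and geometry fields.
#' @export
sample_patterns <- function(intensity, M, geom, N_phi_det = NULL, N_p = 1L,
                            mask_fn = NULL, poisson_scale = NULL,
                            clip_negative = FALSE, seed = 1L) {
  gen <- pattern_stream(intensity, M, geom, N_phi_det, N_p, mask_fn,
                        poisson_scale, clip_negative, seed)
  b <- gen(M)
  structure(list(intensity = b$intensity, mask = b$mask,
                 orientations = b$orientations,
                 case = intensity$case, grid = intensity$grid,
                 N_phi = dim(b$intensity)[3], geom = geom, N_p = N_p,
                 seed = seed),
            class = "fxs_patterns")
}

#' @export
print.fxs_patterns <- function(x, ...) {
  cat(sprintf("<%d %s diffraction snapshots: N=%d shells x N_phi=%d, N_p=%d%s>\n",
              dim(x$intensity)[1], x$case, dim(x$intensity)[2], x$N_phi, x$N_p,
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

## turn an fxs_patterns into a single-use stream
as_stream <- function(patterns) {
  if (is.function(patterns)) return(patterns)
  stopifnot(inherits(patterns, "fxs_patterns"))
  done <- FALSE
  function(n) {
    if (done) return(NULL)
    done <<- TRUE
    list(intensity = patterns$intensity, mask = patterns$mask)
  }
}
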