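## Mask-aware accumulation of the averaged two-point angular
## cross-correlation function (CCF)
##
##   C_M(q_k, q_p, D_t) = sum_i sum_j W_i(q_k,phi_j) W_i(q_p,phi_j+D_t)
##                                    I_i(q_k,phi_j) I_i(q_p,phi_j+D_t)
##                        / sum_i sum_j W_i(q_k,phi_j) W_i(q_p,phi_j+D_t)
##
## computed per snapshot through angular FFTs of the masked rings (circular
## cross-correlation theorem), accumulated in the cross-spectral domain in a
## single streaming pass (constant memory in M).

#' Accumulate the averaged CCF (and SAXS profile) from a pattern stream
#'
#' @param patterns an `fxs_patterns` set or a stream closure from
#'   [pattern_stream()].
#' @param batch_size number of snapshots pulled from a stream per pass.
#' @param grid,case,geom geometry metadata; taken from an `fxs_patterns`
#'   input automatically, must be supplied when a bare stream is used.
#' @return `fxs_ccf`: list with `values` (N x N x N_delta, `NA` where no mask
#'   overlap exists), `valid` (logical), `pair_counts`, `saxs`
#'   (per-shell mean unmasked intensity, `NA` for fully masked shells), `M`,
#'   `delta` (angular lag grid), `grid`, `N_phi`, `case`.
#' @export
accumulate_ccf <- function(patterns, batch_size = 500L,
                           grid = NULL, case = NULL, geom = NULL) {
  meta <- if (inherits(patterns, "fxs_patterns")) patterns
          else list(grid = grid, case = case, geom = geom, mask = NULL)
  gen <- as_stream(patterns)
  S_I <- NULL; S_W <- NULL
  sum_i <- NULL; sum_w <- NULL
  M <- 0L; N <- NULL; Np <- NULL; had_mask <- FALSE
  repeat {
    b <- gen(batch_size)
    if (is.null(b)) break
    x <- b$intensity
    nb <- dim(x)[1]; N <- dim(x)[2]; Np <- dim(x)[3]
    if (is.null(S_I)) {
      S_I <- array(0 + 0i, dim = c(N, N, Np))
      S_W <- array(0 + 0i, dim = c(N, N, Np))
      sum_i <- numeric(N); sum_w <- numeric(N)
    }
    W <- b$mask
    if (!is.null(W)) { x <- x * W; had_mask <- TRUE }
    ## per-snapshot angular spectra: FFT over the phi dimension
    FX <- aperm(x, c(3, 1, 2)); dim(FX) <- c(Np, nb * N)
    FX <- stats::mvfft(FX); dim(FX) <- c(Np, nb, N)
    if (is.null(W)) {
      for (n in seq_len(Np)) {
        Fn <- t(matrix(FX[n, , ], nrow = nb, ncol = N))  # N x nb
        S_I[, , n] <- S_I[, , n] + Conj(Fn) %*% t(Fn)
      }
      sum_i <- sum_i + rowSums(colSums(x, dims = 1))
      sum_w <- sum_w + nb * Np
    } else {
      FW <- aperm(W, c(3, 1, 2)); dim(FW) <- c(Np, nb * N)
      FW <- stats::mvfft(FW); dim(FW) <- c(Np, nb, N)
      for (n in seq_len(Np)) {
        Fn <- t(matrix(FX[n, , ], nrow = nb, ncol = N))
        Gn <- t(matrix(FW[n, , ], nrow = nb, ncol = N))
        S_I[, , n] <- S_I[, , n] + Conj(Fn) %*% t(Fn)
        S_W[, , n] <- S_W[, , n] + Conj(Gn) %*% t(Gn)
      }
      sum_i <- sum_i + rowSums(colSums(x, dims = 1))
      sum_w <- sum_w + rowSums(colSums(W, dims = 1))
    }
    M <- M + nb
  }
  if (M < 1L) stop("no patterns supplied")
  ## inverse FFT over the spectral index -> angular-lag sums
  num <- spec_to_lag(S_I, N, Np)
  masked <- had_mask
  den <- if (masked) spec_to_lag(S_W, N, Np) else array(M * Np, dim = c(N, N, Np))
  valid <- den > 0.5            # mask products are integer counts
  vals <- num / ifelse(valid, den, NA_real_)
  vals[!valid] <- NA_real_
  ok_shell <- if (masked) sum_w > 0 else rep(TRUE, N)
  saxs <- ifelse(ok_shell, sum_i / sum_w, NA_real_)
  structure(list(values = vals, valid = valid, pair_counts = den, M = M,
                 delta = (seq_len(Np) - 1L) * 2 * pi / Np,
                 saxs = saxs, N_phi = Np,
                 grid = meta$grid, case = meta$case, geom = meta$geom),
            class = "fxs_ccf")
}

## real inverse DFT over the third index, scaled 1/N_phi
spec_to_lag <- function(S, N, Np) {
  dim(S) <- c(N * N, Np)
  out <- Re(t(stats::mvfft(t(S), inverse = TRUE))) / Np
  dim(out) <- c(N, N, Np)
  out
}

#' SAXS profile of a pattern stream
#'
#' Per-shell mean of the unmasked intensities over all snapshots.
#'
#' @inheritParams accumulate_ccf
#' @return `fxs_saxs`: list with `I` (length N, `NA` where a shell is fully
#'   masked) and `M`.
#' @export
saxs_profile <- function(patterns, batch_size = 500L) {
  gen <- as_stream(patterns)
  sum_i <- NULL; sum_w <- NULL; M <- 0L
  repeat {
    b <- gen(batch_size)
    if (is.null(b)) break
    x <- b$intensity
    nb <- dim(x)[1]; N <- dim(x)[2]; Np <- dim(x)[3]
    if (is.null(sum_i)) { sum_i <- numeric(N); sum_w <- numeric(N) }
    if (is.null(b$mask)) {
      sum_i <- sum_i + rowSums(colSums(x, dims = 1))
      sum_w <- sum_w + nb * Np
    } else {
      sum_i <- sum_i + rowSums(colSums(x * b$mask, dims = 1))
      sum_w <- sum_w + rowSums(colSums(b$mask, dims = 1))
    }
    M <- M + nb
  }
  if (M < 1L) stop("no patterns supplied")
  structure(list(I = ifelse(sum_w > 0, sum_i / sum_w, NA_real_), M = M),
            class = "fxs_saxs")
}

#' @export
print.fxs_ccf <- function(x, ...) {
  cat(sprintf("<averaged CCF: N=%d, N_delta=%d, M=%d snapshots, %.3g%% cells undefined>\n",
              dim(x$values)[1], x$N_phi, x$M, 100 * mean(!x$valid)))
  invisible(x)
}
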