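#!/usr/bin/env Rscript
## Full-scale reconstruction study (not part of the routine checks): the
## reference protocol at N = 256 radial shells, 1e5 snapshots and large
## reconstruction ensembles.  This takes many CPU-hours; the desk-scale
## statistics are reproduced by scripts/acceptance.R instead.
##
## Usage: Rscript scripts/full_scale.R [--case 2D|3D] [--runs N] [--seed S]

suppressPackageStartupMessages(library(fxsrec))

args <- commandArgs(trailingOnly = TRUE)
argval <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
case <- argval("--case", "3D")
runs <- as.integer(argval("--runs", if (case == "3D") "113" else "120"))
seed <- as.integer(argval("--seed", "1"))

mod <- make_pentagonal_cluster()
N <- 256L
if (case == "3D") {
  L <- 32L
  grids <- make_grids(N, 3.2)              # Q_max = 3.2 1/nm
  geom <- ewald_geometry(0.124)
  ang <- angular_grid(L, "3D")
  I <- intensity_harmonics(density_harmonics(mod, grids, ang, L), grids, ang)
  gen <- pattern_stream(I, 1e5, geom, seed = seed)
  ccf <- accumulate_ccf(gen, grid = grids$reciprocal, case = "3D", geom = geom)
  kern <- build_kernel(grids, geom, L, ccf$N_phi)
  inv <- extract_bl_backsub(ccf, kern)
  inv$B[[1]] <- b0_from_saxs(ccf$saxs, "3D")
  cfg <- mtip_config("3D", support_radius = 80, sigma_start = 2, sigma_end = 1.5)
} else {
  L <- 64L
  grids <- make_grids(N, 3.2)
  geom <- ewald_geometry(0.124, flat = TRUE)
  ang <- angular_grid(L, "2D")
  I <- intensity_harmonics(density_harmonics(mod, grids, ang, L, case = "2D"),
                           grids, ang)
  gen <- pattern_stream(I, 1e5, geom, seed = seed)
  ccf <- accumulate_ccf(gen, grid = grids$reciprocal, case = "2D", geom = geom)
  inv <- extract_bn_2d(ccf, L)
  inv$B[[1]] <- b0_from_saxs(ccf$saxs, "2D")
  cfg <- mtip_config("2D", support_radius = 80, sigma_start = 2, sigma_end = 1.5)
}
ctx <- mtip_context(grids, L, case)
dir.create("results", showWarnings = FALSE)
errs <- vapply(seq_len(runs), function(i) {
  res <- run_mtip(inv, grids, cfg, seed = seed + i, ctx = ctx)
  fxs_save(res, sprintf("results/full_%s_%03d.rds", case, i))
  message(sprintf("run %d/%d: E_real = %.4g", i, runs, res$final_error))
  res$final_error
}, numeric(1))
cl <- classify_converged(errs)
message(sprintf("%s: %.0f%% of %d runs converged", case, 100 * cl$fraction, runs))
results <- lapply(Sys.glob(sprintf("results/full_%s_*.rds", case)), fxs_load)
avg <- select_and_average(results[cl$converged],
                          error_threshold = Inf, ctx = ctx)
fxs_save(avg, sprintf("results/full_%s_average.rds", case))
if (!is.null(avg$prtf))
  message(sprintf("PRTF resolution estimate: %.4g 1/nm", avg$prtf$resolution))
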