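## Workflow driver: the four pipeline stages behind the command-line
## interface.  Each stage reads a YAML settings list (or file), consumes the
## previous stage's product, writes its own product with the settings echoed,
## and returns the output path.

settings_list <- function(settings) {
  if (is.character(settings)) read_settings(settings) else settings
}

## rebuild geometry objects from a settings block
settings_geometry <- function(s) {
  grids <- make_grids(s$N %||% 64L, s$Q_max %||% 0.8)
  geom <- ewald_geometry(s$wavelength %||% 0.124, isTRUE(s$flat))
  list(grids = grids, geom = geom, L_max = s$L_max %||% 8L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a snapshot set from an analytic phantom (pipeline stage)
#'
#' @param settings YAML file path or settings list: blocks `N`, `Q_max`,
#'   `L_max`, `wavelength`, `flat`, `case`, `M`, `N_p`, `seed`, `phantom`
#'   (`type`, geometry fields), `output`.
#' @return output path, invisibly.
#' @export
cmd_simulate <- function(settings) {
  s <- settings_list(settings)
  g <- settings_geometry(s)
  case <- s$case %||% "3D"
  if (case == "2D") g$geom <- ewald_geometry(g$geom$wavelength, flat = TRUE)
  ang <- angular_grid(g$L_max, case)
  ph <- s$phantom %||% list(type = "pentagonal")
  mod <- switch(ph$type %||% "pentagonal",
    pentagonal = make_pentagonal_cluster(
      circumradius = ph$circumradius %||% (70 / 1.45),
      sphere_radius = ph$sphere_radius %||% (0.45 * (ph$circumradius %||% (70 / 1.45))),
      doubled_indices = ph$doubled_indices %||% 1L),
    sphere = sphere_cluster(matrix(unlist(ph$center %||% c(0, 0, 0)), 1, 3),
                            ph$radius %||% 30, ph$density %||% 1),
    stop("unknown phantom type: ", ph$type))
  rho <- density_harmonics(mod, g$grids, ang, g$L_max, case)
  I <- intensity_harmonics(rho, g$grids, ang)
  pat <- sample_patterns(I, s$M %||% 1000L, g$geom, N_phi_det = s$N_phi_det,
                         N_p = s$N_p %||% 1L, seed = s$seed %||% 1L)
  out <- s$output %||% "patterns.rds"
  fxs_save(pat, out, s)
  invisible(out)
}

#' Accumulate the averaged CCF from a snapshot set (pipeline stage)
#'
#' @param settings settings with `input` (pattern product) and `output`.
#' @return output path, invisibly.
#' @export
cmd_correlate <- function(settings) {
  s <- settings_list(settings)
  if (is.null(s$input) || !file.exists(s$input))
    stop("correlate: input pattern file missing: ", s$input %||% "<unset>")
  pat <- fxs_load(s$input)
  if (!inherits(pat, "fxs_patterns")) stop("correlate: input is not a pattern set")
  ccf <- accumulate_ccf(pat, batch_size = s$batch_size %||% 500L)
  message(sprintf("correlate: M=%d snapshots, %.3g%% masked cells undefined",
                  ccf$M, 100 * mean(!ccf$valid)))
  out <- s$output %||% "ccf.rds"
  fxs_save(ccf, out, s)
  invisible(out)
}

#' Extract rotational invariants from a CCF (pipeline stage)
#'
#' @param settings settings with `input` (CCF product), `method`
#'   (`"backsub"`, `"lstsq"` or `"circular"` for the 2D case), `L_max`,
#'   `b0_from_saxs`, `N_p`, `output`.
#' @return output path, invisibly.
#' @export
cmd_extract <- function(settings) {
  s <- settings_list(settings)
  if (is.null(s$input) || !file.exists(s$input))
    stop("extract: input CCF file missing: ", s$input %||% "<unset>")
  ccf <- fxs_load(s$input)
  if (!inherits(ccf, "fxs_ccf")) stop("extract: input is not a CCF product")
  L <- s$L_max %||% 8L
  case <- ccf$case %||% s$case %||% "3D"
  inv <- if (case == "2D") {
    extract_bn_2d(ccf, L)
  } else {
    grids <- make_grids(ccf$grid$N, ccf$grid$max_value)
    kern <- build_kernel(grids, ccf$geom, L, ccf$N_phi)
    if ((s$method %||% "backsub") == "lstsq") extract_bl_lstsq(ccf, kern)
    else extract_bl_backsub(ccf, kern)
  }
  if (isTRUE(s$b0_from_saxs %||% TRUE) && !is.null(ccf$saxs))
    inv$B[[1]] <- b0_from_saxs(ccf$saxs, case)
  if (!is.null(s$N_p) && s$N_p > 1) inv <- normalize_multiparticle(inv, s$N_p)
  inv <- decompose(inv)
  out <- s$output %||% "invariants.rds"
  fxs_save(inv, out, s)
  invisible(out)
}

#' Run seeded MTIP reconstructions (pipeline stage)
#'
#' Launches `runs` independent reconstructions seeded `seed_base + i` and
#' writes one result file per run (`output` treated as a stem); the runs are
#' independent, so their results do not depend on execution order.
#'
#' @param settings settings with `input` (invariants product), grid fields,
#'   a `phasing` block of [mtip_config()] overrides, `runs`, `seed_base`,
#'   `output`.
#' @return character vector of output paths, invisibly.
#' @export
cmd_reconstruct <- function(settings) {
  s <- settings_list(settings)
  if (is.null(s$input) || !file.exists(s$input))
    stop("reconstruct: input invariants file missing: ", s$input %||% "<unset>")
  inv <- fxs_load(s$input)
  if (!inherits(inv, "fxs_invariants")) stop("reconstruct: input is not an invariant set")
  grids <- make_grids(s$N %||% nrow(inv$B[[1]]), s$Q_max %||% 0.8)
  ph <- s$phasing %||% list()
  cfg <- do.call(mtip_config, c(list(case = inv$case), ph))
  ctx <- mtip_context(grids, if (is.null(cfg$L_rep)) inv$L_max else cfg$L_rep,
                      inv$case)
  runs <- s$runs %||% 1L
  stem <- sub("\\.rds$", "", s$output %||% "recon")
  paths <- character(runs)
  for (i in seq_len(runs)) {
    res <- run_mtip(inv, grids, cfg, seed = (s$seed_base %||% 0L) + i, ctx = ctx)
    paths[i] <- sprintf("%s_%03d.rds", stem, i)
    fxs_save(res, paths[i], s)
    message(sprintf("reconstruct: run %d/%d final E_real=%.4g", i, runs,
                    res$final_error))
  }
  invisible(paths)
}

#' Align and average reconstructions (pipeline stage)
#'
#' @param settings settings with `inputs` (vector of result files or a glob
#'   pattern), `error_threshold`, `distance_threshold`, `output`, optional
#'   `vtk`/`png` export paths.
#' @return output path, invisibly.
#' @export
cmd_average <- function(settings) {
  s <- settings_list(settings)
  files <- s$inputs
  if (length(files) == 1 && grepl("[*?]", files)) files <- Sys.glob(files)
  if (!length(files)) stop("average: no input reconstruction files")
  results <- lapply(files, fxs_load)
  thr <- s$error_threshold %||% 1e-2
  errs <- vapply(results, function(r) r$final_error, numeric(1))
  if (!any(errs < thr))
    stop(sprintf("average: no run passes error threshold %g (min error %g)",
                 thr, min(errs)))
  ctx <- mtip_context(results[[1]]$grids, results[[1]]$L_max, results[[1]]$case)
  avg <- select_and_average(results, error_threshold = thr,
                            distance_threshold = s$distance_threshold,
                            ctx = ctx, r_range = unlist(s$r_range))
  out <- s$output %||% "average.rds"
  fxs_save(avg, out, s)
  if (!is.null(s$vtk)) write_vtk(avg$density, ctx, s$vtk, "average_density")
  if (!is.null(s$png)) plot_density_slice(avg$density, ctx, s$png, "averaged density")
  invisible(out)
}
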