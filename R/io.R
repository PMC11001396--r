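## Persistence and export.
##
## Workflow products (pattern sets, CCFs, invariant sets, reconstructions,
## averages) are stored as RDS containers: a named list with a `schema`
## string, the payload, and a `geometry` block, mirroring the group layout
## documented for each stage.  Settings travel as YAML and are echoed
## verbatim into every product.  Densities can be exported to legacy-ASCII
## VTK structured grids on their native polar/spherical sampling and to PNG
## slice renderings.

#' Save a workflow product
#'
#' @param x object to store (any workflow stage).
#' @param path output file path (`.rds`).
#' @param settings optional settings list echoed into the product.
#' @return `path`, invisibly.
#' @export
fxs_save <- function(x, path, settings = NULL) {
  obj <- list(schema = class(x)[1], payload = x, settings = settings,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a workflow product saved by [fxs_save()]
#' @param path file path.
#' @return the stored object (payload), with the settings echo attached as
#'   attribute `"settings"`.
#' @export
fxs_load <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$schema))
    stop("not a workflow product: ", path)
  out <- obj$payload
  attr(out, "settings") <- obj$settings
  out
}

#' Read a YAML settings document
#' @param path YAML file.
#' @return named list.
#' @export
read_settings <- function(path) yaml::read_yaml(path)

#' Write a YAML settings echo
#' @param settings named list; @param path output file.
#' @return `path`, invisibly.
#' @export
write_settings <- function(settings, path) {
  yaml::write_yaml(settings, path)
  invisible(path)
}

#' Export a density field to a legacy-ASCII VTK structured grid
#'
#' Writes the field on its native polar/spherical sampling (shells x angular
#' points converted to Cartesian coordinates) so reconstructions can be
#' inspected without resampling.
#'
#' @param vals real or complex field values on the grid (modulus is written
#'   for complex input).
#' @param ctx [mtip_context()] describing the sampling.
#' @param path output `.vtk` file.
#' @param name dataset name.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(vals, ctx, path, name = "density") {
  xyz <- grid_xyz(ctx, "real")
  v <- if (is.complex(vals)) abs(vals) else vals
  if (ctx$case == "3D") {
    dims <- c(ctx$ang$N_phi, ctx$ang$N_theta, length(ctx$r))
    ord <- function(a) as.vector(aperm(a, c(3, 2, 1)))
    pts <- cbind(ord(xyz$x), ord(xyz$y), ord(xyz$z))
    vv <- ord(array(v, dim = c(length(ctx$r), ctx$ang$N_theta, ctx$ang$N_phi)))
  } else {
    dims <- c(ctx$ang$N_phi, length(ctx$r), 1L)
    ord <- function(a) as.vector(t(a))
    pts <- cbind(ord(xyz$x), ord(xyz$y), 0)
    vv <- ord(matrix(v, length(ctx$r), ctx$ang$N_phi))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("fxsrec", name), "ASCII",
               "DATASET STRUCTURED_GRID",
               paste("DIMENSIONS", paste(dims, collapse = " ")),
               paste("POINTS", nrow(pts), "float")), con)
  utils::write.table(format(pts, digits = 7), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c(paste("POINT_DATA", nrow(pts)),
               paste("SCALARS", name, "float 1"),
               "LOOKUP_TABLE default"), con)
  writeLines(format(vv, digits = 7), con)
  invisible(path)
}

#' Render a density slice (2D field or equatorial cut of a 3D field) to PNG
#'
#' @param vals field values on the grid.
#' @param ctx [mtip_context()].
#' @param path output `.png`; `NULL` draws on the active device.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_density_slice <- function(vals, ctx, path = NULL, main = "density") {
  v <- if (is.complex(vals)) Re(vals) else vals
  if (ctx$case == "3D") {
    i_eq <- which.min(abs(ctx$ang$ct))      # shell row closest to the equator
    v <- matrix(v[, i_eq, ], length(ctx$r), ctx$ang$N_phi)
  }
  if (!is.null(path)) grDevices::png(path, width = 640, height = 640)
  x <- outer(ctx$r, cos(ctx$ang$phi_points))
  y <- outer(ctx$r, sin(ctx$ang$phi_points))
  keep <- ctx$r <= max(ctx$r)
  graphics::plot(NA, xlim = range(x), ylim = range(y), asp = 1,
                 xlab = "x (nm)", ylab = "y (nm)", main = main)
  pal <- grDevices::hcl.colors(64, "viridis")
  zi <- pmax(1L, pmin(64L, 1L + floor(63 * (v - min(v)) / max(diff(range(v)), 1e-300))))
  graphics::points(as.vector(x), as.vector(y), pch = 15, cex = 0.6,
                   col = pal[as.vector(zi)])
  if (!is.null(path)) { grDevices::dev.off(); return(invisible(path)) }
  invisible(NULL)
}

#' Plot the PRTF curve with the 1/e resolution cutoff
#' @param prtf output of [compute_prtf()].
#' @param path optional PNG path.
#' @return `path`, invisibly.
#' @export
plot_prtf <- function(prtf, path = NULL) {
  if (!is.null(path)) grDevices::png(path, width = 640, height = 480)
  graphics::plot(prtf$q, prtf$prtf, type = "l", ylim = c(0, 1),
                 xlab = "q (1/nm)", ylab = "PRTF", main = "phase retrieval transfer function")
  graphics::abline(h = exp(-1), col = "red", lty = 2)
  if (!is.null(path)) { grDevices::dev.off(); return(invisible(path)) }
  invisible(NULL)
}

#' Classify an ensemble of final error metrics into converged / failed
#'
#' Mirrors the histogram-threshold selection used for reconstruction
#' statistics: runs cluster in log error; if the largest gap between sorted
#' log10 errors exceeds `gap` (half an order of magnitude by default) the
#' threshold is placed in that gap, otherwise the ensemble is a single
#' cluster and every run is classified as converged.
#'
#' @param errors final `E_real` values of an ensemble of runs.
#' @param gap minimal log10 separation that splits the histogram.
#' @return list `converged` (logical), `threshold` (numeric or `NA` when no
#'   split exists), `fraction`.
#' @export
classify_converged <- function(errors, gap = 0.5) {
  stopifnot(length(errors) >= 1, all(is.finite(errors)), all(errors > 0))
  le <- sort(log10(errors))
  if (length(le) == 1L)
    return(list(converged = TRUE, threshold = NA_real_, fraction = 1))
  d <- diff(le)
  i <- which.max(d)
  if (d[i] < gap)
    return(list(converged = rep(TRUE, length(errors)), threshold = NA_real_,
                fraction = 1))
  thr <- 10^((le[i] + le[i + 1]) / 2)
  conv <- errors < thr
  list(converged = conv, threshold = thr, fraction = mean(conv))
}
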