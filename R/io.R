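#' Load a frame sequence (with optional mask) from NIfTI files
#'
#' Reads a time series of 3D volumes, clips negative intensities to zero
#' (densities are non-negative by assumption), and, when a binary mask is
#' supplied, crops every volume to the mask's bounding box and zeroes voxels
#' outside the mask — shrinking the optimization domain the way a brain mask
#' reduces a full field-of-view acquisition.
#'
#' @param paths Character vector of NIfTI frame paths, in temporal order.
#' @param mask_path Optional path of a binary (0/1) mask of the same shape.
#' @param every Keep every `every`-th frame (temporal subsampling; default
#'   1 = all).
#' @return A list with `frames` (list of flat vectors), `grid`
#'   ([grid_spec()]), `affine` (of the first frame, translated to the crop
#'   origin) and `mask` (flat cropped mask or `NULL`).
#' @export
load_frames <- function(paths, mask_path = NULL, every = 1L) {
  if (length(paths) < 1L) stop("no input frames", call. = FALSE)
  paths <- paths[seq(1L, length(paths), by = as.integer(every))]
  vols <- lapply(paths, read_nifti)
  dims <- dim(vols[[1L]])
  if (length(dims) != 3L) stop("frames must be 3D volumes", call. = FALSE)
  for (v in vols)
    if (!identical(dim(v), dims)) stop("frame shape mismatch", call. = FALSE)
  affine <- attr(vols[[1L]], "affine")

  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- read_nifti(mask_path)
    if (!identical(dim(mask), dims))
      stop("mask shape does not match the frames", call. = FALSE)
    mv <- unique(as.numeric(mask))
    if (!all(mv %in% c(0, 1)))
      stop("mask must be binary (0/1)", call. = FALSE)
    if (!any(mask > 0)) stop("mask is empty", call. = FALSE)
    bb <- lapply(1:3, function(a) {
      hit <- apply(mask > 0, a, any)
      range(which(hit))
    })
    crop <- function(v) v[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
                          bb[[3]][1]:bb[[3]][2], drop = FALSE]
    mask <- crop(mask)
    vols <- lapply(vols, function(v) crop(v) * (mask > 0))
    affine[1:3, 4] <- affine[1:3, 4] +
      affine[1:3, 1:3] %*% (vapply(bb, `[`, numeric(1), 1L) - 1)
    dims <- dim(mask)
  }
  grid <- grid_spec(dims[1], dims[2], dims[3])
  frames <- lapply(vols, function(v) pmax(as.numeric(v), 0))
  list(frames = frames, grid = grid, affine = affine,
       mask = if (is.null(mask)) NULL else as.numeric(mask))
}

#' Flatten pathlines to a tidy data frame
#'
#' @param pathlines An `romt_pathlines` object (attributes optional).
#' @return Data frame with columns `line_id, step, x, y, z, speed, peclet`
#'   (`step` 0 at the seed; attribute columns `NA` on the final point and
#'   whenever not attached).
#' @export
pathlines_to_df <- function(pathlines) {
  do.call(rbind, lapply(seq_along(pathlines), function(k) {
    pl <- pathlines[[k]]
    np <- nrow(pl$points)
    pad <- function(x) if (is.null(x)) rep(NA_real_, np) else c(x, NA_real_)
    data.frame(line_id = k, step = seq_len(np) - 1L,
               x = pl$points[, 1], y = pl$points[, 2], z = pl$points[, 3],
               speed = pad(pl$speeds), peclet = pad(pl$peclets))
  }))
}

#' Export pathlines as legacy VTK polydata
#'
#' Writes an ASCII legacy-format VTK file with one polyline per pathline and
#' per-point scalar arrays for any attached attributes, readable by standard
#' 3D viewers.
#'
#' @param pathlines An `romt_pathlines` object.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_polylines <- function(pathlines, path) {
  npts_each <- vapply(pathlines, function(pl) nrow(pl$points), integer(1))
  total <- sum(npts_each)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pathlines with per-point attributes",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", total)), con)
  pts <- do.call(rbind, lapply(pathlines, `[[`, "points"))
  writeLines(apply(pts, 1L, function(r) paste(format(r, trim = TRUE),
                                              collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(pathlines),
                     length(pathlines) + total), con)
  offset <- 0L
  for (k in seq_along(pathlines)) {
    ids <- offset + seq_len(npts_each[k]) - 1L
    writeLines(paste(c(npts_each[k], ids), collapse = " "), con)
    offset <- offset + npts_each[k]
  }
  scalar <- function(name, field) {
    vals <- unlist(lapply(pathlines, function(pl) {
      v <- pl[[field]]
      if (is.null(v)) return(NULL)
      c(v, v[length(v)])   # repeat the last value on the terminal point
    }))
    if (is.null(vals) || length(vals) != total) return(FALSE)
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default",
                 format(vals, trim = TRUE)), con)
    TRUE
  }
  has_any <- !is.null(pathlines[[1]]$speeds) || !is.null(pathlines[[1]]$peclets)
  if (has_any) writeLines(sprintf("POINT_DATA %d", total), con)
  scalar("speed", "speeds")
  scalar("peclet", "peclets")
  invisible(path)
}

#' Write / read a plain-text run configuration
#'
#' Serializes an [romt_config()] (plus any extra scalar fields) as
#' `key = value` lines so that every run's effective configuration can be
#' stored next to its outputs and reloaded exactly.
#'
#' @param cfg An [romt_config()].
#' @param path Destination / source path.
#' @param extra Named list of additional scalar fields to record.
#' @return `write_run_config()`: `path`, invisibly. `read_run_config()`: an
#'   [romt_config()].
#' @export
write_run_config <- function(cfg, path, extra = list()) {
  stopifnot(inherits(cfg, "romt_config"))
  kv <- c(unclass(cfg), extra)
  writeLines(sprintf("%s = %s", names(kv),
                     vapply(kv, function(x) format(x, digits = 17),
                            character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(parts, function(p) trimws(p[1]), character(1))
  vals <- vapply(parts, function(p) trimws(paste(p[-1], collapse = "=")),
                 character(1))
  known <- names(formals(romt_config))
  args <- list()
  for (i in seq_along(keys)) {
    if (!keys[i] %in% known) next
    v <- vals[i]
    args[[keys[i]]] <- if (keys[i] %in% c("precond", "mode")) v
      else as.numeric(v)
  }
  do.call(romt_config, args)
}

#' Save a full run's outputs
#'
#' Writes, per loop, the velocity field (4D NIfTI, 3 components) and the
#' interpolated densities (4D NIfTI, `m + 1` states), plus any speed/Peclet
#' maps (3D NIfTI, empty voxels as 0 with a separate coverage volume),
#' pathlines (VTK polydata and flat CSV), flux vectors (CSV), the cost log
#' (CSV) and the effective config; returns a manifest of everything written.
#'
#' @param results List of [solve_pair()] results.
#' @param grid A [grid_spec()].
#' @param cfg The [romt_config()] used.
#' @param out_dir Output directory (created if missing).
#' @param pathlines Optional `romt_pathlines` with attributes attached.
#' @param maps Optional named list of 3D arrays (e.g. `speed`, `peclet`)
#'   from [rasterize_lines()].
#' @param affine 4 x 4 affine stamped on every output volume.
#' @return Character vector of written file paths (the manifest, also saved
#'   as `manifest.json`), invisibly.
#' @export
save_outputs <- function(results, grid, cfg, out_dir, pathlines = NULL,
                         maps = NULL, affine = diag(4)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  d3 <- c(grid$nx, grid$ny, grid$nz)

  cost_rows <- list()
  for (i in seq_along(results)) {
    res <- results[[i]]
    # volumes ordered component-fastest: (x, y, z) of interval 0, then 1, ...
    p_v <- file.path(out_dir, sprintf("velocity_loop%02d.nii.gz", i))
    write_nifti(array(res$v, dim = c(d3, 3L * cfg$m)), p_v, affine = affine)
    add(p_v)
    p_s <- file.path(out_dir, sprintf("interpolations_loop%02d.nii.gz", i))
    write_nifti(array(res$states, dim = c(d3, ncol(res$states))), p_s,
                affine = affine)
    add(p_s)
    h <- res$cost_history
    h$loop <- i
    cost_rows[[i]] <- h
  }
  p_cost <- file.path(out_dir, "cost_history.csv")
  utils::write.csv(do.call(rbind, cost_rows), p_cost, row.names = FALSE)
  add(p_cost)

  for (nm in names(maps)) {
    m3 <- maps[[nm]]
    p_m <- file.path(out_dir, sprintf("%s_map.nii.gz", nm))
    filled <- m3
    filled[is.na(filled)] <- 0
    write_nifti(filled, p_m, affine = affine)
    add(p_m)
    p_c <- file.path(out_dir, sprintf("%s_map_coverage.nii.gz", nm))
    write_nifti(array(as.numeric(!is.na(m3)), dim = dim(m3)), p_c,
                affine = affine)
    add(p_c)
  }

  if (!is.null(pathlines)) {
    p_vtk <- file.path(out_dir, "pathlines.vtk")
    write_vtk_polylines(pathlines, p_vtk)
    add(p_vtk)
    p_csv <- file.path(out_dir, "pathlines.csv")
    utils::write.csv(pathlines_to_df(pathlines), p_csv, row.names = FALSE)
    add(p_csv)
    p_flux <- file.path(out_dir, "flux_vectors.csv")
    utils::write.csv(flux_vectors(pathlines), p_flux, row.names = FALSE)
    add(p_flux)
  }

  p_cfg <- file.path(out_dir, "config.txt")
  write_run_config(cfg, p_cfg, extra = list(nx = grid$nx, ny = grid$ny,
                                            nz = grid$nz))
  add(p_cfg)
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(basename(written), p_man)
  add(p_man)
  invisible(written)
}
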