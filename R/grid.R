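#' Spatial grid specification
#'
#' Describes the cell-centered uniform 3D grid on which densities and
#' velocities live. Cell centers sit at integer coordinates `1..nx` (and
#' likewise for y, z); voxels are stored in x-fastest (column-major, R native)
#' order, so the flat index of center `(ix, iy, iz)` is
#' `ix + (iy - 1) * nx + (iz - 1) * nx * ny`. Every module in the package uses
#' this single convention.
#'
#' @param nx,ny,nz Positive integer voxel counts per axis.
#' @param ks Scalar spatial quadrature weight (voxel volume scale). It enters
#'   the transport cost as a weight only; the stencils assume unit spacing.
#' @return An object of class `grid_spec` with fields `nx`, `ny`, `nz`, `n`
#'   (total voxel count) and `ks`.
#' @examples
#' g <- grid_spec(50, 50, 50)
#' g$n
#' @export
grid_spec <- function(nx, ny, nz, ks = 1) {
  dims <- c(nx, ny, nz)
  if (any(!is.finite(dims)) || any(dims < 1) || any(dims != round(dims)))
    stop("invalid grid: nx, ny, nz must be positive integers", call. = FALSE)
  if (!is.finite(ks) || ks <= 0)
    stop("invalid grid: ks must be a positive scalar", call. = FALSE)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         n = as.integer(nx) * as.integer(ny) * as.integer(nz), ks = ks),
    class = "grid_spec")
}

#' Temporal grid specification
#'
#' The transport between two observed frames is discretized into `m` equal
#' time intervals of length `kt`, with time steps `t_i = i * kt`, `i = 0..m`.
#'
#' @param m Number of time intervals (>= 1).
#' @param kt Length of each interval (> 0).
#' @return An object of class `time_grid` with fields `m` and `kt`.
#' @export
time_grid <- function(m = 10, kt = 0.4) {
  if (!is.finite(m) || m < 1 || m != round(m))
    stop("m must be a positive integer", call. = FALSE)
  if (!is.finite(kt) || kt <= 0) stop("kt must be positive", call. = FALSE)
  structure(list(m = as.integer(m), kt = kt), class = "time_grid")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d (n = %d), ks = %g\n",
              x$nx, x$ny, x$nz, x$n, x$ks))
  invisible(x)
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> m = %d intervals of kt = %g (horizon %g)\n",
              x$m, x$kt, x$m * x$kt))
  invisible(x)
}

# Cell-center coordinates of every voxel, n x 3, in the shared x-fastest order.
grid_centers <- function(grid) {
  cbind(
    x = rep.int(seq_len(grid$nx), grid$ny * grid$nz),
    y = rep.int(rep(seq_len(grid$ny), each = grid$nx), grid$nz),
    z = rep(seq_len(grid$nz), each = grid$nx * grid$ny))
}

# Flatten (ix, iy, iz) triples to the shared linear index.
grid_flat_index <- function(grid, ix, iy, iz) {
  ix + (iy - 1L) * grid$nx + (iz - 1L) * (grid$nx * grid$ny)
}

as_flat_volume <- function(rho, grid, what = "rho") {
  rho <- as.numeric(rho)
  if (length(rho) != grid$n)
    stop(sprintf("%s has length %d, expected n = %d", what, length(rho), grid$n),
         call. = FALSE)
  rho
}
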