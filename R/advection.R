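#' @name advection
#' @title Particle-in-cell advection
#' @description
#' One transport interval advects mass by a particle-in-cell (PIC) scheme:
#' the parcel at each cell center is displaced by `kt * v` evaluated there and
#' its mass is spread with trilinear weights onto the (up to) 8 surrounding
#' cell centers. Destinations falling outside the domain are clamped to the
#' boundary, so every column of the resulting interpolation matrix `S(v)` sums
#' to 1 and advection conserves total mass exactly. Velocities per interval
#' are flat vectors of length `3n` ordered all-x, then all-y, then all-z, each
#' block in the shared x-fastest voxel order.
NULL

# Shared PIC geometry: displaced positions, containing-cell corners, trilinear
# weights and their one-sided derivatives w.r.t. position. Used by both the
# matrix and the Jacobian so the two stay consistent at weight kinks.
pic_geometry <- function(v_i, grid, time) {
  n <- grid$n
  v_i <- as.numeric(v_i)
  if (length(v_i) != 3L * n)
    stop(sprintf("velocity has length %d, expected 3n = %d", length(v_i), 3L * n),
         call. = FALSE)
  if (anyNA(v_i) || any(!is.finite(v_i)))
    stop("invalid velocity: NaN/Inf entries", call. = FALSE)

  pos <- grid_centers(grid) + time$kt * matrix(v_i, nrow = n, ncol = 3L)
  dims <- c(grid$nx, grid$ny, grid$nz)
  i0 <- matrix(1L, n, 3L)
  frac <- matrix(0, n, 3L)
  free <- matrix(FALSE, n, 3L)   # axis unclamped -> derivative active
  for (a in 1:3) {
    d <- dims[a]
    if (d == 1L) next            # degenerate axis: all weight on the one plane
    p <- pos[, a]
    free[, a] <- p > 1 & p < d   # clamped (flat) positions have zero derivative
    p <- pmin(pmax(p, 1), d)
    lo <- pmin(floor(p), d - 1)
    i0[, a] <- as.integer(lo)
    frac[, a] <- p - lo
  }
  list(i0 = i0, frac = frac, free = free, dims = dims, n = n, kt = time$kt)
}

# Iterate over the 8 trilinear corners, calling fun(dest, w, dw) where dw is
# the n x 3 matrix of dweight/dposition (one-sided at kinks, 0 where clamped).
pic_corners <- function(geo, grid, fun, want_deriv = FALSE) {
  off <- as.matrix(expand.grid(cx = 0:1, cy = 0:1, cz = 0:1))
  for (r in seq_len(nrow(off))) {
    c3 <- off[r, ]
    # skip the upper corner on degenerate axes (weight identically 0 there)
    if (any(c3 == 1 & geo$dims == 1L)) next
    w1 <- matrix(0, geo$n, 3L)
    for (a in 1:3)
      w1[, a] <- if (c3[a] == 0L) 1 - geo$frac[, a] else geo$frac[, a]
    w <- w1[, 1] * w1[, 2] * w1[, 3]
    dest <- grid_flat_index(grid,
                            geo$i0[, 1] + c3[1], geo$i0[, 2] + c3[2],
                            geo$i0[, 3] + c3[3])
    dw <- NULL
    if (want_deriv) {
      sgn <- ifelse(c3 == 0L, -1, 1)
      dw <- cbind(sgn[1] * w1[, 2] * w1[, 3] * geo$free[, 1],
                  sgn[2] * w1[, 1] * w1[, 3] * geo$free[, 2],
                  sgn[3] * w1[, 1] * w1[, 2] * geo$free[, 3])
    }
    fun(dest, w, dw)
  }
  invisible(NULL)
}

#' Build the PIC interpolation matrix for one interval
#'
#' @param v_i Flat per-interval velocity, length `3n` (x-block, y-block,
#'   z-block).
#' @param grid A [grid_spec()].
#' @param time A [time_grid()]; the displacement is `kt * v_i`.
#' @return Sparse n x n matrix `S` with `S[dest, src]` the trilinear weight;
#'   all entries non-negative, every column sums to 1, at most 8 nonzeros per
#'   column. `advect(rho) = S %*% rho`.
#' @seealso [advect()], [build_pic_jacobian()]
#' @export
build_pic_matrix <- function(v_i, grid, time) {
  geo <- pic_geometry(v_i, grid, time)
  n <- geo$n
  src <- seq_len(n)
  ii <- vector("list", 8L); jj <- vector("list", 8L); xx <- vector("list", 8L)
  k <- 0L
  pic_corners(geo, grid, function(dest, w, dw) {
    k <<- k + 1L
    ii[[k]] <<- dest; jj[[k]] <<- src; xx[[k]] <<- w
  })
  Matrix::sparseMatrix(i = unlist(ii[seq_len(k)]), j = unlist(jj[seq_len(k)]),
                       x = unlist(xx[seq_len(k)]), dims = c(n, n))
}

#' Advect a density one interval
#'
#' Applies `S(v_i)` to `rho`: mass moves with the flow and is re-allocated to
#' nearest cell centers. Total mass and non-negativity are preserved.
#'
#' @inheritParams build_pic_matrix
#' @param rho Flat density vector of length `n`.
#' @param S Optional precomputed [build_pic_matrix()] result (cache reuse).
#' @return Flat density vector `S %*% rho`.
#' @export
advect <- function(rho, v_i, grid, time, S = NULL) {
  rho <- as_flat_volume(rho, grid)
  if (is.null(S)) S <- build_pic_matrix(v_i, grid, time)
  as.numeric(S %*% rho)
}

#' Velocity Jacobian of the advected mass
#'
#' Returns the sparse n x 3n matrix `B(rho_j) = d(S(v_j) rho_j) / d v_j` for
#' fixed `rho_j`: the analytic derivative of the trilinear spreading weights
#' with respect to the displaced position, scaled by `kt` and by the source
#' mass. One-sided at weight kinks (cell-face crossings) and zero along
#' clamped axes, matching the forward map's boundary behavior. `B` is linear
#' in `rho_j`.
#'
#' @param rho_j Flat density at the interval start, length `n`.
#' @inheritParams build_pic_matrix
#' @param v_j Flat per-interval velocity, length `3n`.
#' @return Sparse n x 3n matrix with column blocks `[Bx | By | Bz]`.
#' @export
build_pic_jacobian <- function(rho_j, v_j, grid, time) {
  rho_j <- as_flat_volume(rho_j, grid, "rho_j")
  geo <- pic_geometry(v_j, grid, time)
  n <- geo$n
  src <- seq_len(n)
  ii <- list(); jj <- list(); xx <- list()
  k <- 0L
  pic_corners(geo, grid, function(dest, w, dw) {
    for (a in 1:3) {
      val <- geo$kt * rho_j * dw[, a]
      nz <- val != 0
      if (!any(nz)) next
      k <<- k + 1L
      ii[[k]] <<- dest[nz]
      jj[[k]] <<- src[nz] + (a - 1L) * n
      xx[[k]] <<- val[nz]
    }
  }, want_deriv = TRUE)
  if (k == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, 3L * n)))
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, 3L * n))
}
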