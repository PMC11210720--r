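#' One advection-diffusion step
#'
#' Advances a density one time interval by operator splitting: a PIC advection
#' step followed by an implicit-Euler diffusion step,
#' `rho_{i+1} = L^{-1} S(v_i) rho_i`. Both sub-steps conserve total mass and
#' preserve non-negativity.
#'
#' @param rho_i Flat density, length `n`.
#' @param v_i Flat per-interval velocity, length `3n`.
#' @param op A `diffusion_op` (carries the grid, `kt` and the cached
#'   factorization).
#' @param time A [time_grid()] (only `kt` is used, must match `op`).
#' @param S Optional precomputed PIC matrix for `v_i`.
#' @return Flat density, length `n`.
#' @export
advdiff_step <- function(rho_i, v_i, op, time, S = NULL) {
  stopifnot(inherits(op, "diffusion_op"))
  diffuse_implicit(advect(rho_i, v_i, op$grid, time, S = S), op)
}

#' Integrate the forward advection-diffusion model
#'
#' Runs the recursion `rho_k = L^{-1} S(v_{k-1}) ... L^{-1} S(v_0) rho_0` for
#' `k = 1..m`, producing the interpolated densities between the two observed
#' frames.
#'
#' @param rho_0 Flat initial density, length `n`.
#' @param v Velocity field: an `n3 x m` matrix (`n3 = 3n`) whose column `j` is
#'   the flat velocity of interval `j-1`, or a flat vector of length `3 m n`.
#' @param op A `diffusion_op`.
#' @param time A [time_grid()] with `m` matching `ncol(v)`.
#' @param S_list Optional list of `m` precomputed PIC matrices.
#' @return An `n x (m + 1)` matrix of states; column `k + 1` is `rho_k`
#'   (column 1 is `rho_0`).
#' @export
forward_integrate <- function(rho_0, v, op, time, S_list = NULL) {
  grid <- op$grid
  v <- as_velocity_matrix(v, grid, time)
  rho_0 <- as_flat_volume(rho_0, grid, "rho_0")
  m <- time$m
  states <- matrix(0, grid$n, m + 1L)
  states[, 1L] <- rho_0
  for (j in seq_len(m)) {
    S <- if (!is.null(S_list)) S_list[[j]] else NULL
    states[, j + 1L] <- advdiff_step(states[, j], v[, j], op, time, S = S)
  }
  states
}

as_velocity_matrix <- function(v, grid, time) {
  n3 <- 3L * grid$n
  if (is.matrix(v)) {
    if (nrow(v) != n3 || ncol(v) != time$m)
      stop(sprintf("velocity matrix must be %d x %d", n3, time$m), call. = FALSE)
    return(v)
  }
  if (length(v) != n3 * time$m)
    stop(sprintf("velocity vector must have length 3mn = %d", n3 * time$m),
         call. = FALSE)
  matrix(as.numeric(v), n3, time$m)
}

#' Precompute the sensitivity cache for a velocity field
#'
#' Assembles, once per Gauss-Newton iteration, everything the matrix-free
#' Jacobian products need: the forward states `rho_0..rho_m`, the PIC matrices
#' `S(v_j)` and the velocity Jacobians `B(rho_j)` for `j = 0..m-1` (each `B`
#' paired with the density at its interval start), plus the shared diffusion
#' factorization. The cache is tied to the exact `v` it was built from and is
#' checked for staleness by the products.
#'
#' @inheritParams forward_integrate
#' @return An object of class `sensitivity_cache`.
#' @export
sensitivity_cache <- function(rho_0, v, op, time) {
  grid <- op$grid
  v <- as_velocity_matrix(v, grid, time)
  S_list <- lapply(seq_len(time$m), function(j) build_pic_matrix(v[, j], grid, time))
  states <- forward_integrate(rho_0, v, op, time, S_list = S_list)
  B_list <- lapply(seq_len(time$m), function(j)
    build_pic_jacobian(states[, j], v[, j], grid, time))
  structure(list(S = S_list, B = B_list, states = states, op = op,
                 time = time, grid = grid, v = v),
            class = "sensitivity_cache")
}

check_cache <- function(cache, v = NULL) {
  if (!inherits(cache, "sensitivity_cache"))
    stop("cache must be a sensitivity_cache", call. = FALSE)
  if (!is.null(v) && !identical(dim(v), dim(cache$v)))
    stop("stale sensitivity cache: velocity shape changed", call. = FALSE)
  if (!is.null(v) && !isTRUE(all(v == cache$v)))
    stop("stale sensitivity cache: velocity differs from the cached field",
         call. = FALSE)
  invisible(cache)
}

#' Final-state Jacobian product `J_m x`
#'
#' Computes the action of `J_m = d rho_m / d v` on a perturbation `x` of the
#' full velocity field, by the forward accumulation
#' `a <- L^{-1} (S(v_j) a + B(rho_j) x_j)` over intervals `j = 0..m-1`,
#' reusing the cached `S`, `B` and diffusion factor.
#'
#' @param x Flat vector of length `3mn` (interval-major: interval 0's 3n
#'   entries first).
#' @param cache A [sensitivity_cache()].
#' @return Flat vector of length `n`.
#' @export
jac_final_vec <- function(x, cache) {
  check_cache(cache)
  jac_states_vec(x, cache, final_only = TRUE)
}

#' Full Jacobian product `J x` (all interpolated states)
#'
#' As [jac_final_vec()] but returns the stacked perturbations of every
#' interpolation `rho_1..rho_m` (the row blocks `J_1 x, ..., J_m x`).
#'
#' @inheritParams jac_final_vec
#' @return Flat vector of length `m n` (block `k` = perturbation of `rho_k`).
#' @export
jac_full_vec <- function(x, cache) {
  check_cache(cache)
  jac_states_vec(x, cache, final_only = FALSE)
}

jac_states_vec <- function(x, cache, final_only) {
  n <- cache$grid$n
  m <- cache$time$m
  x <- matrix(as.numeric(x), 3L * n, m)
  a <- numeric(n)
  out <- if (final_only) NULL else matrix(0, n, m)
  for (j in seq_len(m)) {
    a <- diffuse_implicit(as.numeric(cache$S[[j]] %*% a + cache$B[[j]] %*% x[, j]),
                          cache$op, nonneg = FALSE)
    if (!final_only) out[, j] <- a
  }
  if (final_only) a else as.numeric(out)
}

#' Transposed Jacobian product `J^T y` (adjoint sweep)
#'
#' Computes `J^T y` for the lower-triangular block Jacobian
#' `J = [J_1; ...; J_m]` by a single backward sweep: with `L` symmetric,
#' `t_k = L^{-1} w_k`, gradient block `j = k-1` receives `B(rho_j)^T t_k`, and
#' `w_{k-1} = S(v_{k-1})^T t_k + y_{k-1}`. This is algebraically identical to
#' recursively expanding the per-block products but touches each cached matrix
#' exactly once.
#'
#' @param y Flat vector of length `m n` (block `k` pairs with `rho_k`); to
#'   apply `J_m^T` alone, pass zeros in blocks `1..m-1`.
#' @param cache A [sensitivity_cache()].
#' @return Flat vector of length `3 m n`.
#' @export
jacT_full_vec <- function(y, cache) {
  check_cache(cache)
  n <- cache$grid$n
  m <- cache$time$m
  y <- matrix(as.numeric(y), n, m)
  out <- matrix(0, 3L * n, m)
  w <- numeric(n)
  for (k in rev(seq_len(m))) {
    w <- w + y[, k]
    t_k <- diffuse_implicit(w, cache$op, nonneg = FALSE)
    out[, k] <- as.numeric(Matrix::crossprod(cache$B[[k]], t_k))
    w <- as.numeric(Matrix::crossprod(cache$S[[k]], t_k))
  }
  as.numeric(out)
}

#' Final-state transposed product `J_m^T z`
#'
#' Convenience wrapper around [jacT_full_vec()] with `z` placed in the last
#' block.
#'
#' @param z Flat vector of length `n`.
#' @param cache A [sensitivity_cache()].
#' @return Flat vector of length `3 m n`.
#' @export
jacT_final_vec <- function(z, cache) {
  n <- cache$grid$n
  m <- cache$time$m
  y <- matrix(0, n, m)
  y[, m] <- as.numeric(z)
  jacT_full_vec(y, cache)
}
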