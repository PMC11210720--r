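# Shared fixture builders: everything is generated in code at test time.

# Separable Gaussian blob on a grid, as a flat non-negative density.
gauss_blob <- function(grid, center, width = 2) {
  e <- function(k, c0) exp(-(seq_len(k) - c0)^2 / (2 * width^2))
  as.numeric(e(grid$nx, center[1]) %o% e(grid$ny, center[2]) %o%
               e(grid$nz, center[3]))
}

# A small randomized problem instance with displacements bounded away from
# cell-face crossings (trilinear weights are smooth there).
rand_instance <- function(nx = 6, ny = 6, nz = 6, m = 3, sigma = 0.002,
                          kt = 0.4, seed = 1) {
  set.seed(seed)
  g <- grid_spec(nx, ny, nz)
  tm <- time_grid(m, kt)
  op <- build_diffusion_operator(g, tm, sigma)
  list(g = g, tm = tm, op = op,
       rho0 = runif(g$n, 0.1, 1),
       rho1 = runif(g$n, 0.1, 1),
       v = matrix(runif(3 * g$n * m, 0.05, 0.2), 3 * g$n, m))
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300)

# Dense assembly of the final-state Jacobian from its block-product
# definition (independent of the matrix-free recursion path).
dense_jac_final <- function(cache) {
  m <- cache$time$m
  n <- cache$grid$n
  Ld <- as.matrix(cache$op$L)
  Linv <- solve(Ld)
  acc <- matrix(0, n, 0)
  for (j in seq_len(m)) {
    piece <- Linv %*% as.matrix(cache$B[[j]])
    if (j < m)
      for (l in (j + 1):m) piece <- Linv %*% as.matrix(cache$S[[l]]) %*% piece
    acc <- cbind(acc, piece)
  }
  acc
}
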