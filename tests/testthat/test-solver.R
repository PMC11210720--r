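test_that("objective matches an independent voxel-loop re-implementation", {
  inst <- rand_instance(5, 4, 3, m = 3, seed = 12)
  cfg <- romt_config(m = 3, kt = inst$tm$kt, ks = 1.7)
  op <- build_diffusion_operator(inst$g, inst$tm, cfg$sigma)
  cc <- romt_cost(inst$v, inst$rho0, inst$rho1, op, cfg)
  # naive loop oracle straight from the discrete objective definition
  n <- inst$g$n
  states <- forward_integrate(inst$rho0, inst$v, op, inst$tm)
  energy <- 0
  for (i in seq_len(cfg$m)) for (vox in seq_len(n)) {
    sp2 <- inst$v[vox, i]^2 + inst$v[n + vox, i]^2 + inst$v[2 * n + vox, i]^2
    energy <- energy + cfg$ks * cfg$kt * states[vox, i + 1] * sp2
  }
  fit <- cfg$beta * sum((states[, cfg$m + 1] - inst$rho1)^2)
  expect_lt(abs(cc$energy - energy) / energy, 1e-12)
  expect_lt(abs(cc$fit - fit) / fit, 1e-12)
  expect_equal(cc$total, cc$energy + cc$fit)
  # v = 0: kinetic energy is exactly zero
  c0 <- romt_cost(0 * inst$v, inst$rho0, inst$rho1, op, cfg)
  expect_identical(c0$energy, 0)
  # identity transport with matching frames: total cost 0
  cfg0 <- romt_config(sigma = 0, m = 3)
  op0 <- build_diffusion_operator(inst$g, inst$tm, 0)
  expect_equal(romt_cost(0 * inst$v, inst$rho0, inst$rho0, op0, cfg0)$total, 0)
})

test_that("gradient passes directional finite-difference checks", {
  inst <- rand_instance(6, 5, 4, m = 3, seed = 13)
  cfg <- romt_config(m = 3)
  cache <- sensitivity_cache(inst$rho0, inst$v, inst$op, inst$tm)
  gvec <- romt_gradient(inst$v, inst$rho1, cfg, cache)
  Fv <- function(vv) romt_cost(vv, inst$rho0, inst$rho1, inst$op, cfg)$total
  set.seed(14)
  h <- 1e-6
  for (k in 1:3) {
    d <- rnorm(length(gvec))
    d <- d / sqrt(sum(d^2))
    dm <- matrix(d, nrow(inst$v), ncol(inst$v))
    fd <- (Fv(inst$v + h * dm) - Fv(inst$v - h * dm)) / (2 * h)
    expect_lt(abs(sum(gvec * d) - fd) / abs(fd), 1e-4)
  }
  # at v = 0 with rho_m = rho_1_obs (sigma = 0) the gradient vanishes
  op0 <- build_diffusion_operator(inst$g, inst$tm, 0)
  cfg0 <- romt_config(sigma = 0, m = 3)
  cache0 <- sensitivity_cache(inst$rho0, 0 * inst$v, op0, inst$tm)
  g0 <- romt_gradient(0 * inst$v, inst$rho0, cfg0, cache0)
  expect_equal(g0, numeric(length(g0)))
})

test_that("Hessian action is linear, symmetric, PSD and matches dense assembly", {
  inst <- rand_instance(4, 4, 1, m = 2, seed = 15)
  cfg <- romt_config(m = 2)
  cache <- sensitivity_cache(inst$rho0, inst$v, inst$op, inst$tm)
  nv <- length(inst$v)
  set.seed(16)
  x <- rnorm(nv); y <- rnorm(nv)
  Hx <- romt_hess_vec(x, cfg, cache)
  Hy <- romt_hess_vec(y, cfg, cache)
  # linearity
  expect_equal(romt_hess_vec(2 * x - 3 * y, cfg, cache), 2 * Hx - 3 * Hy,
               tolerance = 1e-12)
  # symmetry and positive semidefiniteness
  expect_lt(abs(sum(y * Hx) - sum(x * Hy)),
            1e-10 * sqrt(sum(x^2)) * sqrt(sum(y^2)))
  expect_gte(sum(x * Hx), 0)
  # dense oracle: H = 2 ks kt diag(M^T rho) + 2 beta J_m^T J_m
  Jm <- dense_jac_final(cache)
  mt_rho <- as.numeric(romt:::rep3_states(cache$states, inst$g, cfg$m))
  Hd <- 2 * cfg$ks * cfg$kt * diag(mt_rho) + 2 * cfg$beta * t(Jm) %*% Jm
  expect_lt(rel_err(as.numeric(Hd %*% x), Hx), 1e-10)
})

test_that("Gauss-Newton solver reduces the end-point mismatch monotonically", {
  g <- grid_spec(10, 10, 10)
  rho0 <- gauss_blob(g, c(4.5, 5.5, 5.5))
  rho1 <- gauss_blob(g, c(6.5, 5.5, 5.5))
  cfg <- romt_config(m = 4, gn_max_iter = 6)
  res <- solve_pair(rho0, rho1, g, cfg)
  h <- res$cost_history
  expect_true(all(diff(h$total) < 0))
  expect_lt(h$fit[nrow(h)], h$fit[1])   # descent step accepted
  expect_true(res$termination %in% c("converged", "line-search-failed",
                                     "max-iter"))
  # every interpolation stays non-negative and conserves the source mass
  expect_true(all(res$states >= 0))
  for (k in seq_len(ncol(res$states)))
    expect_lt(abs(sum(res$states[, k]) - sum(rho0)) / sum(rho0), 1e-8)
  # a frame pair with an all-zero region still solves finitely
  # (optimizing v rather than momentum keeps the objective finite at rho = 0)
  rho0z <- rho0; rho1z <- rho1
  zero_idx <- which(romt:::grid_centers(g)[, 3] > 8)
  rho0z[zero_idx] <- 0; rho1z[zero_idx] <- 0
  resz <- solve_pair(rho0z, rho1z, g, romt_config(m = 3, gn_max_iter = 3))
  expect_true(all(is.finite(resz$cost_history$total)))
  expect_true(all(is.finite(resz$v)))
  expect_error(solve_pair(-rho0, rho1, g, cfg), "non-negative")
})

test_that("sequence modes agree with their serial definitions", {
  g <- grid_spec(8, 8, 8)
  frames <- list(gauss_blob(g, c(3.5, 4.5, 4.5)),
                 gauss_blob(g, c(4.5, 4.5, 4.5)),
                 gauss_blob(g, c(5.5, 4.5, 4.5)))
  cfg_i <- romt_config(m = 2, gn_max_iter = 3, mode = "independent")
  cfg_c <- romt_config(m = 2, gn_max_iter = 3, mode = "chained")

  # p = 2: both modes reduce to a single solve_pair
  r_pair <- solve_pair(frames[[1]], frames[[2]], g, cfg_i)
  r_i2 <- solve_sequence(frames[1:2], g, cfg_i)
  r_c2 <- solve_sequence(frames[1:2], g, cfg_c)
  expect_equal(r_i2[[1]]$v, r_pair$v)
  expect_equal(r_c2[[1]]$v, r_pair$v)

  r_i <- solve_sequence(frames, g, cfg_i)
  r_c <- solve_sequence(frames, g, cfg_c)
  expect_length(r_i, 2L)
  # independent: loop i starts from observed frame i
  expect_equal(r_i[[2]]$states[, 1], frames[[2]])
  # chained: loop i+1 starts from loop i's final interpolation, bit-identical
  expect_identical(r_c[[2]]$states[, 1], r_c[[1]]$states[, cfg_c$m + 1])
  # parallel workers change nothing about the values
  cfg_j <- romt_config(m = 2, gn_max_iter = 3, mode = "independent", jobs = 2)
  r_j <- solve_sequence(frames, g, cfg_j)
  expect_equal(r_j[[1]]$v, r_i[[1]]$v)
  expect_equal(r_j[[2]]$v, r_i[[2]]$v)
  expect_error(solve_sequence(frames[1], g, cfg_i), "at least two")
})
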