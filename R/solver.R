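#' Solver configuration
#'
#' Bundles every tunable of the transport solver. The model defaults are the
#' published parameter set for the geometric phantom and the rat-brain data:
#' `m = 10` time intervals of length `kt = 0.4`, spatial weight `ks = 1`,
#' diffusion coefficient `sigma = 0.002` and end-point fitting weight
#' `beta = 5000`. The numerical controls (Gauss-Newton cap, inexact PCG
#' tolerance, backtracking line search) follow common Gauss-Newton practice
#' and are all exposed here.
#'
#' @param sigma Diffusion coefficient (>= 0).
#' @param beta Weight of the squared end-point mismatch (> 0).
#' @param m Number of time intervals per frame pair.
#' @param kt Time-interval length.
#' @param ks Spatial quadrature weight on the kinetic-energy term.
#' @param gn_max_iter Outer Gauss-Newton iteration cap.
#' @param pcg_rel_tol,pcg_max_iter Inner conjugate-gradient controls for
#'   `H x = -g` (inexact Newton).
#' @param ls_max_backtracks,ls_shrink Backtracking line-search controls;
#'   the step starts at 1 and is multiplied by `ls_shrink` until the total
#'   cost decreases.
#' @param precond `"diag"` (diagonal of the kinetic-energy Hessian block) or
#'   `"identity"`.
#' @param eps_log Floor added inside logarithms / divisions downstream
#'   (augmented velocity, Peclet numbers); interpreted relative to `max(rho)`
#'   when applied.
#' @param pe_cap Cap applied to Peclet values when rasterizing maps.
#' @param n_substeps Euler sub-steps per interval for pathline tracing.
#' @param mode `"chained"` (each loop starts from the previous loop's final
#'   interpolation) or `"independent"` (each loop starts from its observed
#'   frame; loops are embarrassingly parallel).
#' @param jobs Worker count for independent mode (values are identical for
#'   any `jobs`).
#' @return An object of class `romt_config`.
#' @export
romt_config <- function(sigma = 0.002, beta = 5000, m = 10, kt = 0.4, ks = 1,
                        gn_max_iter = 20L, pcg_rel_tol = 1e-2,
                        pcg_max_iter = 20L, ls_max_backtracks = 15L,
                        ls_shrink = 0.5, precond = c("diag", "identity"),
                        eps_log = 1e-8, pe_cap = 100, n_substeps = 1L,
                        mode = c("chained", "independent"), jobs = 1L) {
  precond <- match.arg(precond)
  mode <- match.arg(mode)
  stopifnot(sigma >= 0, beta > 0, m >= 1, kt > 0, ks > 0,
            gn_max_iter >= 1, pcg_max_iter >= 1, ls_max_backtracks >= 1,
            ls_shrink > 0, ls_shrink < 1, pcg_rel_tol > 0,
            eps_log > 0, pe_cap > 0, n_substeps >= 1, jobs >= 1)
  structure(list(sigma = sigma, beta = beta, m = as.integer(m), kt = kt,
                 ks = ks, gn_max_iter = as.integer(gn_max_iter),
                 pcg_rel_tol = pcg_rel_tol,
                 pcg_max_iter = as.integer(pcg_max_iter),
                 ls_max_backtracks = as.integer(ls_max_backtracks),
                 ls_shrink = ls_shrink, precond = precond,
                 eps_log = eps_log, pe_cap = pe_cap,
                 n_substeps = as.integer(n_substeps),
                 mode = mode, jobs = as.integer(jobs)),
            class = "romt_config")
}

#' @export
print.romt_config <- function(x, ...) {
  cat(sprintf(paste0("<romt_config> sigma = %g, beta = %g, m = %d, kt = %g, ",
                     "ks = %g, mode = %s\n"),
              x$sigma, x$beta, x$m, x$kt, x$ks, x$mode))
  invisible(x)
}

# Replicate each interval's end-state density across the three velocity
# components: M^T rho as a flat 3mn vector (M = I_m (x) [I | I | I]).
rep3_states <- function(states, grid, m) {
  out <- matrix(0, 3L * grid$n, m)
  for (j in seq_len(m)) out[, j] <- rep.int(states[, j + 1L], 3L)
  out
}

# Per-interval squared speed summed over components: M (v (.) v), n x m.
speed2_blocks <- function(v, grid, m) {
  n <- grid$n
  out <- matrix(0, n, m)
  for (j in seq_len(m))
    out[, j] <- v[seq_len(n), j]^2 + v[n + seq_len(n), j]^2 +
      v[2L * n + seq_len(n), j]^2
  out
}

#' Discrete transport objective
#'
#' Evaluates the free end-point objective
#' `F(v) = ks * kt * rho^T M (v (.) v) + beta * || rho_m - rho_1_obs ||^2`,
#' where the interpolations `rho_1..rho_m` are produced by the forward
#' advection-diffusion recursion from `rho_0`. The kinetic-energy and fitting
#' terms are returned separately so the `beta` trade-off is observable.
#'
#' @param v Velocity field (`3n x m` matrix or flat `3mn` vector).
#' @param rho_0 Source density (flat, length `n`).
#' @param rho_1_obs Observed target density (flat, length `n`).
#' @param op A `diffusion_op` built with the config's `sigma`, `kt` and grid.
#' @param cfg An [romt_config()].
#' @param states Optional precomputed [forward_integrate()] output for `v`.
#' @return A list with `total`, `energy`, `fit` and the forward `states`.
#' @export
romt_cost <- function(v, rho_0, rho_1_obs, op, cfg, states = NULL) {
  grid <- op$grid
  time <- time_grid(cfg$m, cfg$kt)
  v <- as_velocity_matrix(v, grid, time)
  if (is.null(states)) states <- forward_integrate(rho_0, v, op, time)
  rho_m <- states[, cfg$m + 1L]
  energy <- cfg$ks * cfg$kt *
    sum(states[, -1L, drop = FALSE] * speed2_blocks(v, grid, cfg$m))
  fit <- cfg$beta * sum((rho_m - rho_1_obs)^2)
  list(total = energy + fit, energy = energy, fit = fit, states = states)
}

#' Objective gradient
#'
#' Assembles
#' `g = ks * kt * (2 (M diag(v))^T rho + J^T M (v (.) v)) +
#'  2 beta * J_m^T (rho_m - rho_1_obs)`
#' using the cached matrix-free transposed-Jacobian products. The first term
#' is the direct dependence of the kinetic energy on `v`; the second its
#' indirect dependence through the interpolations; the third the end-point
#' mismatch pulled back to all intervals.
#'
#' @inheritParams romt_cost
#' @param cache A [sensitivity_cache()] built from the same `v`.
#' @return Flat gradient of length `3mn`.
#' @export
romt_gradient <- function(v, rho_1_obs, cfg, cache) {
  grid <- cache$grid
  v <- as_velocity_matrix(v, grid, cache$time)
  check_cache(cache, v)
  m <- cfg$m
  mt_rho <- rep3_states(cache$states, grid, m)
  term_direct <- 2 * cfg$ks * cfg$kt * as.numeric(mt_rho * v)
  y_energy <- as.numeric(speed2_blocks(v, grid, m))
  term_chain <- cfg$ks * cfg$kt * jacT_full_vec(y_energy, cache)
  resid <- cache$states[, m + 1L] - rho_1_obs
  term_fit <- 2 * cfg$beta * jacT_final_vec(resid, cache)
  term_direct + term_chain + term_fit
}

#' Gauss-Newton Hessian-vector product
#'
#' Applies `H x = 2 ks kt diag(rho^T M) x + 2 beta J_m^T (J_m x)` without
#' forming `H`: a diagonal scaling by the interpolated densities plus one
#' forward and one adjoint Jacobian sweep. `H` is symmetric positive
#' semidefinite by construction.
#'
#' @param x Flat vector of length `3mn`.
#' @param cfg An [romt_config()].
#' @param cache A [sensitivity_cache()].
#' @return Flat vector `H x` of length `3mn`.
#' @export
romt_hess_vec <- function(x, cfg, cache) {
  grid <- cache$grid
  mt_rho <- as.numeric(rep3_states(cache$states, grid, cfg$m))
  diag_term <- 2 * cfg$ks * cfg$kt * mt_rho * as.numeric(x)
  gn_term <- 2 * cfg$beta * jacT_final_vec(jac_final_vec(x, cache), cache)
  diag_term + gn_term
}

# Matrix-free preconditioned conjugate gradients for H x = b. Returns the
# iterate together with a breakdown flag (non-finite or non-positive
# curvature); inexactness is intentional (inexact Newton).
pcg_solve <- function(b, cfg, cache) {
  hv <- function(x) romt_hess_vec(x, cfg, cache)
  d <- 2 * cfg$ks * cfg$kt * as.numeric(rep3_states(cache$states, cache$grid, cfg$m))
  if (cfg$precond == "identity") d <- rep(1, length(b))
  d <- pmax(d, 1e-8 * max(d, 1))
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b * b))
  if (b_norm == 0) return(list(x = x, ok = TRUE, iters = 0L))
  for (it in seq_len(cfg$pcg_max_iter)) {
    Hp <- hv(p)
    pHp <- sum(p * Hp)
    if (!is.finite(pHp) || pHp <= 0)
      return(list(x = x, ok = it > 1L, iters = it - 1L))
    alpha <- rz / pHp
    x <- x + alpha * p
    r <- r - alpha * Hp
    if (sqrt(sum(r * r)) <= cfg$pcg_rel_tol * b_norm)
      return(list(x = x, ok = TRUE, iters = it))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, ok = TRUE, iters = cfg$pcg_max_iter)
}

#' Solve the transport problem for one frame pair
#'
#' Gauss-Newton iteration starting from `v = 0`: integrate the forward model,
#' rebuild the sensitivity cache, form the gradient, solve `H x = -g`
#' inexactly by preconditioned conjugate gradients, and backtrack on the total
#' cost. Line-search failure terminates with the current field (the standard
#' stopping rule for this scheme); PCG breakdown falls back to the steepest
#' descent direction for that iteration.
#'
#' @param rho_0 Source density (flat, length `n`), non-negative.
#' @param rho_1_obs Observed target density (flat, length `n`), non-negative.
#' @param grid A [grid_spec()].
#' @param cfg An [romt_config()].
#' @param op Optional prebuilt `diffusion_op` (reused across loops).
#' @param verbose Print per-iteration cost components.
#' @return An object of class `romt_solve` with fields `v` (`3n x m` matrix),
#'   `states` (`n x (m+1)` interpolations), `cost_history` (data frame with
#'   one row per accepted iterate: energy, fit, total, step, pcg_iters) and
#'   `termination` (`"converged"`, `"line-search-failed"` or `"max-iter"`).
#' @export
solve_pair <- function(rho_0, rho_1_obs, grid, cfg, op = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(cfg, "romt_config"))
  time <- time_grid(cfg$m, cfg$kt)
  rho_0 <- as_flat_volume(rho_0, grid, "rho_0")
  rho_1_obs <- as_flat_volume(rho_1_obs, grid, "rho_1_obs")
  if (min(rho_0) < 0 || min(rho_1_obs) < 0)
    stop("densities must be non-negative (clip on input)", call. = FALSE)
  if (is.null(op)) op <- build_diffusion_operator(grid, time, cfg$sigma)

  v <- matrix(0, 3L * grid$n, time$m)
  cur <- romt_cost(v, rho_0, rho_1_obs, op, cfg)
  if (!is.finite(cur$total)) stop("non-finite initial cost", call. = FALSE)
  hist <- data.frame(iter = 0L, energy = cur$energy, fit = cur$fit,
                     total = cur$total, step = NA_real_, pcg_iters = NA_integer_)
  termination <- "max-iter"

  for (it in seq_len(cfg$gn_max_iter)) {
    cache <- sensitivity_cache(rho_0, v, op, time)
    g <- romt_gradient(v, rho_1_obs, cfg, cache)
    if (sqrt(sum(g * g)) <= 1e-12 * max(1, cur$total)) {
      termination <- "converged"
      break
    }
    sol <- pcg_solve(-g, cfg, cache)
    x <- if (sol$ok && any(sol$x != 0)) sol$x else -g
    x <- matrix(x, 3L * grid$n, time$m)

    l <- 1
    accepted <- FALSE
    for (bt in seq_len(cfg$ls_max_backtracks)) {
      trial_v <- v + l * x
      trial <- romt_cost(trial_v, rho_0, rho_1_obs, op, cfg)
      if (is.finite(trial$total) && trial$total < cur$total) {
        accepted <- TRUE
        break
      }
      l <- l * cfg$ls_shrink
    }
    if (!accepted) {
      termination <- "line-search-failed"
      break
    }
    v <- trial_v
    cur <- trial
    hist <- rbind(hist, data.frame(iter = it, energy = cur$energy,
                                   fit = cur$fit, total = cur$total,
                                   step = l, pcg_iters = sol$iters))
    if (verbose)
      message(sprintf("GN %2d: energy %.6g  fit %.6g  total %.6g  (step %g, pcg %d)",
                      it, cur$energy, cur$fit, cur$total, l, sol$iters))
  }
  structure(list(v = v, states = cur$states, cost_history = hist,
                 termination = termination, grid = grid, cfg = cfg),
            class = "romt_solve")
}

#' @export
print.romt_solve <- function(x, ...) {
  last <- x$cost_history[nrow(x$cost_history), ]
  cat(sprintf(paste0("<romt_solve> %d accepted iterations, termination: %s\n",
                     "  energy %.6g  fit %.6g  total %.6g\n"),
              nrow(x$cost_history) - 1L, x$termination,
              last$energy, last$fit, last$total))
  invisible(x)
}

#' Solve a multi-frame sequence
#'
#' Runs one transport solve per adjacent frame pair. In `"chained"` mode loop
#' `i` starts from the previous loop's final interpolation (smoother velocity
#' fields, no re-injection of observation noise, strictly serial). In
#' `"independent"` mode loop `i` starts from observed frame `i`; loops share
#' no state and may run in parallel (`cfg$jobs`), with values identical to a
#' serial run.
#'
#' @param frames List of `p >= 2` flat densities on a common grid.
#' @param grid A [grid_spec()].
#' @param cfg An [romt_config()]; `cfg$mode` selects the sequencing.
#' @param verbose Print progress.
#' @return List of `p - 1` [solve_pair()] results, ordered by loop index.
#' @export
solve_sequence <- function(frames, grid, cfg, verbose = FALSE) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("frames must be a list of at least two volumes", call. = FALSE)
  frames <- lapply(frames, as_flat_volume, grid = grid, what = "frame")
  time <- time_grid(cfg$m, cfg$kt)
  op <- build_diffusion_operator(grid, time, cfg$sigma)
  p <- length(frames)

  if (cfg$mode == "chained") {
    out <- vector("list", p - 1L)
    src <- frames[[1L]]
    for (i in seq_len(p - 1L)) {
      if (verbose) message(sprintf("loop %d/%d (chained)", i, p - 1L))
      out[[i]] <- solve_pair(src, frames[[i + 1L]], grid, cfg, op = op,
                             verbose = verbose)
      src <- out[[i]]$states[, cfg$m + 1L]
    }
    return(out)
  }

  run_one <- function(i) {
    if (verbose) message(sprintf("loop %d/%d (independent)", i, p - 1L))
    solve_pair(frames[[i]], frames[[i + 1L]], grid, cfg, op = op,
               verbose = verbose)
  }
  idx <- seq_len(p - 1L)
  if (cfg$jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_one, mc.cores = cfg$jobs,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, run_one)
  }
}
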