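#' @name lagrangian
#' @title Lagrangian post-processing
#' @description
#' A solved transport problem yields interpolated densities and velocity
#' fields in Eulerian form. For visualization the package follows individual
#' particles instead: the advection-diffusion equation rewritten in
#' conservation form has effective ("augmented") velocity
#' `v_tilde = v - sigma * grad(log rho)`, and integrating
#' `dL/dt = v_tilde(t, L)` from seed points gives pathlines. Decorating each
#' step with the local speed `||v||` or with the Peclet number
#' `Pe = ||v|| / (sigma * ||grad log rho||)` produces speed-lines and
#' Peclet-lines, which can be rasterized to voxel maps or reduced to net
#' displacement ("velocity flux") vectors.
NULL

# Componentwise central-difference gradient (one-sided at the boundary) of a
# flat scalar field; returns an n x 3 matrix. Unit voxel spacing.
grad_field <- function(f, grid) {
  arr <- array(f, dim = c(grid$nx, grid$ny, grid$nz))
  g <- array(0, dim = c(dim(arr), 3L))
  d <- dim(arr)
  for (a in 1:3) {
    k <- d[a]
    if (k == 1L) next
    idx_hi <- pmin(seq_len(k) + 1L, k)
    idx_lo <- pmax(seq_len(k) - 1L, 1L)
    denom <- idx_hi - idx_lo  # 2 interior, 1 at the two faces
    sel <- function(i) switch(a,
                              arr[i, , , drop = FALSE],
                              arr[, i, , drop = FALSE],
                              arr[, , i, drop = FALSE])
    diffd <- (sel(idx_hi) - sel(idx_lo)) /
      array(rep(denom, each = if (a == 1L) 1L else prod(d[seq_len(a - 1L)])),
            dim = d)
    g[, , , a] <- diffd
  }
  matrix(g, nrow = grid$n, ncol = 3L)
}

# grad(log(rho + eps)) with the floor scaled to the field's magnitude.
grad_log_rho <- function(rho, grid, eps_log) {
  eps <- eps_log * max(max(rho), 1e-300)
  grad_field(log(rho + eps), grid)
}

#' Augmented velocity for pathline tracing
#'
#' Computes `v_tilde = v - sigma * grad(log(rho + eps))` on cell centers,
#' the effective velocity under which the advection-diffusion dynamics become
#' a pure conservation law. With `sigma = 0`, or with spatially uniform
#' `rho`, this is `v` itself.
#'
#' @param rho_i Flat density at the interval start, length `n`.
#' @param v_i Flat per-interval velocity, length `3n`.
#' @param sigma Diffusion coefficient.
#' @param grid A [grid_spec()].
#' @param eps_log Relative floor inside the logarithm (times `max(rho)`).
#' @return Flat augmented velocity, length `3n`.
#' @export
augmented_velocity <- function(rho_i, v_i, sigma, grid, eps_log = 1e-8) {
  rho_i <- as_flat_volume(rho_i, grid, "rho_i")
  if (length(v_i) != 3L * grid$n) stop("v_i must have length 3n", call. = FALSE)
  if (sigma == 0) return(as.numeric(v_i))
  as.numeric(v_i) - sigma * as.numeric(grad_log_rho(rho_i, grid, eps_log))
}

# Vectorized trilinear sampling of a flat field at arbitrary points
# (npts x 3, voxel coordinates); points are clamped into the domain.
sample_trilinear <- function(f, pts, grid) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  npts <- nrow(pts)
  i0 <- matrix(1L, npts, 3L)
  fr <- matrix(0, npts, 3L)
  for (a in 1:3) {
    d <- dims[a]
    if (d == 1L) next
    p <- pmin(pmax(pts[, a], 1), d)
    lo <- pmin(floor(p), d - 1)
    i0[, a] <- as.integer(lo)
    fr[, a] <- p - lo
  }
  out <- numeric(npts)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    if ((cx == 1L && dims[1] == 1L) || (cy == 1L && dims[2] == 1L) ||
        (cz == 1L && dims[3] == 1L)) next
    w <- (if (cx == 0L) 1 - fr[, 1] else fr[, 1]) *
      (if (cy == 0L) 1 - fr[, 2] else fr[, 2]) *
      (if (cz == 0L) 1 - fr[, 3] else fr[, 3])
    idx <- grid_flat_index(grid, i0[, 1] + cx, i0[, 2] + cy, i0[, 3] + cz)
    out <- out + w * f[idx]
  }
  out
}

# Sample a 3-component flat field (length 3n) -> npts x 3.
sample_vec3 <- function(v3, pts, grid) {
  n <- grid$n
  cbind(sample_trilinear(v3[seq_len(n)], pts, grid),
        sample_trilinear(v3[n + seq_len(n)], pts, grid),
        sample_trilinear(v3[2L * n + seq_len(n)], pts, grid))
}

#' Seed points for pathline tracing
#'
#' Seeds are the voxel centers where the initial observed frame exceeds a
#' relative intensity threshold (and, optionally, lie inside a mask).
#'
#' @param frame Flat density, length `n`.
#' @param grid A [grid_spec()].
#' @param threshold_frac Seed where `frame > threshold_frac * max(frame)`.
#' @param mask Optional flat 0/1 vector of length `n`.
#' @return Matrix of seed coordinates, one row per seed (x, y, z).
#' @export
seed_points <- function(frame, grid, threshold_frac = 0.1, mask = NULL) {
  frame <- as_flat_volume(frame, grid, "frame")
  keep <- frame > threshold_frac * max(frame)
  if (!is.null(mask)) keep <- keep & (as_flat_volume(mask, grid, "mask") > 0)
  grid_centers(grid)[keep, , drop = FALSE]
}

#' Trace pathlines through a solved sequence
#'
#' Integrates `dL/dt = v_tilde(t, L)` by explicit Euler with trilinear
#' sampling: for each loop and each of its `m` intervals, the augmented
#' velocity is rebuilt from that interval's starting density and velocity,
#' and every particle advances by `kt * v_tilde(point)` (optionally split
#' into `n_substeps` sub-steps, re-sampling the same interval field).
#' Positions are clamped to the domain.
#'
#' @param seeds Matrix of starting coordinates (one row per particle), e.g.
#'   from [seed_points()].
#' @param results List of [solve_pair()] results (one per loop), as returned
#'   by [solve_sequence()].
#' @param grid A [grid_spec()].
#' @param cfg An [romt_config()] (uses `sigma`, `kt`, `eps_log`,
#'   `n_substeps`).
#' @return An object of class `romt_pathlines`: a list of pathlines, each
#'   with `seed` and `points` (a `(steps + 1) x 3` matrix,
#'   `points[1, ] = seed`), plus a shared step table mapping step to
#'   (loop, interval).
#' @export
trace_pathlines <- function(seeds, results, grid, cfg) {
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 3L) stop("seeds must be an npts x 3 matrix", call. = FALSE)
  dims <- c(grid$nx, grid$ny, grid$nz)
  inside <- seeds[, 1] >= 1 & seeds[, 1] <= dims[1] &
    seeds[, 2] >= 1 & seeds[, 2] <= dims[2] &
    seeds[, 3] >= 1 & seeds[, 3] <= dims[3]
  if (!all(inside)) {
    warning(sum(!inside), " seed(s) outside the domain were skipped")
    seeds <- seeds[inside, , drop = FALSE]
  }
  npts <- nrow(seeds)
  m <- cfg$m
  p_loops <- length(results)
  steps <- expand.grid(interval = seq_len(m), loop = seq_len(p_loops))[, 2:1]
  total <- nrow(steps)
  traj <- array(0, dim = c(total + 1L, 3L, npts))
  traj[1L, , ] <- t(seeds)
  pos <- seeds
  sub <- cfg$n_substeps
  dt <- cfg$kt / sub
  row <- 1L
  for (l in seq_len(p_loops)) {
    res <- results[[l]]
    for (i in seq_len(m)) {
      vt <- augmented_velocity(res$states[, i], res$v[, i], cfg$sigma, grid,
                               cfg$eps_log)
      for (s in seq_len(sub)) {
        pos <- pos + dt * sample_vec3(vt, pos, grid)
        for (a in 1:3) pos[, a] <- pmin(pmax(pos[, a], 1), dims[a])
      }
      row <- row + 1L
      traj[row, , ] <- t(pos)
    }
  }
  lines <- lapply(seq_len(npts), function(k)
    list(seed = seeds[k, ], points = traj[, , k, drop = TRUE]))
  structure(lines, class = "romt_pathlines",
            steps = steps, grid_dims = dims)
}

#' @export
print.romt_pathlines <- function(x, ...) {
  st <- attr(x, "steps")
  cat(sprintf("<romt_pathlines> %d lines, %d steps (%d loops x %d intervals)\n",
              length(x), nrow(st), max(st$loop), max(st$interval)))
  invisible(x)
}

# Shared attribute sampler: value_fun(res, interval) must return a flat field
# (length n for scalars, 3n for vectors sampled as norms).
attach_attribute <- function(pathlines, results, grid, field_fun, norm3) {
  steps <- attr(pathlines, "steps")
  total <- nrow(steps)
  vals <- matrix(0, total, length(pathlines))
  pts_all <- vapply(pathlines,
                    function(pl) pl$points[seq_len(total), , drop = FALSE],
                    matrix(0, total, 3L))
  for (t in seq_len(total)) {
    f <- field_fun(results[[steps$loop[t]]], steps$interval[t])
    pts <- t(pts_all[t, , ])
    if (norm3) {
      sv <- sample_vec3(f, pts, grid)
      vals[t, ] <- sqrt(rowSums(sv^2))
    } else {
      vals[t, ] <- sample_trilinear(f, pts, grid)
    }
  }
  vals
}

#' Attach speeds to pathlines (speed-lines)
#'
#' Samples the Euclidean norm of the optimized velocity `v` (not the
#' augmented velocity) trilinearly at the start point of every traced step.
#'
#' @inheritParams trace_pathlines
#' @param pathlines An `romt_pathlines` object.
#' @return The pathlines with a `speeds` vector (one value per step) on each
#'   line.
#' @export
attach_speed <- function(pathlines, results, grid, cfg) {
  vals <- attach_attribute(pathlines, results, grid,
                           function(res, i) res$v[, i], norm3 = TRUE)
  for (k in seq_along(pathlines)) pathlines[[k]]$speeds <- vals[, k]
  pathlines
}

#' Attach Peclet numbers to pathlines (Peclet-lines)
#'
#' Samples `Pe = ||v|| / (sigma * ||grad log(rho + eps)||)` at the start
#' point of every traced step. High values flag advection-dominated
#' transport, low values diffusion-dominated. The denominator is floored at
#' `eps_log` to keep the ratio finite where the log-density gradient
#' vanishes (e.g. uniform density); the attached values are uncapped —
#' `cfg$pe_cap` is applied only when rasterizing to a map.
#'
#' @inheritParams attach_speed
#' @return The pathlines with a `peclets` vector on each line.
#' @export
attach_peclet <- function(pathlines, results, grid, cfg) {
  if (cfg$sigma <= 0)
    stop("Peclet numbers are undefined for sigma = 0 (pure advection: ",
         "the advection/diffusion ratio is infinite)", call. = FALSE)
  speed <- attach_attribute(pathlines, results, grid,
                            function(res, i) res$v[, i], norm3 = TRUE)
  gln <- attach_attribute(pathlines, results, grid, function(res, i) {
    g <- grad_log_rho(res$states[, i], grid, cfg$eps_log)
    sqrt(rowSums(g^2))
  }, norm3 = FALSE)
  pe <- speed / (cfg$sigma * pmax(gln, cfg$eps_log))
  for (k in seq_along(pathlines)) pathlines[[k]]$peclets <- pe[, k]
  pathlines
}

#' Rasterize pathline attributes to a voxel map
#'
#' Bins every sampled (point, value) pair to its nearest voxel and averages
#' within each voxel, producing the smoothed speed map or Peclet map. Voxels
#' not touched by any line are `NA` (never conflated with a data value of 0).
#' Peclet values are capped at `pe_cap` before averaging so near-singular
#' ratios (vanishing log-density gradient) do not dominate the map.
#'
#' @param pathlines An `romt_pathlines` object carrying the requested
#'   attribute (see [attach_speed()], [attach_peclet()]).
#' @param attribute `"speed"` or `"peclet"`.
#' @param grid A [grid_spec()].
#' @param pe_cap Cap applied to Peclet values (default from [romt_config()]).
#' @return A 3D array (`nx x ny x nz`) with `NA` as the empty marker.
#' @export
rasterize_lines <- function(pathlines, attribute = c("speed", "peclet"), grid,
                            pe_cap = 100) {
  attribute <- match.arg(attribute)
  field <- if (attribute == "speed") "speeds" else "peclets"
  total <- nrow(attr(pathlines, "steps"))
  all_idx <- integer(0)
  all_vals <- numeric(0)
  for (pl in pathlines) {
    vals <- pl[[field]]
    if (is.null(vals))
      stop("pathlines carry no '", attribute, "' attribute", call. = FALSE)
    pts <- pl$points[seq_len(total), , drop = FALSE]
    idx <- grid_flat_index(grid,
                           pmin(pmax(round(pts[, 1]), 1), grid$nx),
                           pmin(pmax(round(pts[, 2]), 1), grid$ny),
                           pmin(pmax(round(pts[, 3]), 1), grid$nz))
    all_idx <- c(all_idx, as.integer(idx))
    all_vals <- c(all_vals, vals)
  }
  if (attribute == "peclet") all_vals <- pmin(all_vals, pe_cap)
  out <- rep(NA_real_, grid$n)
  if (length(all_idx)) {
    sums <- rowsum(all_vals, all_idx)
    touched <- as.integer(rownames(sums))
    cnts <- tabulate(all_idx, nbins = grid$n)
    out[touched] <- sums[, 1L] / cnts[touched]
  }
  array(out, dim = c(grid$nx, grid$ny, grid$nz))
}

#' Velocity flux vectors
#'
#' Reduces each pathline to the straight vector from its first to its last
#' point: net displacement and its Euclidean length, summarizing direction
#' and how far mass traveled over the whole traced period.
#'
#' @param pathlines An `romt_pathlines` object.
#' @return A data frame with columns `x0, y0, z0, dx, dy, dz, length`.
#' @export
flux_vectors <- function(pathlines) {
  out <- t(vapply(pathlines, function(pl) {
    s <- pl$points[1L, ]
    e <- pl$points[nrow(pl$points), ]
    d <- e - s
    c(s, d, sqrt(sum(d^2)))
  }, numeric(7L)))
  colnames(out) <- c("x0", "y0", "z0", "dx", "dy", "dz", "length")
  as.data.frame(out)
}
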