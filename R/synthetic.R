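#' Gaussian-sphere phantom specification
#'
#' The benchmark phantom is a sequence of `num_frames` 3D Gaussian spheres of
#' amplitude `100 / sqrt(2 * pi)` and unit standard deviation whose center
#' advances by 0.8 physical units per frame along the main diagonal
#' (advection) while frame `i >= 1` is additionally blurred with a Gaussian
#' filter of standard deviation `(i + 1) * 0.2` voxels (diffusion; voxel
#' units follow the convention of the common volumetric filtering routines).
#' The grid has step `12/(size - 1)` per axis (`12/49` at the base size of
#' 50) and is positioned so that the origin — the first sphere's center — is
#' a grid point; scaled sizes (factors 0.5 .. 1.75 giving 25, 38, 50, 63,
#' 75, 88 points, rounded half up) keep the same 12-unit extent and rescale
#' the step.
#'
#' @param base_size Points per axis at scale 1 (default 50).
#' @param scale Grid scale factor; the grid has `round(base_size * scale)`
#'   points per axis.
#' @param num_frames Number of phantom frames `p` (default 5).
#' @param amplitude Peak of the unfiltered Gaussian (default
#'   `100 / sqrt(2 * pi)`).
#' @param center_step Center advance per frame in physical units (default
#'   0.8).
#' @param filter_sigma_step Filter standard-deviation increment per frame in
#'   voxels (default 0.2).
#' @param half_extent Half-width of the physical domain (default 6).
#' @return An object of class `sphere_spec` with derived fields `size`,
#'   `step` and `coords`.
#' @export
sphere_spec <- function(base_size = 50L, scale = 1, num_frames = 5L,
                        amplitude = 100 / sqrt(2 * pi), center_step = 0.8,
                        filter_sigma_step = 0.2, half_extent = 6) {
  size <- as.integer(floor(base_size * scale + 0.5))  # round half up
  if (size < 2L) stop("scaled grid must have at least 2 points", call. = FALSE)
  step <- 2 * half_extent / (size - 1L)
  coords <- (seq_len(size) - ceiling(size / 2)) * step  # origin on-grid
  structure(list(base_size = as.integer(base_size), scale = scale,
                 size = size, num_frames = as.integer(num_frames),
                 amplitude = amplitude, center_step = center_step,
                 filter_sigma_step = filter_sigma_step,
                 half_extent = half_extent, step = step, coords = coords),
            class = "sphere_spec")
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf("<sphere_spec> %d frames on %d^3 (step %.5g, extent [%g, %g])\n",
              x$num_frames, x$size, x$step, -x$half_extent, x$half_extent))
  invisible(x)
}

# Evaluate an isotropic unit-sd Gaussian of the phantom family at a given
# center (same value on all three axes), on the spec's grid.
sphere_gaussian <- function(center, spec) {
  e1 <- exp(-(spec$coords - center)^2 / 2)
  spec$amplitude * (e1 %o% e1 %o% e1)
}

#' Separable 3D Gaussian filter
#'
#' Blurs a 3D array with an isotropic Gaussian kernel by three 1D
#' convolutions. The boundary uses replicate (nearest) padding, which keeps
#' the filter approximately mass-conserving; the kernel is truncated at 4
#' standard deviations and normalized to unit sum.
#'
#' @param arr 3D numeric array.
#' @param sd_vox Kernel standard deviation in voxels; `sd_vox <= 0` returns
#'   the input unchanged.
#' @return Filtered array of the same dimensions.
#' @export
gaussian_filter3 <- function(arr, sd_vox) {
  if (sd_vox <= 0) return(arr)
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  conv1 <- function(k) {
    r <- max(1L, ceiling(4 * sd_vox))
    w <- stats::dnorm(seq(-r, r), sd = sd_vox)
    w <- w / sum(w)
    C <- matrix(0, k, k)
    for (t in seq(-r, r)) {
      src <- pmin(pmax(seq_len(k) + t, 1L), k)   # replicate padding
      C[cbind(seq_len(k), src)] <- C[cbind(seq_len(k), src)] + w[t + r + 1L]
    }
    C
  }
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    tmp <- aperm(arr, perm)
    dd <- dim(tmp)
    tmp <- conv1(dd[1L]) %*% matrix(tmp, dd[1L])
    dim(tmp) <- dd
    arr <- aperm(tmp, order(perm))
  }
  arr
}

#' Generate one phantom frame
#'
#' Frame `i` (0-based) is the Gaussian `G_i` centered at
#' `(0.8 i, 0.8 i, 0.8 i)` evaluated on the phantom grid; frames `i >= 1` are
#' then blurred with a Gaussian filter of standard deviation
#' `(i + 1) * 0.2` voxels.
#'
#' @param i Frame index, `0 <= i < num_frames`.
#' @param spec A [sphere_spec()].
#' @return 3D array of size `size^3`, non-negative.
#' @export
make_sphere_frame <- function(i, spec) {
  stopifnot(inherits(spec, "sphere_spec"))
  if (i < 0 || i >= spec$num_frames || i != round(i))
    stop("frame index must be an integer in [0, num_frames)", call. = FALSE)
  arr <- sphere_gaussian(spec$center_step * i, spec)
  if (i >= 1)
    arr <- gaussian_filter3(arr, (i + 1) * spec$filter_sigma_step)
  arr
}

#' Approximate ground-truth intermediate
#'
#' The phantom's construction interpolates continuously in the frame index:
#' the state at loop `i`, sub-step `j` of `m` is the Gaussian centered at
#' `0.8 (i + j/m)` blurred with standard deviation `(i + j/m + 1) * 0.2`
#' voxels. These volumes serve as the reference against which solver
#' interpolations are scored.
#'
#' @param i Loop index, `0 <= i <= num_frames - 2`.
#' @param j Sub-step index, nominally `1..m-1` (`0` and `m` are admitted for
#'   continuity checks against the frames themselves).
#' @param m Number of time intervals per loop.
#' @param spec A [sphere_spec()].
#' @return 3D array of size `size^3`.
#' @export
make_ground_truth <- function(i, j, m, spec) {
  stopifnot(inherits(spec, "sphere_spec"))
  if (i < 0 || i > spec$num_frames - 2L || i != round(i))
    stop("loop index out of range", call. = FALSE)
  if (j < 0 || j > m || j != round(j))
    stop("sub-step index out of range", call. = FALSE)
  s <- i + j / m
  arr <- sphere_gaussian(spec$center_step * s, spec)
  gaussian_filter3(arr, (s + 1) * spec$filter_sigma_step)
}

#' Generate the full phantom sequence
#'
#' @param spec A [sphere_spec()].
#' @return A list with `frames` (list of flat vectors), `grid` (a
#'   [grid_spec()]) and `spec`.
#' @export
make_phantom <- function(spec = sphere_spec()) {
  grid <- grid_spec(spec$size, spec$size, spec$size)
  frames <- lapply(seq_len(spec$num_frames) - 1L,
                   function(i) as.numeric(make_sphere_frame(i, spec)))
  list(frames = frames, grid = grid, spec = spec)
}

#' Mean squared error between two volumes
#'
#' @param a,b Numeric arrays or flat vectors of equal length.
#' @return Mean over voxels of the squared difference.
#' @export
mse <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("shape mismatch in mse", call. = FALSE)
  mean((a - b)^2)
}

#' Accuracy curve of a phantom run
#'
#' Scores each solver interpolation against the matching approximate
#' ground-truth intermediate: loop `i`'s state at sub-step `j` is compared
#' with [make_ground_truth()] at `(i, j)` for `j = 1..m-1`, pooling all loops
#' into one curve. Lower is better; the curve's mean and standard deviation
#' summarize the run.
#'
#' @param results List of [solve_pair()] results from a phantom
#'   [solve_sequence()] run.
#' @param spec The [sphere_spec()] the phantom was generated from.
#' @param m Number of time intervals per loop.
#' @return A list with `curve` (data frame: loop, step, mse), `mean` and
#'   `sd`.
#' @export
accuracy_curve <- function(results, spec, m) {
  if (length(results) != spec$num_frames - 1L)
    stop("expected one result per adjacent frame pair", call. = FALSE)
  rows <- list()
  for (i in seq_along(results)) {
    states <- results[[i]]$states
    for (j in seq_len(m - 1L)) {
      gt <- make_ground_truth(i - 1L, j, m, spec)
      rows[[length(rows) + 1L]] <-
        data.frame(loop = i, step = j, mse = mse(states[, j + 1L], gt))
    }
  }
  curve <- do.call(rbind, rows)
  list(curve = curve, mean = mean(curve$mse), sd = stats::sd(curve$mse))
}
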