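test_that("phantom frames realize the stated Gaussian construction", {
  spec <- sphere_spec()
  expect_equal(spec$size, 50L)
  expect_equal(spec$step, 12 / 49)
  # scaled sizes round(50 * scale)
  expect_equal(vapply(c(0.5, 0.75, 1, 1.25, 1.5, 1.75),
                      function(s) sphere_spec(scale = s)$size, integer(1)),
               c(25L, 38L, 50L, 63L, 75L, 88L))
  # unsmoothed first frame peaks at the amplitude at the on-grid origin
  f0 <- make_sphere_frame(0, spec)
  expect_equal(max(f0), 100 / sqrt(2 * pi), tolerance = 1e-12)
  ctr <- which(spec$coords == 0)
  expect_equal(which.max(f0),
               ctr + (ctr - 1) * spec$size + (ctr - 1) * spec$size^2)
  # frame centers advance by 0.8 physical units per frame
  for (i in 0:4) {
    fi <- make_sphere_frame(i, spec)
    amax <- arrayInd(which.max(fi), dim(fi))
    expect_equal(rep(spec$coords[which.min(abs(spec$coords - 0.8 * i))], 3),
                 spec$coords[as.integer(amax)])
  }
  # smoothing approximately conserves mass (frames well inside the domain)
  for (i in 1:4) {
    raw_i <- romt:::sphere_gaussian(0.8 * i, spec)
    fi <- make_sphere_frame(i, spec)
    expect_lt(abs(sum(fi) - sum(raw_i)) / sum(raw_i), 0.01)
  }
  # equal total mass across frames within 1%
  masses <- vapply(0:4, function(i) sum(make_sphere_frame(i, spec)),
                   numeric(1))
  expect_lt(max(abs(masses - masses[1]) / masses[1]), 0.01)
  expect_error(make_sphere_frame(5, spec), "frame index")
})

test_that("ground-truth intermediates interpolate the frame construction", {
  spec <- sphere_spec(scale = 0.5)
  m <- 10L
  # j -> 0 and j -> m limits reproduce the adjacent frames' construction
  g0 <- make_ground_truth(1, 0, m, spec)
  f1 <- make_sphere_frame(1, spec)
  expect_equal(as.numeric(g0), as.numeric(f1), tolerance = 1e-12)
  gm <- make_ground_truth(1, m, m, spec)
  f2 <- make_sphere_frame(2, spec)
  expect_equal(as.numeric(gm), as.numeric(f2), tolerance = 1e-12)
  # centers advance linearly by 0.8 / m per sub-step
  cent <- function(i, j) {
    arr <- make_ground_truth(i, j, m, spec)
    spec$coords[arrayInd(which.max(arr), dim(arr))[1]]
  }
  steps <- vapply(1:(m - 1), function(j) cent(1, j), numeric(1))
  expect_lt(max(abs(diff(steps) - 0.8 / m)), spec$step)
  expect_error(make_ground_truth(4, 1, m, spec), "loop index")
})

test_that("separable Gaussian filter blurs without losing interior mass", {
  set.seed(41)
  arr <- array(runif(12 * 11 * 10), dim = c(12, 11, 10))
  expect_identical(gaussian_filter3(arr, 0), arr)
  sm <- gaussian_filter3(arr, 1.5)
  expect_equal(dim(sm), dim(arr))
  # interior point mass keeps its total and its center of mass
  pm <- array(0, dim = c(15, 15, 15))
  pm[8, 8, 8] <- 3
  sm2 <- gaussian_filter3(pm, 1.2)
  expect_equal(sum(sm2), 3, tolerance = 1e-10)
  expect_equal(arrayInd(which.max(sm2), dim(sm2)), cbind(8L, 8L, 8L))
  # matches a brute-force direct convolution on a small 1D-like array
  a1 <- array(c(1, 0, 0, 2, 0, 0, 0, 1, 0, 0), dim = c(10, 1, 1))
  sd <- 0.8
  r <- ceiling(4 * sd)
  w <- dnorm(seq(-r, r), sd = sd); w <- w / sum(w)
  brute <- numeric(10)
  for (o in 1:10) for (t in seq(-r, r))
    brute[o] <- brute[o] + w[t + r + 1] * a1[min(max(o + t, 1), 10), 1, 1]
  expect_equal(as.numeric(gaussian_filter3(a1, sd)), brute, tolerance = 1e-12)
})

test_that("mse behaves as a mean squared difference", {
  a <- array(runif(24), dim = c(4, 3, 2))
  expect_identical(mse(a, a), 0)
  expect_equal(mse(a, a + 3), 9)
  expect_equal(mse(c(0, 0), c(1, 3)), 5)
  # invariant under a common voxel permutation; zero iff equal
  set.seed(42)
  p <- sample(24)
  b <- array(runif(24), dim = c(4, 3, 2))
  expect_equal(mse(a, b), mse(as.numeric(a)[p], as.numeric(b)[p]))
  expect_gt(mse(a, b), 0)
  expect_error(mse(a, 1:5), "shape mismatch")
})

test_that("accuracy curve pairs interpolations with their ground truths", {
  spec <- sphere_spec(base_size = 12)  # tiny grid: structure check only
  m <- 4L
  # feeding the ground truths themselves as interpolations gives all-zero MSE
  fake <- lapply(seq_len(spec$num_frames - 1L), function(i) {
    states <- vapply(0:m, function(j)
      as.numeric(make_ground_truth(i - 1L, j, m, spec)), numeric(12^3))
    list(states = states)
  })
  acc <- accuracy_curve(fake, spec, m)
  expect_equal(nrow(acc$curve), 4L * (m - 1L))
  expect_equal(max(acc$curve$mse), 0)
  expect_equal(acc$mean, 0)
  expect_error(accuracy_curve(fake[1:2], spec, m), "one result per")
})
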