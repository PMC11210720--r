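# A minimal solved-sequence stand-in: states/v prescribed analytically so the
# tracing contracts can be checked in closed form.
fake_result <- function(g, m, v_fun, rho_fun = function(i) rep(1, g$n)) {
  v <- vapply(seq_len(m), function(i) v_fun(i), numeric(3 * g$n))
  states <- vapply(seq_len(m + 1) - 1L, function(i) rho_fun(i),
                   numeric(g$n))
  structure(list(v = matrix(v, 3 * g$n, m),
                 states = matrix(states, g$n, m + 1)),
            class = "romt_solve")
}

test_that("augmented velocity reduces to v for sigma = 0 or uniform density", {
  g <- grid_spec(6, 5, 4)
  set.seed(31)
  v <- rnorm(3 * g$n)
  rho <- runif(g$n, 0.5, 2)
  expect_identical(augmented_velocity(rho, v, 0, g), v)
  expect_equal(augmented_velocity(rep(3, g$n), v, 0.5, g), v)
  # 1D exponential profile: grad log rho = a exactly under central differences
  a <- 0.3
  gx <- grid_spec(9, 1, 1)
  rho_exp <- exp(a * (1:9))
  vt <- augmented_velocity(rho_exp, rep(0, 27), 0.1, gx, eps_log = 1e-300)
  interior <- 2:8
  expect_equal(vt[interior], rep(-0.1 * a, 7), tolerance = 1e-10)
})

test_that("pathline tracing follows the Euler contract", {
  g <- grid_spec(8, 8, 8)
  cfg <- romt_config(m = 4, sigma = 0)
  seeds <- rbind(c(2, 2, 2), c(4.5, 3, 5))
  # v = 0, uniform rho: stationary at the seed
  res0 <- fake_result(g, cfg$m, function(i) rep(0, 3 * g$n))
  pl0 <- trace_pathlines(seeds, list(res0), g, cfg)
  expect_equal(pl0[[1]]$points[1, ], unname(seeds[1, ]))
  for (k in 1:2)
    expect_true(all(abs(pl0[[k]]$points -
                          matrix(seeds[k, ], cfg$m + 1, 3, byrow = TRUE))
                    < 1e-14))
  # constant field c: final point = seed + m * kt * c (Euler exact)
  cvec <- c(0.5, -0.25, 0.125)
  resc <- fake_result(g, cfg$m, function(i)
    c(rep(cvec[1], g$n), rep(cvec[2], g$n), rep(cvec[3], g$n)))
  plc <- trace_pathlines(seeds, list(resc), g, cfg)
  expect_equal(plc[[2]]$points[cfg$m + 1, ],
               unname(seeds[2, ]) + cfg$m * cfg$kt * cvec, tolerance = 1e-12)
  # seeds outside the domain are skipped with a warning
  expect_warning(pl_bad <- trace_pathlines(rbind(seeds, c(0, 4, 4)),
                                           list(res0), g, cfg),
                 "outside")
  expect_length(pl_bad, 2L)
})

test_that("speed and Peclet attributes sample the stated fields", {
  g <- grid_spec(8, 8, 8)
  cfg <- romt_config(m = 3, sigma = 0.1)
  seeds <- rbind(c(3, 3, 3))
  # constant v = (3, 4, 0): speed 5 everywhere
  res <- fake_result(g, cfg$m, function(i)
    c(rep(3, g$n), rep(4, g$n), rep(0, g$n)))
  pl <- trace_pathlines(seeds, list(res), g, cfg)
  pl <- attach_speed(pl, list(res), g, cfg)
  expect_equal(pl[[1]]$speeds, rep(5, cfg$m))
  # at a cell center the trilinear sample equals the voxel value
  set.seed(32)
  vr <- rnorm(3 * g$n)
  resr <- fake_result(g, cfg$m, function(i) vr)
  idx <- romt:::grid_flat_index(g, 4, 5, 6)
  vox_speed <- sqrt(vr[idx]^2 + vr[g$n + idx]^2 + vr[2 * g$n + idx]^2)
  cfg0 <- romt_config(m = 3, sigma = 0)
  pl1 <- trace_pathlines(rbind(c(4, 5, 6)), list(resr), g, cfg0)
  sp1 <- attach_speed(pl1, list(resr), g, cfg0)
  expect_equal(sp1[[1]]$speeds[1], vox_speed)
  # v = 0: Pe = 0; uniform rho: Pe capped
  res0 <- fake_result(g, cfg$m, function(i) rep(0, 3 * g$n))
  pl0 <- attach_peclet(trace_pathlines(seeds, list(res0), g, cfg),
                       list(res0), g, cfg)
  expect_equal(pl0[[1]]$peclets, rep(0, cfg$m))
  # uniform rho: denominator at the floor on the lines, cap on the map
  plu <- attach_peclet(trace_pathlines(seeds, list(res), g, cfg),
                       list(res), g, cfg)
  expect_equal(plu[[1]]$peclets, rep(5 / (cfg$sigma * cfg$eps_log), cfg$m))
  mapu <- rasterize_lines(plu, "peclet", g, pe_cap = cfg$pe_cap)
  expect_equal(unique(mapu[!is.na(mapu)]), cfg$pe_cap)
  # sigma = 0 makes Pe undefined
  expect_error(attach_peclet(pl, list(res), g, romt_config(m = 3, sigma = 0)),
               "undefined")
})

test_that("Peclet along an exponential density profile matches the closed form", {
  # rho = exp(a x): ||grad log rho|| = a, so Pe = s0 / (sigma a)
  g <- grid_spec(12, 3, 3)
  a <- 0.4
  sigma <- 0.05
  s0 <- 2
  m <- 2
  cfg <- romt_config(m = m, sigma = sigma, pe_cap = 1e6, kt = 0.1)
  rho_fun <- function(i) exp(a * romt:::grid_centers(g)[, 1])
  res <- fake_result(g, m, function(i)
    c(rep(s0, g$n), rep(0, g$n), rep(0, g$n)), rho_fun)
  pl <- trace_pathlines(rbind(c(5, 2, 2)), list(res), g, cfg)
  pl <- attach_peclet(pl, list(res), g, cfg)
  expect_equal(pl[[1]]$peclets, rep(s0 / (sigma * a), m), tolerance = 1e-6)
})

test_that("rasterization averages per nearest voxel with NA empties", {
  g <- grid_spec(5, 5, 5)
  cfg <- romt_config(m = 2, sigma = 0)
  res0 <- fake_result(g, cfg$m, function(i) rep(0, 3 * g$n))
  # one stationary line with constant speed: its voxel carries that value
  pl <- trace_pathlines(rbind(c(2, 3, 4)), list(res0), g, cfg)
  pl[[1]]$speeds <- c(5, 5)
  map <- rasterize_lines(pl, "speed", g)
  expect_equal(map[2, 3, 4], 5)
  expect_equal(sum(!is.na(map)), 1L)
  # two samples in one voxel average; brute-force dictionary oracle
  pl2 <- trace_pathlines(rbind(c(2, 3, 4), c(2.2, 3.1, 3.9)), list(res0),
                         g, cfg)
  pl2[[1]]$speeds <- c(4, 4)
  pl2[[2]]$speeds <- c(6, 6)
  map2 <- rasterize_lines(pl2, "speed", g)
  expect_equal(map2[2, 3, 4], 5)
  acc <- list()
  for (pl_k in pl2) for (t in 1:2) {
    key <- paste(round(pl_k$points[t, ]), collapse = ",")
    acc[[key]] <- c(acc[[key]], pl_k$speeds[t])
  }
  for (key in names(acc)) {
    ijk <- as.integer(strsplit(key, ",")[[1]])
    expect_equal(map2[ijk[1], ijk[2], ijk[3]], mean(acc[[key]]))
  }
  expect_error(rasterize_lines(pl, "peclet", g), "no 'peclet' attribute")
})

test_that("flux vectors connect pathline endpoints", {
  g <- grid_spec(8, 8, 8)
  cfg <- romt_config(m = 3, sigma = 0)
  cvec <- c(0.4, 0.2, -0.1)
  resc <- fake_result(g, cfg$m, function(i)
    c(rep(cvec[1], g$n), rep(cvec[2], g$n), rep(cvec[3], g$n)))
  res0 <- fake_result(g, cfg$m, function(i) rep(0, 3 * g$n))
  seeds <- rbind(c(3, 3, 3), c(4, 5, 6))
  fx <- flux_vectors(trace_pathlines(seeds, list(resc), g, cfg))
  expect_equal(nrow(fx), 2L)
  expect_equal(unlist(fx[1, c("dx", "dy", "dz")], use.names = FALSE),
               cfg$m * cfg$kt * cvec, tolerance = 1e-12)
  expect_equal(fx$length, rep(cfg$m * cfg$kt * sqrt(sum(cvec^2)), 2),
               tolerance = 1e-12)
  # stationary line: zero vector, zero length
  fx0 <- flux_vectors(trace_pathlines(seeds, list(res0), g, cfg))
  expect_equal(fx0$length, c(0, 0))
})

test_that("seed points threshold on the initial frame and respect masks", {
  g <- grid_spec(4, 4, 4)
  frame <- numeric(g$n)
  frame[romt:::grid_flat_index(g, 2, 2, 2)] <- 10
  frame[romt:::grid_flat_index(g, 3, 3, 3)] <- 0.5
  s <- seed_points(frame, g, threshold_frac = 0.1)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, ]), c(2, 2, 2))
  mask <- numeric(g$n)
  mask[romt:::grid_flat_index(g, 3, 3, 3)] <- 1
  s2 <- seed_points(frame, g, threshold_frac = 0.01, mask = mask)
  expect_equal(unname(s2[1, ]), c(3, 3, 3))
})
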