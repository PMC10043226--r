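test_that("coupling term matches hand values and the double-loop oracle", {
  # difference coupling vanishes at synchrony
  b <- build_base_network(6)
  expect_equal(coupling_term(rep(0.3, 6), b), rep(0, 6))
  # two nodes, direct substitution
  S2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(coupling_term(c(1, 0), S2), c(2, -2))
  # random 20-node instance against an explicit double loop
  set.seed(42)
  w <- matrix(runif(400), 20, 20); w <- (w + t(w)) / 2; diag(w) <- 0
  x1 <- rnorm(20)
  oracle <- vapply(1:20, function(i)
    sum(w[i, ] * (x1[i] - x1)), numeric(1))
  expect_equal(coupling_term(x1, w), oracle, tolerance = 1e-12)
})

test_that("a single uncoupled node reproduces the isolated integrator", {
  p <- model_params()
  init <- default_init()
  iso <- integrate_epileptor(p, x0 = -1.6, init = init, duration = 500,
                             dt = 0.05, save_every = 10)
  cfg <- network_run_config(duration = 500, dt = 0.05, seed = 1,
                            jitter = 0, save_every = 10)
  net <- simulate_network(matrix(0, 1, 1), -1.6, params = p, cfg = cfg,
                          init = matrix(init, nrow = 1))
  expect_equal(net$x1, iso$x1, tolerance = 1e-12)
  expect_equal(net$z, iso$z, tolerance = 1e-12)
})

test_that("identical nodes with identical starts stay synchronous forever", {
  S <- build_base_network(8)
  init <- matrix(rep(default_init(), each = 8), nrow = 8)
  cfg <- network_run_config(duration = 2000, dt = 0.05, seed = 1,
                            jitter = 0, save_every = 20)
  tr <- simulate_network(S, rep(-1.6, 8), cfg = cfg, init = init)
  for (k in 2:8) expect_identical(tr$x1[, k], tr$x1[, 1])
})

test_that("node relabeling permutes trajectories exactly", {
  n <- 6
  base <- build_base_network(n)
  fadj <- build_focal_adjacency(focal_topology(3, "regular", k = 2),
                                seed = 2)
  S <- embed_focal(base, fadj, 1:3, K = 10)
  x0 <- c(-1.6, -1.7, -1.65, -2.2, -2.2, -2.2)
  set.seed(99)
  init <- matrix(rep(default_init(), each = n), nrow = n) +
    matrix(runif(n * 6, -0.05, 0.05), n, 6)
  cfg <- network_run_config(duration = 3000, dt = 0.05, seed = 1,
                            jitter = 0, save_every = 20)
  perm <- c(4, 1, 6, 2, 5, 3)
  tr1 <- simulate_network(S$weights, x0, cfg = cfg, init = init)
  tr2 <- simulate_network(S$weights[perm, perm], x0[perm], cfg = cfg,
                          init = init[perm, ])
  # relabeling reorders the floating-point coupling sums, so agreement is
  # to summation-order rounding, not bitwise
  expect_equal(tr2$x1, tr1$x1[, perm], tolerance = 1e-12)
  expect_equal(tr2$z, tr1$z[, perm], tolerance = 1e-12)
})

test_that("zero coupling reduces every node to its isolated dynamics", {
  n <- 4
  x0 <- c(-1.6, -2.2, -1.8, -2.5)
  init <- matrix(rep(default_init(), each = n), nrow = n)
  cfg <- network_run_config(duration = 1000, dt = 0.05, seed = 1,
                            jitter = 0, save_every = 20)
  tr <- simulate_network(matrix(0, n, n), x0, cfg = cfg, init = init)
  for (k in 1:n) {
    iso <- integrate_epileptor(x0 = x0[k], duration = 1000, dt = 0.05,
                               save_every = 20)
    expect_equal(tr$x1[, k], iso$x1[, 1], tolerance = 1e-12)
  }
})

test_that("network runs are bit-reproducible and validate their inputs", {
  S <- build_base_network(5)
  cfg <- network_run_config(duration = 500, dt = 0.05, seed = 7)
  a <- simulate_network(S, rep(-1.6, 5), cfg = cfg)
  b <- simulate_network(S, rep(-1.6, 5), cfg = cfg)
  expect_identical(a$x1, b$x1)
  expect_error(simulate_network(S, rep(-1.6, 4), cfg = cfg), "length")
  expect_error(network_run_config(duration = 0.1, dt = 0.05),
               "duration")
  expect_error(network_run_config(noise_sigma = -1), "noise")
})

test_that("noise enters only through x2 and respects the seed", {
  S <- matrix(0, 2, 2)
  cfg <- function(s) network_run_config(duration = 200, dt = 0.05,
                                        seed = s, noise_sigma = 0.1,
                                        jitter = 0)
  a <- simulate_network(S, c(-2.2, -2.2), cfg = cfg(5))
  b <- simulate_network(S, c(-2.2, -2.2), cfg = cfg(5))
  c <- simulate_network(S, c(-2.2, -2.2), cfg = cfg(6))
  expect_identical(a$x2, b$x2)
  expect_false(identical(a$x2, c$x2))
  # the deterministic run differs from the noisy one
  d <- simulate_network(S, c(-2.2, -2.2),
                        cfg = network_run_config(duration = 200,
                                                 dt = 0.05, seed = 5,
                                                 jitter = 0))
  expect_false(identical(a$x2, d$x2))
})
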