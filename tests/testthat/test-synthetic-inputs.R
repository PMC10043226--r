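test_that("base network weights decay with ring distance", {
  b <- build_base_network(4)
  expect_equal(b$weights[1, 2], 1)
  expect_equal(b$weights[1, 3], 0.5)
  expect_equal(b$weights[1, 4], 1)
  big <- build_base_network(100)
  w <- big$weights
  expect_true(isSymmetric(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w[upper.tri(w)] > 0))
  expect_equal(min(w[upper.tri(w)]), 1 / 50)
  expect_error(build_base_network(1), "at least 2")
})

test_that("sparse random networks hit their binomial edge-count expectation", {
  n <- 100; dens <- 0.1; n_pairs <- n * (n - 1) / 2
  counts <- vapply(1:50, function(s) {
    g <- build_sparse_random_network(n, dens, seed = s)
    sum(g$weights[upper.tri(g$weights)] > 0)
  }, numeric(1))
  se <- sqrt(50 * n_pairs * dens * (1 - dens)) / 50
  expect_lt(abs(mean(counts) - dens * n_pairs), 3 * se)
  expect_identical(build_sparse_random_network(30, 0.2, seed = 7)$weights,
                   build_sparse_random_network(30, 0.2, seed = 7)$weights)
  expect_error(build_sparse_random_network(10, 0), "density")
  expect_error(build_sparse_random_network(10, 1), "density")
})

test_that("lattice focal families reduce correctly at the p extremes", {
  reg <- build_focal_adjacency(focal_topology(10, "regular", k = 2),
                               seed = 1)
  expect_true(all(rowSums(reg) == 2))
  sw0 <- build_focal_adjacency(focal_topology(10, "smallworld", p = 0,
                                              k = 2), seed = 5)
  expect_identical(sw0, reg)
  # Watts-Strogatz sweep: clustering collapses from lattice to random
  cc <- function(p) {
    mean(vapply(1:20, function(s) {
      a <- build_focal_adjacency(focal_topology(24, "smallworld", p = p,
                                                k = 4), seed = s)
      igraph::transitivity(igraph::graph_from_adjacency_matrix(
        a, mode = "undirected"))
    }, numeric(1)))
  }
  expect_gt(cc(0), cc(1))
})

test_that("scale-free focal graphs are heavy-tailed versus same-mean ER", {
  degs <- unlist(lapply(1:100, function(s) {
    a <- build_focal_adjacency(focal_topology(30, "scalefree",
                                              gamma_sf = 2.5), seed = s)
    rowSums(a)
  }))
  expect_true(all(degs >= 1))
  # log-log degree-frequency slope is negative
  tab <- table(degs)
  k <- as.numeric(names(tab))
  fit <- stats::lm(log(as.numeric(tab)) ~ log(k))
  expect_lt(unname(stats::coef(fit)[2]), 0)
  # variance exceeds an Erdos-Renyi graph with the same mean degree
  er_var <- mean(degs) * (1 - mean(degs) / 29)
  expect_gt(stats::var(degs), er_var)
})

test_that("focal graphs of every family are simple, symmetric and connected", {
  specs <- list(focal_topology(12, "regular", k = 4),
                focal_topology(12, "smallworld", p = 0.3, k = 4),
                focal_topology(12, "random", k = 4),
                focal_topology(12, "scalefree", gamma_sf = 2.2))
  for (spec in specs) for (s in 1:5) {
    a <- build_focal_adjacency(spec, seed = s)
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
    expect_true(all(a %in% c(0, 1)))
    if (spec$family %in% c("regular", "scalefree")) {
      # the ring lattice is connected by construction; the scale-free
      # generator enforces connectedness by reattaching stray components
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      expect_true(igraph::is_connected(g))
    }
    expect_identical(a, build_focal_adjacency(spec, seed = s))
  }
})

test_that("focal embedding makes lesion edges uniformly prominent", {
  base <- build_base_network(20)
  fadj <- build_focal_adjacency(focal_topology(5, "regular", k = 2),
                                seed = 3)
  emb <- embed_focal(base, fadj, 6:10, K = 10)
  expect_equal(emb$focal_indices, 6:10)
  w <- emb$weights
  # every embedded focal edge carries K * max(base)
  for (a in 1:5) for (b in 1:5) if (fadj[a, b] == 1)
    expect_equal(w[5 + a, 5 + b], 10 * max(base$weights))
  # prominence: embedded edges beat every other entry
  mask <- matrix(FALSE, 20, 20)
  mask[6:10, 6:10][fadj == 1] <- TRUE
  expect_gt(min(w[mask]), max(w[!mask & upper.tri(w)]))
  # the network stays fully connected
  expect_true(all(w[upper.tri(w)] > 0))
  # empty focal graph leaves the base untouched
  same <- embed_focal(base, matrix(0, 5, 5), 6:10, K = 10)
  expect_identical(same$weights, base$weights)
  expect_error(embed_focal(base, fadj, 18:22, K = 10), "range")
  expect_error(embed_focal(base, fadj, 6:10, K = 0.5), "K")
})

test_that("connectivity invariants are enforced across generated instances", {
  for (s in 1:5) {
    base <- build_base_network(15)
    fadj <- build_focal_adjacency(focal_topology(4, "smallworld", p = 0.5,
                                                 k = 2), seed = s)
    emb <- embed_focal(base, fadj, 1:4, K = 5 + s)
    w <- emb$weights
    expect_identical(w, t(w))
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0))
  }
  expect_error(connectivity_matrix(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
  expect_error(connectivity_matrix(matrix(c(1, 1, 1, 1), 2, 2)),
               "diagonal")
  expect_error(connectivity_matrix(matrix(c(0, -1, -1, 0), 2, 2)),
               "nonnegative")
})

test_that("excitability profiles respect the truncation constraint", {
  prof <- sample_x0(20, 1:5, mu = -1.6, sigma = 0.2, seed = 11)
  expect_true(all(prof$x0_values[1:5] > -2.05))
  expect_true(all(prof$x0_values[6:20] == -2.2))
  # degenerate normal: homogeneous focal nodes
  h <- sample_x0(10, 1:3, mu = -1.6, sigma = 0, seed = 1)
  expect_true(all(h$x0_values[1:3] == -1.6))
  # determinism
  expect_identical(sample_x0(20, 1:5, mu = -1.7, sigma = 0.1, seed = 4),
                   sample_x0(20, 1:5, mu = -1.7, sigma = 0.1, seed = 4))
  # inadmissible parameters rejected
  expect_error(sample_x0(10, 1:2, mu = -2.5, sigma = 0.1), "threshold")
  expect_error(sample_x0(10, 1:2, mu = -1.6, sigma = 0.1,
                         x0_nonfocal = -1.9), "below")
})

test_that("truncated-normal sample mean matches the quadrature oracle", {
  mu <- -1.6; sigma <- 0.1; thr <- -2.05
  # E[X | X > thr] for X ~ N(mu, sigma^2), by numerical quadrature
  num <- integrate(function(x) x * stats::dnorm(x, mu, sigma), thr,
                   Inf)$value
  den <- integrate(function(x) stats::dnorm(x, mu, sigma), thr,
                   Inf)$value
  oracle_mean <- num / den
  prof <- sample_x0(10001, 2:10001, mu = mu, sigma = sigma, seed = 99)
  draws <- prof$x0_values[2:10001]
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - oracle_mean), 3 * se)
})

test_that("rejection cap trips when mu is pinned against the threshold", {
  expect_error(sample_x0(4, 1:2, mu = -2.04, sigma = 1, seed = 1,
                         max_reject = 1), "cap")
})
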