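#' Connectivity matrix constructor
#'
#' Validates and wraps a symmetric nonnegative weight matrix with zero
#' diagonal as an `epi_connectivity` object, recording which nodes form
#' the focal (lesion) subnetwork and a global coupling scale applied to
#' all weights before simulation.
#'
#' @param weights symmetric nonnegative numeric matrix, zero diagonal.
#' @param focal_indices integer vector of focal node indices (1-based);
#'   may be empty.
#' @param global_scale multiplier applied to all weights at simulation
#'   time.
#' @return An `epi_connectivity` object.
#' @export
connectivity_matrix <- function(weights, focal_indices = integer(0),
                                global_scale = 1.0) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("diagonal must be exactly zero")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2  # exact symmetry
  focal_indices <- as.integer(focal_indices)
  if (length(focal_indices) &&
      (any(focal_indices < 1) || any(focal_indices > n) ||
       anyDuplicated(focal_indices)))
    stop("focal_indices out of range or duplicated")
  structure(list(n = n, weights = weights,
                 focal_indices = focal_indices,
                 global_scale = global_scale),
            class = "epi_connectivity")
}

#' @export
print.epi_connectivity <- function(x, ...) {
  cat(sprintf("Connectivity: %d nodes, %d focal, %d nonzero edges, scale %g\n",
              x$n, length(x$focal_indices),
              sum(x$weights[upper.tri(x$weights)] > 0), x$global_scale))
  invisible(x)
}

#' Fully connected base network with distance-decaying weights
#'
#' Nodes sit on a ring indexed `1..n`; the weight of every pair is the
#' reciprocal of their ring distance `d(i, j) = min(|i - j|, n - |i - j|)`,
#' so nearest neighbours couple at 1 and antipodal pairs at `2/n`.  A
#' different decay can be supplied through `weight_rule`, a function of
#' the integer distance.
#'
#' @param n node count, at least 2.
#' @param weight_rule function mapping ring distance (>= 1) to a weight;
#'   default `function(d) 1 / d`.
#' @return An `epi_connectivity` with no focal embedding.
#' @examples
#' b <- build_base_network(4)
#' b$weights[1, 2:4]   # 1, 0.5, 1
#' @export
build_base_network <- function(n, weight_rule = function(d) 1 / d) {
  if (!is.numeric(n) || n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  idx <- seq_len(n) - 1L
  d <- outer(idx, idx, function(i, j) pmin(abs(i - j), n - abs(i - j)))
  w <- matrix(0, n, n)
  off <- d > 0
  w[off] <- weight_rule(d[off])
  if (any(w[off] <= 0)) stop("weight_rule must return positive weights")
  connectivity_matrix(w)
}

#' Sparse Erdos-Renyi-style random network
#'
#' Each unordered node pair receives an edge independently with
#' probability `density`, all edges carrying the same uniform weight.
#' Reproducible under `seed`.
#'
#' @param n node count.
#' @param density edge probability, strictly between 0 and 1.
#' @param weight uniform weight of present edges.
#' @param seed RNG seed.
#' @return An `epi_connectivity`.
#' @export
build_sparse_random_network <- function(n, density, weight = 1.0, seed = 1L) {
  if (!is.numeric(density) || density <= 0 || density >= 1)
    stop("density must be strictly between 0 and 1")
  if (n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- weight * (runif(sum(ut)) < density)
  w <- w + t(w)
  connectivity_matrix(w)
}

#' Focal-subnetwork topology specification
#'
#' @param n_focal number of focal nodes, at least 2.
#' @param family `"regular"` (ring lattice), `"smallworld"`
#'   (Watts-Strogatz rewiring of the lattice with probability `p`),
#'   `"random"` (full rewiring, `p = 1`), or `"scalefree"` (power-law
#'   degree sequence with exponent `gamma_sf`).
#' @param p rewiring probability in \\[0, 1\\] for the lattice families.
#' @param gamma_sf power-law exponent (> 1) for the scale-free family.
#' @param k even mean degree of the ring substrate, `k < n_focal`.
#' @param strength_factor prominence multiplier K (> 1) used when the
#'   focal graph is embedded in a base network.
#' @return A `focal_topology` object.
#' @export
focal_topology <- function(n_focal, family = c("regular", "smallworld",
                                               "random", "scalefree"),
                           p = 0, gamma_sf = 2.5, k = 4,
                           strength_factor = 10) {
  family <- match.arg(family)
  if (n_focal < 2) stop("n_focal must be at least 2")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (k %% 2 != 0 || k < 2) stop("k must be an even degree >= 2")
  if (k >= n_focal) stop("k must be smaller than n_focal")
  if (strength_factor <= 1) stop("strength_factor must exceed 1")
  if (family == "scalefree" && gamma_sf <= 1)
    stop("gamma_sf must exceed 1")
  if (family == "random") p <- 1
  if (family == "regular") p <- 0
  structure(list(n_focal = as.integer(n_focal), family = family, p = p,
                 gamma_sf = gamma_sf, k = as.integer(k),
                 strength_factor = strength_factor),
            class = "focal_topology")
}

# Power-law degree sequence with minimum degree 1, resampled until the sum
# is even and the sequence is graphical enough for simple-graph realization.
sample_powerlaw_degrees <- function(n, gamma_sf, max_deg) {
  ks <- seq_len(max_deg)
  pk <- ks^(-gamma_sf)
  pk <- pk / sum(pk)
  sample(ks, n, replace = TRUE, prob = pk)
}

#' Generate the unweighted focal adjacency
#'
#' Builds the focal subnetwork's adjacency matrix for any
#' [focal_topology()] family.  The lattice families use Watts-Strogatz
#' rewiring (p = 0 reproduces the ring lattice edge-for-edge; p = 1 is
#' fully random); the scale-free family draws a power-law degree sequence
#' with exponent `gamma_sf` (minimum degree 1) and realizes it as a simple
#' graph, reconnecting any disconnected component to a random node so the
#' result is connected.
#'
#' @param spec a [focal_topology()] object.
#' @param seed RNG seed.
#' @return Binary symmetric adjacency matrix (`n_focal` x `n_focal`).
#' @export
build_focal_adjacency <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "focal_topology"))
  set.seed(seed)
  n <- spec$n_focal
  if (spec$family %in% c("regular", "smallworld", "random")) {
    g <- igraph::sample_smallworld(dim = 1, size = n, nei = spec$k / 2,
                                   p = spec$p, loops = FALSE,
                                   multiple = FALSE)
    g <- igraph::simplify(g)
  } else {
    max_deg <- max(2L, n - 1L)
    degs <- NULL
    for (attempt in seq_len(1000)) {
      cand <- sample_powerlaw_degrees(n, spec$gamma_sf, max_deg)
      if (sum(cand) %% 2 == 1) cand[which.min(cand)] <- cand[which.min(cand)] + 1L
      if (igraph::is_graphical(cand)) { degs <- cand; break }
    }
    if (is.null(degs))
      stop("could not realize a graphical power-law degree sequence")
    g <- igraph::sample_degseq(degs, method = "configuration")
    g <- igraph::simplify(g)
    # reconnect any stray components to a node of the largest one
    comp <- igraph::components(g)
    if (comp$no > 1) {
      main <- which.max(comp$csize)
      anchors <- which(comp$membership == main)
      for (cid in setdiff(seq_len(comp$no), main)) {
        from <- which(comp$membership == cid)[1]
        g <- igraph::add_edges(g, c(from, sample(anchors, 1)))
      }
    }
  }
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a[a > 0] <- 1
  dimnames(a) <- NULL
  a
}

#' Embed a focal subnetwork prominently in a base network
#'
#' Copies the base network and overwrites every focal edge with the
#' uniform prominent weight `K * max(base weights)`, leaving every other
#' entry untouched, so the network stays fully connected while the lesion
#' edges dominate all others.
#'
#' @param base an `epi_connectivity` base network.
#' @param focal_adj binary adjacency of the focal subnetwork.
#' @param focal_indices which base nodes the focal graph occupies (length
#'   equal to `nrow(focal_adj)`).
#' @param K prominence multiplier (> 1).
#' @return An `epi_connectivity` with `focal_indices` recorded.
#' @export
embed_focal <- function(base, focal_adj, focal_indices, K = 10) {
  stopifnot(inherits(base, "epi_connectivity"))
  focal_adj <- as.matrix(focal_adj)
  m <- nrow(focal_adj)
  if (ncol(focal_adj) != m) stop("focal_adj must be square")
  focal_indices <- as.integer(focal_indices)
  if (length(focal_indices) != m)
    stop("focal_indices length must match focal_adj")
  if (any(focal_indices < 1) || any(focal_indices > base$n))
    stop("focal index out of range")
  if (K <= 1) stop("K must exceed 1")
  w <- base$weights
  prominent <- K * max(w)
  edges <- which(focal_adj != 0 & upper.tri(focal_adj), arr.ind = TRUE)
  if (nrow(edges)) {
    ii <- focal_indices[edges[, 1]]
    jj <- focal_indices[edges[, 2]]
    w[cbind(ii, jj)] <- prominent
    w[cbind(jj, ii)] <- prominent
  }
  connectivity_matrix(w, focal_indices = focal_indices,
                      global_scale = base$global_scale)
}

#' Sample a truncated-normal excitability profile
#'
#' Focal nodes draw epileptogenicity values i.i.d. from
#' \eqn{N(\mu, \sigma^2)} truncated below at the seizure threshold
#' (rejection sampling, so every focal node is suprathreshold); non-focal
#' nodes share the healthy value `x0_nonfocal`.  With `sigma = 0` the
#' focal nodes are homogeneous at `mu`.
#'
#' @param n_total total node count.
#' @param focal_indices focal node indices (1-based).
#' @param mu mean of the focal distribution; must exceed the threshold.
#' @param sigma standard deviation (>= 0).
#' @param x0_nonfocal healthy value; must lie below the threshold.
#' @param params an [model_params()] (supplies `x_threshold`).
#' @param seed RNG seed.
#' @param max_reject rejection cap per draw; exceeded when `mu` sits too
#'   close to the threshold for the requested `sigma`.
#' @return An `epi_excitability` object with fields `x0_values`,
#'   `focal_indices`, `mu`, `sigma`, `x0_nonfocal`.
#' @export
sample_x0 <- function(n_total, focal_indices, mu, sigma, x0_nonfocal = -2.2,
                      params = model_params(), seed = 1L,
                      max_reject = 1e4) {
  thr <- params$x_threshold
  if (!is.finite(mu) || mu <= thr)
    stop("mu must exceed the seizure threshold")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(x0_nonfocal) || x0_nonfocal >= thr)
    stop("x0_nonfocal must lie below the seizure threshold")
  focal_indices <- as.integer(focal_indices)
  if (any(focal_indices < 1) || any(focal_indices > n_total))
    stop("focal index out of range")
  set.seed(seed)
  x0 <- rep(x0_nonfocal, n_total)
  for (i in focal_indices) {
    if (sigma == 0) { x0[i] <- mu; next }
    ok <- FALSE
    for (draw in seq_len(max_reject)) {
      v <- rnorm(1, mu, sigma)
      if (v > thr) { x0[i] <- v; ok <- TRUE; break }
    }
    if (!ok)
      stop("rejection cap exceeded: mu is too close to the threshold for this sigma")
  }
  structure(list(x0_values = x0, focal_indices = focal_indices,
                 mu = mu, sigma = sigma, x0_nonfocal = x0_nonfocal),
            class = "epi_excitability")
}

#' @export
print.epi_excitability <- function(x, ...) {
  cat(sprintf("Excitability profile: %d nodes, %d focal (mu = %g, sigma = %g), healthy x0 = %g\n",
              length(x$x0_values), length(x$focal_indices), x$mu, x$sigma,
              x$x0_nonfocal))
  invisible(x)
}
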