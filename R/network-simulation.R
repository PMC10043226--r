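#' Permittivity coupling term
#'
#' The difference coupling a node receives through the permittivity
#' variable: \eqn{\sum_j S_{ij} (x_{1,i} - x_{1,j})}, equal to
#' `rowSums(S) * x1 - S %*% x1` but summed in difference form so that a
#' synchronized state yields exactly zero for every node.
#'
#' @param x1_all numeric vector of per-node fast-variable values.
#' @param weights an `epi_connectivity` or a plain weight matrix.
#' @return Numeric vector of per-node coupling sums.
#' @export
coupling_term <- function(x1_all, weights) {
  S <- if (inherits(weights, "epi_connectivity")) weights$weights else
    as.matrix(weights)
  stopifnot(length(x1_all) == nrow(S))
  rowSums(S * outer(x1_all, x1_all, `-`))
}

#' Network run configuration
#'
#' @param duration total simulated time (model units); at least `10 * dt`.
#' @param dt integration step.
#' @param seed RNG seed governing initial-condition jitter and (if on)
#'   noise.
#' @param noise_sigma additive Gaussian noise scale on the x2 equation,
#'   applied Euler-Maruyama style after the deterministic RK4 step; 0
#'   (default) keeps the run fully deterministic.
#' @param jitter half-width of the uniform per-node initial-condition
#'   jitter that breaks symmetry between identical nodes.
#' @param save_every keep every `save_every`-th integration step.
#' @return A `network_run_config` list.
#' @export
network_run_config <- function(duration = 6 * 2857, dt = 0.05, seed = 1L,
                               noise_sigma = 0, jitter = 0.05,
                               save_every = 20L) {
  if (duration < 10 * dt) stop("duration must be at least 10 * dt")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (jitter < 0) stop("jitter must be >= 0")
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 noise_sigma = noise_sigma, jitter = jitter,
                 save_every = as.integer(save_every)),
            class = "network_run_config")
}

#' Simulate a coupled Epileptor network
#'
#' Integrates the whole-brain system: every node runs the six-variable
#' Epileptor, and the nodes interact through the permittivity variable z
#' by difference coupling on the fast variable x1.  Integration is
#' fixed-step RK4 with the coupling vector recomputed at every substage;
#' with `noise_sigma = 0` the run is exact RK4 and bit-reproducible under
#' `(seed, dt)`.
#'
#' Under the default `"spread"` convention a seizing neighbour lowers a
#' node's permittivity, pulling it towards seizure onset, which is what
#' lets focal nodes recruit healthy tissue with a delay;
#' `"printed"` flips the coupling sign in the z-equation (see the methods
#' vignette).
#'
#' @param weights an `epi_connectivity` (its `global_scale` multiplies all
#'   weights) or plain matrix.
#' @param profile an `epi_excitability` from [sample_x0()], or a numeric
#'   vector of per-node x0 values.
#' @param params an [model_params()] object.
#' @param cfg a [network_run_config()].
#' @param init either `NULL` (default init plus seeded jitter) or an
#'   `n x 6` matrix of exact initial states (jitter is then skipped).
#' @param coupling_convention `"spread"` (default) or `"printed"`.
#' @param g_input,f2_branch_on model conventions, see
#'   [epileptor_derivatives()].
#' @return An `epi_trajectory` with one column per node.
#' @export
simulate_network <- function(weights, profile, params = model_params(),
                             cfg = network_run_config(), init = NULL,
                             coupling_convention = c("spread", "printed"),
                             g_input = c("x1", "x2"),
                             f2_branch_on = c("x1", "x2")) {
  coupling_convention <- match.arg(coupling_convention)
  g_input <- match.arg(g_input)
  f2_branch_on <- match.arg(f2_branch_on)
  if (inherits(weights, "epi_connectivity")) {
    S <- weights$weights * weights$global_scale
  } else {
    S <- as.matrix(weights)
  }
  n <- nrow(S)
  x0 <- if (inherits(profile, "epi_excitability")) profile$x0_values else
    as.numeric(profile)
  if (length(x0) != n)
    stop("profile length does not match the connectivity matrix")
  stopifnot(inherits(cfg, "network_run_config"))

  set.seed(cfg$seed)
  if (is.null(init)) {
    base <- matrix(rep(default_init(), each = n), nrow = n)
    if (cfg$jitter > 0)
      base <- base + matrix(runif(n * 6, -cfg$jitter, cfg$jitter), n, 6)
    init <- base
  } else {
    init <- as.matrix(init)
    if (nrow(init) != n || ncol(init) != 6)
      stop("init must be an n x 6 matrix")
  }

  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  raw <- rk4_network_cpp(S, x0, init, cfg$dt, n_steps, cfg$save_every,
                         params$I1, params$I2, params$tau0, params$tau2,
                         params$gamma_filter,
                         coupling_sign = if (coupling_convention ==
                                             "spread") -1L else 1L,
                         g_from_x2 = (g_input == "x2"),
                         f2_on_x2 = (f2_branch_on == "x2"),
                         noise_sigma = cfg$noise_sigma, guard = 1e6)
  new_trajectory(raw, cfg$dt * cfg$save_every, x0, params,
                 meta = list(kind = "network", cfg = cfg,
                             coupling_convention = coupling_convention,
                             focal_indices = if (inherits(profile,
                                                          "epi_excitability"))
                               profile$focal_indices else integer(0)))
}
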