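#' @title Trajectory container
#' @description Internal constructor for the `epi_trajectory` class: time
#'   samples plus one matrix per state variable (samples in rows, nodes in
#'   columns).  `dt` is the spacing of the *saved* samples, which equals
#'   the integration step times `save_every`.
#' @noRd
new_trajectory <- function(raw, dt_out, x0, params, meta = list()) {
  traj <- list(times = as.numeric(raw$times),
               x1 = raw$x1, y1 = raw$y1, z = raw$z,
               x2 = raw$x2, y2 = raw$y2, g = raw$g,
               dt = dt_out, n = ncol(raw$x1), x0 = x0,
               params = params, meta = meta)
  class(traj) <- "epi_trajectory"
  traj
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf("Epileptor trajectory: %d node(s), %d samples, dt = %g, t in [%g, %g]\n",
              x$n, length(x$times), x$dt, x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Integrate an isolated Epileptor oscillator
#'
#' Classic fixed-step fourth-order Runge-Kutta integration of the single
#' (uncoupled) oscillator.  Deterministic: identical inputs reproduce
#' bit-identical trajectories.
#'
#' @param params an [model_params()] object.
#' @param x0 epileptogenicity of the node.
#' @param init named initial state (defaults to [default_init()]).
#' @param duration total integration time in model units; must be at least
#'   `dt`.
#' @param dt integration step in model time units; must be positive.
#' @param save_every keep every `save_every`-th step (plus the initial
#'   state); 1 keeps the full-resolution path.
#' @param g_input,f2_branch_on model conventions, see
#'   [epileptor_derivatives()].
#' @return An `epi_trajectory` with `n = 1`.
#' @examples
#' tr <- integrate_epileptor(x0 = -2.5, duration = 50, dt = 0.05)
#' range(tr$x1)
#' @export
integrate_epileptor <- function(params = model_params(), x0,
                                init = default_init(), duration,
                                dt = 0.05, save_every = 1L,
                                g_input = c("x1", "x2"),
                                f2_branch_on = c("x1", "x2")) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(duration) || duration < dt)
    stop("duration must be at least dt")
  g_input <- match.arg(g_input)
  f2_branch_on <- match.arg(f2_branch_on)
  init <- as_state(init)
  n_steps <- as.integer(round(duration / dt))
  raw <- rk4_network_cpp(matrix(0, 1, 1), x0,
                         matrix(init, nrow = 1), dt, n_steps,
                         as.integer(save_every),
                         params$I1, params$I2, params$tau0, params$tau2,
                         params$gamma_filter, coupling_sign = -1L,
                         g_from_x2 = (g_input == "x2"),
                         f2_on_x2 = (f2_branch_on == "x2"),
                         noise_sigma = 0, guard = 1e6)
  new_trajectory(raw, dt * save_every, x0, params,
                 meta = list(kind = "single", dt_integration = dt))
}

#' Seizure-like-event observable
#'
#' The electrographic readout of a trajectory, combining the two fast
#' variables.  Under the default `"paper"` convention this is `x1 + x2`;
#' `"inverted"` gives `-x1 + x2`, the convention of the original model
#' literature.
#'
#' @param traj an `epi_trajectory`.
#' @param convention `"paper"` or `"inverted"`.
#' @return Numeric matrix (samples x nodes) of the SLE signal.
#' @export
sle_signal <- function(traj, convention = c("paper", "inverted")) {
  stopifnot(inherits(traj, "epi_trajectory"))
  if (length(traj$times) == 0) stop("empty trajectory")
  convention <- match.arg(convention)
  if (convention == "paper") traj$x1 + traj$x2 else -traj$x1 + traj$x2
}

post_transient_rows <- function(traj, transient_fraction) {
  n_samp <- length(traj$times)
  first <- floor(n_samp * transient_fraction) + 1L
  if (first >= n_samp) stop("trajectory too short for the requested transient")
  seq.int(first, n_samp)
}

#' Classify a node's dynamical regime
#'
#' A node is `"oscillatory"` if, after discarding an initial transient,
#' the peak-to-peak range of its fast variable `x1` exceeds `amp_tol`;
#' otherwise `"quiescent"`.  The default tolerance 1.0 sits well below the
#' ictal/interictal x1 excursion (order 2) and well above fixed-point
#' wobble.
#'
#' @param traj an `epi_trajectory` (single- or multi-node).
#' @param transient_fraction fraction of the samples discarded from the
#'   start before measuring amplitude.
#' @param amp_tol peak-to-peak threshold on `x1`.
#' @return Character vector, one of `"oscillatory"`/`"quiescent"` per node.
#' @export
classify_regime <- function(traj, transient_fraction = 1 / 6,
                            amp_tol = 1.0) {
  stopifnot(inherits(traj, "epi_trajectory"))
  if (length(traj$times) < 10) stop("trajectory too short to classify")
  rows <- post_transient_rows(traj, transient_fraction)
  x1 <- traj$x1[rows, , drop = FALSE]
  ptp <- apply(x1, 2, function(v) diff(range(v)))
  ifelse(ptp > amp_tol, "oscillatory", "quiescent")
}

#' Locate the epileptogenicity threshold by bisection
#'
#' Bisects on `x0` between a quiescent and an oscillatory probe, running a
#' long single-node simulation at each midpoint and classifying the
#' post-transient regime.  The bracket is validated at both ends and the
#' quiescent/oscillatory straddle is maintained at every step.
#'
#' @param params an [model_params()] object.
#' @param lo,hi bracket endpoints; `lo` must classify quiescent and `hi`
#'   oscillatory.
#' @param tol bisection tolerance on `x0`; must be positive.
#' @param duration simulation length per probe (default `6 * tau0`).
#' @param dt integration step.
#' @param transient_fraction,amp_tol passed to [classify_regime()].
#' @param trace if `TRUE` the returned value carries a `"trace"` attribute
#'   with the probe history (x0, regime per probe).
#' @return The threshold estimate (midpoint of the final bracket).
#' @export
find_threshold <- function(params = model_params(), lo = -2.5, hi = -1.6,
                           tol = 0.01, duration = 6 * params$tau0,
                           dt = 0.05, transient_fraction = 1 / 6,
                           amp_tol = 1.0, trace = FALSE) {
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  if (lo >= hi) stop("need lo < hi")
  probe <- function(x0) {
    tr <- integrate_epileptor(params, x0, duration = duration, dt = dt,
                              save_every = 20L)
    classify_regime(tr, transient_fraction, amp_tol)
  }
  r_lo <- probe(lo); r_hi <- probe(hi)
  if (r_lo != "quiescent" || r_hi != "oscillatory")
    stop(sprintf(
      "bracket does not straddle the transition: lo (%.3f) is %s, hi (%.3f) is %s",
      lo, r_lo, hi, r_hi))
  hist <- list(list(x0 = lo, regime = r_lo), list(x0 = hi, regime = r_hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r_mid <- probe(mid)
    hist[[length(hist) + 1L]] <- list(x0 = mid, regime = r_mid)
    if (r_mid == "quiescent") lo <- mid else hi <- mid
  }
  est <- (lo + hi) / 2
  if (trace) {
    tr_df <- data.frame(x0 = vapply(hist, `[[`, numeric(1), "x0"),
                        regime = vapply(hist, `[[`, character(1), "regime"))
    attr(est, "trace") <- tr_df
  }
  est
}
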