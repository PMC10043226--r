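#' Epileptor model parameters
#'
#' Constants of the five-variable Epileptor neural-mass model plus the
#' auxiliary low-pass state `g`.  Defaults are the model's standard values:
#' external currents `I1 = 3.1` and `I2 = 0.45`, permittivity timescale
#' `tau0 = 2857`, second-subsystem timescale `tau2 = 10`, and memory-kernel
#' decay constant `gamma_filter = 0.01`.  `x_threshold` is the critical
#' epileptogenicity: nodes with `x0` above it seize autonomously.
#'
#' @param I1 external current of the fast subsystem (dimensionless).
#' @param I2 external current of the slow subsystem.
#' @param tau0 timescale of the permittivity variable `z`; must be positive.
#' @param tau2 timescale of the second subsystem; must be positive.
#' @param gamma_filter decay constant of the exponential memory kernel
#'   realized by the auxiliary state `g`; must be positive.
#' @param x_threshold critical epileptogenicity value separating the
#'   quiescent from the seizing regime.
#' @return An object of class `epi_params`: a named list of the six
#'   constants.
#' @examples
#' p <- model_params()
#' p$tau0
#' @export
model_params <- function(I1 = 3.1, I2 = 0.45, tau0 = 2857, tau2 = 10,
                         gamma_filter = 0.01, x_threshold = -2.05) {
  stopifnot(is.finite(I1), is.finite(I2), is.finite(x_threshold))
  if (!is.finite(tau0) || tau0 <= 0) stop("tau0 must be positive")
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be positive")
  if (!is.finite(gamma_filter) || gamma_filter <= 0)
    stop("gamma_filter must be positive")
  structure(list(I1 = I1, I2 = I2, tau0 = tau0, tau2 = tau2,
                 gamma_filter = gamma_filter, x_threshold = x_threshold),
            class = "epi_params")
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epileptor parameters:\n")
  cat(sprintf("  I1 = %g, I2 = %g, tau0 = %g, tau2 = %g, gamma = %g\n",
              x$I1, x$I2, x$tau0, x$tau2, x$gamma_filter))
  cat(sprintf("  x_threshold = %g\n", x$x_threshold))
  invisible(x)
}

state_names <- c("x1", "y1", "z", "x2", "y2", "g")

#' Default Epileptor initial state
#'
#' A conventional resting start: the fast variable on the interictal branch
#' (`x1 = -1.6`), the permittivity variable inside the bistable range
#' (`z = 3.0`), and the memory filter empty (`g = 0`).
#'
#' @return Named numeric vector of length 6 in the order
#'   `x1, y1, z, x2, y2, g`.
#' @export
default_init <- function() {
  c(x1 = -1.6, y1 = -10, z = 3.0, x2 = -0.6, y2 = 0, g = 0)
}

as_state <- function(x) {
  if (is.null(names(x))) {
    stopifnot(length(x) == 6L)
    names(x) <- state_names
  }
  stopifnot(all(state_names %in% names(x)), all(is.finite(x)))
  x[state_names]
}

#' Fast-subsystem cubic nonlinearity f1
#'
#' Piecewise nonlinearity of the fast subsystem: `x1^3 - 3*x1^2` on the
#' interictal branch (`x1 < 0`) and `(x2 - 0.6*(z - 4)^2) * x1` on the
#' ictal branch (`x1 >= 0`).
#'
#' @param x1,x2,z finite numeric values (vectorized).
#' @return Numeric value(s) of f1.
#' @examples
#' f1(-1, 0, 0)   # -4
#' @export
f1 <- function(x1, x2, z) {
  if (!all(is.finite(x1), is.finite(x2), is.finite(z)))
    stop("f1: inputs must be finite")
  ifelse(x1 < 0, x1^3 - 3 * x1^2, (x2 - 0.6 * (z - 4)^2) * x1)
}

#' Slow-subsystem nonlinearity f2
#'
#' Returns 0 below the branch point and `6 * (x2 + 0.25)` at or above it.
#' The branch condition is evaluated on `x1` by default; set
#' `branch_on = "x2"` to condition on `x2` instead (both conventions occur
#' in the model literature).
#'
#' @param x1,x2 finite numeric values (vectorized).
#' @param branch_on which variable the `-0.25` branch condition tests.
#' @return Numeric value(s) of f2.
#' @examples
#' f2(0, 0.75)  # 6
#' @export
f2 <- function(x1, x2, branch_on = c("x1", "x2")) {
  if (!all(is.finite(x1), is.finite(x2)))
    stop("f2: inputs must be finite")
  branch_on <- match.arg(branch_on)
  bv <- if (branch_on == "x1") x1 else x2
  ifelse(bv < -0.25, 0, 6 * (x2 + 0.25))
}

#' Instantaneous Epileptor derivatives
#'
#' Right-hand side of the six-dimensional per-node system, in R.  This is
#' the reference implementation used for fixed-point analysis and for
#' cross-checking the compiled integrator; the integrators themselves run
#' the same equations in C++.
#'
#' `coupling` is the precomputed permittivity-coupling term
#' \eqn{\sum_j S_{ij} (x_{1,i} - x_{1,j})} (0 for an isolated node).  Its
#' sign in the z-equation follows `coupling_sign`: `-1` (default, the
#' "spread" convention under which seizing neighbours pull a node's
#' permittivity down towards seizure onset) gives
#' \eqn{\dot z = (4(x_1 - x_0) - z + c)/\tau_0}; `+1` gives the
#' opposite sign.  See the methods vignette for why the spread convention
#' is the default.
#'
#' @param state named numeric state vector (`x1, y1, z, x2, y2, g`).
#' @param params an [model_params()] object.
#' @param x0 the node's epileptogenicity.
#' @param coupling the precomputed coupling sum (default 0).
#' @param coupling_sign `-1` or `+1`, see above.
#' @param g_input which variable feeds the memory filter, `"x1"` (default)
#'   or `"x2"`.
#' @param f2_branch_on branch-condition variable for [f2()].
#' @return Named numeric vector of the six derivatives.
#' @export
epileptor_derivatives <- function(state, params = model_params(), x0,
                                  coupling = 0, coupling_sign = -1L,
                                  g_input = c("x1", "x2"),
                                  f2_branch_on = c("x1", "x2")) {
  s <- as_state(state)
  stopifnot(is.finite(x0), is.finite(coupling),
            coupling_sign %in% c(-1L, 1L))
  g_input <- match.arg(g_input)
  f2_branch_on <- match.arg(f2_branch_on)
  x1 <- s[["x1"]]; y1 <- s[["y1"]]; z <- s[["z"]]
  x2 <- s[["x2"]]; y2 <- s[["y2"]]; g <- s[["g"]]
  c(x1 = y1 - f1(x1, x2, z) - z + params$I1,
    y1 = 1 - 5 * x1^2 - y1,
    z  = (4 * (x1 - x0) - z - coupling_sign * coupling) / params$tau0,
    x2 = -y2 + x2 - x2^3 + params$I2 + 0.002 * g - 0.3 * (z - 3.5),
    y2 = (-y2 + f2(x1, x2, branch_on = f2_branch_on)) / params$tau2,
    g  = (if (g_input == "x1") x1 else x2) - params$gamma_filter * g)
}
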