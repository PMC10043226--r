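test_that("piecewise nonlinearities follow their branch definitions", {
  # f1: cubic branch below 0, gated product at and above 0
  expect_equal(f1(-1, 0, 0), -4)
  expect_equal(f1(0, 3, 7), 0)
  expect_equal(f1(1, 0.5, 4), 0.5)
  expect_equal(f1(2, 1, 3), (1 - 0.6) * 2)
  # f2: zero below the branch point, linear above
  expect_equal(f2(-1, 5), 0)
  expect_equal(f2(0, -0.25), 0)
  expect_equal(f2(0, 0.75), 6)
  # branch condition switchable to x2
  expect_equal(f2(x1 = 5, x2 = -1, branch_on = "x2"), 0)
  expect_equal(f2(x1 = -1, x2 = 0.75, branch_on = "x2"), 6)
  expect_error(f1(NaN, 0, 0), "finite")
  expect_error(f2(Inf, 0), "finite")
})

test_that("derivatives match hand values and filter steady state", {
  p <- model_params()
  d0 <- epileptor_derivatives(rep(0, 6), p, x0 = 0)
  expect_equal(unname(d0["y1"]), 1)  # 1 - 0 - 0
  # g is the linear filter dg/dt = x1 - gamma * g: steady state c / gamma
  c_val <- 0.7
  st <- c(x1 = c_val, y1 = 0, z = 0, x2 = 0, y2 = 0,
          g = c_val / p$gamma_filter)
  expect_equal(unname(epileptor_derivatives(st, p, x0 = 0)["g"]), 0)
})

test_that("derivatives vanish at a numerically located fixed point", {
  skip_if_not_installed("pracma")
  p <- model_params()
  rhs <- function(v) unname(epileptor_derivatives(v, p, x0 = -3))
  # start near the quiescent branch and polish with a root finder oracle
  sol <- pracma::fsolve(rhs, c(-1.8, -15, 2.9, -1.1, 0, -180))
  expect_lt(max(abs(rhs(sol$x))), 1e-8)
})

test_that("auxiliary filter state equals the exponential-kernel quadrature", {
  # g(t) = int_0^t exp(-gamma (t - s)) x1(s) ds, evaluated by trapezoid
  p <- model_params()
  dt <- 0.05
  tr <- integrate_epileptor(p, x0 = -1.6, duration = 200, dt = dt)
  x1 <- tr$x1[, 1]
  tt <- tr$times
  gamma <- p$gamma_filter
  kern <- exp(-gamma * (tt[length(tt)] - tt))
  integrand <- kern * x1
  quad <- dt * (sum(integrand) - (integrand[1] + integrand[length(tt)]) / 2)
  expect_equal(tr$g[length(tt), 1], quad, tolerance = 10 * dt^2)
})

test_that("integration converges at fourth order under step halving", {
  p <- model_params()
  endpoint <- function(dt) {
    tr <- integrate_epileptor(p, x0 = -1.6, duration = 10, dt = dt)
    c(tr$x1[nrow(tr$x1), 1], tr$y1[nrow(tr$y1), 1], tr$z[nrow(tr$z), 1],
      tr$x2[nrow(tr$x2), 1], tr$y2[nrow(tr$y2), 1], tr$g[nrow(tr$g), 1])
  }
  e1 <- endpoint(0.05); e2 <- endpoint(0.025); e3 <- endpoint(0.0125)
  ratio <- sqrt(sum((e1 - e2)^2)) / sqrt(sum((e2 - e3)^2))
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("integrator guards against blow-up and bad steps", {
  expect_error(integrate_epileptor(x0 = -1.6, duration = 1, dt = -0.1),
               "dt")
  expect_error(integrate_epileptor(x0 = -1.6, duration = 0.01, dt = 0.05),
               "duration")
  # an absurd initial condition diverges and must be reported, not returned
  bad <- c(x1 = 500, y1 = 0, z = 0, x2 = 0, y2 = 0, g = 0)
  expect_error(integrate_epileptor(x0 = -1.6, init = bad, duration = 5,
                                   dt = 0.05),
               "blow-up")
})

test_that("trajectories are bit-identical under identical inputs", {
  a <- integrate_epileptor(x0 = -1.6, duration = 100, dt = 0.05)
  b <- integrate_epileptor(x0 = -1.6, duration = 100, dt = 0.05)
  expect_identical(a$x1, b$x1)
  expect_identical(a$g, b$g)
})

test_that("SLE observable supports both sign conventions", {
  tr <- fake_trajectory(matrix(1, 50, 1))
  tr$x2 <- matrix(2, 50, 1)
  expect_equal(unique(as.numeric(sle_signal(tr, "paper"))), 3)
  expect_equal(unique(as.numeric(sle_signal(tr, "inverted"))), 1)
  z <- fake_trajectory(matrix(0, 50, 1))
  expect_true(all(sle_signal(z) == 0))
})

test_that("regime classification separates seizing from quiescent x0", {
  p <- model_params()
  osc <- integrate_epileptor(p, x0 = -1.6, duration = 6 * p$tau0,
                             dt = 0.05, save_every = 20)
  qui <- integrate_epileptor(p, x0 = -2.5, duration = 6 * p$tau0,
                             dt = 0.05, save_every = 20)
  expect_equal(unname(classify_regime(osc)), "oscillatory")
  expect_equal(unname(classify_regime(qui)), "quiescent")
  # post-transient amplitude of the quiescent run is genuinely tiny
  expect_lt(diff(range(qui$x1[-(1:5000), 1])), 0.01)
  # a constant synthetic trajectory is quiescent
  expect_equal(unname(classify_regime(fake_trajectory(matrix(-1.6, 200, 1)))),
               "quiescent")
})

test_that("threshold bisection brackets the seizure transition", {
  p <- model_params()
  th <- find_threshold(p, lo = -2.5, hi = -1.6, tol = 0.01, trace = TRUE)
  expect_gte(as.numeric(th), -2.10)
  expect_lte(as.numeric(th), -2.00)
  # bisection contract: just outside the final tolerance the regimes differ
  probe <- function(x0) {
    tr <- integrate_epileptor(p, x0, duration = 6 * p$tau0, dt = 0.05,
                              save_every = 20)
    unname(classify_regime(tr))
  }
  expect_equal(probe(as.numeric(th) - 0.011), "quiescent")
  expect_equal(probe(as.numeric(th) + 0.011), "oscillatory")
  # refinement self-consistency
  th2 <- find_threshold(p, lo = -2.5, hi = -1.6, tol = 0.04)
  expect_lt(abs(as.numeric(th2) - as.numeric(th)), 0.04)
  # bad bracket is rejected
  expect_error(find_threshold(p, lo = -2.5, hi = -2.4, tol = 0.01),
               "straddle")
  trace <- attr(th, "trace")
  expect_s3_class(trace, "data.frame")
  expect_setequal(unique(trace$regime), c("quiescent", "oscillatory"))
})
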