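# Build a minimal trajectory object around a given x1 matrix (other state
# variables zero) so analytics can be tested on hand-constructed signals.
fake_trajectory <- function(x1, dt = 1) {
  x1 <- as.matrix(x1)
  zeros <- matrix(0, nrow(x1), ncol(x1))
  epinetsim:::new_trajectory(
    list(times = seq(0, by = dt, length.out = nrow(x1)),
         x1 = x1, y1 = zeros, z = zeros, x2 = zeros, y2 = zeros,
         g = zeros),
    dt_out = dt, x0 = rep(NA_real_, ncol(x1)), params = model_params())
}

# Square-wave x1 signal: `cycles` alternations of `high_len` samples at
# `high` then `low_len` samples at `low`, preceded by `lead` low samples.
square_wave <- function(cycles = 3, high_len = 400, low_len = 400,
                        high = 0.5, low = -1.6, lead = 10) {
  rep(c(rep(low, lead),
        rep(c(rep(high, high_len), rep(low, low_len)), cycles))[
          seq_len(lead + cycles * (high_len + low_len))], 1)
}
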