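# shared fixtures: a small, fast circuit configuration and a skew-normal
# sampler used as an independent generator for the MLE recovery tests

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(s = 0.1, duration = 1500), list(...))
  do.call(circuit_config, args)
}

# sample from a skew-normal by the delta-representation:
# X = xi + omega * (delta*|Z1| + sqrt(1-delta^2)*Z2)
rskewnorm <- function(n, location = 0, scale = 1, shape = 0) {
  delta <- shape / sqrt(1 + shape^2)
  z1 <- abs(stats::rnorm(n))
  z2 <- stats::rnorm(n)
  location + scale * (delta * z1 + sqrt(1 - delta^2) * z2)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * abs(expected))
}
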