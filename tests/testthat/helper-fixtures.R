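# Fixture builders shared across test files.

# exponential OD trace, optional lag (time shift) and log-normal noise
make_exp_series <- function(r = 0.5, od0 = 0.02, lag = 0, noise_sd = 0,
                            times = seq(0, 5, 0.25), seed = NULL,
                            sample_id = "s", condition = "c",
                            replicate = 1L) {
  mu <- od0 * exp(r * pmax(times - lag, 0))
  ods <- if (noise_sd > 0) {
    withr::with_seed(seed, mu * exp(rnorm(length(mu), 0, noise_sd)))
  } else mu
  od_series(sample_id, condition, replicate, times, ods)
}

# small event tables trip the <10k advisory warning by design
make_events <- function(red, green = rep(100, length(red)), id = "ev") {
  suppressWarnings(flow_event_table(id, green, red))
}

# brute-force BH oracle: adjusted_(i) = min over j >= i of p_(j) * m / j
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
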