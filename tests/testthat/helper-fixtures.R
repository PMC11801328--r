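# Shared fixtures, built in code at test time.

# Full placental protocol, built once per test run.
paper_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_paper_scheme()
    cache
  }
})

# Compact scheme for unit tests that do not need all 240 measurements:
# 3 echo times x 6 b-shells, one direction each.
small_scheme <- function() {
  b <- rep(c(5, 50, 200, 600, 1000, 1600), each = 3)
  te <- rep(c(80, 120, 160), times = 6)
  dirs <- matrix(rep(c(1, 0, 0), length(b)), ncol = 3, byrow = TRUE)
  acq_scheme(b, dirs, te)
}

# Random valid scheme for round-trip property tests.
random_scheme <- function(n = 12, seed = 1) {
  set.seed(seed)
  b <- round(runif(n, 0, 1600), 1)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  acq_scheme(b, dirs, te = round(runif(n, 60, 200), 2))
}

random_ivim_truth <- function() {
  ivim_params(s0 = runif(1, 85, 115), f = runif(1, 0.1, 0.5),
              t2_star_fast = runif(1, 50, 130),
              t2_star_slow = runif(1, 25, 75),
              d_star = runif(1, 0.02, 0.1),
              adc = runif(1, 8e-4, 3.5e-3))
}

relative_error <- function(est, truth) abs(est - truth) / abs(truth)
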