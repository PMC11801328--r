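test_that("the mono-exponential model evaluates to its closed form", {
  # at TE = TE_min and b = 0 both exponents vanish
  s0ref <- acq_scheme(0, rbind(c(1, 0, 0)), 78)
  expect_equal(signal_monoexp(monoexp_params(100, 37, 1e-3), s0ref), 100)
  # direct evaluation: 100 * exp(-36/50) * exp(-0.6 * 2) at TE 114, b 600
  s <- acq_scheme(c(0, 600), rbind(c(1, 0, 0), c(1, 0, 0)), c(78, 114))
  sig <- signal_monoexp(monoexp_params(100, 50, 2e-3), s)
  expect_equal(sig[2], 100 * exp(-36 / 50) * exp(-1.2), tolerance = 1e-12)
  # zero ADC: signal depends on TE only
  s2 <- small_scheme()
  sig2 <- signal_monoexp(monoexp_params(80, 60, 0), s2)
  expect_equal(tapply(sig2, s2$te, function(x) diff(range(x))),
               tapply(sig2, s2$te, function(x) 0))
})

test_that("the two-compartment model evaluates to its closed form and collapses", {
  s1 <- acq_scheme(100, rbind(c(1, 0, 0)), 78)
  p <- ivim_params(100, 0.3, 80, 40, 0.05, 2e-3)
  expect_equal(signal_ivim(p, s1),
               100 * (0.3 * exp(-5) + 0.7 * exp(-0.2)), tolerance = 1e-12)
  # f = 0 collapses onto the slow compartment, f = 1 onto the fast one
  s <- paper_scheme()
  for (seed in 1:10) {
    set.seed(seed)
    tr <- random_ivim_truth()
    p0 <- ivim_params(tr$s0, 0, tr$t2_star_fast, tr$t2_star_slow,
                      tr$d_star, tr$adc)
    expect_equal(signal_ivim(p0, s),
                 signal_monoexp(monoexp_params(tr$s0, tr$t2_star_slow, tr$adc), s),
                 tolerance = 1e-14)
    p1 <- ivim_params(tr$s0, 1, tr$t2_star_fast, tr$t2_star_slow,
                      tr$d_star, tr$adc)
    expect_equal(signal_ivim(p1, s),
                 signal_monoexp(monoexp_params(tr$s0, tr$t2_star_fast, tr$d_star), s),
                 tolerance = 1e-14)
  }
})

test_that("equal compartments make the perfusion fraction unobservable", {
  s <- small_scheme()
  base <- list(s0 = 90, t2 = 55, d = 3e-3)
  sigs <- sapply(c(0.1, 0.4, 0.8), function(f) {
    p <- list(s0 = base$s0, f = f, t2_star_fast = base$t2,
              t2_star_slow = base$t2, d_star = base$d, adc = base$d)
    class(p) <- "ivim_params"
    signal_ivim(p, s)
  })
  expect_lt(max(apply(sigs, 1, function(x) diff(range(x)))), 1e-12)
})

test_that("noiseless signals are positive and monotone in b and TE", {
  s <- paper_scheme()
  for (seed in 1:8) {
    set.seed(seed)
    sig <- signal_ivim(random_ivim_truth(), s)
    expect_true(all(sig > 0))
    for (te in unique(s$te)) {
      i <- s$te == te
      ord <- order(s$b[i])
      expect_true(all(diff(sig[i][ord]) <= 1e-12))
    }
    for (b in unique(s$b)) {
      i <- s$b == b
      ord <- order(s$te[i])
      expect_true(all(diff(sig[i][ord]) <= 1e-12))
    }
  }
})

test_that("tensor signal honours the quadratic form", {
  s <- scheme_at_te_min(paper_scheme())
  iso <- diffusion_tensor(diag(3) * 1.5e-3, s0 = 100)
  sig <- signal_tensor(iso, s)
  expect_equal(sig, 100 * exp(-s$b * 1.5e-3), tolerance = 1e-12)
  s1 <- acq_scheme(c(0, 800), rbind(c(1, 0, 0), c(1, 0, 0)), c(78, 78))
  t2 <- diffusion_tensor(diag(c(2, 1, 1)) * 1e-3, s0 = 50)
  expect_equal(signal_tensor(t2, s1), c(50, 50 * exp(-1.6)), tolerance = 1e-12)
  expect_error(diffusion_tensor(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
})

test_that("noise injection honours sigma, model and seed contracts", {
  sig <- rep(c(100, 10, 0), 200)
  expect_identical(add_noise(sig, 0, "rician"), sig)
  expect_identical(add_noise(sig, 2, "rician", seed = 9),
                   add_noise(sig, 2, "rician", seed = 9))
  expect_false(identical(add_noise(sig, 2, "rician", seed = 9),
                         add_noise(sig, 2, "rician", seed = 10)))
  expect_error(add_noise(sig, -1, "rician"), "non-negative")
  expect_error(add_noise(sig, 1, "poisson"), "arg")
  # Rician floor: zero signal acquires the Rayleigh mean sigma*sqrt(pi/2)
  z <- add_noise(rep(0, 2e4), 3, "rician", seed = 1)
  expect_equal(mean(z), 3 * sqrt(pi / 2), tolerance = 0.02)
  # Gaussian noise remains unbiased
  g <- add_noise(rep(50, 2e4), 3, "gaussian", seed = 1)
  expect_equal(mean(g), 50, tolerance = 0.005)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(monoexp_params(-1, 50, 1e-3), "s0")
  expect_error(monoexp_params(10, 0, 1e-3), "t2_star")
  expect_error(ivim_params(10, 1.2, 80, 40, 0.05, 1e-3), "\\[0, 1\\]")
  expect_error(ivim_params(10, 0.2, 80, 40, 1e-3, 2e-3), "d_star")
})
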