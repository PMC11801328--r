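test_that("noiseless mono-exponential signals are recovered exactly", {
  s <- paper_scheme()
  truth <- monoexp_params(100, 50, 2e-3)
  fit <- fit_monoexp(signal_monoexp(truth, s), s)
  expect_true(fit$converged)
  expect_lt(max(relative_error(unlist(fit$params), unlist(truth))), 1e-4)
  # constant signal across b at fixed TE drives ADC to zero
  flat <- signal_monoexp(monoexp_params(90, 45, 0), s)
  fit0 <- fit_monoexp(flat, s)
  expect_lt(fit0$params$adc, 1e-6)
})

test_that("degenerate voxels are flagged, not fatal", {
  s <- paper_scheme()
  f <- fit_monoexp(rep(0, nrow(s)), s)
  expect_false(f$converged)
  expect_match(f$reason, "non-positive")
  fi <- fit_ivim(rep(-1, nrow(s)), s)
  expect_false(fi$converged)
  expect_error(fit_monoexp(1:10, s), "does not match")
  one_te <- small_scheme()
  one_te <- one_te[one_te$te == 80, ]
  expect_error(fit_monoexp(rep(1, nrow(one_te)), one_te),
               "distinct echo times")
})

test_that("noiseless two-compartment signals are recovered within 1%", {
  s <- paper_scheme()
  truth <- ivim_params(100, 0.3, 80, 40, 0.05, 2e-3)
  for (strat in c("full", "segmented")) {
    fit <- fit_ivim(signal_ivim(truth, s), s, strategy = strat)
    expect_true(fit$converged)
    tol <- if (strat == "full") 0.01 else 0.2
    expect_lt(max(relative_error(unlist(fit$params), unlist(truth))), tol)
  }
})

test_that("compartment labels are canonical: d_star always exceeds adc", {
  s <- paper_scheme()
  truth <- ivim_params(100, 0.3, 80, 40, 0.05, 2e-3)
  # the same physical signal with the labels swapped in the truth object
  swapped <- list(s0 = 100, f = 0.7, t2_star_fast = 40, t2_star_slow = 80,
                  d_star = 2e-3, adc = 0.05)
  class(swapped) <- "ivim_params"
  sig <- signal_ivim(truth, s)
  expect_equal(signal_ivim(swapped, s), sig, tolerance = 1e-14)
  fit <- fit_ivim(sig, s)
  expect_gt(fit$params$d_star, fit$params$adc)
  expect_equal(fit$params$f, 0.3, tolerance = 0.01)
})

test_that("a perfusion-free voxel collapses to the mono-exponential fit", {
  s <- paper_scheme()
  slow <- monoexp_params(100, 45, 1.8e-3)
  p0 <- ivim_params(100, 1e-9, 90, 45, 0.05, 1.8e-3)
  p0$f <- 0
  sig <- signal_ivim(p0, s)
  fiv <- fit_ivim(sig, s)
  fmono <- fit_monoexp(sig, s)
  expect_lt(fiv$params$f, 0.02)
  expect_equal(fiv$params$adc, fmono$params$adc, tolerance = 0.02)
  expect_equal(fiv$params$t2_star_slow, slow$t2_star, tolerance = 0.05)
})

test_that("tensor fits reproduce closed-form fractional anisotropy", {
  s <- scheme_at_te_min(paper_scheme())
  iso <- diffusion_tensor(diag(3) * 1.2e-3, s0 = 100)
  expect_lt(fit_tensor_fa(signal_tensor(iso, s), s)$params$fa, 1e-6)
  pro <- diffusion_tensor(diag(c(2, 1, 1)) * 1e-3, s0 = 100)
  expect_equal(fit_tensor_fa(signal_tensor(pro, s), s)$params$fa,
               1 / sqrt(6), tolerance = 1e-6)
  rank1 <- diffusion_tensor(diag(c(1.5e-3, 1e-9, 1e-9)), s0 = 100)
  expect_equal(fit_tensor_fa(signal_tensor(rank1, s), s)$params$fa,
               1, tolerance = 1e-3)
  # rotating the tensor leaves FA invariant
  set.seed(4)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- diffusion_tensor(q %*% diag(c(2, 1, 1)) %*% t(q) * 1e-3, s0 = 100)
  expect_equal(fit_tensor_fa(signal_tensor(rot, s), s)$params$fa,
               1 / sqrt(6), tolerance = 1e-6)
})

test_that("rank-deficient direction sets are rejected by name", {
  b <- rep(c(0, 800, 800, 800), each = 2)
  dirs <- matrix(rep(c(1, 0, 0), 8), ncol = 3, byrow = TRUE)
  s <- acq_scheme(b, dirs, rep(78, 8))
  expect_error(fit_tensor_fa(rep(10, 8), s), "rank-deficient")
})

test_that("fitted FA and f always respect their bounds under noise", {
  s <- scheme_at_te_min(paper_scheme())
  full <- paper_scheme()
  set.seed(6)
  for (i in 1:10) {
    tr <- random_ivim_truth()
    y <- add_noise(signal_ivim(tr, full), 5, "rician", seed = i)
    fi <- fit_ivim(y, full, seed = i)
    expect_true(fi$params$f >= 0 && fi$params$f <= 1)
    ten <- diffusion_tensor(diag(runif(3, 5e-4, 3e-3)), s0 = 100)
    yt <- add_noise(signal_tensor(ten, s), 4, "rician", seed = i)
    ft <- fit_tensor_fa(yt, s)
    expect_true(ft$params$fa >= 0 && ft$params$fa <= 1)
  }
})

test_that("gradient fits agree with the exhaustive grid oracle", {
  s <- paper_scheme()
  set.seed(42)
  for (i in 1:6) {
    truth <- monoexp_params(runif(1, 60, 140), runif(1, 20, 110),
                            runif(1, 3e-4, 4.5e-3))
    y <- signal_monoexp(truth, s)
    bf <- brute_force_monoexp(y, s)
    nl <- unlist(fit_monoexp(y, s)$params)
    expect_lt(abs(nl["t2_star"] - bf$params["t2_star"]),
              bf$spacing["t2_star"] + 1e-9)
    expect_lt(abs(nl["adc"] - bf$params["adc"]), bf$spacing["adc"] + 1e-9)
    expect_lt(relative_error(nl["s0"], bf$params["s0"]), 0.02)
  }
})

test_that("volume fitting is masked, deterministic and error-checked", {
  p <- make_phantom(26, "control", shape = c(10L, 10L, 10L), seed = 3)
  s <- paper_scheme()
  # exact round trip: data generated from the mono-exponential model itself
  nvox <- prod(p$shape)
  d <- array(0, dim = c(p$shape, nrow(s)))
  for (v in which(p$mask)) {
    pars <- monoexp_params(p$maps$s0[v], p$maps$t2_star[v], p$maps$adc[v])
    d[v + (seq_len(nrow(s)) - 1) * nvox] <- signal_monoexp(pars, s)
  }
  maps <- fit_volume(d, p$mask, s, "monoexp")
  expect_equal(maps$summary$n_nonconverged, 0)
  inm <- p$mask
  expect_true(all(is.finite(maps$maps$t2_star[inm])))
  expect_true(all(is.na(maps$maps$t2_star[!inm])))
  expect_equal(maps$maps$t2_star[inm], p$maps$t2_star[inm], tolerance = 1e-3)
  maps2 <- fit_volume(d, p$mask, s, "monoexp")
  expect_identical(maps$maps, maps2$maps)
  # on two-compartment tissue the mono model measures an effective T2*
  # below the linear compartment mixture, but tracks it monotonically
  d2 <- simulate_subject_data(p, s, snr = Inf)
  eff <- fit_volume(d2, p$mask, s, "monoexp")
  expect_true(all(eff$maps$t2_star[inm] <= p$maps$t2_star[inm] + 1e-6))
  expect_gt(cor(eff$maps$t2_star[inm], p$maps$t2_star[inm]), 0.95)
  expect_error(fit_volume(d, array(FALSE, dim = p$shape), s, "monoexp"),
               "empty")
  expect_error(fit_volume(d[, , , 1:10], p$mask, s, "monoexp"),
               "4th dimension")
  expect_error(fit_volume(d, p$mask[1:5, , ], s, "monoexp"), "mask dimensions")
})
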