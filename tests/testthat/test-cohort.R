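null_config <- function() {
  cfg <- phantom_config()
  cfg$group_scale$pprom <- c(fast = 1, slow = 1)
  cfg$group_scale$intact <- c(fast = 1, slow = 1)
  cfg
}

test_that("controls show the built-in downward T2* trend but ADC stays flat", {
  co <- make_cohort(seed = 7)
  tr <- ga_trend(co, "t2_star")
  expect_lt(tr$estimate, 0)
  expect_lt(tr$p_value, 0.05)
  expect_equal(tr$n, 52)
  # a constant outcome gives slope 0
  co$const <- 5
  tr0 <- suppressWarnings(ga_trend(co, "const"))  # perfect fit warning
  expect_equal(tr0$estimate, 0, tolerance = 1e-10)
  expect_error(ga_trend(co[co$is_case, ], "t2_star"), "at least 3 controls")
})

test_that("FA, generated gestation-constant, shows no trend in expectation", {
  ps <- sapply(1:40, function(i) ga_trend(make_cohort(seed = 100 + i), "fa")$p_value)
  # p-values approximately uniform under the null: around 5% below 0.05
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})

test_that("group contrasts recover injected case effects at study-scale n", {
  co <- make_cohort(seed = 3)
  gc <- group_contrast(co, "t2_star")
  expect_lt(gc$estimate, 0)
  expect_lt(gc$p_value, 0.05)
  expect_equal(gc$n, 75)
  # membranes-ruptured subgroup carries the stronger effect
  pp <- group_contrast(co, "t2_star", "pprom")
  it <- group_contrast(co, "t2_star", "intact")
  expect_lt(pp$estimate, it$estimate)
  expect_error(group_contrast(co[!co$is_case, ], "t2_star"), "empty")
})

test_that("identical group distributions give a near-zero case coefficient", {
  co <- make_cohort(seed = 5, config = null_config())
  gc <- group_contrast(co, "t2_star")
  sd_t2 <- sd(co$t2_star[!co$is_case])
  expect_lt(abs(gc$estimate), sd_t2)
  expect_gt(gc$p_value, 0.01)
})

test_that("the unadjusted contrast equals the closed-form mean difference", {
  co <- make_cohort(n_cases = 10, n_pprom = 5, n_controls = 10, seed = 13)
  gc <- group_contrast(co, "t2_star", adjust_ga = FALSE)
  delta <- mean(co$t2_star[co$is_case]) - mean(co$t2_star[!co$is_case])
  expect_equal(gc$estimate, delta, tolerance = 1e-10)
  # and the classic two-sample pooled-variance t-test p-value
  tt <- t.test(t2_star ~ is_case, data = co, var.equal = TRUE)
  expect_equal(gc$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("the latency ratio follows its definition and direction", {
  expect_equal(latency_score(24, 25, 26), 1)
  expect_equal(latency_score(24, 25, 25), 0)
  # further from delivery -> larger score
  expect_gt(latency_score(24, 25, 30), latency_score(24, 25, 26))
  # strictly decreasing in scan time for fixed onset/delivery
  mris <- seq(24.5, 27.5, by = 0.5)
  scores <- sapply(mris, function(m) latency_score(24, m, 28))
  expect_true(all(diff(scores) < 0))
  expect_warning(r <- latency_score(25, 25, 30), "onset")
  expect_true(is.na(r))
  expect_error(latency_score(26, 25, 30), "onset <= MRI <= delivery")
})

test_that("standardised scores have mean 0, SD 1 and a documented tie rule", {
  z <- standardise_and_split(c(1, 2, 3))
  expect_equal(mean(z$z), 0, tolerance = 1e-10)
  expect_equal(sd(z$z), 1, tolerance = 1e-10)
  expect_equal(as.character(z$side), c("below_zero", "above_zero", "above_zero"))
  expect_equal(z$z, (c(1, 2, 3) - 2) / 1, tolerance = 1e-10)
  set.seed(1)
  r <- rlnorm(23)
  z2 <- standardise_and_split(r)
  expect_equal(mean(z2$z), 0, tolerance = 1e-10)
  expect_equal(sd(z2$z), 1, tolerance = 1e-10)
  expect_error(standardise_and_split(rep(2, 5)), "zero variance")
  expect_error(standardise_and_split(c(1, NA)), "at least 2")
})

test_that("latency-split contrasts detect injected effects and stay calibrated", {
  co <- make_cohort(seed = 17)
  cases <- co[co$is_case, ]
  cases$side <- standardise_and_split(
    latency_score(cases$ga_onset, cases$ga_mri, cases$ga_delivery))$side
  # inject a perfusion-fraction reduction in cases close to delivery
  cases$f[cases$side == "below_zero"] <-
    cases$f[cases$side == "below_zero"] - 0.08
  sc <- split_contrast(cases, "f")
  expect_lt(sc$estimate, 0)
  expect_lt(sc$p_value, 0.05)
  # two identical subjects per side -> exactly zero difference
  twin <- data.frame(f = c(0.2, 0.2, 0.3, 0.3),
                     side = factor(c("below_zero", "below_zero",
                                     "above_zero", "above_zero"),
                                   levels = c("below_zero", "above_zero")))
  expect_equal(suppressWarnings(split_contrast(twin, "f"))$estimate,
               -0.1, tolerance = 1e-12)
  one_sided <- twin[twin$side == "below_zero", ]
  expect_error(split_contrast(one_sided, "f"), "one-sided")
})

test_that("the latency split has an approximately nominal false-positive rate", {
  ps <- sapply(1:200, function(i) {
    co <- make_cohort(seed = 400 + i, config = null_config())
    cases <- co[co$is_case, ]
    cases$side <- standardise_and_split(
      latency_score(cases$ga_onset, cases$ga_mri, cases$ga_delivery))$side
    split_contrast(cases, "t2_star")$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("analyse_cohort returns one tidy row per comparison", {
  co <- make_cohort(seed = 2)
  out <- analyse_cohort(co)
  expect_true(all(c("parameter", "analysis", "estimate", "p_value",
                    "significant") %in% names(out)))
  expect_equal(sort(unique(out$analysis)),
               sort(c("ga_trend_controls", "case_vs_control",
                      "pprom_vs_control", "intact_vs_control",
                      "latency_split")))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
})
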