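# Voxel-wise estimation of the diffusion-relaxation models.
#
# All nonlinear fits use bounded Levenberg-Marquardt least squares
# (minpack.lm::nls.lm) on magnitude signals, seeded from log-linear
# regressions; no Rician-likelihood correction is applied (documented
# limitation) and no spatial regularisation couples neighbouring voxels.

monoexp_bounds <- function() {
  list(lower = c(s0 = 1e-6, t2_star = 1, adc = 0),
       upper = c(s0 = Inf, t2_star = 300, adc = 0.01))
}

ivim_bounds <- function() {
  list(lower = c(s0 = 1e-6, f = 0, t2_star_fast = 1, t2_star_slow = 1,
                 d_star = 1e-3, adc = 0),
       upper = c(s0 = Inf, f = 1, t2_star_fast = 300, t2_star_slow = 300,
                 d_star = 0.5, adc = 0.01))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Expected value of a Rician-distributed magnitude with underlying
# signal S and noise sigma (exact first moment, scaled Bessel form for
# numerical stability). Reduces to S as sigma -> 0.
rician_mean <- function(S, sigma) {
  if (sigma <= 0 || sigma < 1e-8 * max(S, 1)) return(S)
  x <- S^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# Noise level estimate from fit residuals: a robust initial scale,
# refined on measurements where the model is well above the noise floor
# (low-signal residuals under-estimate sigma because the magnitude
# distribution is Rayleigh-compressed there).
estimate_sigma <- function(y, fitted) {
  r <- y - fitted
  s_hat <- 1.4826 * stats::mad(r, center = 0)
  for (k in 1:2) {
    hi <- fitted > 2 * s_hat
    if (sum(hi) >= 10) s_hat <- stats::sd(r[hi])
  }
  s_hat
}

fit_failure <- function(model, reason, n_params) {
  structure(list(params = rep(NA_real_, n_params), model = model,
                 residual_norm = NA_real_, converged = FALSE,
                 n_iterations = 0L, reason = reason),
            class = "dr_fit")
}

dr_fit <- function(params, model, residual_norm, converged, n_iterations,
                   reason = NA_character_) {
  structure(list(params = params, model = model,
                 residual_norm = residual_norm, converged = converged,
                 n_iterations = n_iterations, reason = reason),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<%s fit> converged: %s, residual norm %.4g (%d iterations)\n",
              x$model, x$converged, x$residual_norm, x$n_iterations))
  print(unlist(x$params))
  invisible(x)
}

# Log-linear slope of log(signal) against a regressor, used for
# initialisation only; returns NA when fewer than 2 usable points.
loglin_slope <- function(x, y) {
  ok <- y > 0 & is.finite(y)
  if (sum(ok) < 2) return(c(NA_real_, NA_real_))
  fit <- stats::lm.fit(cbind(1, x[ok]), log(y[ok]))
  fit$coefficients
}

#' Fit the T2*-ADC model to one voxel
#'
#' Estimates (s0, t2_star, adc) of the mono-exponential
#' diffusion-relaxation model by bounded nonlinear least squares.
#' Starting values come from two log-linear regressions: log-signal
#' against echo time on the lowest b-shell (T2*), and against b at the
#' shortest echo time (ADC). T2* is constrained to (1, 300] ms and ADC to
#' \[0, 0.01\] mm^2/s; the physiological > 200 ms exclusion is applied
#' downstream at ROI stage, not as a fit bound. A voxel whose signal is
#' entirely non-positive is flagged (`converged = FALSE`) rather than
#' raising an error, so a volume fit never aborts.
#'
#' Because the input is a magnitude image, an uncorrected least-squares
#' fit is pulled towards the Rician noise floor where the decay is
#' strong. With `rician_correction = TRUE` (default) the fit is refined
#' against the exact Rician first moment of the model, with the noise
#' level estimated from the residuals of an initial uncorrected fit; on
#' noiseless data the estimated sigma vanishes and the correction is a
#' no-op.
#'
#' @param signal numeric vector, one measurement per scheme row.
#' @param scheme an [acq_scheme()] with >= 3 distinct echo times and
#'   >= 3 distinct b-values.
#' @param rician_correction refine against the Rician expectation.
#' @return a `dr_fit`: `params` (named list), `residual_norm`,
#'   `converged`, `n_iterations`.
#' @export
fit_monoexp <- function(signal, scheme, rician_correction = TRUE) {
  check_fit_inputs(signal, scheme, min_te = 3, min_b = 3)
  if (all(signal <= 0))
    return(fit_failure("monoexp", "all signals non-positive", 3L))
  dte <- scheme$te - te_min(scheme)
  start <- monoexp_start(signal, scheme)
  bounds <- monoexp_bounds()
  model_fn <- function(p) p[1] * exp(-dte / p[2]) * exp(-scheme$b * p[3])
  out <- minpack.lm::nls.lm(par = start, lower = bounds$lower,
                            upper = bounds$upper,
                            fn = function(p) signal - model_fn(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (rician_correction) {
    sig_hat <- estimate_sigma(signal, model_fn(as.numeric(out$par)))
    if (sig_hat > 1e-8 * max(signal)) {
      out <- minpack.lm::nls.lm(
        par = out$par, lower = bounds$lower, upper = bounds$upper,
        fn = function(p) signal - rician_mean(model_fn(p), sig_hat),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  p <- as.numeric(out$par)
  dr_fit(params = list(s0 = p[1], t2_star = p[2], adc = p[3]),
         model = "monoexp",
         residual_norm = sqrt(sum(out$fvec^2)),
         converged = out$info %in% 1:4,
         n_iterations = out$niter)
}

monoexp_start <- function(signal, scheme) {
  bounds <- monoexp_bounds()
  dte <- scheme$te - te_min(scheme)
  low_b <- scheme$b == min(scheme$b)
  co_te <- loglin_slope(dte[low_b], signal[low_b])
  t2_init <- if (is.na(co_te[2]) || co_te[2] >= 0) 60 else -1 / co_te[2]
  at_temin <- scheme$te == te_min(scheme)
  co_b <- loglin_slope(scheme$b[at_temin], signal[at_temin])
  adc_init <- if (is.na(co_b[2]) || co_b[2] >= 0) 1e-3 else -co_b[2]
  s0_init <- if (is.na(co_te[1])) max(signal, 1e-3) else exp(co_te[1])
  c(s0 = clamp(s0_init, bounds$lower[["s0"]] + 1e-9, 1e12),
    t2_star = clamp(t2_init, 2, bounds$upper[["t2_star"]]),
    adc = clamp(adc_init, 0, bounds$upper[["adc"]]))
}

ivim_model_eval <- function(p, dte, b) {
  p[1] * (p[2] * exp(-dte / p[3]) * exp(-b * p[5]) +
            (1 - p[2]) * exp(-dte / p[4]) * exp(-b * p[6]))
}

# Canonical compartment labelling: "fast" is the compartment with the
# larger diffusion coefficient, and f is its signal fraction.
canonicalise_ivim <- function(p) {
  if (p[["d_star"]] < p[["adc"]]) {
    p <- c(s0 = p[["s0"]], f = 1 - p[["f"]],
           t2_star_fast = p[["t2_star_slow"]],
           t2_star_slow = p[["t2_star_fast"]],
           d_star = p[["adc"]], adc = p[["d_star"]])
  }
  p
}

#' Fit the two-compartment T2*-IVIM model to one voxel
#'
#' Estimates (s0, f, t2_star_fast, t2_star_slow, d_star, adc). The
#' `"segmented"` strategy first fits the slow (diffusing) compartment by
#' log-linear regression on b >= `b_threshold` (default 200 s/mm^2, the
#' conventional IVIM cut), then the fast (perfusing) compartment on the
#' low-b residual; amplitudes give s0 and f. The `"full"` strategy runs
#' joint bounded nonlinear least squares seeded by the segmented result
#' plus `n_starts - 1` perturbed restarts (deterministic given `seed`),
#' keeping the lowest residual (ties broken by start order). Compartments
#' are relabelled so that `d_star > adc` and `f` always refers to the
#' fast compartment. A fit with `f` pinned at a bound and degenerate
#' compartments is reported with `converged = FALSE` and a reason code.
#' The `"full"` strategy finishes with the same Rician first-moment
#' refinement as [fit_monoexp()] when `rician_correction = TRUE`.
#'
#' @inheritParams fit_monoexp
#' @param strategy `"full"` (default) or `"segmented"`.
#' @param b_threshold segmentation cut, s/mm^2.
#' @param n_starts number of multi-start initialisations for `"full"`.
#' @param seed integer seed controlling the restart perturbations.
#' @return a `dr_fit` with six named parameters.
#' @export
fit_ivim <- function(signal, scheme, strategy = c("full", "segmented"),
                     b_threshold = 200, n_starts = 5L, seed = 1L,
                     rician_correction = TRUE) {
  strategy <- match.arg(strategy)
  check_fit_inputs(signal, scheme, min_te = 3, min_b = 3)
  if (sum(unique(scheme$b) >= b_threshold) < 2 ||
      sum(unique(scheme$b) < b_threshold) < 2)
    stop("scheme needs >= 2 b-values on each side of b_threshold")
  if (all(signal <= 0))
    return(fit_failure("ivim", "all signals non-positive", 6L))

  seg <- ivim_segmented(signal, scheme, b_threshold)
  if (strategy == "segmented") return(seg)

  bounds <- ivim_bounds()
  dte <- scheme$te - te_min(scheme)
  resid_fn <- function(p) signal - ivim_model_eval(p, dte, scheme$b)
  p0 <- unlist(seg$params)
  starts <- list(p0)
  perturb <- with_local_seed(derive_seed(seed, "ivim-starts"), {
    lapply(seq_len(max(0L, n_starts - 1L)), function(k) {
      p0 * exp(stats::rnorm(6, 0, 0.25))
    })
  })
  starts <- c(starts, perturb)
  best <- NULL
  for (st in starts) {
    st <- clamp(st, bounds$lower + 1e-9,
                pmin(bounds$upper, 1e12) - 1e-9)
    out <- try(minpack.lm::nls.lm(par = st, lower = bounds$lower,
                                  upper = bounds$upper, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(maxiter = 300)),
               silent = TRUE)
    if (inherits(out, "try-error")) next
    rn <- sqrt(sum(out$fvec^2))
    if (is.null(best) || rn < best$rn - 1e-12)
      best <- list(out = out, rn = rn)
  }
  if (is.null(best))
    return(fit_failure("ivim", "all starts failed", 6L))
  if (rician_correction) {
    p_best <- as.numeric(best$out$par)
    sig_hat <- estimate_sigma(signal, ivim_model_eval(p_best, dte, scheme$b))
    if (sig_hat > 1e-8 * max(signal)) {
      ref <- try(minpack.lm::nls.lm(
        par = best$out$par, lower = bounds$lower, upper = bounds$upper,
        fn = function(p)
          signal - rician_mean(ivim_model_eval(p, dte, scheme$b), sig_hat),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        silent = TRUE)
      if (!inherits(ref, "try-error"))
        best <- list(out = ref, rn = sqrt(sum(ref$fvec^2)))
    }
  }
  p <- as.numeric(best$out$par)
  names(p) <- names(bounds$lower)
  p <- canonicalise_ivim(p)
  degenerate <- (p[["f"]] <= 1e-6 || p[["f"]] >= 1 - 1e-6) &&
    abs(p[["t2_star_fast"]] - p[["t2_star_slow"]]) < 1e-6
  dr_fit(params = as.list(p), model = "ivim",
         residual_norm = best$rn,
         converged = best$out$info %in% 1:4 && !degenerate,
         n_iterations = best$out$niter,
         reason = if (degenerate) "non-identifiable: f at bound with degenerate compartments" else NA_character_)
}

# Segmented IVIM: log-linear slow-compartment fit on high b, then the
# fast compartment on the low-b residual. Returned as a dr_fit usable on
# its own or as the seed for the joint fit.
ivim_segmented <- function(signal, scheme, b_threshold = 200) {
  bounds <- ivim_bounds()
  dte <- scheme$te - te_min(scheme)
  hi <- scheme$b >= b_threshold
  # log S = log(S0 (1-f)) - dTE/T2s - b ADC on the high-b subset
  ok <- hi & signal > 0
  Xs <- cbind(1, dte[ok], scheme$b[ok])
  cs <- stats::lm.fit(Xs, log(signal[ok]))$coefficients
  a_slow <- exp(cs[1]); t2s <- if (cs[2] < 0) -1 / cs[2] else 200
  adc <- max(-cs[3], 0)
  slow_pred <- a_slow * exp(-dte / t2s) * exp(-scheme$b * adc)
  res <- signal - slow_pred
  lo <- !hi & res > 0
  if (sum(lo) >= 3) {
    Xf <- cbind(1, dte[lo], scheme$b[lo])
    cf <- stats::lm.fit(Xf, log(res[lo]))$coefficients
    a_fast <- exp(cf[1]); t2f <- if (cf[2] < 0) -1 / cf[2] else 100
    d_star <- max(-cf[3], 5e-3)
  } else {
    a_fast <- 0.1 * a_slow; t2f <- 1.5 * t2s; d_star <- 0.05
  }
  s0 <- a_slow + a_fast
  f <- a_fast / s0
  p <- c(s0 = s0, f = clamp(f, 0.01, 0.95),
         t2_star_fast = clamp(t2f, 2, bounds$upper[["t2_star_fast"]]),
         t2_star_slow = clamp(t2s, 2, bounds$upper[["t2_star_slow"]]),
         d_star = clamp(d_star, bounds$lower[["d_star"]], bounds$upper[["d_star"]]),
         adc = clamp(adc, 0, bounds$upper[["adc"]]))
  p <- canonicalise_ivim(p)
  fitted <- ivim_model_eval(p, dte, scheme$b)
  dr_fit(params = as.list(p), model = "ivim",
         residual_norm = sqrt(sum((signal - fitted)^2)),
         converged = TRUE, n_iterations = 2L)
}

#' Fit the diffusion tensor and fractional anisotropy
#'
#' Log-linear weighted-least-squares tensor fit on the measurements at
#' the shortest echo time: log S = log S0 - b g' D g. Requires at least
#' six non-collinear gradient directions plus a low-b reference.
#' Eigenvalues are clamped at zero before FA is computed, so FA always
#' lies in \[0, 1\].
#'
#' @param signal signals at the shortest echo time.
#' @param scheme an [acq_scheme()] containing only TE_min measurements
#'   (see [scheme_at_te_min()]).
#' @return a `dr_fit` with `params$tensor` (3x3 matrix), `params$s0`,
#'   `params$fa` and `params$eigenvalues`.
#' @export
fit_tensor_fa <- function(signal, scheme) {
  if (length(signal) != nrow(scheme))
    stop("signal length does not match the scheme")
  if (length(unique(scheme$te)) != 1)
    stop("tensor fitting expects a scheme restricted to the shortest echo time")
  ok <- signal > 0
  if (sum(ok) < 7)
    return(fit_failure("tensor", "fewer than 7 usable measurements", 4L))
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  X <- cbind(1, -scheme$b * g[, 1]^2, -scheme$b * g[, 2]^2,
             -scheme$b * g[, 3]^2, -2 * scheme$b * g[, 1] * g[, 2],
             -2 * scheme$b * g[, 1] * g[, 3],
             -2 * scheme$b * g[, 2] * g[, 3])
  qrX <- qr(X[ok, , drop = FALSE])
  if (qrX$rank < 7)
    stop(sprintf("rank-deficient direction set: design matrix rank %d < 7 (need >= 6 non-collinear directions plus a low-b reference)",
                 qrX$rank))
  beta <- qr.coef(qrX, log(signal[ok]))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- pmax(eigen(D, symmetric = TRUE)$values, 0)
  fitted <- exp(X %*% beta)
  dr_fit(params = list(tensor = D, s0 = exp(beta[1]),
                       eigenvalues = ev,
                       fa = fractional_anisotropy(ev)),
         model = "tensor",
         residual_norm = sqrt(sum((signal - fitted)^2)),
         converged = TRUE, n_iterations = 1L)
}

check_fit_inputs <- function(signal, scheme, min_te, min_b) {
  if (length(signal) != nrow(scheme))
    stop(sprintf("signal length (%d) does not match scheme length (%d)",
                 length(signal), nrow(scheme)))
  if (length(unique(scheme$te)) < min_te)
    stop(sprintf("need >= %d distinct echo times", min_te))
  if (length(unique(scheme$b)) < min_b)
    stop(sprintf("need >= %d distinct b-values", min_b))
  invisible(TRUE)
}

#' Fit a model voxel-wise over a masked 4D volume
#'
#' Applies [fit_monoexp()], [fit_ivim()] or [fit_tensor_fa()] to every
#' voxel inside the mask and assembles 3D parameter maps. Non-converged
#' voxels are recorded (count and fraction in the attached summary) but
#' never abort the volume. Deterministic for a given seed.
#'
#' @param data_4d 4D array, last dimension matching `nrow(scheme)`.
#' @param mask logical 3D array of voxels to fit.
#' @param scheme an [acq_scheme()].
#' @param model `"monoexp"`, `"ivim"` or `"tensor"`.
#' @param strategy forwarded to [fit_ivim()].
#' @param seed integer seed forwarded to the voxel fits.
#' @return list of class `parameter_maps`: `maps` (named list of 3D
#'   arrays, `NA` outside the mask), `converged` (logical array) and
#'   `summary` (voxel counts, non-convergence fraction, model, seed).
#' @export
fit_volume <- function(data_4d, mask, scheme,
                       model = c("monoexp", "ivim", "tensor"),
                       strategy = "full", seed = 1L) {
  model <- match.arg(model)
  dims <- dim(data_4d)
  if (length(dims) != 4)
    stop("data_4d must be a 4D array")
  if (!all(dims[1:3] == dim(mask)))
    stop("mask dimensions do not match the data volume")
  if (model == "tensor") {
    sub <- scheme_at_te_min(scheme)
    meas_idx <- attr(sub, "index")
    scheme_used <- sub
  } else {
    meas_idx <- seq_len(nrow(scheme))
    scheme_used <- scheme
  }
  if (dims[4] != nrow(scheme))
    stop(sprintf("4th dimension (%d) does not match scheme length (%d)",
                 dims[4], nrow(scheme)))
  idx <- which(mask)
  if (length(idx) == 0) stop("mask is empty: nothing to fit")

  par_names <- switch(model,
    monoexp = c("s0", "t2_star", "adc"),
    ivim = c("s0", "f", "t2_star_fast", "t2_star_slow", "d_star", "adc"),
    tensor = c("s0", "fa"))
  maps <- stats::setNames(lapply(par_names, function(p)
    array(NA_real_, dim = dims[1:3])), par_names)
  conv <- array(FALSE, dim = dims[1:3])
  rnorm_map <- array(NA_real_, dim = dims[1:3])

  nvox <- prod(dims[1:3])
  for (v in idx) {
    sig <- data_4d[v + (meas_idx - 1) * nvox]
    fit <- switch(model,
      monoexp = fit_monoexp(sig, scheme_used),
      ivim = fit_ivim(sig, scheme_used, strategy = strategy,
                      seed = derive_seed(seed, v)),
      tensor = fit_tensor_fa(sig, scheme_used))
    conv[v] <- isTRUE(fit$converged)
    rnorm_map[v] <- fit$residual_norm
    for (p in par_names)
      if (!is.null(fit$params[[p]])) maps[[p]][v] <- fit$params[[p]]
  }
  n_bad <- sum(!conv[idx])
  structure(list(
    maps = maps, converged = conv, residual_norm = rnorm_map,
    summary = list(model = model, n_voxels = length(idx),
                   n_nonconverged = n_bad,
                   fraction_nonconverged = n_bad / length(idx),
                   seed = seed)),
    class = "parameter_maps")
}

#' Exhaustive coarse-grid minimisers (independent oracles)
#'
#' Brute-force least-squares minimisation used to cross-check the
#' nonlinear fits. The decay-shape parameters are enumerated
#' exhaustively on a rectangular grid; the amplitude s0 enters the model
#' linearly and is therefore profiled out exactly at every grid node
#' (\eqn{\hat s_0 = \langle y, m\rangle / \langle m, m\rangle}), which
#' keeps the oracle exhaustive over the nonlinear parameters without an
#' amplitude-quantisation artefact. The gradient-based solution of the
#' same objective should land within one grid spacing of the exhaustive
#' minimum for every parameter the data identify; along the
#' fast-compartment ridge (t2_star_fast, d_star) the sound comparison is
#' on the objective value, which the returned `sse` supports.
#'
#' @param signal measured signal vector.
#' @param scheme an [acq_scheme()].
#' @param grid named list of parameter grids for the nonlinear
#'   parameters; defaults cover the physiological fitting box.
#' @return list: `params` (grid minimiser with the profiled `s0`),
#'   `sse`, `spacing` (grid step per nonlinear parameter).
#' @export
brute_force_monoexp <- function(signal, scheme, grid = NULL) {
  if (is.null(grid))
    grid <- list(t2_star = seq(10, 120, length.out = 45),
                 adc = seq(0, 5e-3, length.out = 41))
  dte <- scheme$te - te_min(scheme)
  A <- exp(-outer(dte, 1 / grid$t2_star))         # n_meas x n_t2
  B <- exp(-outer(scheme$b, grid$adc))            # n_meas x n_adc
  C <- crossprod(A, signal * B)                   # <y, a_i b_j>
  N <- crossprod(A^2, B^2)                        # <m, m> per (i, j)
  sse <- sum(signal^2) - C^2 / N                  # profiled residual SS
  m <- arrayInd(which.min(sse), dim(sse))
  list(params = c(s0 = C[m] / N[m], t2_star = grid$t2_star[m[1]],
                  adc = grid$adc[m[2]]),
       sse = sse[m],
       spacing = vapply(grid, function(g) diff(g[1:2]), numeric(1)))
}

#' @rdname brute_force_monoexp
#' @export
brute_force_ivim <- function(signal, scheme, grid = NULL) {
  if (is.null(grid))
    grid <- list(f = seq(0.05, 0.55, length.out = 21),
                 t2_star_fast = seq(40, 140, length.out = 21),
                 t2_star_slow = seq(20, 80, length.out = 25),
                 d_star = seq(0.01, 0.11, length.out = 21),
                 adc = seq(5e-4, 4e-3, length.out = 15))
  dte <- scheme$te - te_min(scheme)
  shape_grid <- expand.grid(f = grid$f, t2f = grid$t2_star_fast,
                            t2s = grid$t2_star_slow, ds = grid$d_star,
                            adc = grid$adc)
  yy <- sum(signal^2)
  best <- list(sse = Inf)
  chunk <- 4000L
  n <- nrow(shape_grid)
  for (start in seq(1, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    gsub <- shape_grid[rows, ]
    # unit-amplitude model shapes: n_meas x n_combo
    Ef <- exp(-outer(dte, 1 / gsub$t2f)) * exp(-outer(scheme$b, gsub$ds))
    Es <- exp(-outer(dte, 1 / gsub$t2s)) * exp(-outer(scheme$b, gsub$adc))
    M <- Ef * rep(gsub$f, each = length(signal)) +
      Es * rep(1 - gsub$f, each = length(signal))
    ym <- as.numeric(crossprod(M, signal))
    mm <- colSums(M^2)
    sse <- yy - ym^2 / mm
    j <- which.min(sse)
    if (sse[j] < best$sse)
      best <- list(sse = sse[j],
                   params = c(s0 = ym[j] / mm[j], f = gsub$f[j],
                              t2_star_fast = gsub$t2f[j],
                              t2_star_slow = gsub$t2s[j],
                              d_star = gsub$ds[j], adc = gsub$adc[j]))
  }
  list(params = best$params, sse = best$sse,
       spacing = vapply(grid, function(g) diff(g[1:2]), numeric(1)))
}
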