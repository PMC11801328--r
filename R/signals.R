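#' Parameter sets for the diffusion-relaxation signal models
#'
#' `monoexp_params()` holds the T2*-ADC model parameters: `s0`, the signal
#' at the shortest echo time with zero diffusion weighting (arbitrary
#' units), `t2_star` (ms) and `adc` (mm^2/s). `ivim_params()` holds the
#' two-compartment T2*-IVIM parameters: `s0`, the perfusion fraction `f`
#' in \[0, 1\], per-compartment relaxation times `t2_star_fast` and
#' `t2_star_slow` (ms), the pseudo-diffusion coefficient `d_star` and the
#' apparent diffusion coefficient `adc` (both mm^2/s). By labelling
#' convention the fast (perfusing) compartment is the one with the larger
#' diffusion coefficient, so `d_star > adc`.
#'
#' @param s0 signal at TE_min, b = 0 (a.u.), > 0.
#' @param t2_star,t2_star_fast,t2_star_slow effective T2* times, ms, > 0.
#' @param adc apparent diffusion coefficient, mm^2/s, >= 0.
#' @param f perfusion fraction in \[0, 1\].
#' @param d_star pseudo-diffusion coefficient, mm^2/s; must exceed `adc`.
#' @return a named list of class `monoexp_params` or `ivim_params`.
#' @export
monoexp_params <- function(s0, t2_star, adc) {
  if (s0 <= 0) stop("s0 must be positive")
  if (t2_star <= 0) stop("t2_star must be positive")
  if (adc < 0) stop("adc must be non-negative")
  structure(list(s0 = s0, t2_star = t2_star, adc = adc),
            class = "monoexp_params")
}

#' @rdname monoexp_params
#' @export
ivim_params <- function(s0, f, t2_star_fast, t2_star_slow, d_star, adc) {
  if (s0 <= 0) stop("s0 must be positive")
  if (f < 0 || f > 1) stop("perfusion fraction f must lie in [0, 1]")
  if (t2_star_fast <= 0 || t2_star_slow <= 0)
    stop("compartment T2* times must be positive")
  if (adc < 0) stop("adc must be non-negative")
  if (d_star <= adc)
    stop("d_star must exceed adc (fast-compartment labelling convention)")
  structure(list(s0 = s0, f = f, t2_star_fast = t2_star_fast,
                 t2_star_slow = t2_star_slow, d_star = d_star, adc = adc),
            class = "ivim_params")
}

#' Forward signal models
#'
#' `signal_monoexp()` evaluates the T2*-ADC model
#' \deqn{S(TE, b) = S_0 \exp(-(TE - TE_{min})/T_2^*) \exp(-b \cdot ADC)}
#' and `signal_ivim()` the two-compartment T2*-IVIM model
#' \deqn{S(TE, b) = S_0 [ f e^{-(TE - TE_{min})/T_{2,fast}^*} e^{-b D^*}
#'   + (1 - f) e^{-(TE - TE_{min})/T_{2,slow}^*} e^{-b \cdot ADC} ]}
#' for every measurement of an acquisition scheme. Both are isotropic:
#' the gradient direction does not enter. `signal_tensor()` evaluates the
#' single diffusion-tensor model \eqn{S = S_0 \exp(-b \, g^T D g)} on a
#' scheme restricted to one echo time (the tensor substrate for FA).
#'
#' @param params a [monoexp_params()] or [ivim_params()].
#' @param scheme an [acq_scheme()].
#' @return numeric vector of non-negative signals, one per measurement.
#' @examples
#' s <- build_paper_scheme()
#' sig <- signal_monoexp(monoexp_params(100, 50, 2e-3), s)
#' @export
signal_monoexp <- function(params, scheme) {
  if (params$t2_star <= 0) stop("t2_star must be positive")
  dte <- scheme$te - te_min(scheme)
  params$s0 * exp(-dte / params$t2_star) * exp(-scheme$b * params$adc)
}

#' @rdname signal_monoexp
#' @export
signal_ivim <- function(params, scheme) {
  if (params$f < 0 || params$f > 1)
    stop("perfusion fraction f must lie in [0, 1]")
  dte <- scheme$te - te_min(scheme)
  fast <- params$f * exp(-dte / params$t2_star_fast) *
    exp(-scheme$b * params$d_star)
  slow <- (1 - params$f) * exp(-dte / params$t2_star_slow) *
    exp(-scheme$b * params$adc)
  params$s0 * (fast + slow)
}

#' @rdname signal_monoexp
#' @param tensor a [diffusion_tensor()].
#' @export
signal_tensor <- function(tensor, scheme) {
  D <- tensor$D
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  quad <- rowSums((g %*% D) * g)   # g^T D g per measurement
  tensor$s0 * exp(-scheme$b * quad)
}

#' Symmetric diffusion tensor
#'
#' @param D symmetric 3x3 matrix of diffusivities, mm^2/s.
#' @param s0 non-diffusion-weighted signal, a.u.
#' @return object of class `diffusion_tensor` with fields `D` and `s0`.
#' @export
diffusion_tensor <- function(D, s0 = 1) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("diffusion tensor must be symmetric")
  structure(list(D = D, s0 = s0), class = "diffusion_tensor")
}

#' Fractional anisotropy of a tensor or eigenvalue set
#'
#' \deqn{FA = \sqrt{1/2}\,
#'   \sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
#'         (\lambda_3-\lambda_1)^2} / \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}
#'
#' @param x a `diffusion_tensor` or a numeric vector of 3 eigenvalues.
#' @return FA in \[0, 1\]; 0 for a zero tensor.
#' @export
fractional_anisotropy <- function(x) {
  ev <- if (inherits(x, "diffusion_tensor")) eigen(x$D, symmetric = TRUE)$values
        else as.numeric(x)
  denom <- sum(ev^2)
  if (denom <= 0) return(0)
  fa <- sqrt(0.5) * sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                           (ev[3] - ev[1])^2) / sqrt(denom)
  min(max(fa, 0), 1)
}

#' Add measurement noise to a signal vector
#'
#' Rician noise is the magnitude-MRI default:
#' \eqn{\tilde S = \sqrt{(S + n_1)^2 + n_2^2}} with independent
#' \eqn{n_1, n_2 \sim N(0, \sigma)}. Gaussian noise (\eqn{S + n_1}) is
#' offered for oracle tests where an unbiased perturbation is wanted.
#' `sigma = 0` returns the input unchanged; output is reproducible for a
#' fixed seed.
#'
#' @param signal numeric vector of noiseless signals.
#' @param sigma noise standard deviation (a.u.), >= 0.
#' @param model `"rician"` or `"gaussian"`.
#' @param seed optional integer; when given the draw is deterministic.
#' @return noisy signal vector of the same length.
#' @export
add_noise <- function(signal, sigma, model = c("rician", "gaussian"),
                      seed = NULL) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(signal)
  draw <- function() {
    n1 <- stats::rnorm(length(signal), 0, sigma)
    if (model == "gaussian") return(signal + n1)
    n2 <- stats::rnorm(length(signal), 0, sigma)
    sqrt((signal + n1)^2 + n2^2)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
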