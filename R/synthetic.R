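#' Ground-truth configuration of the synthetic placenta generator
#'
#' One editable block holding every population parameter the generator
#' uses. Values are generator configuration chosen to be physiologically
#' plausible for placental tissue, not measured claims: the control
#' slow-compartment T2* declines linearly from about 70 ms at 20 weeks to
#' about 40 ms at 32 weeks; the fast (perfusing) compartment relaxes more
#' slowly (offset +30 ms); preterm cases have T2* scaled down in both
#' compartments when membranes have ruptured (PPROM) and predominantly in
#' the slow compartment when membranes are intact; perfusion fraction,
#' ADC, D* and FA carry no gestational-age or group effect.
#'
#' @return named list of generator settings (units in comments/fields:
#'   ms, ms/week, mm^2/s, dimensionless fractions).
#' @export
phantom_config <- function() {
  list(
    s0 = 100,                     # a.u. at TE_min, b = 0
    t2s_at20 = 70,                # ms, control slow-compartment T2* at 20 wk
    t2s_slope = -2.5,             # ms per week of gestation
    t2_fast_offset = 30,          # ms; t2_fast = t2_slow + offset
    t2_floor = 15,                # ms, lower clamp on any T2*
    group_scale = list(           # multiplicative T2* effects vs control
      control = c(fast = 1.00, slow = 1.00),
      pprom   = c(fast = 0.72, slow = 0.72),
      intact  = c(fast = 0.95, slow = 0.82)),
    f = 0.25,                     # perfusion fraction
    d_star = 0.05,                # mm^2/s, pseudo-diffusion
    adc = 2e-3,                   # mm^2/s
    fa = 0.15,                    # parenchymal fractional anisotropy
    between_sd = list(            # between-subject SD of ROI-mean truth
      t2 = 5, adc = 1.5e-4, f = 0.03, fa = 0.02, d_star = 5e-3),
    roi_noise_sd = list(          # residual ROI-estimation noise
      t2 = 0.5, adc = 2e-5, f = 5e-3, fa = 5e-3, d_star = 2e-3),
    voxel_cv = 0.10,              # amplitude of low-frequency spatial field
    ga_mri_controls = c(20, 36),  # wk, scan window for controls
    ga_onset_cases = c(23, 29.5), # wk, symptom onset window for cases
    onset_to_mri_days = c(0, 10), # d, delay from onset to scan
    ctrl_delivery = c(mean = 39.5, sd = 1.2)  # wk, truncated to [37, 42]
  )
}

group_levels <- function() c("control", "pprom", "intact")

# Population-mean compartment T2* for a group at a gestational age.
t2_group_means <- function(ga_weeks, group, cfg = phantom_config()) {
  t2s <- cfg$t2s_at20 + cfg$t2s_slope * (ga_weeks - 20)
  t2f <- t2s + cfg$t2_fast_offset
  sc <- cfg$group_scale[[group]]
  c(fast = max(t2f * sc[["fast"]], cfg$t2_floor),
    slow = max(t2s * sc[["slow"]], cfg$t2_floor))
}

# Mono-exponential T2* implied by the two-compartment truth: the
# signal-fraction-weighted mean, the effective decay seen by Eq.-1-style
# summaries at moderate echo times.
monoexp_t2_from_ivim <- function(f, t2_fast, t2_slow) {
  f * t2_fast + (1 - f) * t2_slow
}

# Smooth low-frequency 3D modulation field in [-1, 1]-ish range, built
# from a few random cosine modes; deterministic under the active RNG.
smooth_field <- function(shape, n_modes = 4L) {
  ax <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)
  grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  field <- 0
  for (m in seq_len(n_modes)) {
    k <- stats::runif(3, 0.5, 2)         # cycles across the volume
    phi <- stats::runif(3, 0, 2 * pi)
    field <- field + cos(2 * pi * k[1] * grid$x + phi[1]) *
      cos(2 * pi * k[2] * grid$y + phi[2]) *
      cos(2 * pi * k[3] * grid$z + phi[3])
  }
  array(field / n_modes, dim = shape)
}

ellipsoid_mask <- function(shape, semi = c(0.40, 0.32, 0.26)) {
  ax <- lapply(seq_along(shape), function(i) {
    ((seq_len(shape[i]) - 0.5) / shape[i] - 0.5) / semi[i]
  })
  grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  array(grid$x^2 + grid$y^2 + grid$z^2 <= 1, dim = shape)
}

#' Synthetic placenta phantom
#'
#' Builds per-voxel ground-truth parameter maps for one subject: an
#' ellipsoidal parenchyma mask inside a 3D grid, voxel-wise
#' two-compartment (T2*-IVIM) parameters drawn around group- and
#' gestation-dependent means with smooth low-frequency spatial
#' modulation, plus the implied mono-exponential T2* map and an FA map.
#' Control T2* declines with gestational age; PPROM lowers both
#' compartments' T2*; intact-membrane cases predominantly the slow
#' compartment.
#'
#' @param ga_weeks gestational age at scan, weeks (20-41).
#' @param group `"control"`, `"pprom"` or `"intact"`.
#' @param shape integer 3-vector of grid dimensions (default 32^3).
#' @param seed integer seed; identical arguments and seed give identical
#'   phantoms.
#' @param voxel_size voxel edge length, mm.
#' @param config generator configuration, see [phantom_config()].
#' @return list of class `placenta_phantom`: `shape`, `mask` (logical
#'   array), `voxel_size`, `ga_weeks`, `group`, and `maps`, a named list
#'   of 3D arrays (`t2_star_fast`, `t2_star_slow`, `f`, `d_star`, `adc`,
#'   `t2_star`, `fa`, `s0`) defined on the full grid and meaningful
#'   inside the mask.
#' @export
make_phantom <- function(ga_weeks, group, shape = c(32L, 32L, 32L),
                         seed = 1L, voxel_size = 3,
                         config = phantom_config()) {
  if (ga_weeks < 20 || ga_weeks > 41)
    stop("ga_weeks must lie in [20, 41]")
  if (!group %in% group_levels())
    stop(sprintf("unknown group '%s' (expected control/pprom/intact)", group))
  shape <- as.integer(shape)
  with_local_seed(seed, {
    mask <- ellipsoid_mask(shape)
    if (!any(mask)) stop("phantom mask is empty; increase grid size")
    mu <- t2_group_means(ga_weeks, group, config)
    # subject-level deviation shared by all voxels
    subj_t2 <- stats::rnorm(1, 0, config$between_sd$t2)
    subj_f <- stats::rnorm(1, 0, config$between_sd$f)
    mod_t2 <- smooth_field(shape) * config$voxel_cv
    mod_f <- smooth_field(shape) * config$voxel_cv
    mod_s0 <- smooth_field(shape) * config$voxel_cv
    t2f <- pmax((mu[["fast"]] + subj_t2) * (1 + mod_t2), config$t2_floor)
    t2s <- pmax((mu[["slow"]] + subj_t2) * (1 + mod_t2), config$t2_floor)
    f <- pmin(pmax(config$f + subj_f + 0.2 * config$f * mod_f, 0.02), 0.6)
    adc <- config$adc * (1 + 0.1 * mod_f)
    d_star <- array(config$d_star, dim = shape)
    s0 <- config$s0 * (1 + mod_s0)
    maps <- list(
      t2_star_fast = t2f, t2_star_slow = t2s, f = f,
      d_star = d_star, adc = adc,
      t2_star = monoexp_t2_from_ivim(f, t2f, t2s),
      fa = array(pmin(pmax(config$fa * (1 + 0.2 * mod_f), 0), 1), dim = shape),
      s0 = s0)
    structure(list(shape = shape, mask = mask, voxel_size = voxel_size,
                   ga_weeks = ga_weeks, group = group, maps = maps,
                   seed = seed),
              class = "placenta_phantom")
  })
}

#' Simulate a 4D acquisition from a phantom
#'
#' Evaluates the two-compartment forward model voxel-wise on an
#' acquisition scheme and adds measurement noise. `snr` sets sigma
#' relative to the configured `s0` at the shortest echo time and lowest
#' b-value; `snr = Inf` gives noiseless data.
#'
#' @param phantom a [make_phantom()] result.
#' @param scheme an [acq_scheme()].
#' @param snr signal-to-noise ratio at TE_min and the lowest b-value.
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#' @param seed integer seed for the noise draw.
#' @return 4D array `c(shape, nrow(scheme))`; voxels outside the mask are 0.
#' @export
simulate_subject_data <- function(phantom, scheme, snr = 30,
                                  noise_model = "rician", seed = 1L) {
  idx <- which(phantom$mask)
  n_meas <- nrow(scheme)
  data <- array(0, dim = c(phantom$shape, n_meas))
  m <- phantom$maps
  dte <- scheme$te - te_min(scheme)
  sig_ref <- exp(-min(scheme$b) * phantom_config()$adc)
  sigma <- if (is.infinite(snr)) 0 else
    mean(m$s0[idx]) * sig_ref / snr
  vox_sig <- vapply(idx, function(i) {
    p <- ivim_params(m$s0[i], m$f[i], m$t2_star_fast[i], m$t2_star_slow[i],
                     m$d_star[i], m$adc[i])
    signal_ivim(p, scheme)
  }, numeric(n_meas))
  if (sigma > 0)
    vox_sig <- with_local_seed(seed, {
      apply(vox_sig, 2, function(s) add_noise(s, sigma, noise_model))
    })
  nvox <- prod(phantom$shape)
  for (k in seq_len(n_meas)) data[idx + (k - 1) * nvox] <- vox_sig[k, ]
  attr(data, "sigma") <- sigma
  data
}

#' MRI-to-delivery latency distribution
#'
#' Latencies (days from the scan to delivery among preterm cases) are
#' drawn from a gamma distribution moment-matched to the cohort summary
#' of mean 8 days, SD 8.7 days, on support (0, Inf). A gamma is used
#' because no distribution obtained by truncating a normal below zero can
#' carry a coefficient of variation above 1 (here 8.7/8 = 1.09), whereas
#' the gamma reproduces both stated moments exactly.
#'
#' @param n number of draws.
#' @param mean_days,sd_days target mean and SD in days.
#' @param seed optional integer seed.
#' @return numeric vector of positive latencies, days.
#' @export
rlatency <- function(n, mean_days = 8, sd_days = 8.7, seed = NULL) {
  shape <- (mean_days / sd_days)^2
  rate <- mean_days / sd_days^2
  draw <- function() stats::rgamma(n, shape = shape, rate = rate)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a preterm-birth imaging cohort
#'
#' Generates subject records with the structure the cohort statistics
#' assume: `n_cases` women who deliver before 32 weeks (`n_pprom` of them
#' with ruptured membranes at scan time, the rest intact) and
#' `n_controls` who deliver at term (>= 37 weeks). Case gestational ages
#' satisfy onset <= MRI <= delivery; the MRI-to-delivery latency is drawn
#' from [rlatency()] and subjects violating the < 32-week delivery
#' constraint are resampled (the retry count is recorded in attribute
#' `n_retries`).
#'
#' With `roi = "analytic"` (default) the per-subject ROI parameter means
#' are filled directly from the generator's subject-level ground truth
#' plus small ROI-estimation noise, which makes cohort-scale statistics
#' cheap; with `roi = "none"` they are left `NA` for the imaging pipeline
#' to fill.
#'
#' @param n_cases,n_pprom,n_controls cohort sizes (defaults 23/14/52).
#' @param latency_mean_days,latency_sd_days latency distribution moments.
#' @param seed integer seed.
#' @param roi `"analytic"` or `"none"`.
#' @param config generator configuration, see [phantom_config()].
#' @return data frame with one row per subject: `subject_id`, `group`,
#'   `is_case`, `ga_onset`, `ga_mri`, `ga_delivery`, `latency_days`, and
#'   (when filled) ROI-mean columns `t2_star`, `adc`, `f`,
#'   `t2_star_fast`, `t2_star_slow`, `d_star`, `fa`.
#' @export
make_cohort <- function(n_cases = 23, n_pprom = 14, n_controls = 52,
                        latency_mean_days = 8, latency_sd_days = 8.7,
                        seed = 1L, roi = c("analytic", "none"),
                        config = phantom_config()) {
  roi <- match.arg(roi)
  if (n_pprom > n_cases) stop("n_pprom cannot exceed n_cases")
  with_local_seed(seed, {
    n_retries <- 0L
    case_group <- rep(c("pprom", "intact"), c(n_pprom, n_cases - n_pprom))
    cases <- lapply(seq_len(n_cases), function(i) {
      repeat {
        onset <- stats::runif(1, config$ga_onset_cases[1],
                              config$ga_onset_cases[2])
        mri <- onset + stats::runif(1, config$onset_to_mri_days[1],
                                    config$onset_to_mri_days[2]) / 7
        lat <- rlatency(1, latency_mean_days, latency_sd_days)
        delivery <- mri + lat / 7
        if (delivery < 32 && mri < 32) {
          return(data.frame(group = case_group[i], ga_onset = onset,
                            ga_mri = mri, ga_delivery = delivery,
                            latency_days = lat))
        }
        n_retries <<- n_retries + 1L
      }
    })
    ctrls <- data.frame(
      group = rep("control", n_controls),
      ga_onset = NA_real_,
      ga_mri = stats::runif(n_controls, config$ga_mri_controls[1],
                            config$ga_mri_controls[2]),
      ga_delivery = rtrunc_norm(n_controls, config$ctrl_delivery[["mean"]],
                                config$ctrl_delivery[["sd"]], 37, 42),
      latency_days = NA_real_)
    tab <- rbind(do.call(rbind, cases), ctrls)
    tab <- data.frame(subject_id = sprintf("S%03d", seq_len(nrow(tab))), tab)
    tab$is_case <- tab$group != "control"
    for (p in c("t2_star", "adc", "f", "t2_star_fast", "t2_star_slow",
                "d_star", "fa"))
      tab[[p]] <- NA_real_
    if (roi == "analytic") tab <- fill_roi_analytic(tab, config)
    attr(tab, "n_retries") <- n_retries
    tab
  })
}

# Subject-level ROI ground truth: group/GA mean + between-subject
# variation + residual ROI-estimation noise. Uses the active RNG.
fill_roi_analytic <- function(tab, config = phantom_config()) {
  n <- nrow(tab)
  bsd <- config$between_sd
  rsd <- config$roi_noise_sd
  for (i in seq_len(n)) {
    mu <- t2_group_means(tab$ga_mri[i], tab$group[i], config)
    t2f <- mu[["fast"]] + stats::rnorm(1, 0, bsd$t2) + stats::rnorm(1, 0, rsd$t2)
    t2s <- mu[["slow"]] + stats::rnorm(1, 0, bsd$t2) + stats::rnorm(1, 0, rsd$t2)
    f <- min(max(config$f + stats::rnorm(1, 0, bsd$f) +
                   stats::rnorm(1, 0, rsd$f), 0.02), 0.6)
    tab$t2_star_fast[i] <- max(t2f, config$t2_floor)
    tab$t2_star_slow[i] <- max(t2s, config$t2_floor)
    tab$f[i] <- f
    tab$t2_star[i] <- monoexp_t2_from_ivim(f, tab$t2_star_fast[i],
                                           tab$t2_star_slow[i])
    tab$adc[i] <- config$adc + stats::rnorm(1, 0, bsd$adc) +
      stats::rnorm(1, 0, rsd$adc)
    tab$d_star[i] <- max(config$d_star + stats::rnorm(1, 0, bsd$d_star),
                         10 * config$adc)
    tab$fa[i] <- min(max(config$fa + stats::rnorm(1, 0, bsd$fa) +
                           stats::rnorm(1, 0, rsd$fa), 0), 1)
  }
  tab
}
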