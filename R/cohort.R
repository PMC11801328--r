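# Cohort-level statistics: gestational-age trends among controls,
# case-control and membrane-status subgroup contrasts, and the
# standardised latency-ratio split among cases. All models are ordinary
# least squares via stats::lm; significance is two-sided at 0.05 with no
# multiple-testing correction.

regression_report <- function(fit, outcome, term, n, label) {
  co <- summary(fit)$coefficients
  structure(list(outcome = outcome, label = label,
                 coefficients = co,
                 estimate = unname(co[term, "Estimate"]),
                 se = unname(co[term, "Std. Error"]),
                 p_value = unname(co[term, "Pr(>|t|)"]),
                 term = term, n = n, fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression> %s: %s\n", x$outcome, x$label))
  cat(sprintf("  %s = %.4g (SE %.3g), p = %.4g, n = %d\n",
              x$term, x$estimate, x$se, x$p_value, x$n))
  invisible(x)
}

check_parameter <- function(subjects, parameter) {
  if (!parameter %in% names(subjects))
    stop(sprintf("parameter '%s' is not a column of the cohort table",
                 parameter))
}

#' Gestational-age trend among controls
#'
#' Ordinary least-squares regression of a subject's ROI-mean parameter on
#' gestational age at MRI, restricted to controls, reporting the slope
#' per week and its p-value.
#'
#' @param subjects cohort data frame (see [make_cohort()]).
#' @param parameter outcome column name, e.g. `"t2_star"`.
#' @return a `regression_report` whose `estimate` is the GA slope.
#' @export
ga_trend <- function(subjects, parameter) {
  check_parameter(subjects, parameter)
  ctrl <- subjects[subjects$group == "control" &
                     !is.na(subjects[[parameter]]), ]
  if (nrow(ctrl) < 3)
    stop("need at least 3 controls with a defined parameter")
  fit <- stats::lm(stats::reformulate("ga_mri", parameter), data = ctrl)
  regression_report(fit, parameter, "ga_mri", nrow(ctrl),
                    "GA-at-MRI trend among controls")
}

#' Case-control and subgroup contrasts
#'
#' Ordinary least squares of the ROI-mean parameter on gestational age at
#' MRI (covariate, configurable) plus a case indicator with controls as
#' the reference level. Subgroup analyses compare only the named case
#' subset (membranes ruptured, `"pprom"`, or intact, `"intact"`) against
#' all controls.
#'
#' @inheritParams ga_trend
#' @param subgroup `"all_cases"`, `"pprom"` or `"intact"`.
#' @param adjust_ga include GA-at-MRI as a covariate (default TRUE).
#' @return a `regression_report` whose `estimate` is the case effect.
#' @export
group_contrast <- function(subjects, parameter,
                           subgroup = c("all_cases", "pprom", "intact"),
                           adjust_ga = TRUE) {
  subgroup <- match.arg(subgroup)
  check_parameter(subjects, parameter)
  keep <- subjects$group == "control" |
    (if (subgroup == "all_cases") subjects$is_case
     else subjects$group == subgroup)
  dat <- subjects[keep & !is.na(subjects[[parameter]]), ]
  if (!any(dat$is_case))
    stop(sprintf("subgroup '%s' is empty", subgroup))
  if (!any(!dat$is_case)) stop("control group is empty")
  dat$case <- as.integer(dat$is_case)
  rhs <- if (adjust_ga) c("ga_mri", "case") else "case"
  fit <- stats::lm(stats::reformulate(rhs, parameter), data = dat)
  regression_report(fit, parameter, "case", nrow(dat),
                    sprintf("%s vs controls%s", subgroup,
                            if (adjust_ga) " (GA-adjusted)" else ""))
}

#' Latency ratio for a preterm case
#'
#' Ratio of the remaining interval to delivery over the elapsed interval
#' since symptom onset, both measured from the scan:
#' \deqn{ratio = (GA_{delivery} - GA_{MRI}) / (GA_{MRI} - GA_{onset})}
#' so the score decreases as the scan sits relatively closer to delivery
#' than to the first symptom. Vectorised; a subject scanned at symptom
#' onset (`ga_mri == ga_onset`) has an undefined ratio and is returned as
#' `NA` with a warning.
#'
#' @param ga_onset,ga_mri,ga_delivery gestational ages in weeks with
#'   `ga_onset <= ga_mri <= ga_delivery`.
#' @return numeric vector of ratios (dimensionless).
#' @examples
#' latency_score(24, 25, 26)   # 1: equidistant
#' latency_score(24, 25, 25)   # 0: scanned at delivery
#' @export
latency_score <- function(ga_onset, ga_mri, ga_delivery) {
  if (any(ga_onset > ga_mri | ga_mri > ga_delivery, na.rm = TRUE))
    stop("gestational ages must satisfy onset <= MRI <= delivery")
  denom <- ga_mri - ga_onset
  undef <- !is.na(denom) & denom == 0
  if (any(undef)) {
    warning(sprintf("%d subject(s) scanned at symptom onset: ratio undefined, excluded",
                    sum(undef)))
    denom[undef] <- NA_real_
  }
  (ga_delivery - ga_mri) / denom
}

#' Standardise latency ratios and split at zero
#'
#' Transforms the case ratios to z-scores (mean 0, SD 1 across the scored
#' cases) and assigns each case to the side of zero its score falls on.
#' Scores of exactly zero go to the above-zero side (a measure-zero event
#' for continuous ratios).
#'
#' @param ratio numeric vector of latency ratios (NA allowed; dropped
#'   from the standardisation and returned as NA).
#' @return data frame: `ratio`, `z`, `side` (factor, below_zero /
#'   above_zero).
#' @export
standardise_and_split <- function(ratio) {
  ok <- !is.na(ratio)
  if (sum(ok) < 2)
    stop("need at least 2 cases with a defined ratio")
  s <- stats::sd(ratio[ok])
  if (s == 0) stop("zero variance in latency ratios: split undefined")
  z <- (ratio - mean(ratio[ok])) / s
  side <- factor(ifelse(z < 0, "below_zero", "above_zero"),
                 levels = c("below_zero", "above_zero"))
  data.frame(ratio = ratio, z = z, side = side)
}

#' Contrast ROI parameters between latency-split sides
#'
#' Two-sided OLS comparison of the ROI-mean parameter between cases whose
#' standardised latency score is below zero (relatively closer to
#' delivery) and those above zero.
#'
#' @param cases case-only cohort rows carrying a `side` column from
#'   [standardise_and_split()].
#' @inheritParams ga_trend
#' @return a `regression_report` whose `estimate` is the below-zero
#'   effect (above-zero side as reference).
#' @export
split_contrast <- function(cases, parameter) {
  check_parameter(cases, parameter)
  dat <- cases[!is.na(cases$side) & !is.na(cases[[parameter]]), ]
  tabs <- table(dat$side)
  if (any(tabs == 0))
    stop(sprintf("one-sided split: no cases on the '%s' side",
                 names(tabs)[tabs == 0][1]))
  dat$below <- as.integer(dat$side == "below_zero")
  fit <- stats::lm(stats::reformulate("below", parameter), data = dat)
  regression_report(fit, parameter, "below", nrow(dat),
                    "below-zero vs above-zero latency score")
}

#' Run the full set of cohort comparisons
#'
#' Convenience wrapper producing one tidy row per test: GA trends among
#' controls, case-control contrasts (all cases, ruptured and intact
#' subgroups) for every fitted parameter, and the latency-split contrasts
#' among cases.
#'
#' @param subjects cohort table with ROI parameter columns filled.
#' @param parameters outcome columns to analyse.
#' @param alpha significance level recorded alongside each p-value.
#' @return data frame: `parameter`, `analysis`, `estimate`, `se`,
#'   `p_value`, `n`, `significant`.
#' @export
analyse_cohort <- function(subjects,
                           parameters = c("t2_star", "adc", "f",
                                          "t2_star_fast", "t2_star_slow",
                                          "fa"),
                           alpha = 0.05) {
  rows <- list()
  add <- function(rep, analysis) {
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = rep$outcome, analysis = analysis,
      estimate = rep$estimate, se = rep$se, p_value = rep$p_value,
      n = rep$n, significant = rep$p_value < alpha)
  }
  cases <- subjects[subjects$is_case, ]
  cases$ratio <- latency_score(cases$ga_onset, cases$ga_mri,
                               cases$ga_delivery)
  split <- standardise_and_split(cases$ratio)
  cases$side <- split$side
  for (p in parameters) {
    add(ga_trend(subjects, p), "ga_trend_controls")
    add(group_contrast(subjects, p, "all_cases"), "case_vs_control")
    for (sg in c("pprom", "intact"))
      if (any(subjects$group == sg))
        add(group_contrast(subjects, p, sg),
            sprintf("%s_vs_control", sg))
    add(split_contrast(cases, p), "latency_split")
  }
  do.call(rbind, rows)
}
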