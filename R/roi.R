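#' T2* exclusion threshold
#'
#' Removes voxels whose fitted T2* exceeds the supraphysiological cut
#' (default 200 ms) before region averaging. The exclusion is strictly
#' greater-than: a voxel at exactly the threshold is retained. Applied to
#' whichever model's T2* map is being summarised (the mono-exponential
#' map, or each compartment's map of the two-compartment model);
#' thresholding is idempotent.
#'
#' @param t2_map 3D array of T2* values, ms, defined on `mask`.
#' @param mask logical 3D array, the parenchyma region.
#' @param threshold_ms exclusion threshold, ms (> 0).
#' @return logical array: `mask & (t2_map <= threshold_ms)`.
#' @export
apply_t2star_threshold <- function(t2_map, mask, threshold_ms = 200) {
  if (threshold_ms <= 0) stop("threshold_ms must be positive")
  if (!all(dim(t2_map) == dim(mask)))
    stop("t2_map and mask dimensions differ")
  retained <- mask & !is.na(t2_map) & t2_map <= threshold_ms
  retained
}

#' Region-of-interest summary of parameter maps
#'
#' Reduces each parameter map to its arithmetic mean over the retained
#' voxels (the cohort analyses use region-specific mean values; a median
#' is available but never the default). An empty retained mask yields
#' `NA` means with a warning and flags the subject for exclusion from
#' cohort statistics.
#'
#' @param param_maps named list of 3D arrays (or a `parameter_maps`
#'   object from [fit_volume()]).
#' @param retained_mask logical array of voxels to average, typically
#'   from [apply_t2star_threshold()].
#' @param total_mask the pre-threshold parenchyma mask, for bookkeeping;
#'   defaults to `retained_mask`.
#' @param threshold_ms the threshold that produced `retained_mask`
#'   (recorded, not applied).
#' @param fun `"mean"` or `"median"`.
#' @return list of class `roi_summary`: `means` (named), `n_voxels_total`,
#'   `n_voxels_retained`, `threshold_ms`, `excluded` flag.
#' @export
summarise_roi <- function(param_maps, retained_mask,
                          total_mask = retained_mask, threshold_ms = NA,
                          fun = c("mean", "median")) {
  fun <- match.arg(fun)
  if (inherits(param_maps, "parameter_maps")) param_maps <- param_maps$maps
  n_ret <- sum(retained_mask)
  n_tot <- sum(total_mask)
  if (n_ret == 0) {
    warning("retained mask is empty; subject flagged for exclusion")
    means <- stats::setNames(rep(NA_real_, length(param_maps)),
                             names(param_maps))
  } else {
    agg <- if (fun == "mean") mean else stats::median
    means <- vapply(param_maps,
                    function(m) agg(m[retained_mask], na.rm = TRUE),
                    numeric(1))
  }
  structure(list(means = means, n_voxels_total = n_tot,
                 n_voxels_retained = n_ret, threshold_ms = threshold_ms,
                 excluded = n_ret == 0),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<ROI summary> %d/%d voxels retained (threshold %s ms)\n",
              x$n_voxels_retained, x$n_voxels_total,
              format(x$threshold_ms)))
  print(round(x$means, 6))
  invisible(x)
}
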