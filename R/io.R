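# NIfTI and table I/O plus the umbrella end-to-end workflow.

#' Read and write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the affine across round trips.
#' `read_nifti_4d` additionally checks dimensionality and, when a scheme
#' is supplied, cross-checks the 4th dimension against the sidecar
#' length before any fitting happens.
#'
#' @param path NIfTI-1 file path (`.nii` or `.nii.gz`).
#' @param scheme optional [acq_scheme()] to validate against.
#' @return `read_nifti_4d`: 4D array with attributes `affine` and
#'   `voxel_size` (mm). `write_nifti_map` invisibly returns `path`.
#' @export
read_nifti_4d <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop(sprintf("NIfTI file '%s' not found", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop(sprintf("'%s' is %dD where a 4D volume is expected",
                 path, length(dim(img))))
  if (!is.null(scheme) && dim(img)[4] != nrow(scheme))
    stop(sprintf("'%s' has %d volumes but the scheme lists %d measurements",
                 path, dim(img)[4], nrow(scheme)))
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "affine") <- structure(RNifti::xform(img), class = NULL)
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1:3]
  out
}

#' @rdname read_nifti_4d
#' @param volume 3D or 4D numeric array.
#' @param reference optional NIfTI image or array carrying the affine to
#'   reuse; float32 output.
#' @param voxel_size voxel edge lengths, mm, used when no reference is
#'   given.
#' @export
write_nifti_map <- function(volume, path, reference = NULL,
                            voxel_size = c(3, 3, 3)) {
  if (is.null(reference)) {
    nd <- length(dim(volume))
    reference <- RNifti::niftiHeader(list(
      dim = c(nd, dim(volume), rep(1L, 7 - nd)),
      pixdim = c(-1, voxel_size, rep(1, 7 - length(voxel_size))),
      datatype = 16L))  # float32
  }
  img <- RNifti::asNifti(volume, reference = reference, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_nifti_4d
#' @export
read_mask_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("NIfTI file '%s' not found", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop(sprintf("'%s' is %dD where a 3D mask is expected",
                 path, length(dim(img))))
  array(as.numeric(img) > 0.5, dim = dim(img))
}

#' Pipeline configuration
#'
#' Assembles the settings of a full simulate-fit-summarise-analyse run.
#' Defaults reproduce the study settings: the placental multi-echo
#' multi-b protocol, Rician noise, a 200 ms T2* exclusion threshold, 23
#' cases (14 with ruptured membranes) against 52 controls, significance
#' at 0.05.
#'
#' @param n_cases,n_pprom,n_controls cohort sizes.
#' @param shape phantom grid dimensions.
#' @param snr signal-to-noise ratio at TE_min and lowest b.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param strategy IVIM fitting strategy.
#' @param threshold_ms T2* exclusion threshold.
#' @param alpha significance level.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 23, n_pprom = 14, n_controls = 52,
                            shape = c(32L, 32L, 32L), snr = 30,
                            noise_model = "rician", strategy = "full",
                            threshold_ms = 200, alpha = 0.05, seed = 1L,
                            out_dir = tempfile("placentadr_run_")) {
  cfg <- list(n_cases = n_cases, n_pprom = n_pprom, n_controls = n_controls,
              shape = as.integer(shape), snr = snr,
              noise_model = noise_model, strategy = strategy,
              threshold_ms = threshold_ms, alpha = alpha,
              seed = as.integer(seed), out_dir = out_dir)
  stopifnot(cfg$threshold_ms > 0, cfg$n_pprom <= cfg$n_cases,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_cohort_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname run_end_to_end
#' @param path TSV path written by the pipeline.
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort table '%s' not found", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full synthetic pipeline end to end
#'
#' For each simulated subject: build a phantom, synthesise the 4D
#' acquisition on the protocol scheme, fit the mono-exponential,
#' two-compartment and tensor models voxel-wise, apply the T2* exclusion
#' threshold, average over the parenchyma region, and finally run the
#' cohort statistics on the resulting table. Writes the scheme sidecars,
#' the per-subject ROI table, the analysis table and a JSON manifest
#' (config, seed, package version) sufficient to reproduce the run. Any
#' stage failure halts with the stage and subject named; outputs written
#' so far are kept.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `cohort` (subject table with ROI
#'   means), `analysis` (tidy statistics table) and `out_dir`.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  if (config$n_controls == 0) stop("cohort stage: control group is empty")
  if (config$n_cases == 0) stop("cohort stage: case group is empty")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- build_paper_scheme()
  write_scheme(scheme, file.path(config$out_dir, "scheme.bval"),
               file.path(config$out_dir, "scheme.bvec"),
               file.path(config$out_dir, "scheme.te"))
  cohort <- make_cohort(config$n_cases, config$n_pprom, config$n_controls,
                        seed = derive_seed(config$seed, "cohort"),
                        roi = "none")
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    res <- tryCatch(
      simulate_and_fit_subject(cohort$ga_mri[i], cohort$group[i], scheme,
                               config,
                               seed = derive_seed(config$seed, sid)),
      error = function(e)
        stop(sprintf("stage 'subject-fit' failed for subject %s: %s",
                     sid, conditionMessage(e)), call. = FALSE))
    for (p in names(res$means)) cohort[[p]][i] <- res$means[[p]]
  }
  write_cohort_tsv(cohort, file.path(config$out_dir, "cohort.tsv"))
  analysis <- tryCatch(
    analyse_cohort(cohort, alpha = config$alpha),
    error = function(e)
      stop(sprintf("stage 'cohort-analysis' failed: %s",
                   conditionMessage(e)), call. = FALSE))
  write_cohort_tsv(analysis, file.path(config$out_dir, "analysis.tsv"))
  manifest <- list(
    package = "placentadr",
    version = as.character(utils::packageVersion("placentadr")),
    config = unclass(config),
    config_hash = config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, analysis = analysis,
                 out_dir = config$out_dir))
}

config_hash <- function(config) {
  # order-stable digest of the configuration without external deps
  s <- paste(deparse(unclass(config)[sort(names(unclass(config)))]),
             collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

# One subject through phantom -> signal -> three fits -> threshold -> ROI.
simulate_and_fit_subject <- function(ga, group, scheme, config, seed) {
  phantom <- make_phantom(ga, group, shape = config$shape,
                          seed = derive_seed(seed, "phantom"))
  data <- simulate_subject_data(phantom, scheme, snr = config$snr,
                                noise_model = config$noise_model,
                                seed = derive_seed(seed, "noise"))
  mono <- fit_volume(data, phantom$mask, scheme, "monoexp")
  ivim <- fit_volume(data, phantom$mask, scheme, "ivim",
                     strategy = config$strategy,
                     seed = derive_seed(seed, "ivim"))
  tens <- fit_volume(data, phantom$mask, scheme, "tensor")
  keep_mono <- apply_t2star_threshold(mono$maps$t2_star, phantom$mask,
                                      config$threshold_ms)
  keep_ivim <- apply_t2star_threshold(ivim$maps$t2_star_fast, phantom$mask,
                                      config$threshold_ms) &
    apply_t2star_threshold(ivim$maps$t2_star_slow, phantom$mask,
                           config$threshold_ms)
  roi_mono <- summarise_roi(mono$maps["t2_star"], keep_mono, phantom$mask,
                            config$threshold_ms)
  roi_adc <- summarise_roi(mono$maps["adc"], keep_mono, phantom$mask,
                           config$threshold_ms)
  roi_ivim <- summarise_roi(ivim$maps[c("f", "t2_star_fast", "t2_star_slow",
                                        "d_star")],
                            keep_ivim, phantom$mask, config$threshold_ms)
  roi_fa <- summarise_roi(tens$maps["fa"], phantom$mask, phantom$mask, NA)
  list(means = c(as.list(roi_mono$means), as.list(roi_adc$means),
                 as.list(roi_ivim$means), as.list(roi_fa$means)))
}
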