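#' Analysis parameters for the specimen pipeline
#'
#' Bundles the per-stage settings of [run_specimen()] / [run_study()].
#' Segmentation defaults are tuned to the synthetic condyle geometry (a
#' roughly four-fold scaled-down bone relative to a clinical field of view),
#' hence the 13-voxel threshold window; pass a [segmentation_params()] with
#' `window = 50` for clinical-scale volumes.
#'
#' @param segmentation A [segmentation_params()].
#' @param registration A [registration_config()].
#' @param transform `"register"` to estimate the PI-to-CT transform by
#'   mutual information, `"truth"` to use the generator's ground-truth
#'   transform (synthetic data only; isolates the downstream stages).
#' @param register_on `"pi"` registers the PI map itself; `"echo1"`
#'   registers the higher-SNR short echo and applies the transform to PI.
#' @param pi_floor Background floor for [compute_pi()] (`NULL` = automatic).
#' @param clamp_bmd Clamp negative calibrated BMD to zero?
#' @param scatter_n Number of (BMD, PI) voxel pairs retained for plotting.
#' @return An object of class `analysis_params`.
#' @export
analysis_params <- function(segmentation = segmentation_params(window = 13,
                                                               contrast = 1150,
                                                               cut_fraction = 0.45),
                            registration = registration_config(),
                            transform = c("register", "truth"),
                            register_on = c("pi", "echo1"),
                            pi_floor = NULL,
                            clamp_bmd = FALSE,
                            scatter_n = 5000) {
  structure(list(
    segmentation = segmentation, registration = registration,
    transform = match.arg(transform), register_on = match.arg(register_on),
    pi_floor = pi_floor, clamp_bmd = clamp_bmd, scatter_n = scatter_n
  ), class = "analysis_params")
}

#' Run the full analysis on one specimen
#'
#' Calibrates CT to BMD from the phantom inserts, computes the PI map from
#' the two echoes, aligns PI to the CT grid (by registration or with the
#' ground-truth transform), segments the bone and crops the condyle ROI on
#' the CT volume, and regresses PI on BMD voxel-wise inside the ROI.
#'
#' @param specimen A `bone_specimen` (from [simulate_specimen()] or
#'   [load_specimen()]).
#' @param params An [analysis_params()].
#' @param inserts Optional list of `list(mask, density)`; defaults to the
#'   specimen's ground-truth insert masks, or the parametric detector.
#' @param output_dir Optional directory for artifacts (BMD and PI volumes,
#'   masks, transform, scatter sample, resolved parameters).
#' @param horse,limb Labels carried into the result.
#' @param seed Seed for the scatter subsample.
#' @return List with `result` (one-row tibble), `regression`,
#'   `calibration`, `transform`, `bone`, `roi`, `pi_ct` (aligned PI map),
#'   `bmd`, `scatter` (tibble of sampled BMD/PI pairs).
#' @export
run_specimen <- function(specimen, params = analysis_params(), inserts = NULL,
                         output_dir = NULL, horse = NA, limb = NA_character_,
                         seed = 1) {
  stopifnot(inherits(specimen, "bone_specimen"))
  if (is.null(inserts)) {
    inserts <- if (!is.null(specimen$truth$insert_masks)) {
      purrr::map2(specimen$truth$insert_masks, specimen$truth$insert_densities,
                  function(m, d) list(mask = m, density = d))
    } else {
      detect_inserts(specimen$spec)
    }
  }
  calib <- fit_calibration(specimen$ct, inserts)
  bmd <- apply_calibration(specimen$ct, calib, clamp = params$clamp_bmd)
  pi_mr <- compute_pi(specimen$echo1, specimen$echo2, floor = params$pi_floor)
  transform <- if (params$transform == "truth") {
    if (is.null(specimen$truth$transform))
      stop("specimen carries no ground-truth transform", call. = FALSE)
    specimen$truth$transform
  } else {
    moving <- if (params$register_on == "echo1") {
      specimen$echo1
    } else {
      masked <- pi_mr$values$values
      masked[!pi_mr$valid$values] <- 0
      with_values(pi_mr$values, masked)
    }
    register_affine(specimen$ct, moving, config = params$registration)$transform
  }
  pi_ct <- align_pi_to_ct(pi_mr, specimen$ct, transform)
  seg <- segment_bone(specimen$ct, params$segmentation)
  reg <- regress_specimen(bmd, pi_ct, seg$roi, horse = horse, limb = limb)
  sel <- which(as.logical(seg$roi$values) & pi_ct$valid$values)
  take <- if (length(sel) > params$scatter_n) {
    with_seed(seed, sort(sample(sel, params$scatter_n)))
  } else {
    sel
  }
  scatter <- tibble::tibble(bmd = bmd$values[take], pi = pi_ct$values$values[take])
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(bmd, file.path(output_dir, "bmd.nii.gz"), "float")
    write_pi_map(pi_ct, file.path(output_dir, "pi_on_ct.nii.gz"))
    write_volume(seg$bone, file.path(output_dir, "bone_mask.nii.gz"), "uint8")
    write_volume(seg$roi, file.path(output_dir, "condyle_roi.nii.gz"), "uint8")
    write_affine(transform, file.path(output_dir, "transform.txt"))
    write.csv(scatter, file.path(output_dir, "scatter.csv"), row.names = FALSE)
    yaml::write_yaml(resolve_params(params), file.path(output_dir, "params.yaml"))
  }
  list(result = tidy(reg), regression = reg, calibration = calib,
       transform = transform, bone = seg$bone, roi = seg$roi,
       pi_ct = pi_ct, bmd = bmd, scatter = scatter)
}

resolve_params <- function(params) {
  list(
    segmentation = unclass(params$segmentation),
    registration = unclass(params$registration),
    transform = params$transform, register_on = params$register_on,
    pi_floor = params$pi_floor, clamp_bmd = params$clamp_bmd,
    scatter_n = params$scatter_n
  )
}

#' Run a whole study through the pipeline
#'
#' Processes every specimen of a [study_plan()] (simulating each on the
#' fly) or of a study directory written by [generate_study()], then builds
#' the study table and group analyses. A failing specimen does not abort
#' the study: it is recorded as excluded with its error message.
#'
#' @param plan A [study_plan()] tibble, or `NULL` when `dir` is given.
#' @param params An [analysis_params()].
#' @param dir Study directory written by [generate_study()].
#' @param output_dir Optional directory for study-level CSV outputs.
#' @param variant t-test variant for the group comparisons.
#' @return A `pi_study` whose table carries `true_r` per specimen, plus
#'   attribute `"failures"` naming failed specimens.
#' @export
run_study <- function(plan = NULL, params = analysis_params(), dir = NULL,
                      output_dir = NULL, variant = "student") {
  if (is.null(plan) && is.null(dir))
    stop("provide a study plan or a study directory", call. = FALSE)
  if (is.null(plan)) {
    mpath <- file.path(dir, "manifest.csv")
    if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
    plan <- tibble::as_tibble(read.csv(mpath))
    plan$limb <- as.character(plan$limb)
  }
  if (nrow(plan) == 0) stop("empty study", call. = FALSE)
  rows <- list()
  failures <- character()
  for (i in seq_len(nrow(plan))) {
    id <- plan$specimen[i]
    if (isTRUE(plan$excluded[i])) {
      rows[[id]] <- tibble::tibble(
        horse = plan$horse[i], limb = plan$limb[i], n_voxels = NA_integer_,
        slope = NA_real_, slope_se = NA_real_, r = NA_real_, p = NA_real_,
        excluded = TRUE, true_r = NA_real_
      )
      next
    }
    res <- tryCatch({
      specimen <- if (!is.null(dir)) {
        load_specimen(file.path(dir, id))
      } else {
        simulate_specimen(plan$spec[[i]], seed = plan$seed[i])
      }
      out <- run_specimen(specimen, params,
                          output_dir = if (is.null(output_dir)) NULL
                                       else file.path(output_dir, id),
                          horse = plan$horse[i], limb = plan$limb[i])
      dplyr::mutate(out$result, excluded = FALSE,
                    true_r = specimen$truth$true_r)
    }, error = function(e) {
      failures <<- c(failures, setNames(conditionMessage(e), id))
      tibble::tibble(
        horse = plan$horse[i], limb = plan$limb[i], n_voxels = NA_integer_,
        slope = NA_real_, slope_se = NA_real_, r = NA_real_, p = NA_real_,
        excluded = TRUE, true_r = NA_real_
      )
    })
    rows[[id]] <- res
  }
  study <- build_study_table(dplyr::bind_rows(rows), variant = variant)
  attr(study, "failures") <- failures
  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}
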