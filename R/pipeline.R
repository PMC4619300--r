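#' Pipeline configuration
#'
#' Bundles every tunable parameter of the simulate/segment/features/classify
#' chain into one validated list that serialises losslessly to YAML, so a run
#' is a pure function of (inputs, config, seed).
#'
#' @param pixel_size_um Pixel pitch (um per pixel). The default 0.87 um
#'   matches the lateral resolution of the source instrument and should be
#'   overridden with the true calibration when known.
#' @param sigma_px,low_frac,high_frac,bridge_px,se_radius_px,n_rounds,min_area_um2,max_area_um2,min_solidity
#'   Segmentation parameters; see [segment_nuclei()].
#' @param enc_low_cut,enc_high_cut,nddn3_low_cut,nddn3_high_cut Classifier
#'   band edges; see [classify_enc()] and [classify_nddn3()].
#' @param seed Integer seed driving all randomness.
#' @return An object of class `qtp_config` (named list).
#' @export
qtp_config <- function(pixel_size_um = 0.87,
                       sigma_px = 1.5, low_frac = 0.4, high_frac = 0.9,
                       bridge_px = 0L, se_radius_px = 1L, n_rounds = 2L,
                       min_area_um2 = 10, max_area_um2 = 200, min_solidity = 0.7,
                       enc_low_cut = 0.08, enc_high_cut = 0.18,
                       nddn3_low_cut = 21, nddn3_high_cut = 25,
                       seed = 1L) {
  check_number(pixel_size_um, "pixel_size_um")
  check_number(sigma_px, "sigma_px")
  if (!(low_frac > 0 && low_frac < 1)) stop_validation("`low_frac` must be in (0, 1)")
  if (!(high_frac > 0 && high_frac <= 1)) stop_validation("`high_frac` must be in (0, 1]")
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2)) {
    stop_validation("need 0 < min_area_um2 < max_area_um2")
  }
  if (!(enc_low_cut > 0 && enc_low_cut < enc_high_cut && enc_high_cut < 1)) {
    stop_validation("need 0 < enc_low_cut < enc_high_cut < 1")
  }
  if (!(nddn3_low_cut > 0 && nddn3_low_cut < nddn3_high_cut)) {
    stop_validation("need 0 < nddn3_low_cut < nddn3_high_cut")
  }
  structure(
    list(pixel_size_um = pixel_size_um, sigma_px = sigma_px,
         low_frac = low_frac, high_frac = high_frac,
         bridge_px = as.integer(bridge_px),
         se_radius_px = as.integer(se_radius_px), n_rounds = as.integer(n_rounds),
         min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
         min_solidity = min_solidity,
         enc_low_cut = enc_low_cut, enc_high_cut = enc_high_cut,
         nddn3_low_cut = nddn3_low_cut, nddn3_high_cut = nddn3_high_cut,
         seed = as.integer(seed)),
    class = "qtp_config"
  )
}

#' @rdname qtp_config
#' @param path File path for the YAML serialisation.
#' @param config A `qtp_config` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname qtp_config
#' @export
read_config <- function(path) {
  do.call(qtp_config, yaml::read_yaml(path))
}

#' Run the analysis chain on one specimen
#'
#' Segmentation, QTP feature extraction and threshold classification for a
#' single frame. Errors (unreadable input, degenerate geometry, too few
#' nuclei) are caught and reported in the result rather than thrown, so a
#' failing specimen never aborts a cohort run.
#'
#' @param frame A [confocal_frame()], or a file path to a grayscale TIFF.
#' @param config A [qtp_config()].
#' @param roi Optional [roi_mask()]; default whole frame.
#' @param specimen_id,depth_um,truth Metadata carried into the output.
#' @return One-row tibble: identifiers, the four features, `enc_class`,
#'   `nddn3_class`, `truth`, `ok` (logical) and `error` (message or NA).
#' @export
run_specimen <- function(frame, config = qtp_config(), roi = NULL,
                         specimen_id = NA_character_, depth_um = NA_real_,
                         truth = NA_character_) {
  res <- tryCatch({
    if (is.character(frame)) {
      frame <- read_frame_tiff(frame, pixel_size_um = config$pixel_size_um,
                               depth_um = depth_um, specimen_id = specimen_id)
    }
    seg <- segment_nuclei(
      frame, roi = roi,
      sigma_px = config$sigma_px, low_frac = config$low_frac,
      high_frac = config$high_frac, bridge_px = config$bridge_px,
      se_radius_px = config$se_radius_px, n_rounds = config$n_rounds,
      min_area_um2 = config$min_area_um2, max_area_um2 = config$max_area_um2,
      min_solidity = config$min_solidity
    )
    feats <- compute_qtp(seg, specimen_id = specimen_id, depth_um = depth_um)
    classify_specimens(feats, config$enc_low_cut, config$enc_high_cut,
                       config$nddn3_low_cut, config$nddn3_high_cut) |>
      dplyr::mutate(truth = truth, ok = TRUE, error = NA_character_)
  }, error = function(e) {
    tibble(specimen_id = specimen_id, depth_um = depth_um,
           nuclear_area_um2 = NA_real_, cell_density_per_mm2 = NA_real_,
           enc_ratio = NA_real_, nddn3_um = NA_real_,
           n_nuclei = NA_integer_, n_interior = NA_integer_,
           enc_class = disease_factor(NA), nddn3_class = disease_factor(NA),
           truth = truth, ok = FALSE, error = conditionMessage(e))
  })
  res
}

#' Run the analysis chain on a cohort
#'
#' Maps [run_specimen()] over a cohort tibble (as from [generate_cohort()],
#' or any tibble with `specimen_id`, `frame`, optional `roi`, `depth_um` and
#' truth labels) and, when truth labels are present, evaluates both QTP
#' classifiers per depth.
#'
#' @param cohort Tibble with a `frame` list-column; optional `grade` (used as
#'   truth), `truth`, `roi`, `depth_um`, `specimen_id` columns.
#' @param config A [qtp_config()].
#' @return List with `features` (per-specimen tibble including failures) and
#'   `evaluation` (per-depth metrics from [evaluate_depths()], or NULL with a
#'   warning when no truth labels exist).
#' @export
run_cohort <- function(cohort, config = qtp_config()) {
  if (nrow(cohort) == 0L) stop_validation("empty cohort")
  # `truth` in a generated cohort is the ground-truth list-column, not a
  # label: accept it only when atomic; the histology label lives in `grade`
  truth <- if ("grade" %in% names(cohort)) {
    as.character(cohort$grade)
  } else if ("truth" %in% names(cohort) && is.atomic(cohort$truth)) {
    as.character(cohort$truth)
  } else {
    rep(NA_character_, nrow(cohort))
  }
  ids <- if ("specimen_id" %in% names(cohort)) {
    cohort$specimen_id
  } else {
    sprintf("specimen_%03d", seq_len(nrow(cohort)))
  }
  depth <- if ("depth_um" %in% names(cohort)) cohort$depth_um else rep(NA_real_, nrow(cohort))
  feats <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    run_specimen(
      cohort$frame[[i]], config = config,
      roi = if ("roi" %in% names(cohort)) cohort$roi[[i]] else NULL,
      specimen_id = ids[i], depth_um = depth[i], truth = truth[i]
    )
  })
  evaluation <- NULL
  ok <- feats$ok & !is.na(feats$truth)
  if (any(ok)) {
    evaluation <- evaluate_depths(feats[ok, ])
  } else {
    warn("no specimens with truth labels: evaluation skipped")
  }
  list(features = feats, evaluation = evaluation)
}

# --- file I/O ---------------------------------------------------------------

#' Read and write frames as grayscale TIFF
#'
#' Frames are stored as single-channel TIFFs with gray levels scaled to
#' `[0, 1]` over the 0-255 range used internally (the tiff package's native
#' convention); reading reverses the scaling.
#'
#' @param frame A [confocal_frame()].
#' @param path Output/input file path.
#' @return `write_frame_tiff()` returns `path` invisibly; `read_frame_tiff()`
#'   returns a [confocal_frame()].
#' @export
write_frame_tiff <- function(frame, path) {
  tiff::writeTIFF(frame$pixels / 255, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @param pixel_size_um,depth_um,specimen_id Calibration and metadata for the
#'   frame being read (TIFF carries none).
#' @export
read_frame_tiff <- function(path, pixel_size_um, depth_um = NA_real_,
                            specimen_id = NA_character_) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  confocal_frame(px * 255, pixel_size_um = pixel_size_um,
                 depth_um = depth_um, specimen_id = specimen_id)
}

#' Write a synthetic cohort to disk
#'
#' Writes each specimen's frame and ground-truth label mask as TIFF plus a
#' `cohort.csv` manifest (specimen id, grade, seed, generator parameters and
#' file paths) — the on-disk layout consumed by the file-based pipeline.
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    id <- cohort$specimen_id[i]
    fpath <- file.path(outdir, paste0(id, "_frame.tif"))
    lpath <- file.path(outdir, paste0(id, "_labels.tif"))
    write_frame_tiff(cohort$frame[[i]], fpath)
    lab <- cohort$truth[[i]]$label_mask
    tiff::writeTIFF(lab / max(1L, max(lab)), lpath, bits.per.sample = 16L)
    sp <- cohort$spec[[i]]
    tibble(specimen_id = id, grade = cohort$grade[i], seed = cohort$seed[i],
           frame_path = fpath, label_path = lpath,
           pixel_size_um = sp$pixel_size_um,
           field_of_view_um = sp$field_of_view_um,
           spacing_mean_um = sp$spacing_mean_um,
           radius_mean_um = sp$radius_mean_um)
  })
  write.csv(manifest, file.path(outdir, "cohort.csv"), row.names = FALSE)
  invisible(manifest)
}
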