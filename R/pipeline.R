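.default_config <- function() {
  list(
    seed = 0L,
    conditions = c("maintenance", "gsis"),
    n_fields = 2L,
    cells_per_field = 3L,
    acquisition = list(
      laser_rep_rate = 8e7, n_time_bins = 256L, image_shape = c(256L, 256L),
      target_mean_counts = 100, irf_fwhm = 0,
      instrument_phase_offset = 0.35, instrument_mod_factor = 0.88),
    basis = list(n_components = 2L,
                 lifetimes = list(free = 0.4, bound = 3.4, lls = 8)),
    harmonic = 1L,
    tau_ref = 4.0,
    thresholds = list(intensity = 30, lls = 0.15, min_cell_area = 150L,
                      min_nucleus_area = 30L, max_eccentricity = 0.9,
                      relative_intensity_cut = 0.7, min_roi_valid = 20L),
    median_filter = list(window = 3L, passes = 1L),
    confidence_level = 0.90,
    segmentation = "auto"
  )
}

.check_keys <- function(user, ref, path = "") {
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown))
    stop(sprintf("unknown configuration key: '%s%s'", path, unknown[1]))
  for (nm in names(user))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      .check_keys(as.list(user[[nm]]), ref[[nm]], paste0(path, nm, "."))
}

.merge_config <- function(user, ref) {
  for (nm in names(user)) {
    ref[[nm]] <- if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      .merge_config(as.list(user[[nm]]), ref[[nm]]) else user[[nm]]
  }
  ref
}

#' Pipeline configuration
#'
#' Assembles (and validates) the full parameter set of an end-to-end run:
#' acquisition settings, unmixing basis, thresholds, harmonic, confidence
#' level and the top-level seed from which every stage seed is derived.
#' Unknown keys are rejected by name; the object round-trips losslessly
#' through its YAML on-disk form.
#'
#' @param ... named overrides of the defaults (nested lists allowed, e.g.
#'   `thresholds = list(lls = 0.2)`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  ref <- .default_config()
  .check_keys(user, ref)
  cfg <- .merge_config(user, ref)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a configuration list to validate.
#' @export
validate_pipeline_config <- function(config) {
  .check_keys(config, .default_config())
  bad <- names(which(c(
    intensity = config$thresholds$intensity < 0,
    lls = config$thresholds$lls < 0 || config$thresholds$lls > 1,
    min_cell_area = config$thresholds$min_cell_area < 0,
    min_nucleus_area = config$thresholds$min_nucleus_area < 0,
    max_eccentricity = config$thresholds$max_eccentricity < 0,
    relative_intensity_cut = config$thresholds$relative_intensity_cut <= 0,
    min_roi_valid = config$thresholds$min_roi_valid < 0)))
  if (length(bad))
    stop(sprintf("invalid threshold value for field 'thresholds.%s'", bad[1]))
  if (config$confidence_level <= 0 || config$confidence_level >= 1)
    stop("invalid value for field 'confidence_level' (must be in (0,1))")
  if (config$n_fields < 1 || config$cells_per_field < 1)
    stop("'n_fields' and 'cells_per_field' must be >= 1")
  ok <- names(.preset_table)
  if (!all(config$conditions %in% ok))
    stop(sprintf("unknown condition '%s' in field 'conditions'",
                 setdiff(config$conditions, ok)[1]))
  if (!config$basis$n_components %in% c(2L, 3L))
    stop("'basis.n_components' must be 2 or 3")
  invisible(config)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# per-stage seed derivation: single top-level seed, no hidden global state
.stage_seed <- function(seed, cond_idx, field_idx = 0L) {
  as.integer((as.numeric(seed) * 10007 + cond_idx * 101 + field_idx) %% .Machine$integer.max)
}

#' Run the full phasor-FLIM pipeline
#'
#' Executes simulate -> calibrate -> phasor transform -> median filter ->
#' unmix -> segment -> summarize -> compare for every configured condition
#' and writes all intermediate products (phasor and fraction TIFFs, masks,
#' per-ROI CSV summaries), a pairwise `comparison.json` and a run manifest
#' to `out_dir`. Re-running with the same configuration reproduces
#' identical summaries.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @param write_cubes also write the raw decay cubes (large; default FALSE).
#' @return invisibly, a list with the per-condition summaries, the
#'   pairwise comparisons and the manifest.
#' @export
run_pipeline <- function(config, out_dir, write_cubes = FALSE) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phasorflim")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stages = list(), complete = FALSE)
  .save_manifest <- function() .write_json(manifest, file.path(out_dir, "manifest.json"))
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      .save_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  th <- config$thresholds
  lt <- unlist(config$basis$lifetimes)

  # calibration from a simulated reference-dye measurement
  cal <- run_stage("calibrate", {
    acq_ref <- do.call(acquisition_config,
                       c(config$acquisition, list(seed = .stage_seed(config$seed, 0L))))
    ref <- make_reference(config$tau_ref, acq_ref)
    cal <- fit_calibration(ref, config$tau_ref, config$harmonic, th$intensity)
    .write_json(list(tau_ref = cal$tau_ref, harmonic = cal$harmonic,
                     omega_rad_per_ns = cal$omega,
                     measured_phasor = as.list(cal$measured_phasor),
                     phase_correction = cal$phase_correction,
                     mod_correction = cal$mod_correction),
                file.path(out_dir, "calibration.json"))
    cal
  })
  basis <- default_nadph_basis(cal$omega, config$basis$n_components,
                               nadph_lifetimes(unname(lt["free"]),
                                               unname(lt["bound"]),
                                               unname(lt["lls"])))

  summaries <- list()
  for (ci in seq_along(config$conditions)) {
    cname <- config$conditions[ci]
    cond <- condition_preset(cname)
    cond_rows <- list()
    for (fi in seq_len(config$n_fields)) {
      fdir <- file.path(out_dir, cname, sprintf("field_%02d", fi))
      stage <- sprintf("%s/field_%02d", cname, fi)
      cond_rows[[fi]] <- run_stage(stage, {
        acq <- do.call(acquisition_config,
                       c(config$acquisition,
                         list(seed = .stage_seed(config$seed, ci, fi))))
        scene <- build_scene(config$cells_per_field, cond, acq)
        cube <- render_decays(scene, acq)
        if (write_cubes) write_decay_cube(cube, file.path(fdir, "cube"))
        field <- phasor_transform(cube, config$harmonic, th$intensity)
        field <- apply_calibration(field, cal)
        field <- median_filter_phasor(field, config$median_filter$window,
                                      config$median_filter$passes)
        write_phasor_field(field, fdir)
        fmap <- if (config$basis$n_components == 2L)
          two_component_fractions(field, basis)
        else three_component_fractions(field, basis)
        write_fraction_map(fmap, fdir)
        img <- intensity_image(cube)
        mask <- if (identical(config$segmentation, "truth"))
          scene_truth_mask(scene)
        else {
          cells <- segment_cells(img, th$min_cell_area)
          segment_nuclei(img, cells, th$relative_intensity_cut,
                         th$min_nucleus_area, th$max_eccentricity)
        }
        write_label_mask(mask, fdir, "mask")
        write_label_mask(scene_truth_mask(scene), fdir, "truth_mask")
        roi <- roi_phasor_summary(field, mask, fmap, th$min_roi_valid, cname)
        cell <- roi_phasor_summary(field, as_cell_mask(mask), fmap,
                                   th$min_roi_valid, cname)
        roi$level <- "roi"; cell$level <- "cell"
        roi$field <- fi; cell$field <- fi
        rbind(roi, cell)
      })
    }
    summaries[[cname]] <- do.call(rbind, cond_rows)
    write_cell_summaries(summaries[[cname]],
                         file.path(out_dir, cname, "summaries.csv"))
  }

  comparisons <- run_stage("compare", {
    out <- list()
    cn <- config$conditions
    if (length(cn) > 1) {
      for (i in seq_len(length(cn) - 1)) for (j in seq(i + 1, length(cn))) {
        sa <- summaries[[cn[i]]]; sb <- summaries[[cn[j]]]
        sa <- sa[sa$level == "cell", ]; sb <- sb[sb$level == "cell", ]
        cmp <- compare_conditions(sa, sb, config$confidence_level,
                                  test_column = "mean_f_bound")
        out[[paste(cn[i], cn[j], sep = "_vs_")]] <- list(
          condition_a = cmp$condition_a, condition_b = cmp$condition_b,
          center_a = as.list(cmp$ellipse_a$center),
          center_b = as.list(cmp$ellipse_b$center),
          covariance_a = cmp$ellipse_a$covariance,
          covariance_b = cmp$ellipse_b$covariance,
          euclidean_distance = cmp$euclidean_distance,
          rank_test = cmp$rank_test)
      }
    }
    .write_json(out, file.path(out_dir, "comparison.json"))
    out
  })

  manifest$complete <- TRUE
  .save_manifest()
  invisible(list(summaries = summaries, comparisons = comparisons,
                 manifest = manifest))
}
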