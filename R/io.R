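# On-disk formats: multi-page TIFF for image stacks (16-bit counts, 32-bit
# float maps normalized to [0,1] with affine restore coefficients in the
# JSON sidecar), JSON for metadata, CSV for tabular summaries.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
}

.read_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

# float pages: store (v - offset)/scale in [0,1]; NA encoded as offset
.write_float_stack <- function(pages, path) {
  norm <- lapply(pages, function(p) {
    p[is.na(p)] <- min(p, na.rm = TRUE)
    rng <- range(p)
    sc <- if (diff(rng) > 0) diff(rng) else 1
    list(page = (p - rng[1]) / sc, offset = rng[1], scale = sc)
  })
  tiff::writeTIFF(lapply(norm, `[[`, "page"), path, bits.per.sample = 32,
                  reduce = FALSE)
  list(offset = vapply(norm, `[[`, numeric(1), "offset"),
       scale = vapply(norm, `[[`, numeric(1), "scale"))
}

.read_float_stack <- function(path, offset, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  Map(function(p, o, s) p * s + o, pages, offset, scale)
}

#' Write / read a decay cube (multi-page 16-bit TIFF + JSON sidecar)
#'
#' One TIFF page per time bin plus a `meta.json` carrying repetition rate,
#' bin width, distortion, seed and condition tag.
#'
#' @param cube a [decay_cube()].
#' @param dir output directory (created if needed).
#' @return `write_decay_cube` returns `dir` invisibly; `read_decay_cube`
#'   returns the `decay_cube`.
#' @export
write_decay_cube <- function(cube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mx <- max(cube$counts)
  if (mx > 65535) stop("counts exceed the 16-bit range")
  pages <- lapply(seq_len(cube$n_bins), function(k) cube$counts[k, , ] / 65535)
  tiff::writeTIFF(pages, file.path(dir, "counts.tif"), bits.per.sample = 16)
  .write_json(list(
    format = "phasorflim-decay-cube-v1",
    rep_rate_hz = cube$rep_rate_hz, n_bins = cube$n_bins,
    bin_width_ns = cube$bin_width_ns, shape = cube$shape,
    distortion = cube$distortion, seed = cube$seed,
    condition = cube$condition, noiseless = cube$noiseless
  ), file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(dir) {
  meta <- .read_json(file.path(dir, "meta.json"))
  pages <- tiff::readTIFF(file.path(dir, "counts.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  counts <- array(0, c(meta$n_bins, meta$shape[1], meta$shape[2]))
  for (k in seq_along(pages)) counts[k, , ] <- round(pages[[k]] * 65535)
  cfg <- acquisition_config(
    laser_rep_rate = meta$rep_rate_hz, n_time_bins = meta$n_bins,
    image_shape = meta$shape, irf_fwhm = meta$distortion$irf_fwhm,
    instrument_phase_offset = meta$distortion$phase_offset,
    instrument_mod_factor = meta$distortion$mod_factor, seed = meta$seed)
  decay_cube(counts, cfg, condition = meta$condition,
             noiseless = isTRUE(meta$noiseless))
}

#' Write / read a phasor field (3-page float TIFF + JSON sidecar)
#'
#' Pages are g, s and intensity; harmonic, angular frequency, threshold
#' and calibration status travel in `phasor.json`.
#'
#' @param field a `phasor_field`.
#' @param dir output directory.
#' @export
write_phasor_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- .write_float_stack(list(field$g, field$s, field$intensity),
                            file.path(dir, "phasor.tif"))
  .write_json(list(
    format = "phasorflim-phasor-field-v1",
    pages = c("g", "s", "intensity"),
    offset = aff$offset, scale = aff$scale,
    harmonic = field$harmonic, omega_rad_per_ns = field$omega,
    rep_rate_hz = field$rep_rate_hz, period_ns = field$period_ns,
    n_bins = field$n_bins, intensity_threshold = field$threshold,
    calibrated = field$calibrated
  ), file.path(dir, "phasor.json"))
  invisible(dir)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(dir) {
  meta <- .read_json(file.path(dir, "phasor.json"))
  pages <- .read_float_stack(file.path(dir, "phasor.tif"),
                             meta$offset, meta$scale)
  intensity <- pages[[3]]
  valid <- intensity >= meta$intensity_threshold & intensity > 0
  g <- pages[[1]]; s <- pages[[2]]
  g[!valid] <- NA_real_; s[!valid] <- NA_real_
  .phasor_field(g, s, intensity, valid, meta$harmonic, meta$omega_rad_per_ns,
                meta$rep_rate_hz, meta$period_ns, meta$n_bins,
                meta$intensity_threshold, isTRUE(meta$calibrated))
}

#' Write / read a fraction map (multi-page float TIFF + JSON sidecar)
#'
#' One page per component plus an out-of-gamut flag page; component labels
#' and the unmixing basis travel in `fractions.json`.
#'
#' @param fmap a `fraction_map`.
#' @param dir output directory.
#' @export
write_fraction_map <- function(fmap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(fmap$labels, function(lb) fmap$fractions[, , lb])
  pages <- c(pages, list(fmap$out_of_gamut * 1, fmap$valid * 1))
  aff <- .write_float_stack(pages, file.path(dir, "fractions.tif"))
  .write_json(list(
    format = "phasorflim-fraction-map-v1",
    labels = fmap$labels, offset = aff$offset, scale = aff$scale,
    basis = list(labels = fmap$basis$labels, g = fmap$basis$g,
                 s = fmap$basis$s, omega = fmap$basis$omega)
  ), file.path(dir, "fractions.json"))
  invisible(dir)
}

#' @rdname write_fraction_map
#' @export
read_fraction_map <- function(dir) {
  meta <- .read_json(file.path(dir, "fractions.json"))
  pages <- .read_float_stack(file.path(dir, "fractions.tif"),
                             meta$offset, meta$scale)
  k <- length(meta$labels)
  valid <- pages[[k + 2]] > 0.5
  fr <- array(NA_real_, c(dim(valid), k))
  for (j in seq_len(k)) {
    p <- pages[[j]]; p[!valid] <- NA_real_; fr[, , j] <- p
  }
  basis <- component_basis(meta$basis$labels, g = meta$basis$g,
                           s = meta$basis$s, omega = meta$basis$omega)
  .fraction_map(fr, meta$labels, pages[[k + 1]] > 0.5 & valid, valid, basis)
}

#' Write / read a label mask (single-page 16-bit TIFF + JSON sidecar)
#'
#' @param mask a [label_mask()].
#' @param dir output directory.
#' @param name file stem (default "mask").
#' @export
write_label_mask <- function(mask, dir, name = "mask") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (max(mask$labels) > 65535) stop("labels exceed the 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 16)
  .write_json(list(
    format = "phasorflim-label-mask-v1",
    roi_class = as.list(mask$roi_class),
    parent = as.list(mask$parent)
  ), file.path(dir, paste0(name, ".json")))
  invisible(dir)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(dir, name = "mask") {
  meta <- .read_json(file.path(dir, paste0(name, ".json")))
  lab <- round(tiff::readTIFF(file.path(dir, paste0(name, ".tif"))) * 65535)
  storage.mode(lab) <- "integer"
  parent <- unlist(meta$parent)
  label_mask(lab, unlist(meta$roi_class),
             if (is.null(parent)) integer(0) else parent)
}

#' Write / read per-ROI summaries as CSV
#'
#' @param summaries data.frame from [roi_phasor_summary()].
#' @param path CSV file path.
#' @export
write_cell_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_summaries
#' @export
read_cell_summaries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
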