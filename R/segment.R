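#' ROI label mask
#'
#' Integer label image (0 = background) together with the class of every
#' ROI (nucleus / cytoplasm / cell) and, for nuclei, the id of the parent
#' cell. The package convention pairs ROIs without a second mask: per cell
#' k, nucleus label `2k-1`, cytoplasm label `2k`.
#'
#' @param labels integer matrix of labels.
#' @param roi_class named character vector mapping label -> class.
#' @param parent named integer vector mapping nucleus label -> cell id.
#' @return object of class `label_mask`.
#' @export
label_mask <- function(labels, roi_class, parent = integer(0)) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  ids <- sort(unique(labels[labels > 0]))
  if (!all(as.character(ids) %in% names(roi_class)))
    stop("every non-zero label needs a `roi_class` entry")
  nuc <- names(roi_class)[roi_class == "nucleus"]
  if (length(nuc) && !all(nuc %in% names(parent)))
    stop("every nucleus needs a `parent` cell id")
  structure(list(labels = labels, roi_class = roi_class, parent = parent),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tb <- table(x$roi_class)
  cat(sprintf("label mask %dx%d: %s\n", nrow(x$labels), ncol(x$labels),
              paste(sprintf("%d %s", tb, names(tb)), collapse = ", ")))
  invisible(x)
}

#' Merge nucleus/cytoplasm ROIs of a mask into whole-cell ROIs
#'
#' @param mask a `label_mask` using the nucleus `2k-1` / cytoplasm `2k`
#'   convention (masks whose ROIs are already cells are returned as-is).
#' @return a `label_mask` with one `cell` ROI per cell id k.
#' @export
as_cell_mask <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (all(mask$roi_class == "cell")) return(mask)
  lab <- mask$labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- (lab[lab > 0] + 1L) %/% 2L
  ids <- sort(unique(out[out > 0]))
  label_mask(out, stats::setNames(rep("cell", length(ids)), ids))
}

.smooth_image <- function(intensity, sigma) {
  if (sigma <= 0) return(intensity)
  mx <- max(intensity)
  if (mx <= 0) return(intensity)
  img <- EBImage::Image(intensity / mx)
  as.matrix(EBImage::gblur(img, sigma = sigma)) * mx
}

#' Segment cells from an intensity image
#'
#' Foreground/background split by Otsu's histogram threshold on a lightly
#' smoothed image; connected foreground components of at least
#' `min_cell_area` pixels become cells (touching cells are not split --
#' clusters are analyzed as one ROI, matching the cluster-level analysis
#' of adherent beta cells).
#'
#' @param intensity numeric matrix of total counts per pixel.
#' @param min_cell_area minimum component area in pixels.
#' @param smooth_sigma Gaussian smoothing sigma (pixels) before
#'   thresholding.
#' @return a `label_mask` of `cell` ROIs (empty, with a warning, when no
#'   foreground is found).
#' @export
segment_cells <- function(intensity, min_cell_area = 150L, smooth_sigma = 1.5) {
  stopifnot(is.matrix(intensity), length(intensity) > 0)
  empty <- label_mask(matrix(0L, nrow(intensity), ncol(intensity)),
                      stats::setNames(character(0), character(0)))
  mx <- max(intensity)
  if (mx <= 0) {
    warning("no foreground found (blank image)")
    return(empty)
  }
  sm <- .smooth_image(intensity, smooth_sigma)
  img <- EBImage::Image(sm / max(sm))
  th <- EBImage::otsu(img)
  bw <- img > th
  # dim nucleus interiors can fall below the global threshold: fill holes
  # so each cell component is a full cell (nucleus included)
  lab <- EBImage::fillHull(EBImage::bwlabel(bw))
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= min_cell_area])
  if (!length(keep)) {
    warning("no foreground component passes `min_cell_area`")
    return(empty)
  }
  out <- matrix(0L, nrow(intensity), ncol(intensity))
  for (i in seq_along(keep)) out[as.matrix(lab) == keep[i]] <- i
  ids <- seq_along(keep)
  label_mask(out, stats::setNames(rep("cell", length(ids)), ids))
}

#' Segment nuclei within cells by low NAD(P)H intensity and shape
#'
#' Nuclei appear as ellipsoidal regions of markedly lower autofluorescence
#' inside each cell. Within every cell ROI, pixels below
#' `relative_intensity_cut` times the cell's median (smoothed) intensity
#' form candidate regions; candidates must pass a minimum-area and a
#' maximum-eccentricity filter. The union of accepted candidates is the
#' cell's nucleus compartment (cell components can be clusters holding
#' several nuclei), hole-filled and optionally dilated by `dilate_radius`
#' to recover the blurred rim; the cytoplasm is the cell minus its
#' nucleus. Cells without an accepted nucleus are labeled
#' cytoplasm-only and reported in the `no_nucleus` attribute.
#'
#' @param intensity numeric matrix of total counts.
#' @param cells a `label_mask` of cell ROIs (from [segment_cells()] or a
#'   user-supplied mask).
#' @param relative_intensity_cut nucleus threshold relative to the cell
#'   median intensity (default 0.7).
#' @param min_area minimum nucleus area in pixels (default 30).
#' @param max_eccentricity maximum ellipse eccentricity (default 0.9).
#' @param smooth_sigma Gaussian smoothing sigma before thresholding.
#' @param dilate_radius disc radius (pixels) for the final nucleus
#'   dilation, clipped to the cell (0 disables).
#' @return a `label_mask` with nucleus `2k-1` / cytoplasm `2k` labels.
#' @export
segment_nuclei <- function(intensity, cells, relative_intensity_cut = 0.7,
                           min_area = 30L, max_eccentricity = 0.9,
                           smooth_sigma = 0.7, dilate_radius = 0L) {
  stopifnot(inherits(cells, "label_mask"))
  ids <- sort(unique(cells$labels[cells$labels > 0]))
  if (!length(ids)) stop("`cells` mask is empty")
  sm <- .smooth_image(intensity, smooth_sigma)
  out <- matrix(0L, nrow(intensity), ncol(intensity))
  roi_class <- character(0); parent <- integer(0); no_nuc <- integer(0)
  for (k in seq_along(ids)) {
    cellpx <- cells$labels == ids[k]
    med <- stats::median(sm[cellpx])
    cand <- cellpx & (sm < relative_intensity_cut * med)
    nucpx <- NULL
    if (any(cand)) {
      lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
      lab <- EBImage::fillHull(lab)
      labm <- as.matrix(lab)
      objs <- sort(unique(labm[labm > 0]))
      if (length(objs)) {
        feats <- EBImage::computeFeatures.moment(lab)
        feats <- matrix(feats, ncol = ncol(feats),
                        dimnames = list(NULL, colnames(feats)))
        areas <- as.integer(table(factor(labm[labm > 0], levels = objs)))
        ecc <- feats[objs, "m.eccentricity"]
        pass <- which(areas >= min_area & ecc <= max_eccentricity)
        if (length(pass)) {
          # cell components can be clusters with several nuclei; the nucleus
          # compartment is the union of all accepted candidates
          nucpx <- matrix(labm %in% objs[pass], nrow(labm), ncol(labm))
          if (dilate_radius > 0) {
            brush <- EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc")
            nucpx <- as.matrix(EBImage::dilate(EBImage::Image(nucpx * 1), brush)) > 0
          }
          nucpx <- nucpx & cellpx
        }
      }
    }
    if (is.null(nucpx) || !any(nucpx)) {
      out[cellpx] <- 2L * k
      roi_class[as.character(2L * k)] <- "cytoplasm"
      no_nuc <- c(no_nuc, ids[k])
    } else {
      out[nucpx] <- 2L * k - 1L
      out[cellpx & !nucpx] <- 2L * k
      roi_class[as.character(2L * k - 1L)] <- "nucleus"
      roi_class[as.character(2L * k)] <- "cytoplasm"
      parent[as.character(2L * k - 1L)] <- ids[k]
    }
  }
  if (length(no_nuc))
    message(sprintf("no nucleus detected in cell(s): %s (labeled cytoplasm-only)",
                    paste(no_nuc, collapse = ", ")))
  res <- label_mask(out, roi_class, parent)
  attr(res, "no_nucleus") <- no_nuc
  res
}

#' Per-ROI phasor summaries
#'
#' One row per ROI with the intensity-weighted mean phasor over its valid
#' pixels, pixel counts and intensity totals -- the per-cell (or
#' per-compartment) quantities that population scatter plots and
#' confidence ellipses are built from. ROIs with fewer than
#' `min_valid_pixels` valid pixels are dropped with a message.
#'
#' @param field a `phasor_field`.
#' @param mask a `label_mask` of matching shape.
#' @param fractions optional `fraction_map`; adds intensity-weighted mean
#'   fraction columns (`mean_f_<label>`).
#' @param min_valid_pixels minimum valid pixels per ROI (default 20).
#' @param condition condition tag recycled into the output.
#' @return data.frame with columns `roi_label`, `roi_class`, `n_pixels`,
#'   `n_valid`, `mean_g`, `mean_s`, `total_intensity`, `mean_intensity`,
#'   `condition` (plus fraction means if requested).
#' @export
roi_phasor_summary <- function(field, mask, fractions = NULL,
                               min_valid_pixels = 20L,
                               condition = NA_character_) {
  stopifnot(inherits(field, "phasor_field"), inherits(mask, "label_mask"))
  if (!all(dim(field$g) == dim(mask$labels)))
    stop("field and mask shapes disagree")
  ids <- sort(unique(mask$labels[mask$labels > 0]))
  rows <- list(); dropped <- integer(0)
  for (id in ids) {
    inroi <- mask$labels == id
    sel <- inroi & field$valid
    nv <- sum(sel)
    if (nv < min_valid_pixels) { dropped <- c(dropped, id); next }
    w <- field$intensity[sel]
    row <- data.frame(
      roi_label = id,
      roi_class = unname(mask$roi_class[as.character(id)]),
      n_pixels = sum(inroi),
      n_valid = nv,
      mean_g = sum(field$g[sel] * w) / sum(w),
      mean_s = sum(field$s[sel] * w) / sum(w),
      total_intensity = sum(field$intensity[inroi]),
      mean_intensity = mean(field$intensity[inroi]),
      condition = condition,
      stringsAsFactors = FALSE)
    if (!is.null(fractions)) {
      for (lb in fractions$labels) {
        fv <- fractions$fractions[, , lb][sel]
        row[[paste0("mean_f_", lb)]] <- sum(fv * w, na.rm = TRUE) /
          sum(w[!is.na(fv)])
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(dropped))
    message(sprintf("dropped ROI(s) with < %d valid pixels: %s",
                    min_valid_pixels, paste(dropped, collapse = ", ")))
  if (!length(rows))
    return(data.frame(roi_label = integer(0), roi_class = character(0),
                      n_pixels = integer(0), n_valid = integer(0),
                      mean_g = numeric(0), mean_s = numeric(0),
                      total_intensity = numeric(0), mean_intensity = numeric(0),
                      condition = character(0)))
  do.call(rbind, rows)
}
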