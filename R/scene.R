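#' Construct a scene from explicit per-pixel composition
#'
#' Low-level constructor used by [build_scene()] and by tests that need full
#' control over the ground truth. Species order is always
#' (free, bound, lls).
#'
#' @param fractions numeric array `c(rows, cols, 3)` of per-pixel fractional
#'   intensities; each non-background pixel must sum to 1.
#' @param brightness numeric matrix of relative brightness (0 = background).
#' @param labels integer matrix of ground-truth ROI labels (0 background;
#'   per cell k: nucleus `2k-1`, cytoplasm `2k`).
#' @param condition a [condition_preset()] (carries the brightness scale).
#' @param cells optional data frame of cell geometry.
#' @return object of class `flim_scene`.
#' @export
flim_scene <- function(fractions, brightness, labels = NULL,
                       condition = condition_preset("maintenance"),
                       cells = NULL) {
  stopifnot(length(dim(fractions)) == 3, dim(fractions)[3] == 3,
            all(dim(fractions)[1:2] == dim(brightness)))
  if (is.null(labels)) labels <- matrix(0L, nrow(brightness), ncol(brightness))
  fg <- brightness > 0
  tot <- fractions[, , 1] + fractions[, , 2] + fractions[, , 3]
  if (any(fractions < -1e-12) || any(fractions > 1 + 1e-12))
    stop("species fractions must be in [0, 1]")
  if (any(abs(tot[fg] - 1) > 1e-9))
    stop("species fractions must sum to 1 on every non-background pixel")
  structure(list(fractions = fractions, brightness = brightness,
                 labels = labels, condition = condition, cells = cells),
            class = "flim_scene")
}

# interior mask of a rotated ellipse on the pixel grid (pixel centres)
.ellipse_mask <- function(rows, cols, cy, cx, a, b, theta) {
  x <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  y <- matrix(rep(seq_len(rows), cols), rows, cols)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 < 1
}

#' Generate a beta-cell-like ground-truth scene
#'
#' Places `n_cells` non-overlapping elliptical cells in the frame, each with
#' an interior elliptical nucleus. Nuclei are dim (a configurable fraction
#' of the cytoplasm brightness, mirroring the low NAD(P)H signal of nuclei)
#' and enriched in free NAD(P)H; the cytoplasm carries a granular
#' multiplicative brightness texture and the condition-dependent bound
#' fraction. Under stress presets a long-lifetime-species (LLS) fraction is
#' added to the cytoplasm.
#'
#' Label convention: per cell k, nucleus label `2k-1`, cytoplasm `2k`,
#' background 0.
#'
#' @param n_cells number of cells to place (>= 1).
#' @param condition a [condition_preset()].
#' @param config an [acquisition_config()]; its seed fixes the placement.
#' @param nucleus_brightness nucleus brightness as a fraction of the mean
#'   cytoplasm brightness (default 0.4).
#' @param texture half-width of the uniform multiplicative cytoplasm
#'   texture (default 0.3, i.e. +/-30%).
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell
#'   semi-axes.
#' @param cell_radius_range range of the cell major semi-axis in pixels.
#' @param max_attempts placement attempts per cell before giving up.
#' @return object of class `flim_scene`.
#' @export
build_scene <- function(n_cells, condition = condition_preset("maintenance"),
                        config = acquisition_config(),
                        nucleus_brightness = 0.4, texture = 0.3,
                        nucleus_scale = 0.42,
                        cell_radius_range = c(14, 22),
                        max_attempts = 500L) {
  stopifnot(n_cells >= 1, nucleus_brightness > 0, nucleus_brightness < 1,
            texture >= 0, texture < 1, nucleus_scale > 0, nucleus_scale < 0.8)
  rows <- config$image_shape[1]; cols <- config$image_shape[2]

  withr::with_seed(config$seed, {
    cells <- NULL
    for (k in seq_len(n_cells)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        a <- stats::runif(1, cell_radius_range[1], cell_radius_range[2])
        b <- a * stats::runif(1, 0.55, 0.9)
        th <- stats::runif(1, 0, pi)
        if (2 * a + 4 > min(rows, cols))
          stop(sprintf("cells of radius %.0f px cannot fit a %dx%d image",
                       a, rows, cols))
        cy <- stats::runif(1, a + 2, rows - a - 1)
        cx <- stats::runif(1, a + 2, cols - a - 1)
        ok <- TRUE
        if (!is.null(cells)) {
          d <- sqrt((cells$cy - cy)^2 + (cells$cx - cx)^2)
          ok <- all(d > cells$a + a + 2)
        }
        if (ok) {
          # nucleus: same orientation, scaled axes, small interior offset
          na <- nucleus_scale * a; nb <- nucleus_scale * b
          sa <- 0.95 * a - na; sb <- 0.95 * b - nb
          repeat {
            ou <- stats::runif(1, -0.5, 0.5) * sa
            ov <- stats::runif(1, -0.5, 0.5) * sb
            if ((ou / sa)^2 + (ov / sb)^2 <= 0.25) break
          }
          ncy <- cy + ou * sin(th) + ov * cos(th)
          ncx <- cx + ou * cos(th) - ov * sin(th)
          cells <- rbind(cells, data.frame(
            cell = k, cy = cy, cx = cx, a = a, b = b, theta = th,
            na = na, nb = nb, ncy = ncy, ncx = ncx))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(
          "could not place %d non-overlapping cells in a %dx%d image (failed at cell %d after %d attempts)",
          n_cells, rows, cols, k, max_attempts))
    }

    labels <- matrix(0L, rows, cols)
    brightness <- matrix(0, rows, cols)
    fractions <- array(0, c(rows, cols, 3))
    lls <- condition$lls_fraction
    cyt_b <- condition$cytoplasm_bound_fraction
    nuc_b <- condition$nucleus_bound_fraction
    for (k in seq_len(n_cells)) {
      cc <- cells[k, ]
      cellm <- .ellipse_mask(rows, cols, cc$cy, cc$cx, cc$a, cc$b, cc$theta)
      nucm <- .ellipse_mask(rows, cols, cc$ncy, cc$ncx, cc$na, cc$nb, cc$theta) & cellm
      cytm <- cellm & !nucm
      labels[nucm] <- 2L * k - 1L
      labels[cytm] <- 2L * k
      brightness[cytm] <- stats::runif(sum(cytm), 1 - texture, 1 + texture)
      brightness[nucm] <- nucleus_brightness
      # cytoplasm: LLS share first, remainder split bound/free
      f <- matrix(0, sum(cytm), 3)
      f[, 3] <- lls
      f[, 2] <- cyt_b * (1 - lls)
      f[, 1] <- (1 - cyt_b) * (1 - lls)
      idx <- which(cytm)
      for (j in 1:3) fractions[, , j][idx] <- f[, j]
      idx <- which(nucm)
      fractions[, , 1][idx] <- 1 - nuc_b
      fractions[, , 2][idx] <- nuc_b
    }
    flim_scene(fractions, brightness, labels, condition, cells)
  })
}

#' Ground-truth label mask of a synthetic scene
#'
#' @param scene a `flim_scene`.
#' @param level `"roi"` keeps the nucleus/cytoplasm labels (2k-1 / 2k);
#'   `"cell"` merges each cell's nucleus and cytoplasm into label k.
#' @return a [label_mask()].
#' @export
scene_truth_mask <- function(scene, level = c("roi", "cell")) {
  level <- match.arg(level)
  lab <- scene$labels
  if (level == "cell") {
    lab2 <- matrix(0L, nrow(lab), ncol(lab))
    lab2[lab > 0] <- (lab[lab > 0] + 1L) %/% 2L
    ids <- sort(unique(lab2[lab2 > 0]))
    return(label_mask(lab2, stats::setNames(rep("cell", length(ids)), ids)))
  }
  ids <- sort(unique(lab[lab > 0]))
  cls <- ifelse(ids %% 2L == 1L, "nucleus", "cytoplasm")
  par <- stats::setNames((ids + 1L) %/% 2L, ids)
  label_mask(lab, stats::setNames(cls, ids), parent = par[cls == "nucleus"])
}
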