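#' Pure-species basis for phasor unmixing
#'
#' Defines the 2 or 3 pure species anchoring the unmixing geometry. Each
#' component is given either by its mono-exponential lifetime (placed on
#' the universal semicircle at `omega`) or by an explicit (g, s) position.
#'
#' @param labels character vector of component names (e.g.
#'   `c("free", "bound")` or `c("free", "bound", "lls")`).
#' @param lifetimes named/positional lifetimes in ns (NA for components
#'   given by position).
#' @param g,s optional explicit positions overriding the lifetime placement
#'   (NA entries fall back to the lifetime).
#' @param omega angular frequency in rad/ns used to place lifetimes.
#' @return object of class `component_basis`.
#' @export
component_basis <- function(labels, lifetimes = NULL, g = NULL, s = NULL,
                            omega) {
  k <- length(labels)
  if (k < 2 || k > 3) stop("a component basis needs 2 or 3 components")
  gg <- rep(NA_real_, k); ss <- rep(NA_real_, k)
  if (!is.null(lifetimes)) {
    th <- theoretical_phasor(ifelse(is.na(lifetimes), 0, lifetimes), omega)
    gg <- ifelse(is.na(lifetimes), NA_real_, th$g)
    ss <- ifelse(is.na(lifetimes), NA_real_, th$s)
  }
  if (!is.null(g)) gg[!is.na(g)] <- g[!is.na(g)]
  if (!is.null(s)) ss[!is.na(s)] <- s[!is.na(s)]
  if (any(is.na(gg)) || any(is.na(ss)))
    stop("every component needs a lifetime or an explicit (g, s) position")
  pos <- cbind(g = gg, s = ss)
  d <- as.matrix(stats::dist(pos))
  if (min(d[upper.tri(d)]) < 1e-6)
    stop("component positions must be pairwise distinct")
  if (k == 3) {
    area <- abs((pos[2, 1] - pos[1, 1]) * (pos[3, 2] - pos[1, 2]) -
                (pos[3, 1] - pos[1, 1]) * (pos[2, 2] - pos[1, 2])) / 2
    if (area < 1e-9) stop("three-component basis is collinear")
  }
  structure(list(labels = labels, g = gg, s = ss, omega = omega,
                 lifetimes = if (is.null(lifetimes)) rep(NA_real_, k) else lifetimes),
            class = "component_basis")
}

#' Default free/bound NAD(P)H (+ LLS) basis
#'
#' @param omega angular frequency in rad/ns.
#' @param n_components 2 (free, bound) or 3 (plus LLS).
#' @param lifetimes named vector from [nadph_lifetimes()].
#' @return a [component_basis()].
#' @export
default_nadph_basis <- function(omega, n_components = 2L,
                                lifetimes = nadph_lifetimes()) {
  if (n_components == 2L)
    component_basis(c("free", "bound"), lifetimes[c("free", "bound")],
                    omega = omega)
  else
    component_basis(c("free", "bound", "lls"),
                    lifetimes[c("free", "bound", "lls")], omega = omega)
}

#' @export
print.component_basis <- function(x, ...) {
  cat(sprintf("%d-component basis at omega %.4g rad/ns:\n", length(x$labels), x$omega))
  for (i in seq_along(x$labels))
    cat(sprintf("  %-6s g=%.4f s=%.4f%s\n", x$labels[i], x$g[i], x$s[i],
                if (!is.na(x$lifetimes[i])) sprintf(" (tau %.3g ns)", x$lifetimes[i]) else ""))
  invisible(x)
}

.fraction_map <- function(fractions, labels, out_of_gamut, valid, basis) {
  dimnames(fractions)[[3]] <- labels
  bfr <- NULL
  if (all(c("free", "bound") %in% labels)) {
    fb <- fractions[, , "bound"]; ff <- fractions[, , "free"]
    bfr <- ifelse(valid & ff > 0, fb / ff, NA_real_)
  }
  structure(list(fractions = fractions, labels = labels,
                 out_of_gamut = out_of_gamut, valid = valid,
                 bound_free_ratio = bfr, basis = basis),
            class = "fraction_map")
}

#' @export
print.fraction_map <- function(x, ...) {
  cat(sprintf("fraction map (%s): %dx%d px, %d valid, %d out-of-gamut\n",
              paste(x$labels, collapse = "/"),
              nrow(x$valid), ncol(x$valid), sum(x$valid),
              sum(x$out_of_gamut, na.rm = TRUE)))
  invisible(x)
}

#' Two-component fractional intensities along the phasor chord
#'
#' Each valid pixel phasor is orthogonally projected onto the segment
#' joining the two pure-species phasors; the fractional intensity of a
#' component is the normalized distance of the projection from the
#' opposite component. Projections beyond an endpoint are clamped to
#' \{0, 1\} and flagged `out_of_gamut`. The map also carries the per-pixel
#' bound/free ratio when the basis labels contain "free" and "bound".
#'
#' @param field a calibrated `phasor_field`.
#' @param basis a 2-[component_basis()].
#' @return object of class `fraction_map`.
#' @export
two_component_fractions <- function(field, basis) {
  stopifnot(inherits(basis, "component_basis"))
  if (length(basis$labels) != 2) stop("`basis` must have exactly 2 components")
  p1 <- c(basis$g[1], basis$s[1]); p2 <- c(basis$g[2], basis$s[2])
  v <- p1 - p2
  den <- sum(v^2)
  t_raw <- ((field$g - p2[1]) * v[1] + (field$s - p2[2]) * v[2]) / den
  oog <- field$valid & (t_raw < 0 | t_raw > 1)
  t1 <- pmin(pmax(t_raw, 0), 1)
  rows <- nrow(field$g); cols <- ncol(field$g)
  fr <- array(NA_real_, c(rows, cols, 2))
  fr[, , 1] <- ifelse(field$valid, t1, NA_real_)
  fr[, , 2] <- ifelse(field$valid, 1 - t1, NA_real_)
  .fraction_map(fr, basis$labels, oog & field$valid, field$valid, basis)
}

#' Three-component (barycentric) fractional intensities
#'
#' Solves, per pixel, the linear system `[g_i; s_i; 1] f = [g; s; 1]`
#' whose solution is the barycentric coordinates of the pixel phasor in
#' the triangle spanned by the three pure species. Negative raw fractions
#' (pixels outside the triangle) are clamped to 0 with renormalization and
#' flagged `out_of_gamut`.
#'
#' @param field a calibrated `phasor_field`.
#' @param basis a 3-[component_basis()] (non-collinear).
#' @return object of class `fraction_map`.
#' @export
three_component_fractions <- function(field, basis) {
  stopifnot(inherits(basis, "component_basis"))
  if (length(basis$labels) != 3) stop("`basis` must have exactly 3 components")
  m <- rbind(basis$g, basis$s, rep(1, 3))
  minv <- solve(m)
  sel <- which(field$valid)
  rhs <- rbind(field$g[sel], field$s[sel], rep(1, length(sel)))
  f <- minv %*% rhs                          # 3 x n
  neg <- f < -1e-12
  oog_v <- colSums(neg) > 0
  f[f < 0] <- 0
  f <- sweep(f, 2, colSums(f), "/")
  rows <- nrow(field$g); cols <- ncol(field$g)
  fr <- array(NA_real_, c(rows, cols, 3))
  for (j in 1:3) { tmp <- matrix(NA_real_, rows, cols); tmp[sel] <- f[j, ]; fr[, , j] <- tmp }
  oog <- matrix(FALSE, rows, cols); oog[sel] <- oog_v
  .fraction_map(fr, basis$labels, oog, field$valid, basis)
}

#' Flag pixels carrying long-lifetime species
#'
#' Reproducible surrogate of the manual "yellow cursor" selection: pixels
#' whose LLS fractional intensity meets the threshold are flagged, counted
#' and returned with their LLS percentages (histogram-ready).
#'
#' @param fractions a `fraction_map` from a 3-component basis containing a
#'   component labeled `"lls"`.
#' @param threshold minimum LLS fractional intensity (default 0.15).
#' @return list with `mask` (logical matrix), `n_pixels`, and
#'   `lls_percent` (vector of per-flagged-pixel LLS percentages).
#' @export
flag_lls <- function(fractions, threshold = 0.15) {
  stopifnot(inherits(fractions, "fraction_map"))
  if (!"lls" %in% fractions$labels)
    stop("fraction map has no component labeled 'lls'")
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  fl <- fractions$fractions[, , "lls"]
  mask <- fractions$valid & !is.na(fl) & fl >= threshold
  list(mask = mask, n_pixels = sum(mask), lls_percent = 100 * fl[mask])
}
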