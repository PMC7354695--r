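#' Per-pixel phasor coordinates of a FLIM image
#'
#' A `phasor_field` holds per-pixel (g, s) coordinates at a chosen harmonic
#' of the laser repetition rate together with the total-intensity image and
#' a validity mask (pixels with enough photons for the per-pixel phasor to
#' be meaningful). Angular frequency `omega` is stored in rad/ns so that
#' lifetimes are in ns throughout.
#'
#' @name phasor_field
NULL

.phasor_field <- function(g, s, intensity, valid, harmonic, omega, rep_rate_hz,
                          period_ns, n_bins, threshold, calibrated = FALSE) {
  structure(list(g = g, s = s, intensity = intensity, valid = valid,
                 harmonic = as.integer(harmonic), omega = omega,
                 rep_rate_hz = rep_rate_hz, period_ns = period_ns,
                 n_bins = n_bins, threshold = threshold,
                 calibrated = calibrated),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("phasor field: %dx%d px, harmonic %d (omega %.4g rad/ns), %d/%d valid%s\n",
              nrow(x$g), ncol(x$g), x$harmonic, x$omega,
              sum(x$valid), length(x$valid),
              if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' Transform a decay cube to phasor space
#'
#' Computes, per pixel, `g = sum_k c_k cos(omega t_k) / sum_k c_k` and
#' `s = sum_k c_k sin(omega t_k) / sum_k c_k` with `t_k` the bin-centre
#' times and `omega = 2 pi harmonic / period`. A bin-width (sinc) modulus
#' correction `sin(theta/2)/(theta/2)`, `theta = omega dt`, maps the binned
#' transform onto the continuous-time convention so that mono-exponential
#' decays land on the universal semicircle up to a phase-discretization
#' residual of order `omega dt^2 / (12 tau)` (negligible at fine binning
#' and absorbed by calibration otherwise).
#'
#' Pixels whose total counts fall below `intensity_threshold` are masked
#' (g, s set to NA), not zero-filled.
#'
#' @param cube a [decay_cube()].
#' @param harmonic integer >= 1; must satisfy `harmonic <= n_bins / 2`
#'   (otherwise the transform aliases).
#' @param intensity_threshold minimum total counts per pixel (default 30).
#' @return a `phasor_field`.
#' @export
phasor_transform <- function(cube, harmonic = 1L, intensity_threshold = 30) {
  stopifnot(inherits(cube, "decay_cube"), harmonic >= 1)
  n <- cube$n_bins
  dt <- cube$bin_width_ns
  omega <- 2 * pi * harmonic / cube$period_ns
  if (omega * dt > pi + 1e-12)
    stop(sprintf("harmonic %d aliases with %d time bins (omega*dt > pi)",
                 harmonic, n))
  tk <- (seq_len(n) - 0.5) * dt
  cw <- cos(omega * tk); sw <- sin(omega * tk)
  cmat <- matrix(cube$counts, n)
  tot <- colSums(cmat)
  corr <- sin(omega * dt / 2) / (omega * dt / 2)
  g <- as.vector(cw %*% cmat) / tot * corr
  s <- as.vector(sw %*% cmat) / tot * corr
  valid <- tot >= intensity_threshold & tot > 0
  if (!any(valid)) warning("all pixels fall below the intensity threshold")
  g[!valid] <- NA_real_; s[!valid] <- NA_real_
  sh <- cube$shape
  .phasor_field(matrix(g, sh[1], sh[2]), matrix(s, sh[1], sh[2]),
                matrix(tot, sh[1], sh[2]), matrix(valid, sh[1], sh[2]),
                harmonic, omega, cube$rep_rate_hz, cube$period_ns, n,
                intensity_threshold)
}

#' Phasor of a mono-exponential lifetime (universal semicircle)
#'
#' `g = 1 / (1 + (omega tau)^2)`, `s = omega tau / (1 + (omega tau)^2)`:
#' the locus of all mono-exponential decays, a semicircle of radius 0.5
#' centred at (0.5, 0).
#'
#' @param tau lifetime in ns (>= 0); vectorized.
#' @param omega angular frequency in rad/ns.
#' @return list with numeric `g` and `s`.
#' @export
theoretical_phasor <- function(tau, omega) {
  if (any(tau < 0)) stop("`tau` must be >= 0")
  wt <- omega * tau
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Phase and modulation lifetimes from phasor coordinates
#'
#' `tau_phase = tan(phase)/omega = (s/g)/omega`, and
#' `tau_mod = sqrt(1/(g^2+s^2) - 1)/omega`. The two coincide only for
#' mono-exponential decays; for mixtures `tau_phase < tau_mod`. Undefined
#' cases are returned as NA: `tau_phase` where `g <= 0`, `tau_mod` where
#' the phasor lies outside the unit circle (`g^2+s^2 > 1`) or at the
#' origin.
#'
#' @param g,s phasor coordinates (vectorized).
#' @param omega angular frequency in rad/ns.
#' @return data.frame with columns `tau_phase`, `tau_mod` (ns).
#' @export
lifetime_from_phasor <- function(g, s, omega) {
  m2 <- g^2 + s^2
  tau_phase <- ifelse(is.finite(g) & g > 0, (s / g) / omega, NA_real_)
  tau_mod <- ifelse(is.finite(m2) & m2 > 0 & m2 <= 1,
                    sqrt(pmax(1 / m2 - 1, 0)) / omega, NA_real_)
  data.frame(tau_phase = tau_phase, tau_mod = tau_mod)
}

#' Intensity-weighted mean phasor of a field
#'
#' @param field a `phasor_field`.
#' @param mask optional logical matrix restricting the average.
#' @return list with `g`, `s`, `n` (pixels used), `intensity` (total).
#' @export
mean_phasor <- function(field, mask = NULL) {
  sel <- field$valid
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("no valid pixels to average")
  w <- field$intensity[sel]
  list(g = sum(field$g[sel] * w) / sum(w),
       s = sum(field$s[sel] * w) / sum(w),
       n = sum(sel), intensity = sum(w))
}

#' Mask-aware median filter of a phasor field
#'
#' Median-filters the g and s channels independently inside the validity
#' mask; masked pixels are excluded from every window and remain masked.
#' Intensity is untouched. Standard spatial denoising step before
#' per-pixel unmixing.
#'
#' @param field a `phasor_field`.
#' @param window odd window side length (default 3).
#' @param passes number of repeated passes (default 1; 0 returns the field
#'   unchanged).
#' @return a filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, window = 3L, passes = 1L) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window < 1 || passes < 0) stop("invalid `window`/`passes`")
  if (window == 1 || passes == 0) return(field)
  h <- (window - 1L) %/% 2L
  rows <- nrow(field$g); cols <- ncol(field$g)
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  filt1 <- function(m) {
    stack <- array(NA_real_, c(rows, cols, nrow(offs)))
    for (i in seq_len(nrow(offs))) {
      dr <- offs$dr[i]; dc <- offs$dc[i]
      r_src <- seq_len(rows) + dr; c_src <- seq_len(cols) + dc
      rok <- r_src >= 1 & r_src <= rows; cok <- c_src >= 1 & c_src <= cols
      stack[which(rok), which(cok), i] <- m[r_src[rok], c_src[cok]]
    }
    out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
    out[!field$valid] <- NA_real_
    out[is.nan(out)] <- NA_real_
    out
  }
  g <- field$g; s <- field$s
  for (p in seq_len(passes)) {
    gm <- g; gm[!field$valid] <- NA_real_
    sm <- s; sm[!field$valid] <- NA_real_
    g <- filt1(gm); s <- filt1(sm)
  }
  out <- field
  out$g <- g; out$s <- s
  out
}
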