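#' Photon-count decay cube
#'
#' Container for a time-resolved acquisition: per-pixel photon-count
#' histograms over one laser period plus the acquisition metadata needed to
#' interpret them.
#'
#' @param counts numeric/integer array `c(n_bins, rows, cols)`, non-negative.
#' @param config the [acquisition_config()] the cube was rendered with.
#' @param condition condition tag (character).
#' @param noiseless logical, TRUE when counts are expectations.
#' @return object of class `decay_cube`.
#' @export
decay_cube <- function(counts, config, condition = NA_character_,
                       noiseless = FALSE) {
  stopifnot(length(dim(counts)) == 3)
  if (any(counts < 0)) stop("decay counts must be non-negative")
  structure(list(
    counts = counts,
    rep_rate_hz = config$laser_rep_rate,
    n_bins = dim(counts)[1],
    shape = dim(counts)[2:3],
    period_ns = config$period_ns,
    bin_width_ns = config$period_ns / dim(counts)[1],
    distortion = list(phase_offset = config$instrument_phase_offset,
                      mod_factor = config$instrument_mod_factor,
                      irf_fwhm = config$irf_fwhm),
    seed = config$seed,
    condition = condition,
    noiseless = noiseless
  ), class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  cat(sprintf("decay cube: %d bins x %dx%d px, %.1f MHz, mean %.1f counts/px%s\n",
              x$n_bins, x$shape[1], x$shape[2], x$rep_rate_hz / 1e6,
              mean(intensity_image(x)), if (x$noiseless) " (noiseless)" else ""))
  invisible(x)
}

#' Total-intensity image of a decay cube
#' @param cube a `decay_cube`.
#' @return matrix `rows x cols` of per-pixel total counts.
#' @export
intensity_image <- function(cube) {
  apply(cube$counts, c(2, 3), sum)
}

# Normalized per-bin expectation of one species under the full instrument
# model: wrapped periodic mono-exponential delayed by the instrument phase,
# integrated exactly over each time bin, circularly blurred by the Gaussian
# IRF, then demodulated by mixing with a uniform background. Sums to 1.
.species_template <- function(tau, config) {
  if (tau <= 0) stop("species lifetime must be > 0")
  n <- config$n_time_bins
  p <- config$period_ns
  dt <- config$bin_width_ns
  omega <- 2 * pi / p
  tk <- (seq_len(n) - 0.5) * dt
  shift <- config$instrument_phase_offset / omega
  # cumulative integral of the periodic wrapped exponential at any real x
  cum <- function(x) {
    xm <- x %% p
    per_period <- 1 - exp(-p / tau)
    (x - xm) / p * per_period + (1 - exp(-xm / tau))
  }
  edges <- (0:n) * dt - shift
  w <- diff(cum(edges))
  w <- w / sum(w)
  if (config$irf_fwhm > 0) {
    sigma <- config$irf_fwhm / (2 * sqrt(2 * log(2)))
    # circular Gaussian kernel centred on bin 1 (zero delay)
    d <- pmin(tk - dt / 2, p - (tk - dt / 2))
    ker <- exp(-d^2 / (2 * sigma^2))
    ker <- ker / sum(ker)
    w <- Re(stats::fft(stats::fft(w) * stats::fft(ker), inverse = TRUE)) / n
    w <- pmax(w, 0); w <- w / sum(w)
  }
  m <- config$instrument_mod_factor
  m * w + (1 - m) / n
}

#' Render a scene into a photon-count decay cube
#'
#' Per pixel, the expected decay is `brightness x sum_i f_i E_i(t)` where
#' `E_i` is the wrapped periodic mono-exponential of species i carried
#' through the instrument model (phase delay, optional Gaussian IRF,
#' demodulation). The global brightness is scaled so the expected image
#' mean equals `target_mean_counts x brightness_scale` of the condition
#' (emulating the usual "acquire until ~N mean counts" stopping rule), and
#' counts are Poisson-sampled unless `noiseless`.
#'
#' @param scene a [flim_scene()].
#' @param config an [acquisition_config()]; its seed drives the photon noise.
#' @param noiseless skip Poisson sampling and return expectations.
#' @param lifetimes named vector from [nadph_lifetimes()].
#' @return a [decay_cube()].
#' @export
render_decays <- function(scene, config = acquisition_config(),
                          noiseless = FALSE, lifetimes = nadph_lifetimes()) {
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  if (!all(dim(scene$brightness) == c(rows, cols)))
    stop("scene and config image shapes disagree")
  tm <- vapply(lifetimes[c("free", "bound", "lls")], .species_template,
               numeric(config$n_time_bins), config = config)
  bvec <- as.vector(scene$brightness)
  amp <- cbind(bvec * as.vector(scene$fractions[, , 1]),
               bvec * as.vector(scene$fractions[, , 2]),
               bvec * as.vector(scene$fractions[, , 3]))
  mb <- mean(bvec)
  if (mb <= 0) stop("scene has no foreground brightness")
  scale <- config$target_mean_counts * scene$condition$brightness_scale / mb
  lambda <- tm %*% t(amp) * scale          # n_bins x n_pixels
  if (any(lambda < -1e-9)) stop("internal error: negative expected counts")
  counts <- if (noiseless) lambda else
    withr::with_seed(config$seed + 1L,
      array(stats::rpois(length(lambda), pmax(lambda, 0)), dim(lambda)))
  decay_cube(array(counts, c(config$n_time_bins, rows, cols)), config,
             condition = scene$condition$name, noiseless = noiseless)
}

#' Render a spatially uniform mono-exponential reference cube
#'
#' Emulates the calibration measurement on a reference dye of known
#' mono-exponential lifetime (fluorescein at high pH, 4 ns, by default in
#' the downstream calibration helpers). The cube carries the same
#' instrument distortion as [render_decays()] and is Poisson-sampled unless
#' `noiseless`.
#'
#' @param tau_ref reference lifetime in ns (> 0).
#' @param config an [acquisition_config()].
#' @param noiseless skip Poisson sampling.
#' @return a [decay_cube()] with condition tag `"reference"`.
#' @export
make_reference <- function(tau_ref, config = acquisition_config(),
                           noiseless = FALSE) {
  if (tau_ref <= 0) stop("`tau_ref` must be > 0")
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  w <- .species_template(tau_ref, config)
  lambda <- matrix(w, config$n_time_bins, rows * cols) * config$target_mean_counts
  counts <- if (noiseless) lambda else
    withr::with_seed(config$seed + 1L,
      array(stats::rpois(length(lambda), lambda), dim(lambda)))
  decay_cube(array(counts, c(config$n_time_bins, rows, cols)), config,
             condition = "reference", noiseless = noiseless)
}
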