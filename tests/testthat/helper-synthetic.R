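# shared fixtures and independent oracles, all built in code

# spatially uniform scene with constant species fractions (free, bound, lls)
uniform_scene <- function(fr, shape = c(8, 8),
                          condition = condition_preset("maintenance")) {
  fra <- array(0, c(shape, 3))
  for (j in 1:3) fra[, , j] <- fr[j]
  flim_scene(fra, matrix(1, shape[1], shape[2]), condition = condition)
}

# phasor of one noiselessly rendered uniform-composition pixel
noiseless_phasor <- function(fr, config, lifetimes = nadph_lifetimes()) {
  sc <- uniform_scene(fr, config$image_shape)
  f <- phasor_transform(render_decays(sc, config, noiseless = TRUE,
                                      lifetimes = lifetimes))
  list(g = f$g[1, 1], s = f$s[1, 1], omega = f$omega)
}

# basis anchored at the *rendered* pure-species phasor positions
measured_basis <- function(labels, config, lifetimes = nadph_lifetimes()) {
  pure <- diag(3)[match(labels, c("free", "bound", "lls")), , drop = FALSE]
  pos <- apply(pure, 1, function(fr) {
    p <- noiseless_phasor(fr, config, lifetimes)
    c(p$g, p$s)
  })
  component_basis(labels, g = pos[1, ], s = pos[2, ],
                  omega = 2 * pi / config$period_ns)
}

# an undistorted small config for exactness-grade checks
undistorted_config <- function(n_bins = 256L, shape = c(2L, 2L), seed = 0L) {
  acquisition_config(n_time_bins = n_bins, image_shape = shape,
                     instrument_phase_offset = 0,
                     instrument_mod_factor = 1, seed = seed)
}

# independent continuous-time phasor oracle: fine midpoint quadrature of the
# wrapped exponential over one period (no shared code with the package path)
integration_phasor_oracle <- function(tau, period_ns, harmonic = 1,
                                      n_points = 2e5) {
  tt <- (seq_len(n_points) - 0.5) * period_ns / n_points
  w <- exp(-tt / tau)
  om <- 2 * pi * harmonic / period_ns
  c(g = sum(w * cos(om * tt)) / sum(w), s = sum(w * sin(om * tt)) / sum(w))
}

# independent exact Mann-Whitney two-sided p by full enumeration of
# group assignments (doubling convention)
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(utils::combn(n, na), 2, u_of)
  u_obs <- u_of(seq_len(na))
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# independent constrained least-squares oracle for 3-component unmixing:
# eliminate f3 = 1 - f1 - f2 and solve the reduced normal equations
ls3_oracle <- function(g, s, basis) {
  a <- cbind(c(basis$g[1] - basis$g[3], basis$s[1] - basis$s[3]),
             c(basis$g[2] - basis$g[3], basis$s[2] - basis$s[3]))
  y <- c(g - basis$g[3], s - basis$s[3])
  f12 <- solve(crossprod(a), crossprod(a, y))
  c(f12, 1 - sum(f12))
}

# per-condition ROI and cell-level summaries for a scaled-down acquisition;
# calibration is fitted once and shared
condition_summaries <- function(cname, seed, cal, n_fields = 2L,
                                cells_per_field = 3L,
                                shape = c(128L, 128L), n_bins = 64L) {
  rows <- list()
  ci <- match(cname, names(phasorflim:::.preset_table))
  for (fi in seq_len(n_fields)) {
    acq <- acquisition_config(image_shape = shape, n_time_bins = n_bins,
                              seed = seed * 1000L + ci * 100L + fi)
    sc <- build_scene(cells_per_field, condition_preset(cname), acq)
    cube <- render_decays(sc, acq)
    fld <- median_filter_phasor(apply_calibration(phasor_transform(cube), cal))
    img <- intensity_image(cube)
    mask <- suppressMessages(segment_nuclei(img, segment_cells(img)))
    roi <- suppressMessages(roi_phasor_summary(fld, mask, condition = cname))
    cell <- suppressMessages(
      roi_phasor_summary(fld, as_cell_mask(mask), condition = cname))
    roi$level <- "roi"; cell$level <- "cell"
    rows[[fi]] <- rbind(roi, cell)
  }
  do.call(rbind, rows)
}

summary_center <- function(s, level = "cell", cls = NULL) {
  s <- s[s$level == level, ]
  if (!is.null(cls)) s <- s[s$roi_class == cls, ]
  colMeans(s[, c("mean_g", "mean_s")])
}

center_dist <- function(a, b, level = "cell", cls = NULL) {
  sqrt(sum((summary_center(a, level, cls) - summary_center(b, level, cls))^2))
}
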