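test_that("phasor transform matches hand-built decays and the integration oracle", {
  cfg <- undistorted_config()
  # all counts in the first bin: near the zero-lifetime point
  counts <- array(0, c(256, 2, 2)); counts[1, , ] <- 100
  f <- phasor_transform(decay_cube(counts, cfg))
  expect_lt(abs(f$g[1, 1] - 1), 0.013)
  expect_lt(abs(f$s[1, 1] - 0), 0.013)
  # uniform counts: orthogonality of cos/sin over a full period
  countsu <- array(10, c(256, 2, 2))
  fu <- phasor_transform(decay_cube(countsu, cfg))
  expect_equal(fu$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(fu$s[1, 1], 0, tolerance = 1e-12)
  # 4 ns wrapped mono-exponential vs independent fine-quadrature oracle
  f4 <- phasor_transform(make_reference(4, cfg, noiseless = TRUE))
  orc <- integration_phasor_oracle(4, cfg$period_ns)
  expect_lt(abs(f4$g[1, 1] - orc["g"]), 5e-5)
  expect_lt(abs(f4$s[1, 1] - orc["s"]), 5e-5)
})

test_that("empty cubes and aliasing harmonics are rejected", {
  cfg <- undistorted_config(n_bins = 16L)
  zero <- decay_cube(array(0, c(16, 2, 2)), cfg)
  expect_warning(fz <- phasor_transform(zero), "below the intensity threshold")
  expect_true(all(is.na(fz$g)))
  full <- decay_cube(array(10, c(16, 2, 2)), cfg)
  expect_error(phasor_transform(full, harmonic = 9L), "alias")
})

test_that("theoretical phasors lie on the universal semicircle", {
  omega <- 2 * pi * 0.08   # 80 MHz in rad/ns
  expect_equal(unlist(theoretical_phasor(0, omega)), c(g = 1, s = 0))
  apex <- theoretical_phasor(1 / omega, omega)
  expect_equal(apex$g, 0.5, tolerance = 1e-12)
  expect_equal(apex$s, 0.5, tolerance = 1e-12)
  t8 <- theoretical_phasor(8, omega); t4 <- theoretical_phasor(4, omega)
  expect_equal((t8$g - 0.5)^2 + t8$s^2, 0.25, tolerance = 1e-12)
  expect_lt(t8$g, t4$g)
  expect_error(theoretical_phasor(-1, omega), "tau")
})

test_that("calibration inverts the injected instrument distortion", {
  cfg <- acquisition_config(image_shape = c(64L, 64L), seed = 0L)
  cal <- fit_calibration(make_reference(4, cfg), 4)
  expect_equal(cal$phase_correction, -0.35, tolerance = 0.01)
  expect_equal(cal$mod_correction, 1 / 0.88, tolerance = 0.01 / 0.88)
  # the model maps its own reference mean onto the theoretical phasor
  th <- theoretical_phasor(4, cal$omega)
  co <- cos(cal$phase_correction); si <- sin(cal$phase_correction)
  mg <- cal$measured_phasor["g"]; ms <- cal$measured_phasor["s"]
  expect_equal(unname(cal$mod_correction * (mg * co - ms * si)), th$g,
               tolerance = 1e-10)
  expect_equal(unname(cal$mod_correction * (mg * si + ms * co)), th$s,
               tolerance = 1e-10)
  # undistorted noiseless reference at fine binning: identity corrections
  cal0 <- fit_calibration(make_reference(4, undistorted_config(n_bins = 8192L),
                                         noiseless = TRUE), 4)
  expect_lt(abs(cal0$phase_correction), 1e-6)
  expect_lt(abs(cal0$mod_correction - 1), 1e-6)
})

test_that("calibrated noiseless two-species phasors land on the component chord", {
  cfg <- acquisition_config(image_shape = c(8L, 8L), seed = 0L)
  cal <- fit_calibration(make_reference(4, cfg, noiseless = TRUE), 4)
  fra <- array(0, c(8, 8, 3))
  fra[, , 1] <- matrix(seq(0, 1, length.out = 64), 8, 8)
  fra[, , 2] <- 1 - fra[, , 1]
  cube <- render_decays(flim_scene(fra, matrix(1, 8, 8)), cfg, noiseless = TRUE)
  fld <- apply_calibration(phasor_transform(cube), cal)
  th1 <- theoretical_phasor(0.4, fld$omega); th2 <- theoretical_phasor(3.4, fld$omega)
  v <- c(th2$g - th1$g, th2$s - th1$s); v <- v / sqrt(sum(v^2))
  dx <- fld$g - th1$g; dy <- fld$s - th1$s
  dist_to_chord <- abs(dx * (-v[2]) + dy * v[1])
  expect_lt(max(dist_to_chord), 1e-3)
})

test_that("apply_calibration enforces matching harmonics and identity models are no-ops", {
  cfg <- undistorted_config(n_bins = 64L)
  f <- phasor_transform(make_reference(4, cfg, noiseless = TRUE))
  cal <- fit_calibration(make_reference(4, cfg, noiseless = TRUE), 4)
  ident <- cal
  ident$phase_correction <- 0; ident$mod_correction <- 1
  fc <- apply_calibration(f, ident)
  expect_equal(fc$g, f$g, tolerance = 1e-12)
  expect_equal(fc$s, f$s, tolerance = 1e-12)
  f2 <- phasor_transform(make_reference(4, cfg, noiseless = TRUE), harmonic = 2L)
  expect_error(apply_calibration(f2, cal), "harmonic")
})

test_that("phase and modulation lifetimes follow the standard formulas", {
  omega <- 2 * pi * 0.08
  lt <- lifetime_from_phasor(c(1, 0.5, 0), c(0, 0.5, 0), omega)
  expect_equal(lt$tau_phase[1], 0)
  expect_equal(lt$tau_mod[1], 0)
  expect_equal(lt$tau_phase[2], 1 / omega, tolerance = 1e-12)
  expect_equal(lt$tau_mod[2], 1 / omega, tolerance = 1e-12)
  expect_true(is.na(lt$tau_phase[3]) && is.na(lt$tau_mod[3]))
  # interior mixtures: tau_phase < tau_mod (heterogeneity signature)
  th1 <- theoretical_phasor(0.4, omega); th2 <- theoretical_phasor(3.4, omega)
  for (a in c(0.2, 0.5, 0.8)) {
    g <- a * th1$g + (1 - a) * th2$g
    s <- a * th1$s + (1 - a) * th2$s
    mix <- lifetime_from_phasor(g, s, omega)
    expect_lt(mix$tau_phase, mix$tau_mod)
  }
})

test_that("calibrated mono-exponential recovery is exact in the fine-binning regime", {
  cfg <- acquisition_config(n_time_bins = 8192L, image_shape = c(2L, 2L), seed = 0L)
  cal <- fit_calibration(make_reference(4, cfg, noiseless = TRUE), 4)
  for (tau in c(0.4, 3.4, 4, 8)) {
    f <- apply_calibration(phasor_transform(make_reference(tau, cfg, noiseless = TRUE)), cal)
    g <- f$g[1, 1]; s <- f$s[1, 1]
    expect_lt(abs(sqrt((g - 0.5)^2 + s^2) - 0.5), 1e-6)
    lt <- lifetime_from_phasor(g, s, f$omega)
    expect_lt(abs(lt$tau_phase - tau) / tau, 0.001)
    expect_lt(abs(lt$tau_mod - tau) / tau, 0.001)
  }
})

test_that("results at harmonic 1 are stable under time-bin refinement", {
  f1 <- phasor_transform(make_reference(3.4, undistorted_config(n_bins = 4096L),
                                        noiseless = TRUE))
  f2 <- phasor_transform(make_reference(3.4, undistorted_config(n_bins = 8192L),
                                        noiseless = TRUE))
  expect_lt(abs(f1$g[1, 1] - f2$g[1, 1]), 1e-6)
  expect_lt(abs(f1$s[1, 1] - f2$s[1, 1]), 1e-6)
})

test_that("per-pixel phasor noise at 100 counts is unbiased", {
  cfg <- acquisition_config(image_shape = c(100L, 100L), n_time_bins = 64L,
                            seed = 21L)
  sc <- uniform_scene(c(0.55, 0.45, 0), c(100, 100))
  noisy <- phasor_transform(render_decays(sc, cfg))
  clean <- phasor_transform(render_decays(sc, cfg, noiseless = TRUE))
  for (ch in c("g", "s")) {
    v <- noisy[[ch]][noisy$valid]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - clean[[ch]][1, 1]), 3 * se + 1e-12)
  }
})

test_that("the masked median filter denoises without touching masked pixels", {
  cfg <- undistorted_config(n_bins = 64L, shape = c(9L, 9L))
  f <- phasor_transform(make_reference(4, cfg, noiseless = TRUE))
  expect_identical(median_filter_phasor(f, window = 1L), f)
  fc <- median_filter_phasor(f, window = 3L)
  expect_equal(fc$g, f$g, tolerance = 1e-12)        # constant field unchanged
  # single-pixel outlier in a constant field is replaced by the constant
  fo <- f; fo$g[5, 5] <- 99
  fof <- median_filter_phasor(fo, window = 3L)
  expect_equal(fof$g[5, 5], f$g[1, 1], tolerance = 1e-12)
  expect_error(median_filter_phasor(f, window = 4L), "odd")
  # masked pixels stay masked and are excluded from windows
  fm <- f; fm$valid[1, 1] <- FALSE; fm$g[1, 1] <- NA; fm$s[1, 1] <- NA
  fmf <- median_filter_phasor(fm, window = 3L)
  expect_true(is.na(fmf$g[1, 1]))
  expect_equal(fmf$g[1, 2], f$g[1, 2], tolerance = 1e-12)
})
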