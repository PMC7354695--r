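omega80 <- 2 * pi * 0.08

test_that("component bases validate geometry", {
  expect_error(component_basis("free", 0.4, omega = omega80), "2 or 3")
  expect_error(component_basis(c("a", "b"), c(2, 2), omega = omega80),
               "distinct")
  th <- theoretical_phasor(c(0.4, 1, 3.4), omega80)
  mid <- 0.5 * (th$g[1] + th$g[3])
  expect_error(
    component_basis(c("a", "b", "c"),
                    g = c(th$g[1], (th$g[1] + th$g[3]) / 2, th$g[3]),
                    s = c(th$s[1], (th$s[1] + th$s[3]) / 2, th$s[3]),
                    omega = omega80),
    "collinear")
  b <- default_nadph_basis(omega80, 3L)
  expect_identical(b$labels, c("free", "bound", "lls"))
})

# a tiny phasor field built directly from coordinates
field_from_points <- function(g, s, omega = omega80) {
  n <- length(g)
  phasorflim:::.phasor_field(matrix(g, 1), matrix(s, 1),
                             matrix(100, 1, n), matrix(TRUE, 1, n),
                             1L, omega, 8e7, 12.5, 256L, 30)
}

test_that("two-component fractions follow the chord geometry", {
  b <- default_nadph_basis(omega80, 2L)
  f <- field_from_points(c(b$g[2], (b$g[1] + b$g[2]) / 2),
                         c(b$s[2], (b$s[1] + b$s[2]) / 2))
  fm <- two_component_fractions(f, b)
  expect_equal(unname(fm$fractions[1, 1, "bound"]), 1)
  expect_equal(unname(fm$fractions[1, 1, "free"]), 0)
  expect_equal(unname(fm$fractions[1, 2, "bound"]), 0.5, tolerance = 1e-12)
  expect_false(any(fm$out_of_gamut))
  expect_equal(fm$bound_free_ratio[1, 2], 1, tolerance = 1e-12)
  # beyond an endpoint: clamped and flagged
  fo <- field_from_points(b$g[2] - 0.1 * (b$g[1] - b$g[2]),
                          b$s[2] - 0.1 * (b$s[1] - b$s[2]))
  fmo <- two_component_fractions(fo, b)
  expect_true(fmo$out_of_gamut[1, 1])
  expect_equal(unname(fmo$fractions[1, 1, "bound"]), 1)
})

test_that("two-component unmixing recovers generator fractions", {
  cfg <- undistorted_config()
  basis <- measured_basis(c("free", "bound"), cfg)
  # noiseless: exact for f in {0, 0.1, ..., 1}
  for (fb in seq(0, 1, by = 0.1)) {
    p <- noiseless_phasor(c(1 - fb, fb, 0), cfg)
    fm <- two_component_fractions(field_from_points(p$g, p$s, p$omega), basis)
    expect_equal(unname(fm$fractions[1, 1, "bound"]), fb, tolerance = 1e-6)
  }
  # Poisson noise at 100 counts/pixel: ROI mean within 0.02 absolute
  cfgn <- acquisition_config(image_shape = c(24L, 24L), seed = 31L)
  cube <- render_decays(uniform_scene(c(0.7, 0.3, 0), c(24, 24)), cfgn)
  cal <- fit_calibration(make_reference(4, cfgn, noiseless = TRUE), 4)
  fld <- median_filter_phasor(apply_calibration(phasor_transform(cube), cal))
  fmn <- two_component_fractions(fld, default_nadph_basis(fld$omega, 2L))
  expect_lt(abs(mean(fmn$fractions[, , "bound"], na.rm = TRUE) - 0.3), 0.02)
})

test_that("three-component barycentric solve matches vertices, centroid and the LS oracle", {
  b <- default_nadph_basis(omega80, 3L)
  f <- field_from_points(c(b$g[3], mean(b$g)), c(b$s[3], mean(b$s)))
  fm <- three_component_fractions(f, b)
  expect_equal(unname(fm$fractions[1, 1, "lls"]), 1, tolerance = 1e-12)
  expect_equal(as.vector(fm$fractions[1, 2, ]), rep(1 / 3, 3),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    w <- stats::runif(3); w <- w / sum(w)
    g <- sum(w * b$g); s <- sum(w * b$s)
    fmi <- three_component_fractions(field_from_points(g, s), b)
    expect_equal(as.vector(fmi$fractions[1, 1, ]), ls3_oracle(g, s, b),
                 tolerance = 1e-9)
  }
})

test_that("three-component unmixing recovers generator fractions", {
  cfg <- undistorted_config()
  basis <- measured_basis(c("free", "bound", "lls"), cfg)
  for (fr in list(c(0.5, 0.3, 0.2), c(0.2, 0.55, 0.25), c(0.85, 0.05, 0.1))) {
    p <- noiseless_phasor(fr, cfg)
    fm <- three_component_fractions(field_from_points(p$g, p$s, p$omega), basis)
    expect_equal(as.vector(fm$fractions[1, 1, ]), fr, tolerance = 1e-6)
  }
  # with Poisson noise: ROI mean within 0.03
  cfgn <- acquisition_config(image_shape = c(24L, 24L), seed = 41L)
  cube <- render_decays(uniform_scene(c(0.5, 0.3, 0.2), c(24, 24)), cfgn)
  cal <- fit_calibration(make_reference(4, cfgn, noiseless = TRUE), 4)
  fld <- median_filter_phasor(apply_calibration(phasor_transform(cube), cal))
  fmn <- three_component_fractions(fld, default_nadph_basis(fld$omega, 3L))
  for (j in seq_along(c(0.5, 0.3, 0.2)))
    expect_lt(abs(mean(fmn$fractions[, , j], na.rm = TRUE) -
                  c(0.5, 0.3, 0.2)[j]), 0.03)
})

test_that("on-chord pixels give identical 2- and 3-component solutions", {
  b2 <- default_nadph_basis(omega80, 2L)
  b3 <- default_nadph_basis(omega80, 3L)
  a <- seq(0.05, 0.95, by = 0.1)
  f <- field_from_points(a * b2$g[2] + (1 - a) * b2$g[1],
                         a * b2$s[2] + (1 - a) * b2$s[1])
  f2 <- two_component_fractions(f, b2)
  f3 <- three_component_fractions(f, b3)
  expect_true(all(abs(f3$fractions[, , "lls"]) < 1e-9))
  expect_equal(f3$fractions[, , "bound"], f2$fractions[, , "bound"],
               tolerance = 1e-9)
  expect_equal(f3$fractions[, , "free"], f2$fractions[, , "free"],
               tolerance = 1e-9)
})

test_that("increasing the bound fraction moves the phasor monotonically toward the bound vertex", {
  cfg <- undistorted_config()
  b <- measured_basis(c("free", "bound"), cfg)
  d <- sapply(seq(0.3, 0.7, by = 0.1), function(fb) {
    p <- noiseless_phasor(c(1 - fb, fb, 0), cfg)
    sqrt((p$g - b$g[2])^2 + (p$s - b$s[2])^2)
  })
  expect_true(all(diff(d) < 0))
})

test_that("LLS flagging separates oxidative-stress conditions", {
  cfg0 <- undistorted_config(n_bins = 64L, shape = c(20L, 20L))
  b3 <- default_nadph_basis(2 * pi / cfg0$period_ns, 3L)
  unmix_cond <- function(cname, seed) {
    cfg <- acquisition_config(image_shape = c(64L, 64L), n_time_bins = 64L,
                              seed = seed)
    sc <- build_scene(2, condition_preset(cname), cfg, cell_radius_range = c(12, 16))
    cube <- render_decays(sc, cfg)
    cal <- fit_calibration(make_reference(4, cfg, noiseless = TRUE), 4)
    fld <- median_filter_phasor(apply_calibration(phasor_transform(cube), cal))
    three_component_fractions(fld, b3)
  }
  fm_h2o2 <- unmix_cond("h2o2", 1L)
  fm_ctrl <- unmix_cond("maintenance", 1L)
  fl_h <- flag_lls(fm_h2o2); fl_c <- flag_lls(fm_ctrl)
  expect_gt(fl_h$n_pixels, fl_c$n_pixels)
  expect_true(all(fl_h$lls_percent >= 15))
  # degenerate threshold: every valid pixel flagged
  expect_equal(flag_lls(fm_ctrl, threshold = 0)$n_pixels, sum(fm_ctrl$valid))
  # all-zero LLS map: empty mask
  f0 <- field_from_points(b3$g[1], b3$s[1])
  fm0 <- three_component_fractions(f0, b3)
  expect_equal(flag_lls(fm0)$n_pixels, 0)
  # basis without an LLS label is rejected
  fm2 <- two_component_fractions(f0, default_nadph_basis(omega80, 2L))
  expect_error(flag_lls(fm2), "lls")
})
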