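# phasorflim

Phasor-based FLIM analysis of NAD(P)H autofluorescence for label-free
metabolic imaging of β-like cells — with a fully synthetic,
ground-truth-carrying acquisition simulator, so the entire pipeline is
testable without a microscope or any download.

## The problem

Glucose-stimulated insulin secretion in pancreatic β-cells runs on a
metabolic switch: stimulated cells funnel glucose carbons into
mitochondrial oxidative phosphorylation, which shifts the intracellular
pool of the autofluorescent coenzyme NAD(P)H from its free form
(lifetime ≈ 0.4 ns) toward its protein-bound form (≈ 3.4 ns). Chronic
hyperglycemia blunts this response and produces long-lifetime species
(LLS, ≈ 8 ns) — autofluorescent products of ROS-driven lipid oxidation
that flag oxidative stress. Fluorescence-lifetime imaging (FLIM) with the
phasor representation measures all of this label-free, per pixel, in
living cells.

Each pixel's photon-decay histogram over one 80 MHz laser period maps to
phasor coordinates

    g = Σ c_k cos(ω t_k) / Σ c_k      s = Σ c_k sin(ω t_k) / Σ c_k

Mono-exponential lifetimes lie on the universal semicircle
`g = 1/(1+(ωτ)²)`, `s = ωτ/(1+(ωτ)²)`; mixtures lie at intensity-weighted
convex combinations, so free/bound NAD(P)H fractions come from projecting
onto the free–bound chord and a third LLS component from barycentric
coordinates in the free–bound–LLS triangle.

The package covers the full chain:

- **Simulation** (`build_scene`, `render_decays`, `make_reference`):
  β-cell-like fields with dim ellipsoidal nuclei, granular cytoplasm,
  condition presets (maintenance, glucose stimulation, chronic
  hyperglycemia, H₂O₂, non-responder), Poisson photon statistics at ~100
  counts/pixel, and a distorted instrument model plus a fluorescein-like
  4 ns calibration reference.
- **Phasor core** (`phasor_transform`, `fit_calibration`,
  `apply_calibration`, `lifetime_from_phasor`, `median_filter_phasor`).
- **Unmixing** (`two_component_fractions`, `three_component_fractions`,
  `flag_lls`) with out-of-gamut flagging and bound/free ratio maps.
- **Segmentation** (`segment_cells`, `segment_nuclei`,
  `roi_phasor_summary`) into cells, nuclei and cytoplasm.
- **Statistics** (`confidence_ellipse`, `euclidean_shift`, `rank_test`,
  `percent_increment`, `compare_conditions`): 90% coverage ellipses of
  per-cell phasor means, Euclidean condition shifts, Mann–Whitney tests.
- **Pipeline + I/O** (`pipeline_config`, `run_pipeline`, TIFF/JSON/CSV
  readers and writers for every intermediate product).

## Worked example

```r
library(phasorflim)

cfg <- pipeline_config(
  seed = 0, n_fields = 2, cells_per_field = 3,
  acquisition = list(image_shape = c(128L, 128L), n_time_bins = 64L))
res <- run_pipeline(cfg, "demo_run")
res$comparisons$maintenance_vs_gsis$euclidean_distance
#> [1] 0.1038176
res$comparisons$maintenance_vs_gsis$rank_test
#> $U
#> [1] 0
#> $p_value
#> [1] 0.002164502
#> $exact
#> [1] TRUE
```

Reading: between the maintenance condition and acute glucose stimulation
the per-cell mean phasors move 0.104 phasor units toward the bound-NAD(P)H
vertex, and the per-ROI bound fractional intensities separate cleanly
(exact Mann–Whitney p ≈ 0.002) — the glucose-stimulated metabolic shift,
resolved per cell. `demo_run/` then holds calibrated phasor maps,
fraction maps, masks, per-ROI CSV summaries, a `comparison.json` and a
run manifest; re-running the same config reproduces them bit-for-bit.

Single stages work standalone:

```r
acq   <- acquisition_config(seed = 1)                  # 256x256, 80 MHz
cal   <- fit_calibration(make_reference(4, acq), 4)    # fluorescein-like dye
scene <- build_scene(5, condition_preset("h2o2"), acq)
field <- apply_calibration(phasor_transform(render_decays(scene, acq)), cal)
fr    <- three_component_fractions(median_filter_phasor(field),
                                   default_nadph_basis(field$omega, 3))
flag_lls(fr)$n_pixels                                  # oxidative-stress pixels
```

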