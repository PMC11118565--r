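# limrepair

Quantification of mechanosensitive LIM-protein assemblies on F-actin and
of actin-bundle repair, from multi-channel TIRF / confocal time-lapse
movies.

## What this is for

LIM-domain proteins (zyxin and relatives) bind mechanically strained
actin filaments. In reconstitution assays they form elongated assemblies
on filaments under myosin force, recruit repair factors (VASP,
ɑ-actinin), condense into droplets, and restore laser-ablated
contractile bundles. `limrepair` is the image-analysis toolkit for these
experiments, aimed at cytoskeleton labs doing in vitro TIRF
reconstitution or cellular stress-fiber ablation:

* **Patch pipeline** — per-frame detection of LIM-protein objects
  (rolling average → Gaussian blur → Sobel → auto-threshold, Li/Yen →
  fill → erode; 10–150 px bandpass), gap-tolerant tracking by
  depth-first traversal of the object-overlap graph (±3-frame window),
  gap/outlier repair, and per-frame topological classification against
  the actin mask: two overlap regions → *bridge*; one region with
  overlap fraction ≥ 0.70 → *actin-bound patch*, else *tail*.
  Trajectories are filtered (actin overlap ≥ 75% of lifetime, maximum
  local-background enrichment ≥ 1.3) and summarised as lifetime
  `n frames × Δt`, maximum Feret length in µm, and enrichment
  `mean(object) / mean(dilated ring)`.
* **Partner analyses** — VASP / ɑ-actinin binding events on patches vs
  bare F-actin (mask-product substrates, preset thresholds and search
  windows, enrichment floors, transient ≤ 2 s vs stable), single-frame
  −ATP colocalization, and actin fold increase in 20 × 20 px boxes
  (integrated density over the mean of the first 5 frames, paired
  against control regions).
* **Condensates** — droplet masks as the product of per-channel Otsu
  masks (≥ 20 px), area fraction, per-droplet enrichment (exclusions:
  < 0.18 µm² or enrichment < 1.1), FRAP traces with histogram-matching
  bleach correction and min–max normalization (the plateau estimates the
  mobile fraction).
* **Repair** — bundle thickness index (erosions to first-frame area),
  strain-site kymographs and normalized traces, repair-frequency tables
  with Fisher's exact test, 10%/80%/10% end/center segment recovery
  rates by linear regression (fit 40–320 s) with a paired end-vs-center
  t test, and an advisory recovery-path classifier (even / center /
  one end + center / both ends) that never overrides manual annotations.
* **Synthetic-movie generator** — plants filaments, patches/bridges/
  tails with blink gaps and exact enrichment ratios, binding events,
  droplets with FRAP recovery `I(t) = I₀(immobile + mobile(1 − e^{−kt}))`,
  and strain sites with chosen spatial recovery paths and per-segment
  rates — with a ground-truth table, so every stage above is verifiable
  against planted truth.

## Worked example

Simulate a noisy 12-frame movie with 12 planted objects (4 per class) and
run the full pipeline:

```r
library(limrepair)

scene   <- sim_scene(field = c(256, 256), n_frames = 12, frame_interval = 3,
                     psf_sigma = 1, noise = TRUE, camera_offset = 0, seed = 7)
objects <- plant_lim_field(scene, n_patch = 4, n_bridge = 4, n_tail = 4, seed = 8)
sim     <- simulate_gliding_movie(scene, objects)

res <- analyze_patches(sim$movie)
res$summary
```

```
   traj_id             class lifetime_s max_length_um max_enrichment n_frames filled_frames
1      1.1 actin_bound_patch         36          1.62           1.57       12             3
2      2.1 actin_bound_patch         36          1.67           1.58       12             0
3      3.1              tail         36          1.70           1.57       12             0
...
12    12.1            bridge         36          1.72           1.60       12             0
```

All 12 planted objects are recovered with their planted class (4
patches, 4 bridges, 4 tails), the full 36 s lifetime (12 frames at
3 s/frame), maximum lengths of ~1.6–1.7 µm for the planted 24-px
segments, and measured enrichments ~1.6 for a planted ratio of 2 — the
expected dilution when measuring through segmented masks at SNR ≈ 3
(see the methods vignette). `filled_frames` counts records synthesised
by gap repair. Lifetime distributions and half-lives come from
`lifetime_cdf()`; `detect_binding_events()`, `droplet_mask()`,
`frap_analyze()`, `bundle_thickness_index()`, `make_kymograph()` and
`recovery_rates()` cover the other assays, and `run_pipeline()` drives
everything from a YAML config (see `inst/cli/limrepair.R` for the
command-line wrapper).

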