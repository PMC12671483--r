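# rushquant

Quantitative tools for studying how newly synthesized integrins reach the
plasma membrane and shape cell adhesion. Newly made integrin heterodimers
leave the endoplasmic reticulum, pass (mostly) through the Golgi, and are
delivered to the cell surface; when that delivery is synchronized with an
ER retention/release ("RUSH"-style) assay and imaged live, it can be seen
to be polarized, ligand-dependent, and focused on focal adhesions — and
the extra receptor availability makes adhesions grow. `rushquant`
implements both halves of that analysis:

* **A stochastic motor-clutch simulator** of adhesion growth. Myosin
  motors load integrin "clutches" through a series spring; the
  integrin–substrate bond unbinds with a catch–slip law
  `k_off(F) = k_c e^{-F/F_c} + k_s e^{F/F_s}`; talin unfolds with a Bell
  law `k_u(F) = k_u0 e^{F/F_u}`; and each unfolding event reinforces the
  adhesion by raising the implicit integrin density by `d_add`, capped at
  three times its initial value. The observable is the integrin density
  normalized to its starting value — a growth-only trace whose speed and
  extent increase with `d_add`, the integrin-availability dial.
* **A quantification pipeline** for two-channel cargo/adhesion movies and
  TIRF flash movies: focal-adhesion segmentation (Otsu + 8-connected
  labelling + strict 0.6 µm² size filter), cargo recruitment relative to
  pre-release intensity, equal-count 4-area tip-to-center delivery
  profiles, adhesion track filtering (lifetime ≥ 15 min, near-edge),
  ratiometric exocytosis detection (each frame divided by the previous)
  with a uniform random-point null and an unpaired comparison,
  protrusion/retraction classification by mask set-differences, longest
  protrusion length, micropattern line profiles and dot enrichment, and
  scalar surface-delivery (geometric-mean ratio, T0-subtracted) and
  band maturation metrics.
* **A synthetic-movie generator** with complete ground truth (adhesion
  label masks, event positions, cell masks, schedules) standing in for
  unavailable microscopy data, so every operator above is tested against
  known truth.

## Worked example

Simulate adhesion growth under low and high integrin availability, then
run the exocytosis pipeline on a synthetic TIRF movie:

```r
library(rushquant)

hi <- simulate_adhesion_growth_multi(clutch_params(d_add = 0.01,  seed = 1), 20)
lo <- simulate_adhesion_growth_multi(clutch_params(d_add = 0.005, seed = 1), 20)
s_hi <- summarize_traces(hi, threshold = 2)
s_lo <- summarize_traces(lo, threshold = 2)
cat(sprintf("final density: high d_add %.2f +/- %.2f, low d_add %.2f +/- %.2f\n",
            tail(s_hi$mean, 1), tail(s_hi$sd, 1),
            tail(s_lo$mean, 1), tail(s_lo$sd, 1)))
#> final density: high d_add 2.41 +/- 0.16, low d_add 1.60 +/- 0.06
cat(sprintf("median time to doubling (high d_add): %.0f s\n",
            median(attr(s_hi, "time_to_threshold"), na.rm = TRUE)))
#> median time to doubling (high d_add): 1408 s

cfg <- movie_config(seed = 1)
tv  <- generate_tirf_movie(cfg)
ev  <- detect_events(ratiometric_stack(tv$movie$channels$tirf),
                     tv$truth$cell_mask, frame_range = c(1, cfg$n_frames - 3))
seg <- segment_adhesions(tv$movie$channels$tirf[, , cfg$n_frames], cfg$pixel_size)
d_ev   <- nearest_fa_distances(ev, seg$labels > 0, cfg$pixel_size)
null   <- random_null_points(tv$truth$cell_mask, nrow(ev), seed = 99)
d_null <- nearest_fa_distances(null, seg$labels > 0, cfg$pixel_size)
compare_distances(d_ev, d_null)
#> Event-to-FA distances: events 0.101 um (n=50) vs null 0.46 um (n=50)
#>   t_test: statistic -5.55, p = 4.32e-07
```

The growth traces say that doubling the per-event integrin increment
raises the mean final adhesion density from about 1.6× to about 2.4× the
starting value within 30 simulated minutes, with every trace starting at
exactly 1, never decreasing, and never exceeding the 3× cap. The distance
comparison says the detected exocytosis events sit an order of magnitude
closer to adhesions than uniformly placed random points — the movie was
generated with 80 % of events adhesion-biased, and the pipeline recovers
that spatial association.

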