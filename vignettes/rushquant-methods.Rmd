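---
title: "Models and methods behind rushquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rushquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rushquant)
```

`rushquant` packages two things that belong together: a stochastic
motor-clutch model of focal-adhesion growth driven by integrin
availability, and the image-quantification pipeline used to measure how
newly synthesized integrin cargo reaches the plasma membrane — adhesion
recruitment, exocytosis detection with a spatial null, polarity and
micropattern metrics, and flow-cytometry/immunoblot-style scalar readouts.
Because raw microscopy movies for this kind of study are rarely shareable,
the package also contains a first-class synthetic-movie generator with
complete ground truth; every downstream operator is tested against that
truth.

## The motor-clutch model

The simulator follows the molecular clutch picture of adhesion
mechanosensing. Myosin motors drive actin retrogradely with a linear
force–velocity relation,

$$v = v_0\,\max\!\left(0,\; 1 - \frac{\sum_i F_i}{n_m F_s}\right),$$

where $n_m$ motors each stall at $F_s$. A fixed set of substrate binding
sites is engaged by integrin "clutches"; a bound clutch is loaded through
the series combination of the clutch and substrate springs,
$k_\mathrm{eff} = k_c k_\mathrm{sub}/(k_c + k_\mathrm{sub})$, its
extension advancing by $v\,\mathrm{d}t$ per step. Binding sites are
explicit; integrins are implicit through a surface density
$d_\mathrm{int}$, so a free site binds with propensity
$k_\mathrm{on} d_\mathrm{int}$.

Three force-dependent kinetic laws close the model:

* **Integrin–fibronectin unbinding** is a catch–slip bond, the sum of a
  force-relieved and a force-accelerated exponential:
  $k_\mathrm{off}(F) = k_c^0 e^{-F/F_c} + k_s^0 e^{F/F_s}$. The rate has
  a minimum at intermediate force — bonds are longest-lived when loaded
  moderately.
* **Talin unfolding** follows a Bell law,
  $k_\mathrm{unfold}(F) = k_u^0 e^{F/F_u}$.
* **Talin refolding** is force-independent at $k_f^0$.

The functional forms are the standard choices of the clutch-model
lineage; all coefficients are configuration (`clutch_params()`), not
code, and can be loaded wholesale from JSON (`read_clutch_config()`).

**Reinforcement.** Each talin unfolding event models adhesion
reinforcement as a density increment $d_\mathrm{add}$; multiple events in
one step add independently before capping. The density never decreases
(the model describes growth only) and saturates at `cap_factor` (default
3) times its initial value, so adhesions grow to a bounded size. The
reported observable is $d_\mathrm{int}(t)/d_\mathrm{int}(0)$, the growth
trace. $d_\mathrm{add}$ is the integrin-availability dial: the
low-delivery condition uses 0.005 and the high-delivery condition 0.01
integrins/µm², and the model's prediction is that the high condition
grows faster and further. The acceptance script recomputes this ordering
from scratch (roughly 2.4× versus 1.6× mean final density over 50 seeds
under the defaults).

**Integration.** The ensemble is advanced by a fixed-timestep Monte Carlo
scheme (Rcpp core): a deterministic force update followed by stochastic
transitions with exponential probabilities $1 - e^{-r\,\mathrm{d}t}$.
These probabilities are bounded for arbitrarily large transient rates, so
a briefly overloaded clutch simply unbinds within the step rather than
producing an invalid probability; a configuration whose *zero-force*
rates cannot be resolved by the chosen `dt` is rejected by
`simulate_adhesion_growth()` (and warned about at construction) instead.
An event-driven Gillespie simulation is deliberately *not* the engine —
it serves as the independent oracle in the test suite, where single-site
occupancy from the fixed-timestep engine must agree with it within
Monte-Carlo error. A timestep-halving test checks that the default
`dt = 0.02` s sits in the converged regime.

**Parameter provenance.** The kinetic constants shipped as defaults are
documented placeholders drawn from the published clutch-model family for
fibronectin-binding integrins (75 motors × 2 pN, 110 nm/s unloaded flow,
catch–slip scales of a few pN); the talin unfolding prefactor
($10^{-4}$/s) was fixed once so that the default high-availability run
spans the tens-of-minutes timescale on which adhesion growth is observed,
and the acceptance properties are insensitive to the exact values (they
assert the cap, monotonicity, null limits and the d_add ordering, not
absolute densities). Users with a calibrated parameter set should replace
the defaults via the JSON config.

**Seeding.** One integer seed fully determines a trace;
`simulate_adhesion_growth_multi()` derives child seeds by unit
increments. The RNG state of the session is saved and restored around
each simulated run.

## The synthetic-movie generator

The generator emulates the study conditions the pipeline was built for,
not photorealistic optics:

* a roughly circular cell whose edge advances or recedes in angular
  sectors at stated speeds (µm/min), giving exactly computable mask
  areas (the suite checks pixel counts against the polygon integral
  within 2 %);
* elongated adhesions (default 3 × 0.75 µm, anisotropic Gaussian
  intensity with a 4:1 axis ratio, oriented radially) that nucleate at a
  distal tip near the edge and extend inward at a stated rate — so cargo
  arriving on the adhesion footprint appears distal-first on growing
  adhesions, the ground truth behind the tip-to-center profile tests;
* a secretory schedule for the cargo channel: perinuclear ER texture
  before the release frame, a Golgi blob for `golgi_residence` minutes
  (default 15), then either adhesion-targeted accumulation (`"FN"`) or
  diffuse membrane accumulation (`"collagen"`);
* pHluorin-style flashes for TIRF movies: instantaneous rise at a
  ground-truth subpixel position, exponential decay (2-frame constant),
  a fraction ρ placed within 0.5 µm of an adhesion pixel and the rest
  uniform over the cell mask, with events kept a few pixels/frames apart
  so truth matching is unambiguous;
* Poisson photon noise at a stated camera gain followed by Gaussian read
  noise — on a flat patch the variance/mean ratio of the Poisson stage
  equals the gain.

The default flash amplitude (120 counts) is set so that the peak is
about five noise standard deviations above the frame-difference noise at
the membrane background — the noise the ratiometric detector actually
faces. Trapped-cargo accumulation at adhesions, which in the real assay
makes the movie's last frame segmentable into adhesions, is rendered only
in the final two frames, after the event window closes; detection is
correspondingly run on the pre-accumulation window via the `frame_range`
option, mirroring the common practice of restricting detections to an
early post-release window.

What the generator does **not** emulate: realistic point-spread optics,
vesicle transport before fusion, adhesion sliding or disassembly,
photobleaching, or cell-to-cell variability in expression. Tests passing
on these movies demonstrate that the operators implement their contracts
on unambiguous input, not that they are robust to every artifact of real
microscopy.

## Quantification pipeline: numerical choices

* **Adhesion segmentation**: global Otsu threshold by default (explicit
  numeric thresholds are accepted and the applied threshold is attached
  to the result), optional Gaussian pre-smoothing in place of a trained
  denoiser, 8-connected labelling (own Rcpp flood fill; the installed
  labelling routine in EBImage is 4-connected), and a strict
  `area > 0.6 µm²` size filter. Degenerate (blank/constant) images yield
  empty tables rather than errors.
* **4-area subdivision**: ROI pixels are ranked by projection onto the
  principal axis oriented from the distal tip inward and split at rank
  quartiles, giving four contiguous areas equal within one pixel, Area 1
  distal. This resolves the open question of how the equal-area split is
  defined on irregular ROIs.
* **Appearance and baseline**: cargo "appears" in an adhesion at the
  first frame its ROI mean exceeds 1.5× the pre-release mean; each
  sub-area is normalized to its own value 2.5 min before appearance.
  When the threshold is never crossed (e.g. constant cargo) the release
  frame serves as the appearance reference, flagged via the `appeared`
  attribute. Zero baselines flag the area instead of dividing.
* **Track linking**: nearest-centroid frame-to-frame linking with a
  displacement gate (default 5 px), area-priority when contested; tracks
  are filtered by lifetime ≥ 15 min (inclusive) and edge distance ≤ 2 µm
  by default ("close to the edge" is otherwise unquantified; the value
  is configurable and reported).
* **Exocytosis detection**: each frame divided by the previous with a
  one-count stabilizing offset; pixels above ratio 2.0 (an explicit,
  logged stand-in for the historical manual threshold) inside the cell,
  8-connected spots of ≥ 2 px, intensity-weighted centroids; an event
  within 3 px of an accepted spot in the previous ratio frame is merged
  as the same fusion's decay. Only accepted-spot pixels populate the
  merge buffer — isolated noise pixels must not suppress a genuine event
  one frame later.
* **Spatial null**: uniform random pixels over the cell mask, by default
  as many as there are events; nearest-adhesion distances come from the
  exact Euclidean distance transform of the adhesion mask; the
  comparison is a two-sided Welch t test (a label-permutation test is
  available and seeded).
* **Polarity**: protrusion/retraction are mask set-differences per
  interval and cumulative unions over the movie (a deliberate,
  documented simplification of contour-tracking map tools); longest
  protrusion is the maximum distance-transform value of newly gained
  pixels to the initial mask.
* **Scalar metrics**: geometric means are computed in log space and
  require strictly positive samples; the surface-delivery index is
  geomean(surface)/geomean(total) per time point minus its T0 value, so
  it is exactly 0 at T0 and invariant under common rescaling.

## Problem sizes

The shipped tests and the acceptance script use: 50 seeds for the clutch
cap and ordering checks (1800 s simulated at `dt = 0.02` s), $10^5$
steps for the Gillespie comparison, 160 × 160 px movies of 30 frames for
the imaging pipeline, 100 seeded runs each for the spatial-bias
(ρ = 1) and type-I (ρ = 0) pipeline checks, and $10^5$ samples for the
log-normal calibration. These sizes keep every Monte-Carlo band far from
its decision boundary while the whole suite completes in a couple of
minutes.

## Known limitations

The clutch model predicts a normalized density, not adhesion geometry;
coupling it to the imaging side is out of scope, as are substrate
rigidity sweeps. The simplified segmentation and polarity operators are
functional equivalents, not numerical replicas, of the interactive
tools they stand in for, and the synthetic movies are a benchmark, not a
microscope.
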