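---
title: "Methods: droplet co-culture counting, autofocus control and phage lysis simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet co-culture counting, autofocus control and phage lysis simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedrop)
```

# The system being modelled

`phagedrop` analyses label-free time-lapse experiments in which two
morphologically distinct bacterial species — a rod-shaped *P. aeruginosa*
strain (PA, a low-motility flagellar mutant) and a cocci-shaped *S. aureus*
strain (SA) — grow inside anchored water-in-oil droplets (~60 µm diameter,
~6 µm high, ~11 pL) and are challenged with a PA-specific lytic phage.
Each droplet is imaged as a brightfield Z-stack (typically 40 slices every
0.5 µm) every 5 minutes; an object detector emits per-slice bounding boxes
with class and confidence, and everything downstream of those detection
files is what this package implements: experiment-design arithmetic,
autofocus control, Z-stack counting, growth/lysis kinetics, and a
stochastic simulator that generates every input the pipeline consumes.

# Encapsulation arithmetic

The droplet is an oblate ellipsoid of volume
$V = \tfrac{4}{3}\pi (d/2)^2 (h/2)$, with 1 pL = 1000 µm³; the default
60 × 6 µm trap gives 11.31 pL. Cell loading is Poissonian:
$\lambda = c \cdot V \cdot 10^{-9}$ for a concentration $c$ in CFU/mL and
$V$ in pL. OD600 converts to CFU/mL through a per-species linear
calibration fitted through the origin (Beer–Lambert proportionality at low
OD) to the paired loading conditions shipped in `calibration_pairs()`.

The multiplicity of infection is the ratio of phage particles to host
cells in the mixed inoculum,
$\mathrm{MOI} = (T \cdot V_p) / \sum_s (c_s \cdot V_s)$; the shared
dilution factor cancels. Two of the tabulated lysis conditions (MOI 20 and
2.5) reproduce exactly under this formula when the host count includes
only the susceptible PA species (the condition table lists no SA plate
count, and the printed 2.5 is exactly the PA-only ratio). Three other
printed MOIs (0.6, 0.2, 5) differ from the PFU/CFU ratio computed from
their own rows (formula values 0.67, 0.37, 2.86); `compute_moi()` returns
the formula value and `lysis_conditions()` carries the printed number
alongside, with no attempt to reconcile the discrepancy (rounding or a
different working titer are both plausible, and guessing would be worse
than reporting).

# Autofocus

A 5-class focus classifier (heavily below / slightly below / in focus /
slightly above / heavily above the plane, classes $c = 1..5$) is reduced
to the focal score $S = \sum_c c\, w_c$ with the confidences $w_c$
normalized to sum to one — classifier confidences need not form an exact
distribution, and the score presumes one. $S \in [2.8, 3.5]$ (inclusive at
both ends) is "in focus", with 3 the predicted best focus. Below-band
scores mean the plane is below focus and the objective moves up (+z) by
one step (0.8 µm default); above-band scores move it down. One published
description of the direction convention states "upwards" for both cases;
we follow the figure-level convention (positive movement for below-focus),
treating the doubled "upwards" as a typo. A separately printed 0–0.5 score
scale is a factor-of-ten normalization inconsistency with the 2.8–3.5
band; the 1–5 scale is adopted.

If the controller takes more than 5 consecutive steps one way
(~4 µm) without reaching the band, that is focus instability: the
direction reverses once and is then held. The reversed run is allowed the
overshoot plus another 5 steps — with only the nominal budget the
controller could not even retrace its own overshoot, making the reversal
useless by construction. A second exhaustion raises a focus-not-found
error. For any classifier whose score is continuous and monotone in
signed defocus with the in-focus band mapping inside ±1 step of true
focus, the loop converges in at most $\lceil |z_0|/\text{step}\rceil + 1$
iterations; `simulated_defocus_classifier()` (Gaussian class-response
curves, default width 0.8 µm chosen to satisfy exactly that band
condition) is the test double standing in for the trained network.

Lateral drift is corrected per timepoint by detecting the circular trap:
Sobel edge map, gradient-directed circular Hough voting over the radius
range into a single center accumulator, modal edge-distance radius, then
an iterated algebraic (Kåsa) least-squares circle fit on the edge pixels
within 4 px of the Hough circle, weighted by gradient magnitude. The
two-stage design exists because voting across a 40 px radius range smears
the center peak into a plateau of ±(range/2) px; the algebraic refinement
recovers the center to well under 0.1 px on rendered fixtures, and the
stage correction is simply expected minus detected center.

# The counting pipeline

Detections are one text line per box (`class cx cy w h conf`, normalized
to the 640×480 frame). The pipeline:

1. keeps detections with confidence strictly above 40%;
2. converts to physical coordinates (pixel origin top-left, configurable
   µm/px, default 0.17 — the source system never states its pixel scale,
   so it is a required config with a plausible 40×/small-sensor default);
3. deduplicates each timepoint's stack with the 3 µm exclusion sphere:
   processing detections in z-then-raster order, a detection joins the
   cluster of its nearest already-processed detection if that detection is
   within 1.5 µm (3-D Euclidean), else seeds a new cluster. This is greedy
   single linkage. A running-centroid variant was rejected: a cell visible
   through a 3 µm depth of field spans the full exclusion sphere, and the
   drifting centroid splits the chain, breaking the exact zero-noise
   count-equals-truth identity that single linkage satisfies (and single
   linkage is precisely the "two detections in different slices within
   the sphere are one cell" rule, pairwise between detections);
4. assigns species per cluster by majority vote (>50% PA detections → PA),
   with an exact 50/50 tie going to the class with higher mean confidence;
5. removes static tracks: cell points from all timepoints are clustered at
   the displacement tolerance (0.5 µm, sub-diffraction over a frame
   interval), and clusters present in ≥5 consecutive timepoints (25 min)
   are deleted — real cells drift, trap imperfections do not;
6. smooths per-species counts with a centered 8-point moving average
   (window at index $i$ covering $i-3..i+4$; truncated at the series
   edges), reporting the window standard deviation. Whether the source
   analysis smoothed with a trailing or centered window is unstated;
   centered is adopted as the less lagged choice.

# Growth and lysis kinetics

The maximum specific growth rate slides a 20-min window across the series
at native sampling and fits $\ln N$ against time by least squares in each
window with ≥3 points; windows containing zero counts are invalid rather
than floored (a specific growth rate is a log-slope, and the source
computes "specific growth rates", which settles the ln-vs-linear question
in favour of ln). The doubling time is $T_D = \ln 2 / \mathrm{SR}$;
nonpositive rates (lysis, stationary) yield `NA`. Note that the maximum
over windows of a noisy slope is upward-biased; for parameter-recovery
tests of the simulator we therefore regress the across-seed mean
trajectory, while the windowed maximum is what the platform reports for
real droplets.

One-step growth curves are summarized by two estimators. The latent
period is the first sampled time at which the PFU count exceeds twice the
baseline (the longest initial run within 20% of the first sample). An
interpolated crossing was considered and rejected: for a step curve the
interpolation collapses to the pre-step sample, whereas the first
exceeding sample reproduces the step time exactly. With a 2× rise factor
the threshold sits near the 2nd percentile of burst times, so the
estimator runs a few minutes early on jittered curves (typically 35 min
for a true 37 min latent with 3 min jitter at 5-min sampling) — a known,
documented bias of the threshold rule, not of the implementation. The
burst size is the ratio of the final to the initial plateau (maximal
end-runs with <20% relative spread; the 20% tolerance is a chosen value,
as the source does not describe its plateau criteria). Each unlysed
infected cell counts as one infective center and its progeny count
individually after lysis, so the plateau ratio estimates the mean burst
size directly.

Lysis metrics report the smoothed-count peak and the first post-peak
crossing below 5 cells ("suppressed"), matching the <5-cell phrasing used
to describe long-term suppression.

# The simulator

`load_droplet()`/`sim_step()`/`simulate_droplet()` implement a
discrete-time (τ-leap style, dt = 0.5 min) agent-based model: exact
Gillespie stepping is unnecessary because every event rate is slow
relative to dt and the observable stream is frame-sampled at 5 min
anyway; halving dt must not move recovered parameters beyond tolerance,
and a regression test enforces that.

* **Division.** Interdivision times are Gamma-distributed with CV 0.2
  (matching the droplet-to-droplet spread of measured doubling times).
  The Gamma mean is Euler–Lotka-corrected,
  $m = T_D\, k (2^{1/k} - 1)/\ln 2$ with $k = 1/\mathrm{CV}^2$, so the
  *population* doubling time equals the configured value (with
  uncorrected means, variability would make the population double faster
  than $T_D$). Default doubling times are the measured droplet averages:
  PA 33.96 min, SA 69.49 min. Daughters appear 1 µm away in a uniform
  random direction; SA daughters stay attached with probability 0.7
  (cocci form diplococci and grape-like clusters in still droplets),
  which makes the simulator reproduce the documented SA undercount, since
  attached cells sit inside one exclusion sphere.
* **Infection.** Well-mixed mass action: each susceptible healthy cell is
  infected with probability $1 - e^{-a F \mathrm{d}t}$ for free-phage
  count $F$, consuming one phage (integer bookkeeping is exact:
  free = initial + released − adsorbed at every step). The adsorption
  rate $a$ is not published; the default 0.005 min⁻¹ per phage is a
  heuristic calibration making a low-MOI (~0.6) population peak near
  50 min before declining, and is flagged as such.
* **Lysis.** Infected cells burst at the latent period (37 min default)
  plus Gaussian jitter (3 min), releasing Poisson(45) phages
  (fixed-burst mode exists for exact tests). Infected rods switch
  morphology to a rounded spheroplast-like intermediate at 70% of the
  latent period — the intermediate is observed but its timing is not, so
  0.7 is a chosen value; morphology only affects detectability (the rod
  detector tends to miss rounded cells, default extra miss probability
  0.7) and rendered shape. SA is insusceptible: with no susceptible
  cells the infection machinery consumes no randomness, so SA
  trajectories are bit-identical with and without a phage pool under the
  same seed.
* **Motion.** Reflected random walk at the configured speed (PA 0.5,
  SA 0.2 µm/s — the PA strain is a flagellar mutant, far below the
  ~15 µm/s countability ceiling), confined to the ellipsoid.

`emit_detections()` converts frames to the detection-file dialect with
the documented error modes: per-slice misses interpolating from 5% at the
droplet center to 30% within 5 µm of the boundary, 3% class flips,
Beta(8,2) confidences, and fixed-position debris sources that are always
detected. Debris is modelled as a fixed 3-D point visible through the
depth of field (not stamped on every slice): that way one debris source
deduplicates to exactly one static track per timepoint, which is the
object the static-removal rule targets.

## What the generator does and does not emulate

It emulates Poisson loading, growth-rate heterogeneity, SA aggregation,
boundary-dependent misses, misclassification, spheroplast invisibility,
debris, and MOI-dependent lysis timing. It does **not** emulate pyocyanin-
mediated interspecies inhibition, oxygen transport through the oil,
resistance evolution, biofilm mechanics, or real optics (the rendered
images are schematic fixtures). A green end-to-end test therefore
establishes that the pipeline inverts the simulator's error model at the
stated noise levels — not that it would achieve the same accuracy on real
brightfield stacks, whose detector errors are structured rather than
independent.

# Numerical and degenerate-input choices

* Confidence threshold is strict (`conf > 0.40`): "above a threshold".
* The exclusion-sphere test is inclusive (`d ≤ 1.5 µm`).
* Deduplication order (z, then y, then x) makes the greedy clustering
  deterministic and permutation-stable.
* An all-zero classification vector is an error (no-classification), not
  a score.
* Windows with zero counts, series shorter than the window, empty
  clusters, zero-bacteria MOI, and nonpositive rates all raise or flag
  rather than silently coercing.
* Seeded helpers save and restore the caller's RNG state.

# Known limitations

The ~80-cell counting ceiling and ~15 µm/s speed limit are treated as
empirical guidance, not derived limits; counting accuracy degrades above
~80 cells in simulation as exclusion spheres begin to overlap, consistent
with that guidance. The count-error regression bound (median absolute
error ≤ 2 cells under default noise) is asserted for the rod species
below the 80-cell ceiling; SA aggregation makes the cocci count a
documented underestimate, which no post hoc correction is attempted for.
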