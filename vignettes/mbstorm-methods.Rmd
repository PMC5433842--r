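---
title: "Models and methods behind mbstorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbstorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mbstorm)
```

mbstorm covers the computational chain of a molecular-beacon FISH +
astigmatic 3D-STORM experiment: probe design against a short non-repetitive
genomic target, forward simulation of the single-molecule acquisition,
per-frame localization, fiducial drift correction, nanostructure calling,
and the derived statistics. This vignette documents the models, the
defaults and why they were chosen, the numerical choices, and what the
simulations do and do not establish.

## Probe thermodynamics

Duplex stability uses unified nearest-neighbor parameters (enthalpy and
entropy per dinucleotide stack plus terminal initiation terms). The melting
temperature of a duplex at total strand concentration $C_T$ is

$$T_m = \frac{\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15
        + 16.6\,\log_{10}[\mathrm{Na}^+] - 0.65\,f$$

with $f$ the formamide percentage. The reference condition is 1 M Na⁺ and
no formamide, so the hybridizing-region Tm is the plain thermodynamic
quantity the ≥ 70 °C design rule refers to; `design_config()` exposes
`na_mM`, `formamide_pct` and `probe_nM` for buffer-specific predictions.

**Arm melting temperature.** The 50–60 °C window for the 7-nt arms is
evaluated as the arm–arm *duplex* Tm at a 50 µM reference strand
concentration (`arm_ref_uM`). Two candidate formulations were considered:
a unimolecular hairpin-closure Tm with Jacobson–Stockmayer loop entropy
places essentially every GC-rich 7-mer above 70 °C, making the published
window unsatisfiable, whereas the duplex formulation at tens of micromolar
puts roughly half of the admissible arm pool (C-start, ≥ 85 % GC) inside
[50, 60] °C — a window that selects meaningfully but is satisfiable for
most hybridizing regions. The duplex model was therefore adopted; the
concentration is a single documented constant, not a per-target tuning
knob.

**Folding.** `fold_check()` enumerates every maximal intramolecular stem
(≥ 4 bp, loop ≥ 3 nt) and scores it by nearest-neighbor stacking free
energy at 37 °C. There is no partition function: the design question is
whether the *intended* 7-bp arm stem is the unique dominant fold. A beacon
passes when no competing stem is as long as the arms or within
`fold_margin_kcal` (3 kcal/mol) of the arm-stem stability; a bare
hybridizing region passes when its strongest stem stays below
`hybrid_stem_max_kcal` (9 kcal/mol, roughly a 6-bp GC stem). Both margins
are config-exposed interpretations of the qualitative "no secondary
structure formation" rule.

**Uniqueness.** Off-target identity is the longest *exact* substring match
between the probe (either strand) and the background genome, excluding the
target interval itself, found by binary search over match length. The
published rule caps this at 22 nt (human) / 25 nt (mouse). Gapped or
mismatched near-matches are out of scope: the cap phrase "maximum identical
sequence" reads as exact identity, and exact matching is deterministic and
index-free.

**Tiling.** `tile_target()` scans left to right; at each position the +
strand is tried before the −, the first fully qualifying candidate is
accepted, and the scan jumps the hybridizing length plus `min_gap` (10 nt,
the closest approach two beacons are designed to tolerate; with two 7-nt
arms the nearest dye–quencher pair is then 24 nt ≈ 7.9 nm at 0.33 nm/nt).
The greedy order makes the design deterministic; on targets ≤ 500 nt it is
verified against an exhaustive-enumeration reference. On a *permissive*
random target the greedy tiler approaches the packing bound
(≈ 19 probes/kb); published genome-constrained designs land lower
(11.6–13.6 probes/kb) because real genomes reject windows through repeats
and off-target hits, a feature a uniform random fixture does not have.

**Binding curve.** `predict_bound_fraction()` treats the probe as a
two-state competition: hairpin closure (arm stacking plus a loop entropy
$\Delta S_{loop} = -R(3 + 1.75 \ln n)$ for the 42-nt loop) against the
probe–target duplex, solved exactly by mass action. It reproduces the
qualitative titration shape — binding rising as temperature falls through
the working range, vanishing far above both melting temperatures — and is
cross-checked against an independent root-finding solver. It is not a
kinetic model and does not predict absolute fluorescence.

## The synthetic acquisition

The generator emulates the acquisition the analysis stages were built for:

* **Blinking**: a three-state Markov chain (fluorescent / dark / bleached)
  at frame resolution. Defaults `k_off = 50/s` (mean on-time 20 ms, about
  1.7 frames at 85 Hz), `k_bleach = 1.7/s` (mean switching events per dye
  $(k_{off}+k_{bleach})/k_{bleach} \approx 30$), `k_on = 0.5/s` (dark
  recovery fast enough that the blinking budget completes inside a
  36000-frame, 85 Hz acquisition). These rates are not published; they were
  fixed once so that a fluorophore yields on the order of 10–100 switching
  events per acquisition, the stated operating range, with 3000 detected
  photons per on-frame (typical for Alexa-647).
* **PSF**: astigmatic defocus widths
  $w_{x,y}(z) = w_0\sqrt{1 + u^2 + Au^3 + Bu^4}$, $u = (z \mp \gamma)/d$,
  defaults $w_0 = 150$ nm, $\gamma = 200$ nm, $d = 400$ nm, $A = B = 0$.
  Spots are rendered as *integrated* Gaussians (pixel-edge error
  functions), not sampled center values.
* **Camera**: expected photon maps receive pixel-level Poisson noise, a
  gain of `counts_per_photon` (5), Gaussian read noise (10 counts), and a
  baseline (100 counts) on a 160 nm back-projected pixel; 16-bit clipping.
  The EM-register excess-noise cascade is deliberately omitted — threshold
  behavior, not noise-model fidelity, is what the downstream tests need.
* **Scenes**: `nanostructure` confines 29 dyes to a disc of 0.15 µm²
  (under the 0.2 µm² candidate limit) at a random in-nucleus position,
  with beads kept ≥ 1.5 µm away so the scene represents the analyzable
  case (bead-overlapping structures are the *rejection* path, exercised
  separately); `blank_control` carries only autofluorescence (2 events/µm²
  equivalent density, ~350 photons, single-frame) and beads;
  `uniform_sparse` scatters dyes at 0.5/µm². Fiducial beads (3, 20000
  photons/frame, continuously on) are placed ≥ 2.5 µm apart — closer pairs
  would annihilate each other under the 1.2 µm proximity rule. Stage drift
  defaults to a linear trace; a random-walk generator is provided. Axial
  drift is not simulated (hardware-stabilized in the imaging setup this
  emulates).

What passing these simulations does *not* show: performance under real
cellular background structure, aberrated or depth-dependent PSFs, EM
excess noise, or dye kinetics far from the assumed rates. The simulations
establish that each stage implements its stated rule and that the chain
composes correctly, not that the thresholds are optimal for any particular
microscope.

## Localization and cleaning

Frames are band-pass filtered (difference of Gaussians, σ equal to the PSF
σ in pixels and 3× that; zero-DC by construction), candidates are local
maxima above 5 robust SDs with non-maximum suppression, and each 11×11 ROI
is fit by Levenberg–Marquardt with an axis-aligned elliptical Gaussian plus
constant background. Photons are the integrated amplitude
$2\pi A \sigma_x \sigma_y$ over the gain; the "correlation index" is the
Pearson correlation between fitted model and ROI. Non-convergence yields
correlation 0 and rejection through the correlation rule — no silent
fallback.

The four cleaning thresholds run in the fixed order photons (< 300), PSF
size (fitted width > 4 px, read as an upper bound — broader spots are
out-of-focus or aggregates), correlation (< 0.95), and same-frame
proximity (< 1.2 µm, both members dropped, since overlapping PSFs corrupt
both fits). `reject_reason` records the first failing rule. The axial
window (±350 nm) applies after the ellipticity-to-z lookup, which
minimizes $(\sqrt{w_x}-\sqrt{w_x^{cal}})^2 + (\sqrt{w_y}-\sqrt{w_y^{cal}})^2$
on a 1-nm grid with parabolic refinement (the √w metric is standard
practice for astigmatic calibrations); a residual above `tol_sqrt_nm`
(2.5) marks the ellipticity as inconsistent with the calibration.

## Drift correction

Beads are near-continuously emissive, so they are auto-detected as
first-frame localizations whose nearest-neighbor *link chain* covers ≥ 90 %
of frames — following the chain rather than a fixed radius tolerates total
drifts far larger than the 500 nm link radius. Per-frame drift is the mean
bead displacement from frame 1, linearly interpolated across gaps and
smoothed by a 50-frame centered moving average (the smoothing scale is an
interpretation; no value is published). `residual_rms_nm` reports the
frame-to-frame noise of the estimate — the deviation of the unsmoothed
mean-bead trace from the smoothed one — which shrinks like
$1/\sqrt{n_{beads}}$. Correction subtracts the trace; z is untouched.

## Nanostructure identification

Clustering is DBSCAN on (x, y), implemented in-package with a grid-hashed
neighbor search (no grouping algorithm is named in the source experiment).
`cluster_localizations()` defaults to `eps = 50 nm`, `min_pts = 10`, the
right scale for separating distinct blinking emitters; the end-to-end
pipeline (`identify_nanostructures()`) links at `eps = 100 nm` instead,
because a labeled structure's localizations concentrate around discrete
dye positions whose nearest-neighbor spacing (tens to ~150 nm inside a
0.2 µm² disc) exceeds the localization precision — at 50 nm, rim dyes
split off as partial clusters and genuine structures fragment, while at
100 nm blank-field autofluorescence (far below one event/µm² per
acquisition) still cannot chain into a cluster. The six
acceptance criteria are evaluated for every cluster, all verdicts
recorded, acceptance being their conjunction (hence order-independent):

1. centroid inside the nucleus mask (polygon; "accept-all" when absent);
2. centroid > 300 nm from every bead (200 nm bead diameter plus margin);
3. not temporally concentrated — a cluster with ≥ 80 % of its
   localizations inside one contiguous 5 %-of-frames window is transient
   noise (the quantification of "short series of continual frames"; both
   fractions are config-exposed interpretations);
4. density ≥ `min_locs/max_area` = 500 locs/µm²;
5. 100–3000 localizations;
6. convex-hull area ≤ 0.2 µm² (the hull is the simplest defensible
   reading of "projected lateral dimension").

Cross-section profiles project localizations onto a line (or the z axis),
bin them (default 10 nm), and fit one or two Gaussians;
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$ and the two-component peak
separation are reported.

## Statistics

`pooled_precision()` re-centers each blinking cluster on its centroid,
pools deviations, and fits a per-axis Gaussian to a Freedman–Diaconis
histogram (sample SD reported alongside as a cross-check; degenerate
zero-spread input short-circuits to 0). `hypergeom_detection_p()` is the
one-sided tail $P(X \ge k_{pos})$ for detections assigned to cells without
replacement, in log-gamma arithmetic; with zero control detections it
reduces to $\binom{n_{pos}}{K}/\binom{N}{K}$, which reproduces both
published specificity values — this reduction is why the one-sided
convention was adopted. The condition FDR is the control-to-labeled event
density ratio (undefined, not infinite, at zero labeled density).

## Problem sizes and determinism

The packaged tests and `scripts/acceptance.R` run fields of 6 × 6 µm with
800 frames (blank controls, 20 seeds) or 1200 frames (planted
nanostructures, 20 seeds), a 53-cluster / 1378-localization precision
replica, 200 dyes × 36000 frames for the blinking calibration, and a
2.5 kb random tiling target — sizes chosen so a full run completes in
minutes on one CPU while leaving every acceptance quantity
simulation-limited rather than fit-limited. Every stochastic step is
seeded; movies are byte-identical for identical (scene, calibration,
seed), and the design pipeline is fully deterministic.

## Known limitations

Exact-match uniqueness (no gapped near-homology), stem enumeration rather
than a partition function, axis-aligned PSFs, single-emitter fitting (no
multi-emitter deconvolution), lateral-only drift correction, and
convex-hull areas that slightly overestimate sparse clusters. These mirror
the scope of the experiment the toolkit models; each is isolated behind a
documented function boundary where a richer model could be substituted.
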