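---
title: "Tracing mitotic trigger waves to their pacemakers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing mitotic trigger waves to their pacemakers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cycling *Xenopus* egg extract spread in a thin layer behaves as a spatially
extended cell-cycle oscillator. Mitosis does not begin everywhere at once:
after the first, nearly concerted division, each mitosis nucleates at
discrete loci and spreads outward as circular fronts of microtubule
depolymerization travelling at constant speed — trigger waves of the
bistable mitotic switch. The loci that fire earliest (pacemakers) entrain
their surroundings; the scientific question is which structures act as
pacemakers and how strongly they accelerate the local cell cycle.

`wavepace` implements the analysis chain that answers this from two-channel
time-lapse movies (a microtubule reporter such as SiR-tubulin, and a
nuclear reporter such as NLS-mCherry): per-pixel mitotic-entry-time maps,
expanding-region source detection, source classification by the nearest
structure, front-speed estimation from kymographs, the cycle-time advance
of each source relative to the slowest cytoplasm, and a spatial bootstrap
for source–structure proximity. Because raw experimental movies are not
required to validate the machinery, the package also contains a synthetic
movie generator with exact ground truth, and every stage is benchmarked
against it.

## The kinematic wave model

The canonical generator is kinematic: it prescribes arrival times rather
than integrating dynamics, so ground truth is exact and cheap.

Each pixel $y$ owns an autonomous schedule
$$\tau_c(y) = t_0 + \sum_{j<c}\bigl(P - a(y)\bigr) = t_0 + (c-1)\,(P - a(y)),$$
where $P$ is the bulk period (default 40 min), $t_0$ the time of the first
(concerted) mitosis, and $a(y)$ a local phase advance: zero in the bulk and
`advance_min` inside each pacemaker disk. The first cycle is concerted by
construction — advances act from cycle 2 onward — matching the observation
that the first mitosis happens almost simultaneously everywhere.

Entrained entry is the generalized distance transform
$$T_c(x) = \min_y \left[\tau_c(y) + \frac{d(x,y)}{v_\text{entry}}\right],$$
with Euclidean $d$; wells are required to be convex so in-mask geodesics
are straight lines. Because $\tau_c$ is piecewise constant, the minimum
reduces to one distance transform per advance class, which the
implementation evaluates exactly (it matches a brute-force double loop over
all pixel pairs bitwise; this is a test).

Mitotic exit is wave-borne. An exit (microtubule repolymerization) front
launches from each pacemaker $M$ minutes after the pacemaker enters mitosis
and travels at $v_\text{exit} < v_\text{entry}$:
$$E_c(x) = \min\Bigl(T_c(x) + M_\text{bulk},\;
  \min_k\bigl[T_c(s_k) + M + d(x,s_k)/v_\text{exit}\bigr]\Bigr).$$
Two durations appear deliberately. $M$ (default 10 min) is the mitosis
length at a source; $M_\text{bulk}$ (default 18 min) is the autonomous
mitosis length of cytoplasm that no exit wave reaches. If instead the cap
were $T_c(x) + M$, the cap itself would travel at $v_\text{entry}$ and a
slower exit wave could never be seen — contradicting the observed
kymographs, in which the dark mitotic wedge widens with distance from the
source precisely because exit is slower than entry. The widening is capped
at $M_\text{bulk}$; fits of the exit front are therefore restricted (by the
geometry of the simulated well) to radii where the wave beats the cap.

**Pacemaker extent.** Sources in this system are finite structures (nuclei
are tens of micrometres across), so a pacemaker is a disk of reduced period
(default radius 30 µm), not a point. The spatial extent over which a
nucleus accelerates the cycle is not known; the disk radius is an explicit
free parameter and the delta-cycle recovery is insensitive to it as long as
the disk is small compared to the entrained zone.

## Rendering

The tubulin channel sits at `I_interphase` (200) outside mitosis and
`I_mitotic` (80) inside, with logistic ramps of width 1 min at both
transitions; additive Gaussian noise (default SD 10% of the dynamic range)
is applied inside the mask. The NLS channel renders each nucleus as a
Gaussian blob (σ = 20 µm) visible during the trailing half of the local
interphase — nuclei become visible about midway through interphase and
vanish at nuclear envelope breakdown — and nucleus counts can be grown
across cycles by a stochastic lineage (division probability per cycle,
symmetric daughter displacement), giving the sub-doubling exponential
growth seen in sperm-supplemented extracts.

What the generator deliberately omits: photobleaching, stage drift, tile
seams, intensity inhomogeneity, apoptotic waves, and cell-like-compartment
boundaries. Tests passing on these movies therefore validate the
*estimators* (timing, geometry, statistics), not robustness to every
real-microscopy artefact.

## Segmentation choices

"First significant decline" is operationalized as the first downward
crossing of θ = 0.75 of the per-cycle min–max-normalised, smoothed trace,
with sub-frame linear interpolation (window 3 frames in time; Gaussian
σ = 1 px in space, replicate boundary). A fixed normalised level makes
front timing independent of local amplitude, which is what keeps kymograph
slopes unbiased. Exit is the first upward crossing of the same level after
entry.

Cycles are delimited by mitotic episodes — maximal runs of the normalised
trace below 0.5, at least 2 frames long — rather than by explicit
interphase peak finding; the window between consecutive episodes contains
the interphase maximum, so per-cycle normalisation is identical for
well-behaved traces and the run-based rule is simpler and robust to
plateaus. Pixels whose dynamic range falls below a quarter of the
well-wide 95th-percentile range are invalid (flat or empty), as are pixels
whose cycle count deviates from the well-wide mode (keeps per-cycle maps
consistently indexed). The first partial interphase before mitosis 1 is
never analysed.

The spatial pre-smoothing matters for one subtle reason: a region's onset
is the *minimum* entry time over its first-frame pixels, and the minimum of
many noisy estimates is biased early. Smoothing shrinks the per-pixel
timing jitter and with it this bias (to ≈ 0.2–0.4 min at 10% noise, which
is well inside one acquisition frame).

## Source detection

Candidate mitotic regions are connected components of
$\{x : T_c(x) \le t\}$ tracked over frame times. A region is retained only
if it *expands*: its area must strictly increase over its first
`n_expand = 3` assessable steps with at least 20% total growth. A step is
assessable only while the apparent boundary speed (growth of the
equivalent-circle radius per frame) stays below 300 µm/min: a genuine
trigger wave advances at tens of µm/min, whereas concerted (phase-wave)
entry of the surrounding bulk makes a region's area jump essentially
instantaneously. Truncating at that jump lets weak sources that expand for
only a frame or two still be assessed, while microtubule-depleted areas
that never expand, and the salt-and-pepper regions created by timing noise
at concerted bulk entry, are all rejected. When the first occupied frame
already covers ≥ 90% of the well, the cycle is flagged "concerted" and no
localised sources are reported (the first-mitosis phenotype).

The source is the first-frame centroid, with onset the earliest entry time
in the region. First frames with solidity < 0.8 and two distance-transform
maxima are dumbbells — mitosis that initiated nearly simultaneously from
two adjacent structures — and are split by watershed into two simultaneous
sources placed at the distance-transform maxima of the two largest basins
(the inscribed-circle centres, i.e. the lobe centres).

Classification uses the fixed precedence nucleus > centrosome > edge >
other at a 100 µm proximity radius (and a 100 µm edge band, mirroring the
radius; both configurable). Nuclei are matched within the cycle in which
the source fires; all three distances are stored regardless of the class,
so the taxonomy can be re-cut.

## Delta-cycle times

The benchmark is the latest 15% of valid pixels to enter mitosis in the
focal cycle (ties at the cutoff included). For each source,
`duration_source` = onset in cycle *c* minus the entry time at the source
position in cycle *c − 1*; `duration_benchmark` is the mean entry-to-entry
interval over the benchmark mask; and
`delta_cycle = duration_benchmark − duration_source`, so **positive values
mean the source cycles faster**. The percent form divides by the benchmark
duration. The sign convention is stated once and used everywhere,
including for edge sources (reported elsewhere with the opposite sign in
some figures of the source literature); a negative delta simply means the
locus cycled slower than the slowest 15%.

## Kymographs and front speeds

Linear kymographs average intensity across a short slice width per
position bin; radial kymographs average over mask-clipped annuli (13 µm
bins, two pixels at the 5× objective scale) and re-origin time at the
source onset. Front times per bin are θ-crossings of the bin-normalised
trace (downward for entry, upward-after-entry for exit), and the speed is
the least-squares slope of distance on time. The fit window starts beyond
the source footprint (the pacemaker disk enters simultaneously, so its
bins carry no slope information) and stops where the front stalls — a
per-bin time increment below 0.04 min marks a wave collision or concerted
bulk entry. Fits with R² < 0.9, non-positive slope, or fewer than 3 front
points are flagged or refused.

Event-averaged kymographs (align each event at its onset, resample to the
coarsest common grid, average pointwise) carry one caveat that the package
quantifies in its tests: the θ-crossing of a pointwise *average* of
logistic fronts sits at a quantile of the event arrival-time distribution,
so the fitted speed of an averaged kymograph exceeds the mean of per-event
fits by an amount that grows with the speed spread (≈ +8% at CV 0.25,
negligible at CV 0.10). Ensemble speed summaries in this package therefore
average per-event fits rather than fitting the averaged image.

## Bootstrap proximity test

Observed = number of sources within 100 µm of any reference structure.
The null randomises source positions uniformly over the valid mask pixels
(not the bounding box — uniform-over-well is the only physical choice) and
p = (# iterations with at least the observed count) / 10⁵, reproducible
under a seed. When no null iteration reaches the count, the raw 0 is
reported alongside the label "< 1/n_iter". Against the closed-form null
(sources independently uniform, coverage fraction *f*), the p-value matches
the binomial tail P(Bin(n, f) ≥ k) within Monte-Carlo error; this is an
acceptance test.

## Reaction–diffusion validation model

The kinematic generator imposes waves; a FitzHugh–Nagumo-type relaxation
oscillator with diffusion of the fast activator provides waves that
*emerge*:
$$u_t = k\,(u - u^3/3 - w) + D\,\nabla^2 u, \qquad
  w_t = \varepsilon(x)\,(u + a - b\,w),$$
with $a = 0$, $b = 0.8$ placing the fixed point on the middle branch
(oscillatory); the bulk period scales as $1/\varepsilon$ and a pacemaker is
a disk of increased $\varepsilon$. Explicit Euler with a 5-point Laplacian
and zero-flux boundaries; the step is rejected unless
$\Delta t \le h^2/(4D)$. Properties verified numerically: zero diffusion
keeps a homogeneous field perfectly in phase; a pacemaker launches fronts
whose radius grows linearly (R² > 0.99 after the first cycle); and in the
frozen-recovery limit ($\varepsilon = 0$, a seeded excited disk) the pure
bistable front speed scales as $\sqrt{D}$ within a few percent, with
instantaneous-speed CV below 5% — the classical benchmarks for such an
integrator. Front speeds in the oscillating regime drift toward the
asymptotic trigger-wave speed over the first cycles (early waves get a
phase-gradient assist), which is why the scaling test uses the frozen
limit.

## Default calibration and problem sizes

Defaults mirror the imaging regime of the motivating experiments: 5×
objective class (6.5 µm/px; delta-cycle ensembles use 13 µm/px, the same
optics binned 2×), acquisition every 0.5–2 min, bulk period 40 min,
source mitosis 10 min, entry/exit speeds 60/40 µm/min. Weak edge sources
(advances of a few minutes) expand for only `advance/Δt` frames, so edge
ensembles are simulated at the fast end of the acquisition range
(0.5 min/frame); even so, a source must lead the bulk by roughly two
frames to be detectable at all, which slightly biases the mean recovered
advance of a *truncated-at-zero* advance distribution upward — an
unavoidable selection effect that the package reports rather than hides.

Simulated wells are 1.6–3.2 mm squares; speed ensembles use 33
single-pacemaker events and delta-cycle ensembles 15 wells with 2–4
pacemakers each. These sizes put every estimator comfortably in its
asymptotic regime while keeping a full verification run in minutes on one
CPU.

## Degenerate inputs and numerical conventions

Pixel indices are 0-based conceptually, with physical coordinates in µm
from the top-left corner (pixel (i, j) centred at ((j−½)s, (i−½)s)); all
times are minutes from movie start; all distances µm. Calibration is never
guessed: reading a movie without it is an error. Empty masks, flat traces,
all-undefined entry maps, empty kymograph lists, benchmark masks without
valid pixels, pacemakers outside the mask, advances exceeding the period,
exit speeds above entry speeds, non-convex masks (for the kinematic
generator) and unstable PDE steps are all rejected with explicit messages.
Ties are inclusive (benchmark cutoff, best-source cutoff); quantiles use
the default type-7 rule.

## Known limitations

* The generator is two-dimensional and noise is white; real movies carry
  drift, bleaching and structured background.
* Source identity is not tracked across cycles (sources that divide with
  their nuclei appear as new sources each cycle).
* Only the dumbbell exception to "source = first-frame centroid" is
  implemented.
* Curvature-dependent wave-speed corrections are not applied; speeds are
  measured where fronts are locally planar on the bin scale.
* The classification taxonomy is total by forced precedence; a source that
  is both near a nucleus and near the edge counts as nuclear.
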