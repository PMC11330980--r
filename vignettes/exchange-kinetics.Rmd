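---
title: "Modeling and measuring cytosol–aggregate exchange in neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring cytosol–aggregate exchange in neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aggflux)
```

# The problem

Neurons expressing an aggregation-prone protein — the motivating case is a
polyglutamine-expanded huntingtin exon-1 fragment fused to a fluorescent or
HaloTag reporter — gradually deposit that protein into micron-scale puncta,
most of them in axons. Time-lapse confocal imaging over weeks shows
cytosolic fluorescence rising, aggregates appearing at a roughly constant
rate, and cytosolic levels then declining as the aggregates sequester the
soluble pool. Pulse-chase labeling shows that individual aggregates keep
gaining newly synthesized protein and losing old copies, and fluorescence
recovery after photobleaching (FRAP) puts a time constant of about 9 hours
on that exchange: the aggregates behave as concentrated sinks near
equilibrium with the cytosol, not as inert deposits. Blocking two
N-terminal ubiquitination sites (the K6,9R substitution) inverts the
picture: few aggregates, many of them nuclear, no measurable exchange, and
sustained high cytosolic levels.

`aggflux` turns that qualitative account into an explicit, testable
pipeline: a kinetic model of the cytosol–aggregate exchange with full
pulse-chase label bookkeeping, a synthetic microscope that renders model
trajectories into realistic multi-channel z-stack movies with ground truth,
and the analysis chain (projection, punctum detection, tracking, ROI
quantification, compartment assignment, FRAP and pulse-chase fitting) that
recovers the model's parameters from those movies.

# The kinetic model

One well-mixed cytosolic pool and a set of point aggregates. Protein mass
carries a label state $x \in \{\mathrm{L1}, \mathrm{blocked}, \mathrm{L2},
\mathrm{dark}, \mathrm{bleached}\}$. With $c_x$ the cytosolic concentration
of label $x$ and $a_{i,x}$ the amount bound in aggregate $i$:

$$
\frac{dc_x}{dt} = s\,[x = x_\mathrm{syn}] - k_\mathrm{deg} c_x
  - \frac{1}{V}\Big(n_b k_\mathrm{on} c_x - k_\mathrm{off} \sum_i a_{i,x}\Big),
\qquad
\frac{da_{i,x}}{dt} = k_\mathrm{on} c_x\,[x \ \mathrm{bindable}] - k_\mathrm{off} a_{i,x}.
$$

New aggregates appear as an inhomogeneous Poisson process with rate
$V k_\mathrm{nuc} \max(0, c_\mathrm{tot} - c_\mathrm{nuc})$ and are placed
into a compartment (axon / dendrite / soma / nucleus) by a preset
probability vector. $V$ is the simulated volume fraction relative to a full
640×480 field of view: downscaled fields scale nucleation with $V$ and the
per-aggregate drain with $1/V$, so concentrations and per-aggregate
contents are scale-invariant in expectation.

This is deliberately the *minimal* model consistent with the observations
it formalizes — first-order synthesis, degradation, association,
dissociation, and threshold nucleation. No spatial gradients, no
oligomer-size distribution, no fragmentation or secondary nucleation (the
near-linear aggregate appearance argues against the latter two; exponential
growth of counts would be their signature).

## Parameters and the packaged presets

| parameter | units | WT | KR | role |
|---|---|---|---|---|
| `s` | a.u. h⁻¹ | 1 | 1 | synthesis (sets the intensity scale) |
| `k_deg` | h⁻¹ | 0.003 | 0.003 | cytosolic degradation |
| `k_nuc` | events h⁻¹ per a.u. | 0.012 | 4.5e-4 | nucleation propensity |
| `c_nuc` | a.u. | 110 | 110 | nucleation threshold |
| `k_on` | h⁻¹ | 0.0036 | 0.001 | per-aggregate association |
| `k_off` | h⁻¹ | 1/9 | 0 | per-aggregate dissociation |
| `placement` | — | axon-dominated (0.83) | nucleus-heavy (0.5) | compartment of new aggregates |

The WT dissociation rate is fixed first: the FRAP recovery of a fully
bleached aggregate under a constant ambient pool is
$f(t) = f_\infty(1 - e^{-k_\mathrm{off} t})$, so the reported ≈9 h time
constant pins $k_\mathrm{off} = 1/9\ \mathrm{h^{-1}}$ exactly. The
remaining WT rates were calibrated jointly (deterministic-expectation
simulation plus grid search) against three observables at full-FOV scale:
per-FOV counts of ~30 at experiment day 6 and ~45 at day 12, an old-label
pulse-chase peak near 30 h, and a cytosolic trace that rises for days
before nucleation onset and then declines. The KR preset sets
$k_\mathrm{off}=0$ (permanent deposits), excludes the post-block label L2
from binding, nucleates ~25× more slowly (~5 aggregates per FOV at day 6,
calibrated against the stochastic mean because the strong
nucleation–cytosol feedback makes the stochastic mean exceed the
deterministic expectation at these low rates), and places about half of
its aggregates in nuclei.

Two caveats are worth stating plainly. First, `k_on` and `c_nuc` are not
separately identifiable from these observables — only composite quantities
are constrained — so the preset values are one documented choice along a
degeneracy. Second, the symmetric linear exchange model cannot reproduce
the *depth* of the late cytosolic decline seen in real data: whenever
nucleation is ongoing, the feedback pins the cytosolic concentration just
above $c_\mathrm{nuc}$ (each freshly nucleated aggregate transiently
consumes the entire synthesis flux), and the true fixed point with
$k_\mathrm{off} > 0$ is $c^* = s/k_\mathrm{deg}$ with zero net aggregate
flux. The calibrated trajectory therefore rises, peaks near nucleation
onset, and declines only mildly toward the pinned level. A deep sustained
decline would need an ingredient this model excludes by design, e.g.
degradation of aggregate-bound protein or size-dependent uptake.

## Label bookkeeping

Labeling events are instantaneous conversions plus a change of the
synthesis destination: a fluorescent ligand converts the ligand-free
(`dark`) pool — cytosolic *and* aggregate-bound — to its label and captures
subsequent synthesis while it stays in the bath; the non-fluorescent
blocker converts `dark` to `blocked` and, because it also saturates protein
made while it is present, routes synthesis to `blocked` until the next
label event. This last choice matters: it keeps the bound second-label
content of non-exchanging (KR-like) aggregates *exactly* zero, which is the
defining observation for that construct. Photobleaching moves the
fluorescent bound content of selected aggregates to a `bleached` state —
fluorescence is destroyed, mass stays in place and keeps exchanging.

Every labeled pool is explicit, so mass conservation is testable: with
synthesis and degradation off, total mass is conserved to integrator
tolerance through any event schedule.

## Numerical scheme

Fixed-step classical Runge–Kutta (RK4) with substeps of at most 0.05 h;
the system is linear between nucleation events and far from stiff at these
rates, so a fixed explicit scheme is accurate and — important here —
deterministic for a given seed. Nucleation is realised by thinning between
substeps (the rate is frozen over one substep); a deterministic mode
replaces the Poisson draw by integer crossings of the cumulative expected
count, which is what the calibration and the deterministic pulse-chase
readout use. Negative amounts beyond float round-off abort integration
rather than being clipped.

# The synthetic microscope

`make_geometry()` lays out somata with concentric nuclei, grows dendrites
and one axon per neuron as persistent random walks, and adds background
axons entering from the field boundary — the axonal segments of unseen
neurons that dominate real fields. `render_series()` turns a kinetic
trajectory into a T×C×Z×Y×X series: aggregates are 3-D Gaussian puncta
(σ_xy = 1.3 px, σ_z = 1 plane) whose integrated intensity is proportional
to fluorescent bound amount, moving along their host skeleton as a
reflected random walk; the cytosol fills the morphology as a weight map
proportional to the fluorescent cytosolic amount; the morphology channel is
constant over time. Signal then receives Poisson shot noise, Gaussian read
noise (sd 1.5 counts), and 12-bit clipping/quantization. Axons render at
10% of dendrite weight in the morphology channel — faint enough to
reproduce the visibility problem that makes compartment assignment hard —
and at partial volume (0.35) in the reporter channel. Neurites taper
toward tips that end inside the field: an untapered rasterized end cap is a
punctum-sized blob that any spot detector would (wrongly, and persistently)
flag. Nucleation placement keeps a minimum spacing between aggregates
(6–8 px): nucleation sites deplete local monomer, and the study counts
*distinct visible* aggregates.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: a realistic point-spread function beyond
the Gaussian, focal drift and stage jitter, photobleaching of the
morphology marker, autofluorescence texture, cell death and debris,
heterogeneous expression between neurons, and compartment switching of
moving aggregates. Detector performance on real acquisitions must be
validated against real annotations.

Per-frame noise draws use a seed derived from the run seed and the frame
index, so a lazily rendered series (frames produced on demand, constant
memory — how the long simulations are processed) is bit-identical to the
eagerly materialized one.

# The analysis chain

Detection operates on maximal-intensity projections, per the source
acquisitions: difference-of-Gaussians at the punctum scale, candidate
maxima above `median + k·MAD` of the filtered image (k = 100 by default —
the MAD of a band-passed max projection reflects dark-background noise,
while clutter on cytosol-filled structures sits an order of magnitude
higher), a local raw-background criterion (peak ≥ local median + 8 local
MADs in a 15×15 window), a blobness criterion (ratio of band-pass Hessian
eigenvalues ≥ 0.35, which rejects ridge responses along neurites and their
crossings), minimum response area, minimum separation, a 3-px border
margin, and parabolic sub-pixel refinement. All parameters are explicit
configuration with these defaults; the contract is the ground-truth suite
(precision and recall ≥ 0.95, track identity ≥ 0.9 at default motion).

Linking is greedy on ascending frame-pair displacement (ties by lowest
track id — deterministic), gated at 15 px/frame, with gap closing over up
to 2 missed frames, merge-event bookkeeping, and a minimum track length of
2 detections. Greedy equals the optimal assignment on well-separated
instances, which a brute-force permutation oracle checks in the tests.

Compartment assignment uses every frame of a track, forward and backward:
nucleus if inside the nucleus mask with the best-focus plane within ±2
planes of the soma's plane (projection overlap alone must not make nuclear
calls), else soma by the same rule, else the nearest axon/dendrite skeleton
within 3 px whose local morphology (3×3 mean at one nearest point per
candidate skeleton — single noisy pixels must not decide visibility)
exceeds `median + 2·MAD` of the morphology projection. The majority
structure must support ≥ 60% of *all* frames, otherwise the track is
`unresolved`; a transient dendrite approach therefore never becomes a
dendrite call, and with axons invisible, axonal aggregates become
unresolved rather than mislabeled.

FRAP fitting profiles the residual sum of squares of
$F(t) = F_\infty - (F_\infty - F_0)e^{-(t-t_b)/\tau}$ over $\tau$ (the
model is linear in the other two parameters), refines by golden-section
search, and polishes with Levenberg–Marquardt. A flat trace, or a $\tau$
at the profile boundary, is reported `converged = FALSE` with a zero or
undefined mobile fraction — never an exception. Pulse-chase summaries
smooth with a 3-frame moving average, take the old-label argmax, fit a
log-linear post-peak decay, and call a new-label rise only if the final
smoothed value exceeds both the pre-addition background
(median + 3·MAD) and 10% of the old-label peak; the relative floor keeps
diffuse cytosolic new label crossing the ROI (on the pipeline side,
aggregate ROIs are annulus-background-subtracted punctum photometry) from
masquerading as exchange.

## The deterministic pulse-chase readout

The packaged deterministic pulse-chase reports the old-label trace of a
*reference aggregate introduced at the first-label time*. Under this model
an aggregate relaxes to its quasi-static content with time constant
$1/k_\mathrm{off} = 9$ h, so aggregates that existed long before labeling
peak within hours; a ~30 h mean rise is only attainable by aggregates that
appeared near the labeling time — consistent with the source analysis,
which aligned tracked aggregates to their moment of appearance. The
reference-aggregate trace peaks at 30 h under the WT preset.

# Problem sizes

The test suite and the acceptance script run everything at reduced scale,
chosen to keep each stage's statistics meaningful: quarter-area fields
(240×320 px, 12 z-planes) for all rendered analyses; 12 localization
fields totalling ~384 aggregates for the axonal-fraction recovery —
localization scenes allocate compartments by expectation-exact quota
rather than i.i.d. draws, emulating a sample *with* the preset's
composition (the reported fraction of a fixed sample), so the recovery
measures classification fidelity rather than placement sampling noise;
8 fields per preset for the long-term count
recovery, scaled to full-FOV equivalents by the area ratio; 35 traces for
the FRAP median; deterministic single runs where the quantity is
deterministic. Counts recovered from rendered images run ~5–15% below
ground truth (newborn aggregates sit below the detection floor for their
first ~2 h, and converged pairs merge optically), which is the same
censoring a human scorer of "visible aggregates" applies — the presets are
therefore calibrated so the *measured* counts, not the latent truth, match
the target levels.

# Known limitations

* The exchange model's reachable set does not include a deep late
  cytosolic decline concurrent with ongoing nucleation (see above); the
  packaged calibration favors the count and turnover observables.
* KR old-label content never decreases (with $k_\mathrm{off}=0$ nothing
  leaves an aggregate); the variable decline seen in real KR aggregates
  (photobleaching, in-place degradation) is not modeled.
* The detector's defaults are calibrated for the default optics; changing
  gains or noise substantially means revalidating against the ground-truth
  suite.
* Compartment assignment relies on geometry supplied as masks and
  skeletons; segmenting real immunofluorescence is out of scope.
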