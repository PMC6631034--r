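---
title: "Scoring the multi-well optomotor response: models, geometry and statistics"
author: "omrplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the multi-well optomotor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omrplate)
```

## The assay

Zebrafish larvae have an innate optomotor response (OMR): shown whole-field
motion such as moving stripes, sighted larvae turn and swim with the
perceived motion. The plate-based version of the assay places one larva per
well of a 48-well plate on a tablet screen that plays a three-segment
animation: 5 s of solid white (to record initial positions), 30 s of black
and white bars moving right-to-left, and a final 5 s of white (to record
final positions). Visually responsive larvae accumulate on the side of the
well the stripes move towards; blind or visually impaired larvae do not.
An accompanying startle assay counts motion bursts after five abrupt light
interruptions that follow a 30-minute baseline in constant light.

`omrplate` implements the entire assay in software: the stimulus, the
scoring geometry, a behavioural simulator that stands in for the animals, a
synthetic plate-image renderer with an automated reader, the statistical
battery, and the startle counter. Everything downstream of the simulator
treats its output exactly as it would treat observations of real larvae.

## Scoring geometry

Each circular well is split into four areas by three chords perpendicular
to the motion axis. Fractions are of **well area**, not diameter: Area 1
(least aligned) is the half of the well away from the motion direction,
Areas 2 and 3 are 20% bands, and Area 4 (most aligned) is the far 10%.
The area-fraction reading is the one consistent with randomly placed
larvae: uniform positions over the disk then give the observed baseline
occupancy of roughly 50/20/20/10% in Areas 1/2/3/4, which is exactly what
`initCohort()` reproduces.

The chord at cumulative fraction $f$ solves
$$\frac{A(x)}{\pi} = f, \qquad A(x) = x\sqrt{1 - x^2} + \arcsin x + \frac{\pi}{2}$$
for the unit disk; `computeAreaPartition()` finds the roots with
safeguarded bisection to a tolerance of $10^{-13}$ in $x$, giving chords at
$x/R = -0.6870, -0.3197, 0$ for the default fractions:

```{r chords}
geom <- computeAreaPartition()
chordXs(geom)
```

The area label doubles as the position score; the post-stimulus change
score is final minus initial position, an integer in $-3..+3$:
positive = improved alignment. Points landing exactly on a chord are
assigned to the more-aligned side — a deterministic, measure-zero
tie-break. Area ordering runs 1 to 4 *along* the motion direction so that
improvement is monotone movement with the stripes.

Scoring uses the larva's **head** point throughout. Where a real scorer
might hesitate between head tip and eye midpoint for a larva straddling a
chord, the renderer defines the head point explicitly, so synthetic ground
truth is unambiguous; this convention is stated here once and used by
every module.

## The stimulus

`StimulusSpec` defaults: 5 s white / 30 s grating / 5 s white, 30 fps,
60 px bars moving at 120 px/s right-to-left. Bar width and speed are not
dictated by the assay itself, so they are configuration; the defaults put
8 bar pairs across a 960 px canvas (at least 6 bars span a 48-well plate
footprint). The luminance profile is a square wave whose transitions are
softened over 60 degrees of spatial phase using a clipped sine,
$L(\theta) = \mathrm{clip}(\sin\theta / \sin 30^\circ, -1, 1)/2 + 1/2$.
The "60-degree" figure could also be read as a spatial phase offset or a
bar orientation; we implement the edge-softness reading (with a pure
square-wave fallback) because it is the only one that changes what the
fish actually sees at a fixed viewing geometry. Pixels are sampled at
column centres ($x = j - 0.5$), which keeps the mean of one full spatial
period at exactly 50% gray and makes consecutive frames exact shifted
copies when the per-frame displacement is a whole number of pixels. The
phase function `phaseAt()` exposes motion as a closed form
($d\phi/dt = -2\pi\,\mathrm{speed}/(2\,\mathrm{barWidth})$ during the
grating) so tests can verify motion without pixel differencing.

## The behavioural simulator

The simulator is deliberately minimal: the assay reads out *position*, so
alignment is modelled as positional drift, not as a turning-rate model.

* Each larva is a **responder** with probability `pAlign`, drawn once per
  larva per trial — matching the dichotomous responsive/non-responsive
  populations the assay is designed to separate, rather than a per-step
  coin flip that would average everyone to the same behaviour.
* Responders drift towards the motion direction at `driftGain` well-radii
  per second while the grating is on; all larvae diffuse with isotropic
  Gaussian noise of `noiseSd` radii per root-second; positions reflect at
  the wall.
* `runTrial()` snapshots the cohort on a timeline (default every 15 s to
  60 s) and scores records between 0 s and `finalTime` (default 30 s, the
  assay's standard exposure).

Defaults (`pAlign = 0.7`, `driftGain = 0.06` R/s, `noiseSd = 0.15`
R/$\sqrt{s}$) were chosen once so that a control cohort finishes with
roughly three quarters of larvae in Areas 3+4 after 30 s — the qualitative
signature of sighted cohorts — while a `pAlign = 0` cohort stays uniform.
The presets `mbl` (0), `rbm24a` (0.15) and `crim1` (0.55) differ only in
`pAlign`: the phenotypes they mimic are visual, not motor. No attempt is
made to match real larval kinematics (burst-and-glide swimming, speed
distributions, wall-following); consequently, passing tests demonstrate
the correctness of the scoring, statistics and imaging machinery on
plausible positional data, not fidelity to real swimming behaviour.

The reflected diffusion is reversible with respect to the uniform
distribution on the disk, and initial positions are uniform, so for a
non-responsive cohort the (initial, final) pair is exchangeable — the
symmetry null holds *exactly* regardless of how long the cohort mixes.
This is what makes the simulator a proper null generator for calibrating
the symmetry test.

`estimateResponsiveness()` inverts the model by the method of moments: the
excess of final Areas 3+4 occupancy over the 30% uniform baseline, divided
by the same excess for a fully responsive reference cohort simulated under
the same dynamics, clipped to [0, 1]. With $n = 2000$ the estimate is
within $\pm 0.04$ of truth across the whole range in our property tests.

## Synthetic plates and the automated reader

`renderPlate()` draws well rims and larvae (grey elongated body, darker
head blob at the stored head position) with soft ~1 px edges, so intensity
centroids localise to sub-pixel accuracy. Image coordinates: origin
top-left, x rightward, y downward, pixel $(i, j)$ centred at
$(j - 0.5,\, i - 0.5)$. Positions are mapped into a *reachable disk* of
radius `wellRadius - wallClearance` (3.5 px by default), modelling the
fact that a head cannot overlap the wall; `scoreFrames()` applies the same
convention when mapping detected heads to areas, so the two stay
consistent by construction.

Detection works only on the solid-white lead-in and tail frames — the
moving grating defeats naive dark-blob tracking, which is precisely why
the animation brackets the grating with white segments. `detectWells()`
thresholds the dark rims, keeps hollow ring-shaped components and refines
each centre with an algebraic (Kasa) circle fit; with a layout hint it
registers the grid by a robust median translation and reports any
unmatched well in a structured error. `detectLarva()` takes the largest
dark component inside the well, orients it by its intensity-weighted
principal axis, calls the darker end the head, and localises the head as
the darkness-weighted centroid of the darkest pixel cluster. The renderer
guarantees the head is the darkest part of the larva, so head-calling is
well-posed on synthetic frames; real-video nuisances (glare, meniscus
shadows, multiple larvae) are explicitly out of scope. On rendered plates
the round trip simulate → render → detect → score reproduces the
simulator's area labels exactly in our tests (the acceptance check
requires ≥ 95% agreement).

## The statistical battery

All four tests are implemented in the package and cross-checked against
independent oracles (enumeration, permutation, simulation) and base-R
equivalents in the test suite.

* **Bowker's test of symmetry** on the 4×4 initial→final transition
  table: $T = \sum_{i<j} (n_{ij} - n_{ji})^2 / (n_{ij} + n_{ji})$ over
  informative pairs ($n_{ij} + n_{ji} > 0$), one df per informative pair
  — skipping empty pairs avoids 0/0 terms on plate-sized cohorts. On 2×2
  it reduces to McNemar's test. An **exact conditional** variant
  enumerates the null distribution (each discordant pair is
  Binomial$(m, 1/2)$ under symmetry) by convolution. The chi-square
  approximation is noticeably conservative at plate size: under the
  simulated null at $n = 48$ it rejects at ~2–3% for nominal 5%, while
  the exact variant holds 4–5%. The exact variant is therefore the
  recommended (and test-calibrated) choice for single-plate cohorts; the
  chi-square form is fine from a few hundred larvae.
* **Two-sided exact binomial improvement test**: larvae with no change
  are excluded by design; improved vs decreased is Binomial$(n, 1/2)$
  under the null. Two-sidedness follows the minimum-likelihood convention
  (sum of all outcomes no more probable than the observed one), the same
  convention as `binom.test`; tail-doubling is available as an option.
  Being exact and discrete, its realised size at plate-sized $n$ sits
  below the nominal 5% (about 2.5% in our null calibration) — that is a
  property of any exact binomial test at small $n$, not an implementation
  artefact.
* **Wilcoxon–Mann–Whitney** with midranks: the exact two-sided
  permutation p-value is computed by full enumeration whenever
  $\binom{n_a+n_b}{n_a}$ is affordable (ties included — area scores are
  heavily tied, and the enumeration handles them naturally); otherwise
  the normal approximation with tie correction and continuity correction,
  which matches a $10^5$-draw permutation oracle to within 0.01 on tied
  area scores.
* **One-way ANOVA** for startle counts across groups, with guarded
  degenerate paths (all-equal constants flagged rather than divided by
  zero).

No multiple-testing correction is applied across time points by default —
the standard analysis reports unadjusted p-values — but a Bonferroni
option exists in `analyzeTrial()`.

## The startle (VIZN-style) counter

An activity trace is per-second motion over a 30-minute constant-light
baseline followed by five light interruptions (default: 30 s apart
starting 30 s after the baseline, for a ~33-minute assay; the exact
spacing within the testing window is configurable since only "regularly
spaced" is specified). A response to interruption $i$ is a motion maximum
within 5 s after it exceeding baseline mean + 3 baseline SDs; both the
multiplier and the window are exposed because the underlying detection
rule is our concretisation of the assay's counting step. A zero-variance
baseline falls back to mean + $\varepsilon$ with a flag. The trace
simulator adds exponentially decaying bursts (height `spikeGain` baseline
SDs) for responders; at defaults, responder cohorts score 5/5 and
non-responder cohorts below 1/5, reproducing the qualitative
sighted-vs-eyeless separation.

## Numerical choices and degenerate inputs

* Chord root-finding: `uniroot` on $[-1, 1]$, tolerance $10^{-13}$; the
  half-disk chord is snapped to exactly 0 when within $10^{-9}$.
* Chord tie-break: boundary points to the higher (more aligned) area.
* Boundary reflection: radial, repeated up to 8 times, with a clamp to
  just inside the rim for pathological overshoots (steps longer than the
  diameter).
* Empty transition tables (nobody moved): Bowker returns $p = 1$, df 0,
  with a `no_movement` flag. Zero movers: binomial test returns $p = 1$
  with a `degenerate` flag. Identical constant groups: Mann–Whitney and
  ANOVA return $p = 1$ with `no_variance` flags.
* Connected-component labelling is 8-connective (diagonally touching
  pixels merge), which thin rings and oblique larva bodies require.
* Wells with a failed detection are emitted with `missing = TRUE`, never
  dropped; larvae touching the wall are kept with lowered confidence.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to give
tight Monte Carlo error while staying quick on a laptop: $10^5$ points for
occupancy checks (3-SE binomial tolerance), 2000 cohorts of 48 for the
type-I calibration of the symmetry test, $n = 2000$ per point for the
responsiveness-recovery grid, one full 48-well plate for the end-to-end
imaging round trip, and $n = 10^4$ for the null median change score.

## Limitations

The simulator is a positional null/alternative generator, not a kinematic
model of larval swimming; the renderer produces idealised frames (uniform
background, no glare or meniscus effects, exactly one larva per well); and
the startle counter implements one reasonable detection rule rather than
reverse-engineering any particular tracking box. Results on real videos
would additionally depend on illumination, optics and larva pigmentation,
none of which are modelled here.
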