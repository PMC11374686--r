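---
title: "Methods and design choices in batmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in batmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`batmap` analyzes hippocampal recordings from bats that rest in the upper
corners of a flight room, fly to tripods occupied by two human
experimenters, and observe the humans walking arced traverse paths. This
vignette explains the statistical machinery, the parameters that matter,
what the synthetic-session generator does and does not emulate, and the
design decisions taken where the methodology left genuine freedom.

## The measurement model

Every analysis reduces to the same template: restrict behavior and spikes
to a set of *included epochs*, bin the relevant position variable (the
bat's own xy position, its arc-length position along a flight trajectory,
the conspecific's trajectory position, or a human's xy position), form an
occupancy-normalized firing-rate map, summarize it with a statistic, and
calibrate that statistic against a null that destroys the alignment
between spikes and behavior while preserving everything else.

**Rate maps.** 2D maps use 0.15 m square bins anchored at the room origin.
Both the spike-count map and the occupancy map are smoothed with a Gaussian
kernel (sigma = 1.5 bins, truncated at 3 sigma) and the rate is their
bin-by-bin ratio. The smoothing is *masked*: invalid bins neither receive
nor contribute weight, and kernel weights renormalize over the valid
support, so occupancy never bleeds into unvisited space. Bins occupied less
than the cutoff (150 ms in bat frames, 1 s in the data-sparse human frames)
are invalidated unless at least one 8-neighbor is valid. 1D maps bin the
cumulative distance from take-off, after rescaling each flight to its
cluster's mean path length so that the same path flown at different speeds
bins identically; both 1D maps are smoothed with a 7-tap Gaussian window.
The window's sigma is not fixed by the width alone; we use sigma = 1 bin,
configurable (`smoothSigma1D`).

**Spatial information.** The per-spike information of a map is
SI = sum_i (p_i lambda_i / lambda) log2(lambda_i / lambda), summed over
valid bins, where p_i is the smoothed occupancy normalized over valid bins,
lambda_i the smoothed rate, and lambda = sum_i p_i lambda_i. Using the
smoothed occupancy for p_i keeps the identity sum_i p_i lambda_i = lambda
exact, so SI is non-negative (Jensen) and invariant to rate rescaling.
Bins with lambda_i = 0 contribute 0 (the x log x limit); a map with
lambda = 0 is not analyzable.

**Circular-shift null.** The included epochs are concatenated into a
gap-free timeline; all spikes inside them are shifted circularly by a
uniform random offset and the map and SI recomputed, 1,000 times. The shift
preserves the spike train's internal structure and total count and destroys
only its alignment with behavior. A minimum offset of 1 s prevents
near-identity shifts (the method statement is silent; without a floor the
null would include shuffles nearly identical to the data). The empirical
value is called significant when it exceeds the 95th percentile of its null
— our reading of "upper 95% confidence interval of the shuffled
distribution"; a normal-theory bound (mean + 1.96 sd) is available via
`nullUpper = "normal"`. p-values use the (1 + k)/(1 + n) convention so they
are never zero. Bonferroni correction uses the number of analyzable targets
in the family (trajectories for 1D frames, humans for the identity frame).

**Permutation tests.** Identity and conspecific-presence modulation compare
the absolute difference of mean peri-event window rates (2-s windows:
take-off −1.75 to +0.25 s, landing −0.25 to +1.75 s, half-open) against a
label-shuffle null. When the number of distinct label assignments C(n, n1)
is enumerable (≤ 1e5) the null is exact; otherwise 1,000 random
relabelings are drawn. Tests whose resolution 1/C(n, n1) exceeds 0.02 are
not analyzable, as are location × event cells failing the trial/spike
minima. The statistic is unsigned (two-sided); the sign is reported
separately.

**Conjunctive model.** Peri-landing rates are regressed on human identity,
landing location and their interaction with sum-to-zero contrasts. Term
p-values come from nested model comparisons in type-II order (each main
effect against the two-main-effects model, the interaction against the
additive model); empty human × location cells drop their unestimable
interaction coefficients with a message. The class rules follow the
standard reading: a significant interaction makes a unit conjunctive; both
main effects without interaction, additive; exactly one main effect,
human-only / location-only; nothing, none. A unit with *only* a significant
interaction is classed conjunctive by default — interaction presence
governs — with the stricter reading (requiring at least one main effect)
behind `interactionAlone = "none"`.

**Remapping.** The rate-remapping score is |r1 − r2| / (r1 + r2) on two
conditions' mean rates (undefined at 0/0). Global remapping is diagnosed
with map correlations over common valid bins and peak/centroid distances;
ties at the peak break to the smallest bin index. Three nulls serve three
questions: non-paired-unit map pairs (one random partner per unit, never
itself) calibrate correlation and distance under field relocation;
trial-label shuffles calibrate the score under no rate change; random
half-splits calibrate the first-half/second-half stability correlation.

## Behavioral segmentation

Bat positions are smoothed by Savitzky–Golay filtering (order 2, 1-s
window) — exactly a local quadratic regression, so quadratic paths are
reproduced to machine precision. Speed is the norm of the central
difference of smoothed positions. Flights are runs above 0.5 m/s, merged
across gaps shorter than 0.3 s (tracking noise can split one flight), and
extended at both ends to the nearest sample where every axis speed is below
0.05 m/s. This automated trim replaces a manual endpoint-inspection step:
reproducibility requires an algorithmic rule, and the threshold is
configurable (`trimVThresh`). Landing/take-off locations are the nearest
tripod within 2 m; the human at a location comes from the block schedule.

The coat-pocket tag defines human position (the method text uses it for
velocity; which tag defines position for the human-frame maps is not
stated — the coat tag is the least limb-motion-contaminated choice, and the
wrist tags are carried along for sensitivity analyses). Coat series are
median-filtered (2 s). Because the running median tracks individual noisy
samples, adjacent-sample differences are noise-dominated, so the coat speed
uses a ±0.1 s central difference; this widens threshold crossings by well
under the 0.2 s segmentation tolerance. Traverses start when coat speed
exceeds 0.4 m/s within 0.1 m (xy) of the traverse start, end at the first
time > 12 s later below 0.4 m/s within 0.3 m of it, and are discarded if
speed dips below 0.2 m/s mid-traverse outside the excluded feed/handling
spans (event intervals buffered by 100 samples = 1 s, applied in time
units so irregular sampling is safe). Rest is speed < 0.4 m/s within
200 cm of the preferred resting centroid (k-means on sub-threshold
positions, k = 2 by default: bats rest almost exclusively in two upper
corners). Conspecific presence at a landing requires the other bat within
200 cm of the tripod at sub-threshold speed; a tracking gap there returns
"unknown" and the trial is excluded downstream.

## The synthetic-session generator

`generateBehavior()` emulates the study's structure at desk scale: a
5.6 × 5.2 × 2.5 m room; two humans on a tripod pair who swap every 5-min
block; a recorded bat resting in one upper corner that flies
quadratic-Bezier paths (minimum-jerk speed profile, 3 m/s peak) to the
occupied tripods, 8 trials per block; an optional conspecific that
accompanies every 4th trial; and two traverses per human per block — arced
walks (0.5 m/s, opposite bow per human) with a 5-s feeding pause at the
apex, lasting ~13.5 s so they clear the 12-s rule with margin. Two
traverses per block (12 per session) were chosen because six is the
*inclusion minimum* of the human-frame analyses, and a generator that sits
exactly on an inclusion boundary makes analyzability a coin flip. Path
jitter (sigma = 0.05 m on the Bezier control point) makes repeated flights
stereotyped but not identical; white positional noise (1 cm) stands in for
tracking error.

`generateSpikes()` draws an inhomogeneous Poisson train by thinning at the
peak rate. The rate is baseline plus Gaussian place-field terms evaluated
in the self, conspecific and human frames, times an identity gain applied
inside the landing analysis window (−0.25 to +1.75 s) of flights to a
configured human × tripod, and a presence gain on accompanied trials.
Applying the gain over the analysis window (rather than the final 2 s of
flight) keeps the injected effect and the measured window aligned;
otherwise the two would overlap by only 0.25 s and ground-truth recovery
would be testing the overlap, not the method. One global seed drives
everything; per-unit substreams are derived by counter, so adding a unit
never changes earlier units' draws.

**What the generator does not emulate** — and hence what green tests do
not show about real data: spike-sorting errors, bursting/theta structure,
wing-beat modulation, nonstationary behavior (fatigue, satiation),
RTLS-scale (10–20 cm) tracking error and dropouts, and experimenter
idiosyncrasies beyond path geometry. Passing recovery tests demonstrates
that the estimators are correct and calibrated under the assumed
generative structure, not that the biological claims hold.

## Numerical choices and degenerate inputs

* Fraction formatting: one decimal by default, integer rendering available
  for reports that use integers.
* Bin grids anchor at the room origin; arc-length bins at the take-off.
* Zero-length flights are excluded from linearization with a message; a
  zero-length downsampled path returns seven copies of its single point.
* The exact permutation null includes the identity assignment, so exact
  p ≥ 1/C(n, n1); Monte-Carlo p uses (1 + k)/(1 + n).
* Wilcoxon comparisons with fewer than 5 pairs report descriptives only;
  all-zero paired differences give p = 1.
* Reward metrics define baseline as the session-wide rate excluding all
  peri-landing windows ("baseline" is otherwise undefined); a zero
  baseline makes the ratios not analyzable.
* The 2D self-motion shuffle timeline is the concatenated flight epochs
  (occupancy is flight-restricted, so removing rests and removing
  non-flight crawling coincide here).
* Trajectory clustering defaults to single linkage cut at 1.3 m (midpoint
  of the 1.2–1.4 m working range); the criterion and cut are configurable
  because cluster counts are sensitive to both and no objective selection
  rule exists.

## Problem sizes

The test suite runs on sessions of 2–6 five-minute blocks (32–96 flight
legs, 8–24 traverses), 1,000-unit null calibrations at 1,000 shuffles
each, 500–1,000-unit permutation type-I checks, and 200-unit coding
populations per class; the acceptance script uses the generator's default
6-block session. These sizes put every shuffle distribution and recovery
check within a few minutes on one CPU while keeping all inclusion minima
satisfied with margin.

## Known limitations

* The automated flight-endpoint trim is a proxy for manual inspection;
  endpoint placement can differ near slow, meandering take-offs.
* Human-frame maps rest on ~10 bins of arc in a default session; their SI
  values are coarse and the shuffle null is correspondingly wide.
* The conjunctive classifier inherits the per-term alpha = 0.05 budget:
  with two irrelevant terms, a single-main-effect unit is misclassified
  with probability ≈ 1 − (1 − alpha)² ≈ 10% even with perfect calibration.
* Exact permutation enumeration is capped at 1e5 assignments; beyond that
  the Monte-Carlo p carries sampling error of order 0.005.
* `contextPair2D` compares the top two human configurations only; sessions
  with three or more well-sampled contexts are summarized pairwise.
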