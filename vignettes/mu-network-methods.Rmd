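---
title: "Methods: synchronization-likelihood networks of the developing mu rhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronization-likelihood networks of the developing mu rhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices
behind `munet`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what validation on synthetic cohorts
does and does not demonstrate about real recordings.

## The analysis problem

The mu rhythm is the idling oscillation of the sensorimotor cortex. Its
peak frequency rises through development (from below 5 Hz in young
infants to ~10 Hz in adults), and it desynchronizes during action.
`munet` analyses multichannel sensor-space recordings positioned over
one sensorimotor cortex and asks how the *functional network* spanned
by the sensors — who synchronizes with whom inside the individual mu
band — is organized, and how that organization differs between groups
(ages) and conditions (rest versus prehension).

Working in sensor space has two consequences that shape the pipeline.
First, volume-conduction-like effects can make neighbouring sensors
look connected for trivial reasons; the distance-bias QC below exists
to screen exactly that. Second, absolute anatomical localization is
unavailable, so all conclusions are about global network properties,
not specific cortical areas.

## Pre-processing

Recordings are band-pass filtered at 0.5–40 Hz with a third-order
forward–reverse Butterworth filter (zero phase; the effective magnitude
response is the squared one-pass response). The same design is reused
for the individual mu band, IMPF ± 2 Hz. Two numerical choices:

- **Low-cutoff clamp.** For very young infants the nominal band can dip
  below the wideband floor (IMPF 2.0 → 0.0 Hz); the low edge is clamped
  at 0.5 Hz so the mu band never extends below the wideband pass.
- **Edge transients.** IIR forward–reverse filtering rings at the
  record edges. Channels are filtered after odd-reflection padding of
  about two low-frequency periods, and epochs are always cut from the
  filtered *continuous* record, never filtered per epoch, so no
  analysis window sits on a filter transient.

When an external ICA decomposition is available, `reproject_ics()`
reconstructs sensor signals from a mixing matrix and a retained
component list. Component selection itself is visual/expert work and is
deliberately out of scope: the pipeline consumes its result.

Epochs are 4 s. Prehension epochs span [onset − 1 s, onset + 3 s), the
leading second capturing anticipatory activity. Rest epochs tile the
recording in non-overlapping 4-s windows whose every sample is at least
5 s from any onset; the 5 s margin operationalizes "far from movement"
and is configurable (`rest_margin_s`).

## Synchronization likelihood

SL is a recurrence-based measure of generalized synchronization.
Parameters follow a band-adapted scheme (the method literature gives
heuristics, not universal constants):

| parameter | default rule | meaning |
|---|---|---|
| lag *l* | round(fs / (3·high)) | ~⅓ period of the fastest band component |
| dimension *m* | ceil(3·high/low) + 1 | covers the slowest cycle |
| Theiler window *w₁* | 2·l·(m−1) | excludes autocorrelated neighbours |
| outer window *w₂* | w₁ + round(90/p_ref), capped | bounds the candidate set |
| *p*<sub>ref</sub> | 0.01 | target recurrence fraction |

For a 10 Hz adult band (8–12 Hz) at 500 Hz this gives l = 14, m = 6,
w₁ = 140 on 2000-sample epochs. The per-time critical distance ε(i) is
the empirical *p*<sub>ref</sub>-quantile of distances to embedded
vectors j with w₁ < |i − j| < w₂ (ties at the boundary included), so
the realised recurrence fraction matches *p*<sub>ref</sub> up to
1/N_w(i). A constant channel yields ε = 0 with a warning rather than an
error.

**Normalization.** The pairwise statistic is the time-averaged
simultaneous-recurrence count H_i normalised by the *realised*
per-channel recurrence counts, SL_i = H_i · p_ref · N_w(i) /
(n_k(i)·n_q(i)), clipped to [0, 1]. The naive normalisation by the
nominal p_ref·N_w(i) inherits the integer rounding of the recurrence
quantile (the realised fraction is round(p_ref·N_w)/N_w, a few percent
off at typical window sizes, and the bias squares under independence).
Normalising by realised counts makes the independence limit exactly
p_ref in expectation while leaving the identity limit at 1 within
1/(p_ref·N_w) — both limits are asserted in the test suite. The kernel
is compiled (Rcpp): recurrence sets are built once per channel and
intersected per pair, which keeps a 76-channel epoch tractable and a
12-channel epoch at ~0.5 s.

## Network construction and QC

Average SL matrices (one per condition) are thresholded at Median +
1·MAD of the upper-triangle value distribution — a robust rule that
presumes nothing about the (non-Gaussian) SL distribution. Numerical
choices: the distribution excludes the structural zero diagonal and
uses each symmetric value once; MAD is raw (no normal-consistency
constant); retention is strictly greater-than; an all-equal
distribution (MAD = 0) or an empty survivor set is an error, not a
silent empty network.

Distance-bias r² correlates the thresholded matrix (zeros included)
with the inter-sensor Euclidean distances. Zeros are included because
the bias of concern — proximity inflating short-distance SL — manifests
precisely in which pairs survive thresholding; a survivors-only r²
would be blind to it. Subjects pass QC when both conditions give
r² < 0.1 and, for the degree condition, when rest and prehension retain
exactly the same edge count. Exact equality is demanded (no tolerance):
it is the strict reading of the comparability requirement, and the
pipeline exposes `require_equal_degree = FALSE` for designs where that
condition would discard most of a small cohort — for continuous SL
values, exact equality of two independent edge counts is a rare event,
which is also why real infant cohorts lose many subjects to it.

## Graph measures

All measures operate on the retained weighted network; edge lengths for
path-based measures are reciprocal weights, d = 1/W (strong
synchronization = short functional distance). Disconnected pairs are
excluded from the characteristic path length L (their fraction is
reported alongside) and contribute zero to global efficiency. Nodes
with fewer than two edges contribute zero to clustering and local
efficiency rather than being dropped, keeping n fixed across
conditions. Local efficiency restricts paths between the neighbours of
node i to the subgraph induced by those neighbours (i removed), and is
the mean nodal value — the convention under which a complete
unit-weight graph scores exactly 1.

**Raw versus normalized weights.** By default all four measures are
computed on the raw retained SL weights. This is a deliberate design
choice: SL values are already bounded in [0, 1], and the scale of
synchronization is part of the signal — a cohort whose networks carry
uniformly stronger weights genuinely is more efficient, which is
exactly what max-normalization would erase (after dividing by the
maximum, C and E_loc become scale-free and group contrasts reduce to
topology alone). The magnitudes this produces (efficiencies of the
order of the mean SL; L of the order of several reciprocal SL values)
are the meaningful scale for these networks. `normalize = TRUE` (and
`normalize_weights()`) provide the scale-invariant variant, whose exact
invariance under global rescaling is asserted in the tests.

All four measures are validated against exhaustive brute-force oracles
(triangle enumeration, Floyd–Warshall, neighbourhood path enumeration)
on 200 random weighted graphs to 1e-9.

## Group statistics

Each measure is analysed with a mixed ANOVA: group between subjects,
condition within subjects (every subject contributes both conditions,
so condition is treated as a repeated factor — the natural reading of a
groups × conditions design on paired data). Partial η² uses each
effect's own error stratum. Post-hoc comparisons are pooled-SD t tests
on condition-averaged subject means over all group pairs, with p values
multiplied by the number of comparisons and capped at 1. The ANOVA is
checked against a textbook sums-of-squares decomposition and its type-I
rate is calibrated on null cohorts (rejection rate within [0.02, 0.09]
at α = 0.05 over 200 replicates). Observed power is not computed: no
defined estimator accompanies the quantity, and guessing one would
manufacture unverifiable numbers.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline needs to
see, not MEG physics:

- **Layout.** Sensors on a spherical cap (radius 75 mm) via a Fibonacci
  lattice whose cap area is calibrated so the realised median
  nearest-neighbour pitch equals the requested spacing (default 13 mm,
  76 channels). The layout is deterministic; the `seed` argument is
  interface plumbing.
- **Signals.** Channels are jointly Gaussian narrowband processes:
  correlated white-noise drivers (correlation = the requested pairwise
  coupling, i.e. the shared-signal fraction under the
  x = √(1−c)·private + √c·shared mixing model) are band-pass filtered
  at IMPF ± 1 Hz, scaled to unit variance, and summed with independent
  broadband noise (sd 1 by default). Linear filtering preserves the
  coupling structure exactly.
- **Events.** Movement onsets are evenly spaced with ±0.3 s jitter,
  kept clear of the record edges; mu amplitude is multiplied by the
  suppression factor (default 0.5) during the 3 s after each onset —
  the 1 s anticipatory segment stays unsuppressed.
- **Reproducibility.** One RNG stream per subject, keyed by the global
  seed and subject index (kept below 2³¹), so cohorts are bit-identical
  across runs and subjects are independent.

What the generator does *not* emulate: forward-model field spread,
1/f background spectra, artifacts (motion, chewing, bad channels),
nonstationarity beyond event-locked suppression, or ICA mixing.
Passing tests therefore demonstrate that the estimators and the
pipeline logic are correct and well calibrated on signals with known
ground truth — not that any particular real-data finding would
replicate. In particular the distance-bias QC is exercised with
synthetic proximity-driven matrices, since the generator itself has no
volume conduction.

## Validation problem sizes

The planted two-group contrast (modular coupling 0.7/0.3 in two
six-channel blocks versus uniform 0.08) uses 12 channels, 72-s
recordings, four prehension events and up to three epochs per
condition, with six subjects per group — sizes chosen so that the full stack from
raw signal to group ANOVA is exercised end to end while an entire
ten-cohort validation sweep stays within minutes on a single core. The
degree-equality QC is disabled in this contrast (see above); the
distance-bias QC stays on. The statistical stage is calibrated at the
metrics level (cohort tables drawn directly from the subject-effect
model), where 200 null replicates are cheap and the question — the
type-I rate of the ANOVA — does not involve the signal path at all.

## Known limitations

- SL embedding parameters follow one band-adapted heuristic; other
  parameterizations of the same estimator exist and will shift absolute
  SL values (comparisons within a parameterization are unaffected).
- The MAD threshold adapts per subject; extremely uniform SL
  distributions (MAD = 0) are rejected rather than thresholded.
- The mixed ANOVA assumes the usual normality/sphericity conditions;
  with two conditions sphericity is trivial, but heavy-tailed measures
  would call for nonparametric alternatives, which are out of scope.
- Hemispheric sensor coverage means integration measures describe the
  covered patch, not whole-brain integration.
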