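---
title: "A self-avoidance model of epithelial branching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-avoidance model of epithelial branching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfavoid)
```

## The biological problem

Ureteric bud trees in kidney rudiments cultured flat grow essentially in two
dimensions, yet their branches spread out and almost never touch — even when
two rudiments are deliberately aimed at one another, the trees distort
rather than collide. A second, quantitative signature of the same system is
that the first bifurcation of a bud is markedly wider (divergence angles
around 130–150°) than later bifurcations (around 80–100°), and experiments
with isolated tips show this is controlled by the *presence of neighbouring
tips*, not by an intrinsic branching programme.

Both observations are economically explained by **self-avoidance**: every
part of the tree secretes a diffusible repellent, and growing tips steer
away from, slow in, and decline to branch in high concentrations of it.
`selfavoid` implements this hypothesis as a deliberately minimal lattice
model, together with the morphometrics needed to measure its output the way
cultured organs are measured.

## Model rules and their assumptions

The tissue is a `domain_width × domain_height` grid of cells (default
200 × 200). A tubule tree is a set of 8-connected occupied cells with
distinct *tip* and *stalk* identities; stalks are left behind by advancing
tips the way a snail leaves a slime trail.

**Field.** Each occupied cell contributes `s·exp(−d/λ)` to the repellent
concentration at Euclidean distance `d` (in cells); tips contribute with a
larger strength `s_tip`. The total at any point is the sum over all
occupied cells, plus one zero-mean Gaussian noise draw (sd `noise_sd`) per
evaluation, clamped at zero. The exponential kernel is the steady state of
diffusion with first-order loss — appropriate because protein diffusion in
these cultures is fast compared with tree growth, so the field can be
recomputed from current anatomy at every step with no memory of history.
No explicit PDE time-stepping is performed, and the field has no sources
outside the domain and no periodic wrap.

**Sensing.** A tip senses the field at its own position *excluding its own
cell* (otherwise every tip would carry an identical constant offset); its
own trail, its sibling, and every other tree all contribute. Candidate
directions are evaluated at probe points at Euclidean radius 1 from the tip
centre. Sampling at the neighbour cell centres instead would make the four
diagonal candidates sit at radius √2 — farther from every source behind the
tip — which systematically locks trajectories onto 45° lattice diagonals.
Unit-radius probes keep direction choice isotropic; this is a lattice
implementation detail, not extra biology.

**Advance.** Each step a tip moves with probability `1/(1 + C/K)`, where
`C` is its sensed concentration and `K` (`speed_half_saturation`) sets the
concentration at which speed halves: growth slows in crowded regions, even
to a stop. When it moves, it moves to the free 8-neighbour whose direction
has the lowest (noisy) field; exact ties break uniformly at random. A tip
with no free neighbour is permanently enclosed — occupancy never clears —
so it retires from the active list but remains a tip-identity cell.

**Branching.** A tip bifurcates only when its sensed concentration falls
below `branch_threshold` and it has travelled at least `refractory_length`
cells since the last bifurcation. The daughters instantly become sources
themselves. We place the two daughters on a diametrically opposite pair of
free neighbour cells, choosing the opposite pair with the lowest summed
field (and falling back to the lowest-field mutually non-adjacent pair when
crowding leaves no opposite pair free). This "lateral tip-splitting"
placement encodes only that a bifurcation creates two *distinct* directions;
it is identical for every generation, so any generation-dependence of the
*realized* divergence angle — measured after the daughters have elongated —
emerges from the surrounding field, not from the rule. The threshold gate
itself is a modelling convenience for creating branch points at intervals;
we make no claim that real buds time their branching by the inhibitor
concentration.

**Update order.** Tips act in a freshly shuffled random order each step
(bifurcation check, then advance), which avoids systematic first-mover
bias. Daughters created during a step first act on the following step.
Runs are bit-reproducible for a given seed because every random draw —
shuffle, noise, move acceptance, tie-breaks — comes from the single seeded
RNG stream in a fixed call order.

## The reference parameter set

```{r}
unclass(model_params())[1:8]
```

The defaults were calibrated once, as a set, so that the single-bud
scenario reproduces the emergent behaviours described above, and then
frozen; they are conventions of this implementation, not measured
quantities. The reasoning:

* `decay_length = 16` cells. The repellent must act at the scale of the
  spacing between neighbouring branches (one to two branch segments), so
  that the crowd of surrounding tips — not just the immediate sibling —
  shapes later bifurcations. Short decay lengths (≤ 4 cells) leave each
  tip feeling only its own trail, and all generations then branch at
  similar angles.
* `tip_source_strength = 20 × source_strength`. Tips are the strongest
  secretion sites of the relevant repellent in the developing kidney, and
  the isolated-tip experiments show divergence angles are controlled by
  the presence of other *tips*. Implementing that asymmetry is what
  separates the wide first branch (whose daughters feel only each other
  and a short trunk) from the narrower later branches (whose daughters are
  hemmed in by several surrounding tips). With uniform source strengths no
  parameter combination we examined separated the two by more than ~20°.
* `branch_threshold = 20.5`. The own-trail concentration at a straight
  tip asymptotes to ~15.5 under the defaults, so the gate sits 5 units
  above it: a lone tip can always branch once refractory, while a
  neighbouring tip within roughly `λ·ln(s_tip/5) ≈ 22` cells suppresses
  branching — branch spacing is therefore field-limited, as in the
  biological intuition, rather than set by the refractory length.
* `noise_sd = 0.05` adds sensory jitter without drowning the shallow
  field differences between candidate directions.
* `speed_half_saturation = 16.5` makes an unimpeded tip advance roughly
  every other step; approaching tips slow smoothly and stop without
  touching.
* `refractory_length = 10` cells guards against degenerate instant
  re-branching and keeps branch segments long enough for the angle lever
  arm (below); it is settable to 0.
* Starting trunks (default 15 cells) are treated as mature: their tip may
  branch immediately.

Under this set, 20-seed batches of `single_bud` (250 steps, ~1 s per run)
give a mean generation-1 divergence angle of ~140° and a pooled
generation-≥2 mean of ~101–105°, with the first branch wider by ≥ 30° in
over 90% of runs; `head_on_pair` runs produce no inter-tree contact in 20
of 20 seeds, while setting `source_strength = 0` (an in-silico secretion
block) produces contacts in essentially every run. These are the batch
sizes used throughout the test suite and the acceptance script.

## Morphometrics conventions

* **Divergence angle.** Skeleton lines are already explicit on the
  lattice, so the electronic equivalent of protractor measurement is: from
  a branch point, walk each daughter to the skeleton point at arc length
  `L` (default 10 cells, the `arc_length_L` parameter) — or to its end, if
  it is shorter or bifurcates first — and take the angle between the two
  chord vectors. The lever arm matters: angles are defined only "after the
  branches have elongated", and 10 cells is one branch segment under the
  reference parameters. Branch generation is counted in bifurcations from
  the root; the first bifurcation's daughters are generation 1.
* **Collisions.** Cultures are scored categorically — collision or no
  collision — with a contact defined as Chebyshev distance
  ≤ `contact_chebyshev` (default 1, i.e. no free cell between the trees:
  the lattice analogue of "no gap discernible by light microscopy").
  Within one tree, contacts whose through-tree path exceeds
  `loop_min_path` (default 10 cells of arc) are reported as self-loops;
  shorter paths are ordinary parent/daughter adjacency. Raising the
  contact threshold can only add events. The engine additionally records
  inter-tree contacts the moment a cell is deposited, so runs that only
  ask *whether* trees touched can stop early (`stop_on_contact`).
* **Kinematics.** Tip speed is frame-to-frame displacement over elapsed
  time for frame pairs sampled every `stride` frames (default 5). For a
  pair of tips, the separation is computed per frame (Pythagoras) and the
  raw velocity is `(d[n+1] − d[n])/Δt`, negative on approach; the reported
  *closing speed* is its negation, so approach is positive. Both columns
  are emitted, and the sign convention is stated in the output headers.

## Synthetic fixtures: what they do and do not show

`gen_pair_tracks()` generates head-on tip pairs whose per-frame closing
speed follows `max(0, c·ln(d/d₀))` plus Gaussian frame noise — a log-linear
approach law with a complete stop at separation `d₀` (default 30 length
units, matching the observed stopping separation of approaching tips).
The deterministic law is floored at zero and the noise is added afterwards
unfloored, so below `d₀` recorded speeds jitter around zero with mean
zero; this is what lets a t test "detect the stop regime" without bias.
The log-linear form is a *test scaffold* chosen to match the shape of the
observed speed–log-separation relation; it is not a claim about mechanism.
Because the generator stores its truth, the analysis chain
(`closing_speed_table()` → `linreg_r_p()`) can be validated end to end:
over 20 seeds the regression recovers `c` with a median relative error
under 15%.

`gen_toy_tree()` rasterises straight branches at prescribed divergence
angles. Recovery is exact up to rasterisation error: a cell centre can be
half a cell off the ideal line, so a chord of length `L = 10` can be off by
up to ~4°; the tests allow 2–4° accordingly.

What passing these tests shows is that the *measurement chain* is correct.
They do not show that real time-lapse data follow the generating law, and
the simulated trees lack everything a real organ has beyond one repellent:
no mesenchymal cap, no chemoattractant signalling, no tubule remodelling
or retraction, no third dimension.

## Statistical conventions

For categorically scored cultures (k "yes" of n), the 95% confidence
half-width is `1.96·√(p(1−p)/n) + 1/(2n)` with `p = k/n` — a Wald interval
with a continuity term that keeps it non-degenerate at p = 0 or 1
(`0/10 → ±5%`). Half-widths at or above 10% are conventionally printed to
the whole percent, smaller ones to one decimal. Hypothesis tests on
proportions use the pooled two-sample z statistic without continuity
correction; tests on summary means use the pooled-variance Student t
(Welch available behind a flag). Both default to one-tailed — the
convention under which the package's worked examples match their expected
values — and record the convention in their return value. Regression
follows the spreadsheet-LINEST convention: least squares, Pearson R, and a
two-tailed p from `t = R·√((n−2)/(1−R²))` on `n−2` degrees of freedom,
which also recovers a p-value from a reported (R, n) pair alone.

Two caveats a user should know. First, p-values recomputed from *rounded*
summary statistics generally differ in the last digit or two from p-values
computed on the underlying raw data; recovering a published p exactly from
published summaries is not always possible, and the test suite documents
one such case. Second, the z test's finite-sample size is only
approximate: under a simulated null (equal proportions, n = 20 per arm)
its two-tailed rejection rate at α = 0.05 is ~0.043.

## Numerical and degenerate-input choices

* Concentrations are clamped at zero after noise; distances are Euclidean
  in cell units throughout, with micron conversion only via the optional
  `cells_per_micron` scale.
* Exact ties in candidate fields (possible only with `noise_sd = 0`) break
  uniformly at random from the seeded stream.
* A branch point must have exactly two daughters for an angle to be
  defined; anything else is an error, not a silent skip.
* Empty track tables, header-only CSV files and bare trunks (no branch
  points) round-trip and measure as empty results, not errors; non-monotone
  track times and mismatched frame grids are errors.
* Tree JSON is the lossless format (byte-identical round trips); the SWC
  dialect (z = 0, radius = 1, type codes 1/3/4 for root/stalk/tip) carries
  topology and coordinates only, with generations recomputed from topology
  on read and birth steps reset to 0.

## Known limitations

The model is a two-dimensional abstraction with a single signalling
system; it is qualitative by design. Branch segments are one cell wide, so
tubule calibre, tip flattening and anastomosis mechanics are out of scope.
The divergence-angle statistics of cultured organs (means near 133°/100°)
come from biological material and are *not* targets of the simulation; the
simulation's own calibrated behaviour (~140°/~103° under the reference
set) reproduces the qualitative contrast and its emergence, not those
specific numbers. Absolute simulated angles drift by a few degrees if the
lever arm `L`, the refractory length or the domain size are changed, which
is why those are explicit, documented parameters rather than constants.
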