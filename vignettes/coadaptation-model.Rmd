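---
title: "Modeling topographic axon guidance with growth-cone co-adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling topographic axon guidance with growth-cone co-adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coadapt)
```

## The problem

In the retinotectal projection, retinal ganglion cell axons build a
neighborhood-preserving map: temporal retina projects to anterior tectum,
nasal retina to posterior tectum. The guidance information is carried by
*quantitative* countergradients of EphA receptors and ephrin-A ligands on
both the retina and the target, signaling repulsively in the forward
(EphA on the axon reads ephrin-A cue) and reverse (ephrin-A on the axon
reads EphA cue) direction. At the same time, growth cones demonstrably
*adapt* to these very cues — they desensitize on a cue field and
re-sensitize after growing some distance on a cue-free substrate. Naively,
adaptation should erase the quantitative information that positions each
axon. This package implements a stochastic agent-based model in which a
specific mode of adaptation — *co-adaptation*, the concomitant
multiplicative modulation of both sensor species by a common coefficient,
opposed by a Hookian resetting force — reconciles the two observations,
and reproduces in silico the mapping, gap-assay, double-cue, tectal-entry
and knock-in/regeneration experiments. A second, independent component
quantifies gap-assay micrographs by per-row fiber counting and validates
itself against a synthetic image generator with known ground truth.

## The model

Fiber terminals are discs (diameter about 7 field units) carrying the two
sensors as Gaussian-shaped surface densities, moving on a rectangular
field of unit squares whose cues `L_T` (ephrin-A) and `R_T` (EphA) vary
along x. Each iteration evaluates, per terminal, a guidance potential

$$D = \left|\,\ln\frac{\sum_x L_F(x)\,[R_T(x) + R_F(x) + C(i)\,R_f(x)]}
{\sum_x R_F(x)\,[L_T(x) + L_F(x) + C(i)\,L_f(x)]}\,\right|$$

summed over the footprint squares: total reverse over total forward
signaling, including fiber–target, cis (own-surface) and fiber–fiber
terms, the latter weighted by a ramp `C(i)`. `D = 0` exactly where total
reverse balances total forward — the terminal's correct target position,
which is determined by its sensor ratio `R_F/L_F` and therefore by its
retinal origin.

Movement is a biased random walk: the four unit displacements are drawn
with probability proportional to `base_prob * exp(-beta * D(candidate))`,
with moves off the field rejected. On cue-free ground an inherent forward
bias `q_x = 0.37` avoids prolonged dwelling.

Adaptation closes the loop. The recent history of `D` (window `h = 10`,
linearly weighted toward the present) sets a common coefficient
`a = 1 + ln(1 + mu * weighted mean)`, and both sensors update as
`S <- a*S + lambda*(S0 - S)`. Because the *same* `a` multiplies both
channels and the resetting force pulls each back proportionally, the
ratio `R_F/L_F` — the topographic identity — is exactly invariant, while
the common deflection `g = S/S0` rises under sustained signaling
(desensitization) and relaxes on cue-free ground (re-sensitization). The
comparison variant, canonical adaptation, relaxes each channel
independently toward the local cue of its own species and destroys the
ratio, and with it the map.

Global constants follow the published set: `n = 200` terminals,
`i = 30000` iterations, `mu = 0.006`, `lambda = 0.0045`, `h = 10`;
in-vitro style scenarios switch the fiber–fiber ramp off (`C = 1`) and
use `n = 12`, `i = 2000` on a 200 x 8 field with cue level 4.

## Footprint semantics

The model equation leaves open whether sensor amounts enter per square as
*totals spread over the footprint* or as *surface densities*. The two
differ by the footprint area (~38 squares): with totals, the cis terms
are ~38-fold diluted against the printed cue level `L_T = 4`, no adapted
terminal can ever cross a simulated gap, and the reduced potential for a
single axon on homogeneous ephrin would not collapse to
`D = |ln(1/(L_T/L_F + 1))|` with `L_F` on the same scale as `L_T`. We
therefore use density semantics: the disc carries a truncated Gaussian
density profile with peak `S` (`sigma = radius/2`, weights normalised to
maximum 1), and edge clipping drops squares without renormalisation — a
disc hanging over the field edge presents less total sensor but unchanged
local density. On a single-square footprint the reduced form is then
exact, which the test suite asserts to 1e-12.

## Calibrated stand-ins

Four constants of the underlying movement/gradient machinery are not
printed anywhere and were calibrated once, jointly, against the
qualitative outcomes the model must reproduce; they are ordinary
parameters of `model_params()` and scenario builders.

* `beta = 8` (move-rule sharpness). Crossing a potential barrier `D`
  within a time budget behaves like `exp(-beta * D)`; `beta` must be
  large enough that naive terminals stop at cue boundaries for the whole
  assay (`beta * D_naive` ~ 10+) yet small enough that adapted terminals
  (deflection 30) cross small gaps within `i = 2000`. Values 8–12 work;
  we use 8, the value most permissive for tectal entry.
* `retinal_gamma = 3` (gradient steepness, retina and tectum). Steepness
  must accommodate the printed knock-in strengths: at `gamma = 2` the
  sensor-ratio range is only ~7-fold, both `R_ki = 2` and `R_ki = 4`
  saturate beyond the most temporal fiber, and the heterozygous and
  homozygous knock-ins become indistinguishable. `gamma = 3` (ratio range
  ~e^6) preserves the dose ordering while keeping barriers crossable.
* `C0 = 40` with a linear ramp (`j = 10000`, `ramp_len = 5000`). The
  fiber–fiber weight ceiling is set so that competition can overwrite the
  target cues, which the half-retina expansion experiment requires
  (coverage saturates at ~80% of the field for `C0 <= 20`).
* `kappa = 0.05` (canonical-adaptation rate). Sensor matching must act on
  the dwelling timescale (tens of iterations); at slower rates the
  canonical population first forms a correct map and is merely frozen by
  adaptation afterwards, which would make the comparison vacuous.

## Scenario-specific choices

* **Gap assays** use mid-retinal terminals (`origin_u = 0.5`), whose two
  sensor baselines are equal, so ephrin-A and EphA fields repel naive
  terminals identically and double-cue assays are exactly comparable to
  single-cue ones. Adapted populations start on the first field with both
  sensors deflected 30-fold — the same adapted deflection used for tectal
  entry — standing in for axons that grew on the cue for hours before the
  recorded window. The forward walk bias applies across the whole arena
  (`q_x_scope = "everywhere"`): axons on a printed substrate have an
  inherent growth drive. Stopping is scored from the running maximum of
  x: a terminal stops if it never exceeded the far boundary plus a
  2-unit penetration allowance.
* **Tectal entry** places terminals directly in front of the target. Two
  mechanisms the source account itself invokes are modeled explicitly:
  the target gradients carry a 10-unit anterior margin, so the entry edge
  presents cue levels above every fiber's balance point (no axon's target
  is the pole itself, and the entrance is a genuine reverse-signaling
  barrier for all naive fibers); and a pre-adapting factor in the optic
  tract holds sensor levels constant while a terminal stands on cue-free
  ground (`hold_off_target`), so the arriving population keeps its
  deflection until it is inside, where the resetting force and
  re-adaptation take over. Without the hold, the 30-fold deflection
  decays with time constant `1/lambda` ~ 220 iterations — faster than the
  population can negotiate the boundary region. Fiber–fiber interactions
  are excluded here (`C = 0`); experiments show they are required neither
  for entry nor for mapping, and a mixed-ratio crowd pressed against the
  entrance otherwise jams it.
* **Knock-in** adds `R_ki` to every second fiber's receptor baseline and
  reduces its ligand reciprocally, `L_F0 / (1 + R_ki/R_F0)`.
* **Remnant scenarios** (no-expansion, polarity reversal) add immobile,
  non-adapting resident terminals that contribute cue fields only; the
  reversal variant starts the fiber–fiber ramp early (`j = 2000`).

## Numerical and procedural details

Terminals are processed in fixed order within an iteration and see the
already-updated state of earlier terminals (Gauss–Seidel style); together
with a single seeded RNG stream this makes runs bit-identical under
identical `(seed, params, scenario)`, which the suite checks at the file
level. Histories are zero-padded (terminals begin unadapted). Sensors are
floored at 1e-9. Candidate potentials of `+Inf` (a vanished signaling
channel) get zero move weight; if every candidate is inadmissible the
terminal stays. The guidance potential exists twice by design — a plain R
reference (`guidance_potential()`) and the compiled simulation path — and
both are checked against an independent brute-force evaluation of the
signaling sums on random instances.

## The synthetic world, and what a green test establishes

The synthetic image generator renders parallel, lightly meandering fiber
traces with a known fraction terminating just before the gap's far edge
(where stalling growth cones accumulate in the real assay), then blurs
and adds Gaussian noise. It emulates the geometry the per-row counting
algorithm relies on — fibers roughly parallel to the growth axis, ROIs
perpendicular to it — but not fasciculation, crossing fibers, debris or
uneven illumination; a passing round-trip (recovered stop fraction within
0.1 of truth) validates the counting pipeline, not its robustness to
those artifacts. Likewise, the simulation reproduces the *qualitative*
experimental pattern (stopping returning with gap width, cross-cue
ignorance, entry requiring pre-adaptation); the printed wet-lab
percentages are measurements of a different physical system and are not
targets.

## Known limitations

One mapping axis only (no dorsoventral/mediolateral dimension); no
molecular model of the endosomal cis-signaling mechanism; the move rule,
gradient constants and fiber–fiber ramp are calibrated stand-ins for a
prior model's unpublished constants; stopping/entry thresholds
(2-unit penetration, corridor geometry) are operational definitions of
outcomes the source reports only graphically.
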