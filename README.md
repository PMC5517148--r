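# coadapt

Agent-based simulation of retinotopic map formation with growth-cone
**co-adaptation**, plus the gap-assay image quantification that goes with
it.

## The science

The retinotectal projection maps the temporal–nasal axis of the retina
onto the anterior–posterior axis of the optic tectum. Guidance is
quantitative: countergradients of EphA receptors (R) and ephrin-A ligands
(L) on both retina and target signal repulsively in the forward (axonal
EphA reads target ephrin-A) and reverse (axonal ephrin-A reads target
EphA) directions, and the *ratio* R_F/L_F carried by a growth cone
encodes where on the target its signals balance. Yet growth cones also
*adapt* to exactly these cues — a paradox, since adaptation should erase
the quantitative information.

The model resolves it with co-adaptation. Each fiber terminal minimizes a
guidance potential

    D = | ln( Σ_x L_F(x) [R_T(x) + R_F(x) + C(i) R_f(x)]
            / Σ_x R_F(x) [L_T(x) + L_F(x) + C(i) L_f(x)] ) |

(total reverse over total forward signaling over its footprint squares x,
including fiber–target, cis and ramped fiber–fiber terms) via a biased
random walk, with step probabilities ∝ `exp(-beta * D(candidate))`. The
recent history of D drives a **common** adaptation coefficient

    a(i) = 1 + ln(1 + mu * Σ k D_k / Σ k),      k = 1..h

applied multiplicatively to **both** sensors together with a Hookian
resetting force:

    S(i+1) = a(i) S(i) + lambda (S(0) - S(i))

Because both channels share `a`, the ratio R_F/L_F — and with it
topographic identity — is exactly invariant while overall sensitivity
falls and recovers. The canonical alternative (each channel independently
matching its local cue) destroys the map. Defaults follow the published
global set: n = 200 terminals, i = 30000 iterations, mu = 0.006,
lambda = 0.0045, h = 10; gap assays use n = 12, i = 2000, cue level 4 and
a switched-off fiber ramp (C = 1).

Scenario builders cover mapping (`mapping_scenario()`), single- and
double-cue gap assays (`gap_assay_scenario()`), tectal entry with a
30-fold pre-adaptation deflection (`tectal_entry_scenario()`), EphA3
knock-in (`knockin_scenario()`), and expansion / compression / mismatch /
remnant / polarity-reversal experiments (`innervation_scenario()`).
`quantify_stopping()` implements the micrograph quantification
(threshold, two ~20 µm ROIs flanking the gap's far edge, per-row peak
counts, percent stopping from the mean counts) and
`generate_gap_image()` renders synthetic fiber images with known ground
truth to validate it.

## Worked example

```r
library(coadapt)

sc  <- mapping_scenario(n = 50, seed = 1)
res <- simulate(sc, params = list(n_iterations = 5000L, seed = 1))
res
#> <coadapt_sim 'mapping_coadaptation'>  n = 50 terminals, i = 5000 iterations, mode = coadaptation
#>   final x in [0.86, 49.28]; max ratio deviation 4.71e-15
mapping_summary(res)
#> mapping: rho = 0.995, diagonal fraction = 0.98 (tol 0.10), span = 0.97
```

Fifty co-adapting terminals sort into an almost perfect topographic map
(Spearman rho 0.995 between retinal origin and target position; 98% of
terminals within 10% of the ideal diagonal), and the largest relative
deviation of any terminal's R_F/L_F ratio over the whole run is 5e-15 —
co-adaptation modulated sensitivity without touching identity. The same
run with canonical adaptation collapses:

```r
res2 <- simulate(mapping_scenario(n = 50, adaptation_mode = "canonical",
                                  seed = 1),
                 params = list(n_iterations = 5000L, seed = 1))
mapping_summary(res2)
#> mapping: rho = 0.191, diagonal fraction = 0.20 (tol 0.10), span = 0.97
```

And the image pipeline recovers a known stopping fraction from a
synthetic gap-assay micrograph:

```r
g <- generate_gap_image(40, stop_fraction = 0.8, roi_spec(150),
                        width = 240, height = 160, seed = 1)
quantify_stopping(g$image, roi_spec(150))$stopping_percent
#> 77.9   # truth: 80
```

A command-line front end ships in `inst/cli/coadapt`
(`simulate`, `quantify-gap`, `reproduce`, `list-scenarios`), with one
JSON preset per simulated figure panel under
`inst/extdata/scenarios/`.

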