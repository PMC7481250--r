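---
title: "Models and methods behind vigorlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vigorlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigorlab)
```

`vigorlab` quantifies early vigor in a two-cultivar hydroponic rice
experiment. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the design
was genuinely open.

## Photosynthesis models

### FvCB A–C_i fitting

Net assimilation under the Farquhar–von Caemmerer–Berry model is the
minimum of a Rubisco-limited and a RuBP-regeneration-limited rate:

$$A_c = V_{cmax}\frac{C_i - \Gamma^*}{C_i + K_c(1 + O/K_o)} - R_d,
\qquad
A_j = J\frac{C_i - \Gamma^*}{4C_i + 8\Gamma^*} - R_d,
\qquad A = \min(A_c, A_j).$$

Choices and their rationale:

* **Kinetic constants.** Defaults are the standard in-vivo tobacco
  calibration at 25 °C: $K_c = 404.9$ µmol mol⁻¹, $K_o = 278.4$ mmol mol⁻¹,
  $\Gamma^* = 42.75$ µmol mol⁻¹, $O = 210$ mmol mol⁻¹
  (`kinetic_constants()`, all configurable). No temperature correction is
  applied: the measurement protocol holds block temperature at a single
  value (26 °C), so a temperature-response scheme would add parameters
  without data to constrain them.
* **$J = J_{max}$.** The A–C_i protocol fixes light at 1800 µmol photons
  m⁻² s⁻¹, which we treat as saturating for electron transport, so the
  fitted $J$ is reported as $J_{max}$.
* **No TPU limitation.** The protocol's maximum CO₂ is 1800 µmol mol⁻¹ and
  triose-phosphate limitation is typically only diagnosable from a
  high-CO₂ plateau with declining assimilation; including a third state
  would be unidentifiable here.
* **C_i as given.** Intercellular CO₂ is instrument-computed; no stomatal
  model is applied.

**Fitting algorithm.** Both limitation rates increase monotonically with
$C_i$ and the Rubisco rate binds at low $C_i$, so any consistent assignment
of points to limitation states is a contiguous split of the $C_i$-sorted
points. `fit_aci()` enumerates all $n + 1$ such segmentations. The key
observation is that under a *fixed* assignment the model is **linear** in
$(V_{cmax}, J_{max}, R_d)$, so each candidate is solved exactly by QR least
squares — no iterative optimiser, no starting values, no convergence
failures. A candidate is *admissible* when the parameters are positive
($R_d \ge 0$) and, at every point, the assigned state's modelled rate does
not exceed the other state's by more than 0.5 µmol m⁻² s⁻¹ (the tolerance
absorbs round-off near the transition point). Among admissible candidates
the minimal-SSE fit wins; exact ties (within $10^{-12}$ relative) are broken
toward fewer RuBP-limited points. Degenerate single-state curves are
handled naturally: the unused parameter is returned as `NA` and its
limitation is treated as unconstraining.

### Non-rectangular hyperbola A–Q fitting

$$A(Q) = \frac{\phi Q + A_{max} -
\sqrt{(\phi Q + A_{max})^2 - 4\theta\phi Q A_{max}}}{2\theta} - R_d$$

with apparent quantum yield $\phi \in (0, 0.125]$ (the theoretical maximum
of 1/8 CO₂ per photon), convexity $\theta \in (0, 1]$, and the
rectangular-hyperbola limit $\phi Q A_{max}/(\phi Q + A_{max}) - R_d$ used
below $\theta = 10^{-6}$, where the quadratic branch loses precision (the
function is continuous there; `fit_aq()` can land on either branch).

`fit_aq()` minimises SSE by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a 3×3 multistart grid ($\phi \in \{0.03, 0.05,
0.08\}$, $\theta \in \{0.3, 0.7, 0.95\}$) with data-driven starts
$R_{d,0} = \max(0, -A(Q_{min}))$ and $A_{max,0} = \max(A) + R_{d,0}$; the
multistart guards against the well-known $\theta$–$\phi$ trade-off ridge.
The fit requires at least one point below $Q = 100$ so that $\phi$ is
constrained by the near-linear region.

**Asat is the plateau.** The light-saturated rate is reported as the fitted
asymptote $A_{max} - R_d$ rather than the model value at the highest
measured light (2000 µmol photons m⁻² s⁻¹). "Light-saturated" denotes the
plateau of the response; at $\theta$ near 1 the model value at 2000 differs
from the asymptote by a few percent, and the plateau definition is the one
that is invariant to the measurement grid. This was an open design choice;
the alternative (model value at 2000) is a one-line change.

## Mass balances

**Uptake rates.** Per-plant daily rates come from a nutrient-depletion
balance over exactly one day (the sampling protocol is same-time
next-day, so no interval rescaling is applied):
$$v(\mathrm{ion}) = \frac{V_1 c_1 - V_2 c_2 - (V_1' c_1' - V_2' c_2')}{N_p},$$
where primes denote the plant-free blank pots that absorb abiotic losses
(volatilisation, denitrification, evaporation), and the transpiration rate
uses the same structure on volumes alone. Total nitrogen uptake is the
molar sum of the two ions; each carries one N atom, so the molar-ion and
N-atom conventions coincide. **Negative rates are returned, not clipped**,
and flagged `suspect`: with measurement noise the blank correction can
legitimately overshoot, and clipping would bias group means upward.

**Root areas.** The sequential methylene-blue assay uses three beakers:
dye lost from beakers 1–2 saturates the whole surface (total area), dye
lost from beaker 3 can only be absorbed by actively absorbing surface
(active area):
$$\mathrm{total} = [(C_1^0 - C_1^1)V_1 + (C_2^0 - C_2^1)V_2] \times 1.1,
\qquad
\mathrm{active} = (C_3^0 - C_3^1)V_3 \times 1.1.$$
The units of the 1.1 constant (classically 1.1 m² per mg of adsorbed dye)
are not fully determinate from the formulas alone, so the equations are
implemented literally with concentrations in g L⁻¹ and volumes in L and the
outputs treated as internally consistent relative areas; every downstream
result is a ratio or a normalisation, where the scale cancels.

**Leaf nitrogen.** For a 10-cm leaf segment of width $w_L$ cm, dry mass
$m_L$ g and nitrogen mass fraction $c_N$,
$\mathrm{LNC} = c_N m_L/(10 w_L) \times 10^4$ g m⁻². Dimensional analysis
requires $c_N$ as a mass fraction even though elemental analysers report
percent; `percent = TRUE` divides by 100. The identity
$\mathrm{LNC} = \mathrm{SLW} \times c_N$ ties LNC to specific leaf weight
and is asserted in the tests.

## Statistics

Cultivar contrasts are **percent differences of group means** (ratio of
means, not mean of ratios) — which is why contrasts of derived quantities
need not be mutually consistent (e.g. the Vcmax and LNC contrasts do not
multiply into the Vcmax/LNC contrast). Tests are two-sided
pooled-variance Student's t-tests (`stats::t.test(var.equal = TRUE)`;
Welch available via `welch = TRUE`) with stars at 0.05/0.01 and no
multiple-testing correction, since contrasts are reported per panel.
Seed-cut regressions pool both cultivars in one OLS fit, matching the
design's interest in the overall seed-reserve effect irrespective of
genotype.

## The synthetic-data generator

`simulate_experiment()` is the package's test bed: it generates every
measured table from known truth values *via the forward models of the
analysis stages* (curves by FvCB/NRH evaluation on the protocol grids —
13 PPFD levels, 6 + 7 CO₂ setpoints; beaker assays and pot samples by
inverting the area and mass-balance equations; leaf segments by inverting
the LNC relation), so that with zero noise every stage recovers truth to
floating-point accuracy, and the configured cultivar ratios are recovered
as percent differences exactly.

* **Contrasts are anchored; baselines are not.** The default 9311/HHZ
  ratios encode the study's reported percent differences (e.g. Vcmax 1.53,
  LNC 1.26, 50-DAG NO₃⁻ uptake 2.99, 10-DAG active area 3.44, 2 mM biomass
  2.52). HHZ absolute baselines (Vcmax 80 µmol m⁻² s⁻¹, Jmax 130, Asat 27,
  LNC 1.2 g m⁻², pot uptake and area baselines, dry weights) are documented
  arbitrary constants chosen to be physiologically plausible for rice
  seedlings and feasible for the inversions (pot nutrients cannot deplete
  below zero; beaker dye drops cannot exceed the 0.064 g L⁻¹ initial
  concentration). At timepoints where no percent is reported, interior
  ratios consistent with the qualitative time course are used (e.g. the
  NH₄⁺ ratio crosses 1 at 25 DAG).
* **Design sizes** follow the study: n = 5 replicates per cultivar per
  timepoint (n = 9 in the nitrogen-gradient arm), timepoints 10/25/40/50
  DAG, nitrogen levels 0.1/0.5/1/2 mM, 68 seed-cut pairs at 10 DAG and 42
  at 30 DAG, qPCR with 3 replicates and 6 validated genes against an actin
  control, and a DEG table with exactly 15 nitrogen-keyword significant
  genes of which 10 are up in 9311 (plus decoys on both sides of each
  filter gate).
* **Noise model.** Multiplicative Gaussian, CV-parameterised per table,
  truncated at zero — appropriate for positive-valued physiological
  measurements. All CVs default to 0: the generator's primary job is exact
  round-trip validation, and the within-cultivar variances were a free
  choice (no variance figures are available to anchor them).
* **Seed-cut calibration.** Pairs follow
  $y = \beta x + \alpha + \varepsilon$ with seed fresh weights uniform on
  5–25 mg. The residual SD is derived from the target pooled R² (0.86 at
  10 DAG, 0.78 at 30 DAG) via
  $\sigma = \beta\,\mathrm{sd}(x)\sqrt{1/R^2 - 1}$, so the generated
  cohorts reproduce the target R² in expectation.
* **RNG discipline.** Each output table draws from an independent substream
  derived from the master seed, so adding or reordering tables never
  perturbs the others, and identical configurations produce byte-identical
  tables.
* **What it does not emulate**: instrument drift and autocorrelated
  gas-exchange noise, stomatal/mesophyll conductance (C_i is generated as
  the driver directly), pot-to-pot variation in blank losses,
  within-cohort genotype differences in the seed-cut arm, RNA-seq reads
  (the DEG table is generated at the gene/padj/GO level). Passing tests
  therefore demonstrate correctness of the *computations*, not robustness
  to every failure mode of real field data.

## Problem sizes and runtime choices

The packaged validation runs fit 50 random parameter sets per fitter on the
13-point protocol grids, check the segmentation fitter against a 20³
brute-force grid oracle on 20 five-point curves, and average the seed-cut
R² over 200 cohorts of 68 pairs; the full pipeline on the default
experiment (10 leaves, 40 pot pairs + 4 blank pairs, 40 assays, 112 plant
records) completes in about a second. These sizes give stable estimates
while keeping the complete suite fast enough to run on every change.

## Known limitations

* The A–Ci fitter assumes a single limitation transition (no TPU state) and
  equal weight per point; an error-weighted cost would change fits on noisy
  curves.
* The admissibility tolerance (0.5 µmol m⁻² s⁻¹) is a pragmatic constant;
  very noisy curves near the transition can still select a neighbouring
  breakpoint (harmless for the parameters, which vary smoothly there).
* Blank correction assumes the abiotic loss in planted pots equals the
  blank pots' loss in absolute amount, the same assumption the experimental
  design itself makes.
* `2^{-\Delta\Delta C_T}` uses the group-mean calibrator ΔCt (the common
  convention); per-replicate pairing is not implemented.
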