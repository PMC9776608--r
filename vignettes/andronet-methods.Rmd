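---
title: "Methods: the AR/NF-κB network model and the enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AR/NF-kB network model and the enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(andronet)
```

## The dynamic network model

`andronet` models the crosstalk between six regulators of prostate cancer
cell state — the androgen receptor (AR), the kinase PI3K, its antagonist
phosphatase PTEN, the inflammatory transcription factor p65 (NF-κB), its
inhibitor IκB, and the oncogene c-Myc — as an almost-linear ODE system:

$$\frac{dx_i}{dt} = J_i - d_i x_i + \sum_{j=1}^{6} A_{ij} x_j + \sigma_i,
\qquad x_i \ge 0.$$

Each activity $x_i$ is in arbitrary units; $J_i$ (activity·time⁻¹) is a
constitutive base production, $d_i$ (time⁻¹) a first-order decay, and
$A_{ij}$ (time⁻¹) the per-unit effect of node $j$ on node $i$'s rate of
change. The only nonlinearity is the positivity boundary condition: an
activity that would turn negative is clamped at zero until its net
production becomes positive again. This keeps the model analytically
transparent — away from the boundary it is a linear system whose fixed point
and spectrum are exact — while respecting that protein activities cannot be
negative.

The built-in parameterisation (`ar_nfkb_model()`) uses
`J = (1.5, 2, −0.1, 2, −0.1, 0.8)`, a common decay rate of 1 for all six
nodes (proteins assumed degraded at approximately the same rate; this also
sets the time unit), and an interaction matrix encoding the biology with
hand-chosen magnitudes: PI3K inhibits AR while p65 and c-Myc induce it; PTEN
inhibits PI3K and is itself induced by PI3K (a negative feedback on the
kinase axis); AR represses p65; PI3K and c-Myc push p65 while IκB strongly
inhibits it; p65 strongly induces IκB, closing the canonical NF-κB negative
feedback loop; and PI3K and p65 drive c-Myc. The matrix convention is
row = target, column = source; the two small negative `J` entries (PTEN,
IκB) represent a constitutive drain that makes these nodes depend entirely
on their upstream inducers.

Two remarks on conventions that were genuinely open:

* **Matrix orientation.** The row/target–column/source reading is the one
  under which every signed link above matches its stated biology (e.g.
  `A["p65","IkB"] = −3` and `A["IkB","p65"] = +3`). The transpose reading
  would invert the feedback loop's roles and does not reproduce the
  directional treatment responses.
* **Decay vector length.** The common decay rate is applied to all six
  nodes, consistent with the equal-degradation assumption.

### Fixed point and stability

With noise off, the steady state solves $(\mathrm{diag}(d) - A)x^* = J$.
`fixed_point()` solves this directly and reports the spectrum of
$A - \mathrm{diag}(d)$: the system is *stable* when all real parts are
negative and *feasible* when $x^* > 0$ component-wise — feasibility matters
because it means the clamp is inactive at equilibrium, so the linear
analysis is exact there. For the default model both hold (the slowest modes
have real part ≈ −0.54, so transients decay on a timescale of ~2 time
units), and the long-run Euler solution matches the solve to ~1e−13.
Near-singular systems (reciprocal condition estimate below 1e−12) are
rejected with an explicit "no unique fixed point" error rather than
returning an unreliable solve.

### Rescaling

Activities are in arbitrary units, so the model family is closed under
per-node rescaling $y_i = \lambda_i x_i$. Substituting into the rate
equation gives the transformed parameters
$J'_i = \lambda_i J_i$, $A'_{ij} = \lambda_i A_{ij} \lambda_j^{-1}$ and
$d'_i = d_i$ — decay rates are in units of inverse time and are invariant,
as are diagonal interaction entries. `scale_model()` implements this
trajectory-preserving form, and the suite verifies
$y_i(t) = \lambda_i x_i(t)$ to 1e−8 along whole trajectories. (A plausible
alternative transform that also scales $d$ does not preserve trajectories
and is deliberately not implemented.)

### Integration

`simulate_network()` uses fixed-step explicit (Newton-forward) Euler with
`dt = 0.001` by default, the positivity clamp applied after every full
update. No adaptive or implicit scheme is offered: the dynamics are mildly
stiff at worst (|Re λ| ≤ ~1.5), first-order convergence is verified
empirically (halving `dt` halves the closed-form error), and the fixed grid
makes perturbation timing and noise reproducibility exact. Three numerical
choices worth stating:

* **Noise semantics.** The stochastic forcing $\sigma_i$ is redrawn
  independently per node per step from uniform(−a, +a), default amplitude
  a = 0.01 and off unless requested. The amplitude is not scaled by
  $\sqrt{dt}$; this is a bounded forcing term matching the model's
  definition, not an attempt at an SDE discretisation, so trajectories at
  different `dt` are not statistically identical under noise.
* **Event timing.** A switch scheduled at time $t$ is applied before the
  step leaving $t$; simultaneous events apply in schedule order. Every
  application is logged with old and new values.
* **Output stride.** States are stored every 100 steps by default (every
  0.1 time units at the default `dt`); stride 1 gives full resolution.

## The treatment scenario

`ablation_scenario()` runs the model from `x(0) = (1, 1.2, 1.4, 1.6, 1.8, 2)`
with three halving switches: `J_AR` 1.5 → 0.75 at t = 50 (androgen
ablation), `J_p65` 2 → 1 at t = 100 (NF-κB inhibition), `J_PI3K` 2 → 1 at
t = 150 (PI3K inhibition). The default horizon is 200, giving each regime a
full 50 time units; a horizon of exactly 150 would schedule the third
switch at the final instant and hide its consequences, so horizons ≤ 150
are rejected.

Regimes are compared by late-window means — the final 40% of each regime —
which excludes the post-switch transient (~2–5 time units here) with a wide
margin; the baseline is the mean over [40, 50), which equals the fixed
point to ~1e−11. `direction_check()` turns the comparison into named
verdicts using a relative tolerance, 1% by default: a change must exceed
1% of the reference level to count as "up" or "down". The tolerance is
matched to the default noise amplitude (0.01 on O(1) activities): with
noise off the verdicts are deterministic, and the suite additionally checks
they are unchanged under noise at the working amplitude for several seeds.
The "slightly below baseline" claim for c-Myc after NF-κB inhibition is
tested as a strict tolerance-gated inequality only; no magnitude is
asserted because the effect is genuinely small (~3% here).

## Enrichment statistics

The package implements the scoring pipeline downstream of a
differential-expression table (gene, log2FC, p):

* **Ranking.** Genes are ordered by `sign(log2FC) · (−log10 p)`. Ties are
  broken lexicographically by identifier (C locale) so ranked lists are
  fully deterministic. p-values of exactly 0 are rejected rather than
  clamped — a 0 would map to an infinite statistic and silently dominate
  any list.
* **DEG filter.** Strict inequalities exactly as conventionally printed:
  adjusted p < 0.05 and |log2FC| > 1 (one-sided variants for
  induced/repressed lists). BH adjustment is validated in-package and
  delegated to `stats::p.adjust`.
* **Pre-ranked GSEA.** The running sum gains
  $|s|^w / \sum_{members}|s|^w$ at member positions (weight $w = 1$ by
  default) and loses $1/(N-K)$ elsewhere; the enrichment score is the
  signed extremum. Only a *gene-permutation* null is offered — from a
  ranked list alone, phenotype permutation is not available — with
  $p = (1 + \#\{|ES_{perm}| \ge |ES_{obs}|,\ \text{same sign}\}) /
  (1 + \#\{\text{same sign}\})$ and NES normalising by the mean |ES| of
  sign-matched permutations. A structural tie between the positive and
  negative excursion (possible e.g. for a single mid-list member) resolves
  to the positive side, with a 1e−10 tolerance so the choice does not
  depend on floating-point accumulation order. Permutation scores are
  computed from member positions in O(K) per draw, verified against the
  full O(N) running sum.
* **ORA.** Exact upper-tail hypergeometric via `stats::phyper`, checked
  against Monte-Carlo draw frequencies in the suite.
* **Set activity.** Per-sample mean of the set genes' z-scores (sample sd;
  genes constant across samples contribute 0). This is an *emulation* of
  per-sample pathway-activity readouts — published violin plots of this
  kind rarely state their exact transformation — and is documented as such,
  not as a reproduction of any specific figure.
* **Rank-sum comparison.** Two-sided Wilcoxon rank-sum; for groups of ≤ 8
  the null is enumerated exactly over all group assignments of the
  midranks (which stays exact under ties, unlike the classical exact
  distribution), otherwise the normal approximation with tie and
  continuity correction is used.

## The synthetic generator

`synthetic_spec()` defines a two-group design (A = control, B = treated)
with independent Gaussian expression: gene $g$ in sample $s$ is
$N(\mu + \delta_g [s \in B],\ \sigma)$, where $\delta_g$ is the signed
shift of any planted set containing $g$. The defaults — 2000 genes, 10
samples per group, one planted 50-gene set shifted by 2, $\sigma = 1$,
$\mu = 7$ — emulate a modest log2-scale microarray experiment with a
clearly but not trivially enriched pathway: per-gene power at these
settings is high but not saturated (the DEG filter typically recovers
~70–80% of planted genes), which is the interesting regime for testing
rank-based recovery. The background mean of 7 is a typical log2 intensity
and cancels out of every downstream statistic.

What the generator deliberately does *not* emulate: probe structure and
collapsing, background correction and normalisation artefacts, heavy-tailed
or gene-dependent variances, and correlation between genes. Passing tests
therefore demonstrate that the statistics are correct and calibrated under
their own assumptions — uniform null p-values, super-uniform permutation
p-values, planted-signal recovery — not that they are robust to microarray
artefacts, which is out of scope.

Welch's unequal-variance t-test is used per gene rather than the pooled
test: under the generator the variances are equal and the two coincide
asymptotically, but Welch is the safer default for user-supplied matrices.
All generators take an explicit seed and restore the caller's RNG state.

## Problem sizes and determinism in the test suite

The suite exercises the integrator at the working resolution
(`dt = 0.001`, horizons 200–500) for the scenario and fixed-point checks,
and smaller grids (`dt` 0.005–0.01, horizons 10–30) for trajectory-level
properties such as scaling invariance, where the property holds at any
resolution. Exhaustive ES verification covers every list of length 3–12
against every member subset of size ≤ 4; permutation calibration uses 100–200
repetitions at 99–199 permutations; the end-to-end power check runs the
default planted design 50 times at 499 permutations against 20 decoy sets.
Every stochastic test fixes its seeds, so the suite is deterministic.

## Known limitations

* The six-node model is a caricature: linear interactions, hand-set
  magnitudes, no receptor-level pharmacology, no stroma/epithelium
  crosstalk. Its value is qualitative — signed responses to perturbations —
  not quantitative prediction.
* Perturbations act multiplicatively on base production only; modelling a
  drug as changing interaction strengths or decay rates is not supported.
* The GSEA null is gene permutation; sample-label permutation (which
  preserves inter-gene correlation) would require the expression matrix and
  is not implemented.
* The synthetic generator's independence assumption makes calibration tests
  sharper than real data would allow; correlated designs would widen null
  distributions for set-level statistics.
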