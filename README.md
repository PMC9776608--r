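# andronet

Androgen deprivation is the standard therapy for metastasizing prostate
cancer, yet nearly all tumors relapse in a castration-resistant form. One
proposed mechanism is that blocking the androgen receptor (AR) de-represses
NF-κB-driven inflammatory and survival signalling. `andronet` provides the
computational side of that hypothesis for systems biologists: a small
mechanistic model of the AR/NF-κB crosstalk that can be perturbed like a
patient is treated, together with the gene-set scoring statistics used to
read out such effects from two-group expression experiments.

## The model

Six nodes — AR, PI3K, PTEN, p65 (NF-κB), IκB and c-Myc — evolve by an
almost-linear ODE system

```
dx_i/dt = J_i − d_i x_i + Σ_j A_ij x_j + σ_i ,     x_i ≥ 0
```

where `J` is base production, `d` first-order decay, `A` the signed
interaction matrix (row = target, column = source; e.g. p65 induces IκB
while IκB inhibits p65, closing the pathway's negative feedback loop), and
`σ_i` a small uniform noise term. The system is linear except for the
positivity boundary condition, which clamps activities at zero. The
unperturbed model is stable and its fixed point
`x* = (diag(d) − A)⁻¹ J` is strictly positive.

Treatments are modelled as multiplicative switches of base-production terms:
halving `J_AR` at t = 50 (androgen ablation), `J_p65` at t = 100 (NF-κB
inhibition) and `J_PI3K` at t = 150 (PI3K inhibition).

The statistical half implements signed `−log10(p)` gene ranking, strict DEG
filtering (adjusted p < 0.05, |log2FC| > 1), pre-ranked gene set enrichment
(weighted running sum, gene-permutation null, sign-matched NES),
hypergeometric overrepresentation, per-sample gene-set activity z-scores and
a Wilcoxon rank-sum comparison, plus a seeded synthetic two-group expression
generator with planted gene sets so every stage has a recoverable ground
truth.

## Worked example

```r
library(andronet)

model <- ar_nfkb_model()
fixed_point(model)
#> <fixed_point>
#>       AR     PI3K     PTEN      p65      IkB     cMyc
#> 2.018068 0.357997 0.615995 0.158972 0.376916 1.137971
#> eigenvalue real parts: -1.4258 -1.4258 -0.5418 -0.5418 -1.0647 -1.0000
#> stable: TRUE   feasible (all x* > 0): TRUE

report <- ablation_scenario(t_end = 200)
direction_check(report)
#>                                       claim node         comparison pass
#> 1                 nfkb_up_after_ar_ablation  p65 regime1 > baseline TRUE
#> 2                 cmyc_up_after_ar_ablation cMyc regime1 > baseline TRUE
#> 3 cmyc_below_baseline_after_nfkb_inhibition cMyc regime2 < baseline TRUE
#> 4  cmyc_falls_further_after_pi3k_inhibition cMyc  regime3 < regime2 TRUE
#> 5  nfkb_falls_further_after_pi3k_inhibition  p65  regime3 < regime2 TRUE
```

Every component of the fixed point is positive (the clamp never engages at
equilibrium), all eigenvalues have negative real part (the state relaxes to
`x*` before the first treatment), and the directional table reads: androgen
ablation raises both NF-κB and c-Myc activity; subsequently inhibiting NF-κB
drops c-Myc slightly below its pre-ablation level; adding PI3K inhibition
lowers c-Myc and NF-κB further — the model's argument for combining
anti-androgen, anti-inflammatory and anti-PI3K treatment.

On the transcriptomic side:

```r
spec <- synthetic_spec()            # 2000 genes, 10/group, planted 50-gene set, shift 2
de   <- generate_de_table(spec)     # per-gene Welch t-test + BH adjustment
rl   <- build_ranked_list(de)       # signed -log10(p) ranking
gsea_permutation(rl, spec$planted_sets[[1]]$set, n_perm = 999, seed = 1)
#> <enrichment_result> planted_up: ES = 0.9944, NES = 2.7536, p_perm = 0.001264 (999 perms, overlap 50)
```

The planted set is recovered with the maximal possible significance at this
permutation depth.

The `analysis/` directory holds three narrative drivers —
`01_fixed_point.R`, `02_ablation_scenario.R`, `03_synthetic_enrichment.R` —
that run these stages end to end and write their tables under `results/`.

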