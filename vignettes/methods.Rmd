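---
title: "Models and methods in bayeswgr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bayeswgr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
pieces are designed the way they are. It states no empirical numbers beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The whole-genome regression models

All four fitted models share one linear model for `n` training animals and
`p` panel SNPs,

$$y_i = \sum_k X_{ik}\beta_k + \sum_j \tilde x_{ij}\alpha_j + e_i,
\qquad e_i \sim N(0, \sigma^2_e),$$

where `X` is the 0/1 incidence of hatch-within-generation classes
(class-means coding, flat priors) and $\tilde x_{ij} = x_{ij} - 2p_j$ are
dosages centered by twice the training allele frequency. The four models
differ only in the prior on the SNP effects:

| model   | $\pi$ (share of zero effects) | effect variance | df $(\nu_\alpha, \nu_e)$ |
|---------|------|----------------------------------|-----------|
| BayesB  | 0.99 | per locus, $\sigma^2_{\alpha j}$ | (4, 10)   |
| BayesC  | 0.99 | common $\sigma^2_\alpha$         | (4, 10)   |
| BayesC0 | 0    | common, estimated                | (4, 10)   |
| GBLUP   | 0    | common, df so high it is effectively known | (100, 100) |

The df-100 parameterization is the marker-effect formulation of GBLUP: with
the variance ratio fixed, its GEBVs are mathematically identical to an
animal-model solve with the genomic relationship matrix
$G = \tilde X\tilde X'/\sum_j 2p_jq_j$; the test suite verifies this
duality numerically, and also checks the fixed-variance chain against the
exact joint ridge solution.

Variances follow scaled-inverse-chi-square priors. The scales are derived
from target variances $\tilde\sigma^2_g, \tilde\sigma^2_e$ so the prior
means aggregate correctly:
$S^2_\alpha = \tilde\sigma^2_g\,\frac{\nu_\alpha-2}{\nu_\alpha}\big/
\big[(1-\pi)\sum_j 2p_jq_j\big]$ and
$S^2_e = \tilde\sigma^2_e\,(\nu_e-2)/\nu_e$. When the user supplies no
targets, each defaults to half the hatch-corrected phenotypic variance of
the training data — a deliberately weak, data-scaled choice that the df-4
models quickly overwhelm.

## The Gibbs sampler

One iteration updates, in order: every fixed-effect class from its normal
full conditional; every locus in index order; the common effect variance
(non-BayesB models); the residual variance. The locus update draws the
inclusion indicator with the effect integrated out: with
$r_j = \tilde x_j'(e + \tilde x_j\alpha_j^{old})$,

$$\Pr(\delta_j = 1) =
\frac{(1-\pi)\,m_1(r_j)}{(1-\pi)\,m_1(r_j) + \pi\,m_0(r_j)},$$

where $m_0, m_1$ are the densities of $r_j$ under the excluded
($N(0, x'x\,\sigma^2_e)$) and included
($N(0, x'x\,\sigma^2_e + (x'x)^2\sigma^2_{\alpha j})$) models; an included
effect is then drawn from its ridge conditional
$N(r_j/c_j, \sigma^2_e/c_j)$, $c_j = x'x + \sigma^2_e/\sigma^2_{\alpha j}$.
For BayesB the locus variance is drawn next from
scaled-inv-$\chi^2(\nu_\alpha+1, (\nu_\alpha S^2_\alpha +
\alpha_j^2)/(\nu_\alpha+1))$ when included — a function of the squared
effect sample, which is what leaves large effects nearly unshrunk — and
from the prior when excluded. This marginalized single-site scheme has the
same stationary distribution as joint $(\delta, \alpha)$ proposals and
mixes well at these scales; its correctness anchors are a quadrature oracle
for $\Pr(\delta=1)$ (to 1e-6 on a 5-animal fixture), closed-form moments of
the variance sampler, and the exact-ridge and duality checks above.

Implementation notes: the residual vector and the per-window genomic values
are maintained incrementally (one dot product and at most three axpy
operations per locus, in compiled code); the final state is returned so
tests can re-derive the residual from scratch (agreement to 1e-8 is an
invariant). R's RNG is used throughout, so a chain is bit-reproducible
under `set.seed()`/`mcmc_config(seed=)`. Initialization: class means for
the fixed effects, zero SNP effects, indicators at their prior mode,
variances at prior means. Degenerate loci ($x'x = 0$ after centering) are
forced out of the model. Defaults follow the reference analysis: chains of
35,000 with 5,000 burn-in for real use; the replicated studies in the
tests and the acceptance script use 5,000/1,000, which is where the
posterior summaries used here stabilize at desk scale.

## 1-Mb window reports

Every SNP belongs to the half-open physical bin `[k Mb, (k+1) Mb)` of its
chromosome, labeled `chrom_k`. Per stored sample the window's genetic
variance is the variance across training animals of its genomic value —
not the $\sum 2p_jq_j\alpha_j^2$ approximation, so LD within a window is
handled — and `%Var` is the posterior mean of the window's share of the
total. `p > 0` (the share of samples in which the window explains more
than 0 % of variance) is "at least one included SNP with nonzero effect"
for the mixture models; for the all-SNP models, whose effects are never
exactly zero, the event is `v_w > 1e-12 * total` as a floating-point
guard. On orthogonal windows the shares sum to one exactly; under LD they
need not.

## Validation design

Training is forward-in-time: all of generations 1–7, or one generation
alone. Accuracy is the Pearson correlation between predictions and
hatch-corrected phenotypes of a later generation, with the hatch-class
means computed within the validation generation (training-model hatch
estimates do not exist for unseen classes). The averages row is the
arithmetic mean over validation generations. Top-window-only predictions
use the evaluated fit's own top window, with effects still taken from the
all-SNP fit. The shrinkage-bias regression follows the single-marker
design: the most significant SNP of the top window (largest
$2p_jq_j\hat\alpha_j^2$) supplies predictions $\tilde x_j\hat\alpha_j$ for
generation 8, and the OLS slope of corrected phenotype on those
predictions is reported; 1 is the no-bias point, above 1 means the effect
was overshrunk. The same marker fitted as a fixed covariate in the
pedigree animal model gives the reference "unshrunk" estimate.

## The simulator

`simulate_population()` emulates the statistical structure of a closed
commercial layer line rather than any particular genome:

* **Genome and panel.** 3 chromosomes of 100 Mb / 1 Morgan (uniform map),
  1,000 evenly spaced markers each — about 10 markers per 1-Mb window and
  300 windows, enough for window-level localization at chain lengths of
  minutes. Meiosis is Haldane: Poisson crossover count with mean equal to
  the map length, uniform positions, no interference — standard and
  closed-form testable.
* **LD from a bottleneck.** Founders start in linkage equilibrium with
  allele frequencies uniform on (0.1, 0.5); a closed population of
  effective size 50 — the order of magnitude of intensely selected
  commercial lines — is then bred by random mating for 20 warm-up
  generations. Drift at that size builds strong local LD (adjacent-marker
  r² well above 0.5, decaying over a few Mb), which is what lets panel
  markers tag a causal variant that is itself absent from the chip. The
  generator records the maximum founder r² between the large QTL and a
  same-window marker and warns below 0.2.
* **Architecture.** 300 background QTL (masked from the panel, like the
  large QTL, unless `qtl_in_panel = TRUE`) with i.i.d. normal effects
  rescaled so the founder background variance is $(1-f_Q)\sigma^2_g$; the
  large-QTL effect solves $2p(1-p)a^2 = f_Q\sigma^2_g$ at the
  post-warm-up founder frequency. Its base frequency starts at 0.5 so the
  target fraction ($f_Q = 0.25$ by default) remains attainable after
  drift. Founder genetic variance is normalized to 1 trait unit².
* **Phenotypes.** $y = \text{hatch} + g + e$ with hatch-within-generation
  effects $N(0, 0.5^2)$ (four hatches per generation; the reference data
  report no hatch structure, so an even split is assumed) and residual
  variance $(1-h^2)/h^2$ for heritability $h^2 = 0.5$.
* **Generations.** Eight recorded generations with sizes following the
  reference design (295, 323, 294, 360, 290, 252, 300, 210 by default).
  Parents are drawn from the previous generation, at random or by
  truncation selection on phenotype within sex — the selection practiced
  in the real line is undocumented, so selection is a configuration
  choice, not an emulation claim, and the default is random mating.

What the simulator does **not** emulate: coalescent-accurate LD spectra,
variable marker density and allele-frequency ascertainment of a real chip,
genotyping error and missingness (quality control is exercised on
constructed fixtures instead), sex chromosomes, overlapping generations.
Passing the replicated studies therefore shows that the samplers and the
validation harness behave correctly under a realistic *statistical*
structure — strong local LD, one large masked QTL, polygenic background —
not that real-chip numbers are reproduced. Two consequences at desk scale
are worth knowing when reading results: with only 300 windows and strong
LD, the ridge models localize the QTL window more often than on a 24K-SNP
genome-wide panel (though they still attribute only a few percent of
variance to it), and single-generation training occasionally tops an
adjacent window.

## Pedigree BLUP

`ped_Ainverse()` computes inbreeding by the Meuwissen–Luo recursion and
assembles the sparse inverse numerator relationship matrix by Henderson's
rules with inbreeding; `make_A()` (tabular method) is kept as an
independent cross-check, with agreement to 1e-10 on inbred fixtures.
`solve_animal_model()` solves the sparse mixed-model equations directly and
verifies the solved system's relative residual to 1e-8; the optional SNP
covariate yields the fixed substitution-effect estimate used in the bias
diagnosis. `estimate_variance_components()` is EM-REML — derivative-free
and robust, convergence to relative change 1e-6 with an iteration cap
(200 by default; the estimate is returned with a flag if the cap binds).
Desk-scale pedigrees make the speed disadvantage of EM irrelevant. Unknown
parents are unrelated founders; no genetic groups.

## Design choices in the replicated studies

The tests run a 10-seed study (8 generations × 300 animals, 3,000
markers, masked QTL at 25 % of genetic variance, h² = 0.5) shared across
the detection, accuracy/persistence, bias and baseline checks; chains are
5,000/1,000. The variance-recovery check runs BayesC0 (df 4/10) on
populations of 2,000 with the causal loci *included* in the panel: total
genetic variance is only identifiable from markers up to the variance the
panel spans, so the recovery question is asked where the panel spans it
all; with masked causal loci the genomic variance estimates the
marker-captured share instead. The acceptance script runs the same design
at 3 replicate seeds with the reference generation sizes and reports
averaged headline quantities; pedigree BLUP there uses the true simulated
variance ratio (h² = 0.5) rather than re-estimating it each run, keeping
the baseline's accuracy independent of REML convergence at small n.

## Known limitations

* BayesA, Bayesian LASSO, single-step methods and multi-trait models are
  out of scope.
* π is fixed, not estimated.
* The sampler is single-threaded; replicate seeds parallelize trivially at
  the process level instead.
* EM-REML near a zero variance boundary converges slowly; the iteration
  cap plus convergence flag make this visible rather than silent.
* Window reports use physical 1-Mb bins only — no sliding or LD-aware
  windows.
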