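---
title: "Methods: the double-pedigree animal model and its simulator"
author: "dualped"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the double-pedigree animal model and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualped)
```

# The model

`dualped` fits the mixed model

$$
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{a} + \mathbf{c}
  + \mathbf{m} + \mathbf{k} + \mathbf{u} + \mathbf{e},
$$

$$
\mathbf{a} \sim N(0, \sigma^2_A \mathbf{A}), \quad
\mathbf{c} \sim N(0, \sigma^2_C \mathbf{C}), \quad
\mathbf{e} \sim N(0, \sigma^2_R \mathbf{I}),
$$

where $\mathbf{m}$ (maternal), $\mathbf{k}$ (common brood) and
$\mathbf{u}$ (shared rearing environment) are optional i.i.d. grouping
effects with variances $\sigma^2_M$, $\sigma^2_{CB}$, $\sigma^2_{ENVT}$.
The total phenotypic variance decomposes as
$\sigma^2_P = \sigma^2_A + \sigma^2_C + \sigma^2_M + \sigma^2_{CB} +
\sigma^2_{ENVT} + \sigma^2_R$, and `heritabilities()` reports each
component's share, including the narrow-sense heritability
$h^2 = \sigma^2_A/\sigma^2_P$ and its cultural analogue
$\sigma^2_C/\sigma^2_P$.

## The two relationship matrices

**Genetic.** `additiveMatrix()` builds $\mathbf{A}$ with
$A_{ij} = 2\Theta_{ij}$ (twice the coefficient of coancestry) by the
single-pass tabular method over a parent-first topological ordering.
Diagonals are $1 + F_i$, with the inbreeding coefficient
$F_i = \Theta_{\mathrm{sire}(i),\mathrm{dam}(i)}$. `kinshipCoefficient()`
implements the classical pairwise recursion independently; the test suite
checks the two against each other and against gene-dropping Monte Carlo.

**Cultural.** Three structures are available:

1. `culturalRelatednessMatrix()` (the default used throughout): the same
   tabular recursion, applied to *rearing* links instead of genetic ones.
   We chose the recursion over simpler alternatives because it gives the
   cultural component the same covariance algebra as the genetic one —
   cultural "relatedness" decays by halves across rearing links exactly
   as genetic relatedness does across parentage links — which is what
   makes the degenerate case (no fostering) collapse to
   $\mathbf{C} = \mathbf{A}$ *exactly*, entry for entry. Founders of the
   same culture are treated as culturally unrelated, mirroring the
   genetic convention that founders are unrelated and non-inbred.
2. `cultureIdentityMatrix()`: $C_{ij} = 1$ if $i$ and $j$ carry the same
   culture label, else 0 — a coarse block structure for when only group
   membership is known.
3. `contactMatrix()`: weighted social-contact records, symmetrized,
   max-normalized to unit scale, with unit diagonal — for populations
   where learning is diffuse rather than parental.

`pedigreeOverlap()` quantifies the collinearity of $\mathbf{A}$ and
$\mathbf{C}$ (off-diagonal correlation, Frobenius distance, fraction of
individuals cross-fostered); `gxcInteractionMatrix()` forms the
gene-by-culture interaction structure
$\mathbf{D}^{-1/2}(\mathbf{A}\circ\mathbf{C})\mathbf{D}^{-1/2}$, which
has unit diagonal and is positive semidefinite by the Schur product
theorem.

# REML estimation

`fitAnimalModel()` maximizes the restricted log-likelihood

$$
\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|\mathbf{V}|
 + \log|\mathbf{X}^\top\mathbf{V}^{-1}\mathbf{X}|
 + \mathbf{y}^\top\mathbf{P}\mathbf{y}\right],
$$

(`restrictedLoglik()` exposes this dense formula directly; it is tested
to $10^{-8}$ against a brute-force projection oracle). Internally the
fit works on REML contrasts $\mathbf{z} = \mathbf{Q}_2^\top\mathbf{y}$,
where $\mathbf{Q}_2$ is an orthonormal basis of the null space of
$\mathbf{X}^\top$, which removes the fixed effects once and for all.

Numerical choices, and why:

* **Profiled residual, log-ratio parameterization.** The residual
  variance is profiled out analytically, and the remaining components
  are optimized as $\theta_k = \log(\sigma^2_k/\sigma^2_R)$. This makes
  the search unconstrained, scale-free, and one dimension smaller;
  boundary estimates ($\sigma^2_k \to 0$) correspond to
  $\theta_k \to -\infty$ and are truncated to effectively zero.
* **Optimizer.** One variance component reduces, after an
  eigendecomposition, to a one-dimensional problem solved by
  `optimize()` on $\theta \in [-30, 30]$. Two or more components use
  Nelder–Mead with `reltol = 1e-8`, `maxit = 500`, and `nStarts`
  multi-starts (the origin plus seeded jitter); Nelder–Mead is
  derivative-free and robust to the flat ridges that arise when
  $\mathbf{A}$ and $\mathbf{C}$ are nearly collinear.
* **Collinearity guard.** When two random structures have
  $|\mathrm{cor}| > 0.999$ between their projected covariance matrices,
  the fit attaches a warning: the individual components then trade off
  along a ridge and only their sum is well determined.
* **PSD stabilization.** Cholesky factorizations retry once with a
  ridge of $\varepsilon = 10^{-8}$ on the diagonal, enough to absorb
  accumulated rounding in large relationship matrices without
  measurably changing any estimate.
* **Standard errors** come from the inverse observed information of the
  contrast likelihood (numerical Hessian); heritability SEs use the
  delta method. Near a boundary these are approximations and should be
  read as such.

## Hypothesis tests and model comparison

`lrtComponent()` drops exactly one variance component. Because the null
value $\sigma^2 = 0$ lies on the boundary of the parameter space, the
LRT statistic is asymptotically a 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$, so the corrected p-value is
$\tfrac12 P(\chi^2_1 > \mathrm{stat})$, with $p = 0.5$ at
$\mathrm{stat} = 0$. In replicated null simulations this test is
well calibrated but mildly anticonservative at moderate sizes — we
observed rejection rates at nominal 5% of about 0.07 with $n \approx 290$
and about 0.055 with $n \approx 580$ — a finite-sample property of the
boundary mixture, worth remembering when samples are small.
`compareModels()` ranks fits by AIC ($-2\ell_R + 2q$, $q$ counting
variance parameters including the residual) and refuses to compare fits
with different fixed effects or different data (REML likelihoods are not
comparable across fixed-effect structures; a hash of the model frame
enforces this).

# The cross-fostering simulator

`makeDesign()` lays out a factorial *cultures × environments × families*
design: monogamous founder pairs per cell, broods of fixed size,
optionally multiple generations (offspring pair within their natal cell,
avoiding full-sib matings, and each new brood is located at the dam's
*rearing* cell — behaviour follows upbringing). Constraints:
`broodSize >= 2` so every brood can both give and keep offspring, and
`swapFraction + controlSwapFraction <= 1`.

`applyCrossFostering()` performs reciprocal swaps between paired broods
of *different* cultures (`swapFraction` of each brood, rounded half away
from zero, always retaining at least one natal offspring when the
fraction is below 1) and, optionally, control swaps between broods of
the *same* culture (`controlSwapFraction`) to separate the effect of
being moved from the effect of acquiring another culture.
`simulatePhenotypes()` then draws phenotypes from the model above via a
joint Cholesky factor, with options for fixed environment effects,
maternal effects following either the rearing or the genetic dam
(rearing is the default: in a cross-fostering experiment the post-natal
maternal environment is provided by the foster dam), and a direct
manipulation effect on moved individuals.

What the simulator *does not* emulate: overlapping generations,
non-monogamous or repeated matings, selection or non-random mate choice,
brood-size mortality, horizontal/oblique learning within generations
(use `contactMatrix()` to model such structures on real data), or
measurement error beyond the residual term.

Reproducibility is hierarchical: one master seed plus counter-based
child seeds (a Lehmer-style mixing of scenario and replicate indices)
give every replicate an independent, reconstructible stream, so
`powerAnalysis()` results are invariant to the order or subset of
scenarios run (`scenarioIndices`), which also makes interrupted runs
resumable from the command line.

# Design evaluation

`powerAnalysis()` sweeps design specifications and reports, per
scenario, the mean, bias and RMSE of $\hat\sigma^2_A$ and
$\hat\sigma^2_C$, the rejection rate of the cultural LRT, the sampling
correlation of the two estimates, and the $\mathbf{A}$–$\mathbf{C}$
overlap. Two qualitative results recur and are enforced as properties in
the test suite:

* **Without manipulation the model is blind.** At `swapFraction = 0`,
  $\mathbf{C} = \mathbf{A}$ exactly; the two estimates trade off along a
  ridge (sampling correlation near $-1$) and their individual RMSEs are
  several-fold those of a 50% fostering design of the same size, even
  though their *sum* remains well estimated.
* **Ignoring culture inflates heritability.**
  `misattributionExperiment()` fits a genetic-only model to data whose
  inherited variance is purely cultural: without fostering essentially
  all cultural variance is absorbed into $\hat\sigma^2_A$;
  cross-fostering removes most of the artifact.

# Problem sizes and defaults

Default design parameters (2 cultures, 2 environments, broods of 4–8,
tens of families per cell) mirror what is practical in avian and rodent
cross-fostering studies, and keep a full double-pedigree REML fit at
$n = 1000$ under ten seconds on a laptop-class machine. `nStarts = 3` is
a compromise between robustness to ridge topology and runtime; for
replicated power studies `powerAnalysis()` defaults to one start per
fit, which we found sufficient away from the degenerate
`swapFraction = 0` case.
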