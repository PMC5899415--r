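---
title: "Blended single-step relationship matrices: model, verification, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blended single-step relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssblend)
```

## The model

Single-step genomic evaluation treats a population in two groups: Group 1,
individuals with pedigree information only, and Group 2, individuals that
are also genotyped. The pedigree numerator relationship matrix $A$ covers
everyone; the genomic relationship matrix $G$ (VanRaden form,
$G = (Z-P)(Z-P)^\top / \sum_j c\,p_j(1-p_j)$ with observed-frequency
centering) covers Group 2. The combined matrix replaces the within-Group-2
pedigree relationships by genomic ones and propagates that correction to
the rest of the matrix through the conditional structure of $A$.

In practice the combination is parameterized on the inverse with two
scalar weights,

$$H^{-1}_{\tau,\omega} = A^{-1} +
 \begin{pmatrix} 0 & 0 \\ 0 & \tau G^{-1} - \omega A_{22}^{-1} \end{pmatrix},$$

originally introduced to improve the convergence of iterative solvers and
to temper the inflation of genomic predictions. The package's central
object is the closed covariance-level form of the same matrix,

$$H_{\tau,\omega} = A +
 \begin{pmatrix}
 A_{12}B\,\Delta\,B A_{21} & A_{12}B\,\Delta \\
 \Delta\,B A_{21} & \Delta
 \end{pmatrix},
 \qquad
 H_{22} = \left(\tau G^{-1} + (1-\omega) A_{22}^{-1}\right)^{-1},$$

with $B = A_{22}^{-1}$ and $\Delta = H_{22} - A_{22}$. Three consequences
drive everything else in the package:

* **Reversed weights.** Inside $H_{22}$, $\tau$ multiplies $G^{-1}$ but
  $\omega$ enters as $1-\omega$ on $A_{22}^{-1}$. So $\omega$ is *not*
  simply "the weight of the pedigree part": with $A_{22} = I$ and
  $(\tau,\omega) = (1, 0.5)$ the off-diagonals of $H_{22}$ move away from
  the corresponding entries of $G$ (`h22_block()` reproduces the
  $14/15, 4/15$ example exactly).
* **Validity region.** For positive definite $A$ and $G$, $H_{\tau,\omega}$
  is positive semi-definite whenever $\tau \ge 0$ and $\omega \le 1$,
  excluding only the joint boundary $\tau = 0,\ \omega = 1$. Negative
  $\omega$ is a perfectly valid covariance model, which is why the default
  screening grid spans $\omega \in [-1, 1]$ rather than $[0, 1]$. For
  $\omega > 1$ the inner sum can become indefinite; the package permits
  such combinations but raises a dedicated `non_psd_combination` signal
  when the inner sum has an eigenvalue at or below tolerance.
* **Monotonicity.** At fixed $\omega$, increasing $\tau$ decreases
  $H_{22}$ (and hence $H$, and hence the BLUP smoother
  $K = (I + \lambda H^{-1})^{-1}$) in the Löwner order; at fixed $\tau$,
  increasing $\omega$ increases them. Combined with the empirical-variance
  ordering of smoothed predictions (valid when additionally
  $K_1 K_1 \succeq K_2 K_2$ and the means agree), this yields the
  practical tendency: **increasing $\tau$ or decreasing $\omega$ shrinks
  the EBV variance and raises the dispersion slope $b$, i.e. reduces
  inflation.** The premises are genuinely restrictive — the squared-kernel
  ordering often fails on real instances — so `variance_ordering()`
  reports the premise flags and the count of negative eigenvalues of
  $K_1K_1 - K_2K_2$ instead of asserting the conclusion unconditionally.

Special weights recover familiar models: $(1,1)$ the classical single-step
matrix with $H_{22} = G$; $(0,0)$ plain $A$ (pedigree BLUP);
$\tau = \omega = \lambda$ a weighted harmonic mean of $G$ and $A_{22}$;
$\omega = 1$ gives $H_{22} = G/\tau$, so growing $\tau$ empties the
genotyped blocks and drives $H_{11}$ to the Schur complement
$A_{11} - A_{12}A_{22}^{-1}A_{21}$ (`schur_limit_profile()` traces this
limit); $\tau = 1$ leaves the general form. `classify_blend()` labels all
of these.

## Evaluation model

Breeding values are predicted from the mixed model $y = \mu + g +
\varepsilon$ with $g \sim N(0, \sigma_g^2 H_{\tau,\omega})$ and i.i.d.
errors. With every individual phenotyped and no fixed effect the BLUP is
$\hat g = (I + \lambda H^{-1})^{-1} y$, $\lambda =
\sigma_\varepsilon^2/\sigma_g^2$; `solve_mme()` generalizes this to
partial phenotyping and an intercept via the standard mixed model
equations. Evaluation metrics follow validation practice: *predictive
ability* is the Pearson correlation between withheld phenotypes and EBVs,
and *inflation* is the slope $b$ of the regression of phenotypes on EBVs
($b<1$: inflated, $b>1$: deflated). The regression direction —
observations on predictions — is deliberate; the reverse regression is not
a calibration diagnostic.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `tau`, `omega` | — | dimensionless blending weights; screened on a grid |
| `beta` | 0.05 | weight of $A_{22}$ blended into $G$ before inversion. The centered VanRaden $G$ has $G\mathbf{1}=0$ and is structurally singular, so some adjustment is required whenever $G^{-1}$ is formed; a small pedigree blend is the dominant field practice. `beta = 0` is allowed and surfaces the singularity error. Recorded in every manifest. |
| `ridge` | 0 | optional diagonal added after blending, for marker sets so small that the blend alone is insufficient |
| `h2` | 0.5 | assumed narrow-sense heritability; converted to $\lambda = (1-h^2)/h^2$. Variance components are a user input here — REML estimation is out of scope — so $\lambda$ is logged with every result |
| `intercept` | on | a single mean fixed effect; the no-intercept path reduces exactly to the closed-form BLUP |
| `pcg_tol`, `pcg_maxit` | 1e-12, 10000 | conjugate gradient with Jacobi preconditioner; "iterations" in all reports means PCG iterations of this solver |
| PSD/symmetry tolerance | 1e-8 relative | shared by `is_psd()`, `invert_spd()` and the blend validity screens |

Grid values are generated on an exact decimal lattice (no floating-point
drift), inclusive at both ends; the default $\tau \in [0.1, 2]$,
$\omega \in [-1, 1]$ in steps of 0.1 gives 420 combinations. Ties at a
grid optimum are broken towards the classical weights — smallest
$(\tau-1)^2 + \omega^2$, then lexicographic — so reported optima are
conservative. Cross-validation masks *phenotypes only*: test individuals
stay in $H$, mirroring evaluation designs where genomic information of
all animals/lines is in the covariance model throughout. Per-combination
summaries are arithmetic means over folds; the per-fold table is retained
(`tidy()`) so any other pooling can be recomputed. Cells whose blend is
invalid are recorded as failed rather than aborting the sweep.

## What the simulator emulates — and what it does not

`simulate_population()` produces a pedigree-linked panel in the spirit of
a selfing-free line panel split by panel order into a non-genotyped first
half and a genotyped second half. Defaults: 30 unrelated founders, three
generations of 40 offspring (n = 150), 500 biallelic markers with founder
frequencies uniform on $[0.1, 0.9]$, Mendelian gene dropping, 50 causal
markers with i.i.d. normal effects, $h^2 = 0.5$, and DArT-like
presence/absence output derived from the diploid dosage. Phenotypes come
from explicit marker effects rather than from a draw
$g \sim N(0, \sigma^2 H)$: this gives a ground-truth $g$ that is
independent of any particular $H$, so recovery tests are honest rather
than self-confirming.

The generator deliberately omits linkage maps and recombination along
chromosomes (markers are unlinked), selection, assortative mating, and
genotype-by-environment structure. Real panels also carry genotyping
error, missingness (rejected at parse time here; imputation is a
pre-processing decision), and pedigree errors. Passing tests on this
generator therefore demonstrate the correctness of the matrix algebra,
the solvers and the evaluation bookkeeping under a known truth — not that
any particular (τ, ω) is optimal for a real population. On real data the
location of the predictive-ability optimum is data-set specific; the
structural results (equivalence of the two forms, PSD region,
monotonicity of $b$) are the transferable content.

## Numerical choices

* All inversions of symmetric positive definite matrices go through an
  eigenvalue screen (singular if $\lambda_{\min} \le 10^{-8}
  \lambda_{\max}$, with the error naming the offending role — a singular
  $G$ is distinguished from a singular $A_{22}$) followed by Cholesky.
* $H$ is always built from the covariance-level formula; the numeric
  inversion of the inverse-level form appears only in the equivalence
  cross-checks, where the two routes agree to ~1e-15 relative error on
  random instances (tolerance 1e-6).
* $A$ is built by the tabular recursion with inbreeding
  ($a_{ii} = 1 + \tfrac12 a_{s d}$), processing parents before offspring;
  out-of-order pedigrees are re-sorted with a warning, cycles are errors.
  The test oracle is an independent Wright path-counting implementation.
* $\tau = 0$ with $\omega < 1$ is well-defined ($H_{22} =
  A_{22}/(1-\omega)$) and allowed; $\tau = 0, \omega = 1$ is rejected.
  The closed forms for $\tau = 0$ and $\omega = 1$ are evaluated exactly
  rather than through the general inverse.
* Empirical variances in the variance-ordering diagnostics use the $1/n$
  definition, matching the theory they verify; everything else uses the
  usual sample conventions.
* Random sweep instances combine a pedigree-derived $A$ (realistic block
  structure) with a Wishart-style $G$ rescaled to mean diagonal 1; all
  sweeps are seeded.

## Problem sizes

The shipped verification runs use 200 random instances of up to 10
individuals per sweep, a default simulated population of n = 150 with 10
cross-validation folds, and 10 simulation seeds for the inflation-trend
check; these sizes give stable verdicts (violation counts are exactly
zero, trend agreement 9–10 of 10 seeds) while keeping a full test run in
well under a minute per suite. All of them are plain function arguments,
so larger studies are one call away.

## Known limitations

* Variance components are assumed known; a mis-specified $\lambda$ shifts
  both metrics (the package exploits this deliberately in its
  inflation-trend checks).
* Unknown-parent groups, metafounders, and the scaling/coding-consistency
  adjustments of $G$ versus $A_{22}$ are out of scope; unknown parents
  are simply unrelated founders.
* The blupf90-style triplet export is a file-format convenience; no
  claim is made about matching any specific external solver's iteration
  counts, which depend on that solver's preconditioning and convergence
  rules.
* Dense algebra throughout: fine into the low thousands of individuals,
  not intended for national-evaluation scale.
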